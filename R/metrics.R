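# Clustering validity metrics implemented from their defining formulas:
# three external (ARI, AMI, V-Measure; contingency-table / entropy based)
# and three internal (Davies-Bouldin, Calinski-Harabasz, Silhouette;
# feature-geometry based), plus K-Means with k-means++ seeding, Borda rank
# aggregation and Bonferroni-corrected paired comparisons.

comb2 <- function(x) x * (x - 1) / 2

check_label_pair <- function(true_labels, pred_labels) {
  if (length(true_labels) != length(pred_labels)) {
    stop("label vectors differ in length (", length(true_labels), " vs ",
         length(pred_labels), ")")
  }
  if (length(true_labels) < 2L) stop("need at least 2 points")
}

#' Rand index
#'
#' Fraction of point pairs on which two labelings agree (same cluster in
#' both, or different cluster in both): `agreements / (agreements +
#' disagreements)` over all `choose(n, 2)` pairs. Invariant to relabeling
#' either side.
#'
#' @param true_labels,pred_labels label vectors of equal length (>= 2).
#' @return scalar in `[0, 1]`.
#' @export
rand_index <- function(true_labels, pred_labels) {
  check_label_pair(true_labels, pred_labels)
  ct <- table(true_labels, pred_labels)
  n <- length(true_labels)
  agreements <- comb2(n) + 2 * sum(comb2(ct)) -
    sum(comb2(rowSums(ct))) - sum(comb2(colSums(ct)))
  agreements / comb2(n)
}

#' Adjusted Rand index
#'
#' Rand index corrected for chance under the permutation model via the
#' contingency table: `(RI - E[RI]) / (max RI - E[RI])` in its pair-count
#' form. 1 for identical partitions (up to relabeling), about 0 for
#' independent ones. When both partitions are trivial (both one cluster or
#' both all singletons) the index is defined as 1.
#'
#' @inheritParams rand_index
#' @return scalar in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(true_labels, pred_labels) {
  check_label_pair(true_labels, pred_labels)
  ct <- table(true_labels, pred_labels)
  sum_ij <- sum(comb2(ct))
  sum_a <- sum(comb2(rowSums(ct)))
  sum_b <- sum(comb2(colSums(ct)))
  expected <- sum_a * sum_b / comb2(length(true_labels))
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}

# Entropy (natural log) of a vector of counts.
count_entropy <- function(counts) {
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log(p))
}

#' Mutual information of two labelings
#'
#' `MI(U, V) = sum_ij |Ui ∩ Vj|/N log(N |Ui ∩ Vj| / (|Ui| |Vj|))`,
#' natural logarithm.
#'
#' @inheritParams rand_index
#' @return scalar >= 0 (nats).
#' @export
mutual_information <- function(true_labels, pred_labels) {
  check_label_pair(true_labels, pred_labels)
  ct <- table(true_labels, pred_labels)
  n <- sum(ct)
  a <- rowSums(ct); b <- colSums(ct)
  mi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      nij <- ct[i, j]
      if (nij > 0) mi <- mi + nij / n * log(n * nij / (a[i] * b[j]))
    }
  }
  as.numeric(mi)
}

# Exact expected mutual information under the permutation (hypergeometric)
# model, as used by the adjusted mutual information.
expected_mutual_information <- function(a, b, n) {
  emi <- 0
  lfn <- lfactorial(n)
  for (ai in a) {
    for (bj in b) {
      lo <- max(1L, ai + bj - n)
      hi <- min(ai, bj)
      if (lo > hi) next
      nij <- lo:hi
      lp <- lfactorial(ai) + lfactorial(bj) + lfactorial(n - ai) +
        lfactorial(n - bj) - lfn - lfactorial(nij) -
        lfactorial(ai - nij) - lfactorial(bj - nij) -
        lfactorial(n - ai - bj + nij)
      emi <- emi + sum(nij / n * log(n * nij / (ai * bj)) * exp(lp))
    }
  }
  emi
}

#' Adjusted mutual information
#'
#' Mutual information corrected for chance:
#' `(MI - E[MI]) / (mean(H(U), H(V)) - E[MI])`, with the expectation taken
#' exactly under the permutation model ("average" normalisation). Two
#' zero-entropy labelings score 1 by convention. The value is clipped into
#' `[0, 1]`: chance-level agreement can otherwise yield tiny negative
#' values, and the metric's documented range is `[0, 1]`.
#'
#' @inheritParams rand_index
#' @return scalar in `[0, 1]`.
#' @export
adjusted_mutual_information <- function(true_labels, pred_labels) {
  check_label_pair(true_labels, pred_labels)
  ct <- table(true_labels, pred_labels)
  n <- sum(ct)
  a <- rowSums(ct); b <- colSums(ct)
  hu <- count_entropy(a); hv <- count_entropy(b)
  if (hu == 0 && hv == 0) return(1)
  mi <- mutual_information(true_labels, pred_labels)
  emi <- expected_mutual_information(as.integer(a), as.integer(b),
                                     as.integer(n))
  denom <- (hu + hv) / 2 - emi
  if (abs(denom) < .Machine$double.eps) return(0)
  min(max((mi - emi) / denom, 0), 1)
}

#' V-Measure (homogeneity / completeness)
#'
#' Homogeneity `1 - H(C|K)/H(C)` rewards clusters containing only one
#' class; completeness `1 - H(K|C)/H(K)` rewards classes gathered into one
#' cluster; the V-Measure is their weighted harmonic mean
#' `(1 + beta) h c / (beta h + c)`. Zero-entropy sides score 1 for their
#' component by convention.
#'
#' @inheritParams rand_index
#' @param beta weight of homogeneity in the harmonic mean (default 1).
#' @return list with `homogeneity`, `completeness` and `v`.
#' @export
v_measure <- function(true_labels, pred_labels, beta = 1) {
  check_label_pair(true_labels, pred_labels)
  ct <- table(true_labels, pred_labels)
  n <- sum(ct)
  hc <- count_entropy(rowSums(ct))
  hk <- count_entropy(colSums(ct))
  # conditional entropies from the contingency table
  h_c_given_k <- 0
  h_k_given_c <- 0
  for (j in seq_len(ncol(ct))) {
    nk <- sum(ct[, j])
    nz <- ct[, j][ct[, j] > 0]
    h_c_given_k <- h_c_given_k - sum(nz / n * log(nz / nk))
  }
  for (i in seq_len(nrow(ct))) {
    nc <- sum(ct[i, ])
    nz <- ct[i, ][ct[i, ] > 0]
    h_k_given_c <- h_k_given_c - sum(nz / n * log(nz / nc))
  }
  h <- if (hc == 0) 1 else 1 - h_c_given_k / hc
  cm <- if (hk == 0) 1 else 1 - h_k_given_c / hk
  v <- if (h + cm == 0) 0 else (1 + beta) * h * cm / (beta * h + cm)
  list(homogeneity = h, completeness = cm, v = v)
}

cluster_centroids <- function(X, labels) {
  levs <- sort(unique(labels))
  cent <- matrix(0, length(levs), ncol(X))
  for (i in seq_along(levs)) {
    cent[i, ] <- colMeans(X[labels == levs[i], , drop = FALSE])
  }
  list(levels = levs, centroids = cent)
}

#' Davies-Bouldin score
#'
#' Mean over clusters of the worst-case similarity
#' `R_ij = (s_i + s_j) / d_ij`, with `s_i` the mean distance of cluster
#' `i`'s points to their centroid and `d_ij` the distance between
#' centroids. Lower is better; 0 is the ideal. Scale-invariant (a ratio of
#' distances). Coincident centroids of distinct clusters are an error
#' (the similarity would divide by zero).
#'
#' @param features a [feature_set()] or numeric matrix.
#' @param labels cluster labels, at least two non-empty clusters.
#' @return scalar >= 0.
#' @export
davies_bouldin <- function(features, labels) {
  X <- as_feature_matrix(features)
  cc <- cluster_centroids(X, labels)
  k <- length(cc$levels)
  if (k < 2L) stop("need at least 2 clusters")
  s <- vapply(seq_len(k), function(i) {
    pts <- X[labels == cc$levels[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2L, cc$centroids[i, ])^2)))
  }, numeric(1))
  d <- as.matrix(stats::dist(cc$centroids))
  if (any(d[upper.tri(d)] == 0)) {
    stop("coincident cluster centroids: similarity undefined")
  }
  r <- outer(s, s, "+") / d
  diag(r) <- -Inf
  mean(apply(r, 1L, max))
}

#' Calinski-Harabasz score (variance ratio criterion)
#'
#' `tr(B_k)/tr(W_k) * (n - k)/(k - 1)`, the ratio of between-cluster to
#' within-cluster dispersion (sums of squared distances), scaled by the
#' degrees of freedom. Higher is better. Zero within-cluster dispersion is
#' an error (the score would be infinite).
#'
#' @inheritParams davies_bouldin
#' @return scalar >= 0.
#' @export
calinski_harabasz <- function(features, labels) {
  X <- as_feature_matrix(features)
  cc <- cluster_centroids(X, labels)
  k <- length(cc$levels)
  n <- nrow(X)
  if (k < 2L || k >= n) stop("need 2 <= k < n")
  grand <- colMeans(X)
  tr_w <- 0; tr_b <- 0
  for (i in seq_len(k)) {
    pts <- X[labels == cc$levels[i], , drop = FALSE]
    tr_w <- tr_w + sum(sweep(pts, 2L, cc$centroids[i, ])^2)
    tr_b <- tr_b + nrow(pts) * sum((cc$centroids[i, ] - grand)^2)
  }
  if (tr_w == 0) stop("zero within-cluster dispersion: score infinite")
  tr_b / tr_w * (n - k) / (k - 1)
}

#' Silhouette score
#'
#' Mean over points of `(b - a) / max(a, b)`, with `a` the mean distance
#' to the other points of the point's own cluster and `b` the mean
#' distance to the points of the nearest other cluster. -1 indicates an
#' incorrect clustering, 0 overlapping clusters, 1 dense well-separated
#' ones. Points in singleton clusters contribute 0 (documented
#' convention), and the reported score is the mean over all points.
#'
#' @inheritParams davies_bouldin
#' @return scalar in `[-1, 1]`.
#' @export
silhouette_score <- function(features, labels) {
  X <- as_feature_matrix(features)
  n <- nrow(X)
  levs <- sort(unique(labels))
  if (length(levs) < 2L) stop("need at least 2 clusters")
  D <- as.matrix(stats::dist(X))
  sizes <- table(factor(labels, levels = levs))
  s <- numeric(n)
  # mean distance from every point to every cluster, via group sums
  member <- outer(labels, levs, "==") * 1           # n x k
  sums <- D %*% member                              # n x k distance sums
  for (p in seq_len(n)) {
    own <- match(labels[p], levs)
    if (sizes[own] == 1L) { s[p] <- 0; next }
    a <- sums[p, own] / (sizes[own] - 1L)
    b <- min(sums[p, -own] / sizes[-own])
    s[p] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

#' k-means++ initial centres
#'
#' Spreads the initial centroids: the first is a uniformly drawn point,
#' each further centre is drawn with probability proportional to the
#' squared distance to the nearest centre chosen so far. Deterministic per
#' seed.
#'
#' @param features a [feature_set()] or matrix.
#' @param k number of centres.
#' @param seed integer RNG seed.
#' @return a `k x d` matrix of centres (rows of the data).
#' @export
kmeanspp_centers <- function(features, k, seed = 1L) {
  X <- as_feature_matrix(features)
  n <- nrow(X)
  if (k > n) stop("k exceeds the number of points")
  with_seed(seed, {
    centers <- matrix(0, k, ncol(X))
    idx <- sample.int(n, 1L)
    centers[1L, ] <- X[idx, ]
    if (k > 1L) {
      d2 <- rowSums(sweep(X, 2L, centers[1L, ])^2)
      for (j in 2L:k) {
        prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
        idx <- sample.int(n, 1L, prob = prob)
        centers[j, ] <- X[idx, ]
        d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ])^2))
      }
    }
    centers
  })
}

#' K-Means clustering of a feature set
#'
#' Euclidean K-Means (Lloyd iterations) from k-means++ initial centres,
#' deterministic for a fixed seed. Labels are returned 0-based, matching
#' the convention that cluster identities are arbitrary integers in
#' `[0, k)`.
#'
#' @param features a [feature_set()] or matrix.
#' @param k number of clusters (`<= n`).
#' @param seed integer RNG seed.
#' @param iter_max Lloyd iteration cap.
#' @return An object of class `clustering_result`: list with `labels`
#'   (0-based), `k`, `seed`, `inertia` (total within-cluster sum of
#'   squares), `empty_clusters` flag and the `features` clustered.
#' @export
kmeans_labels <- function(features, k, seed = 1L, iter_max = 100L) {
  X <- as_feature_matrix(features)
  if (nrow(X) == 0L) stop("empty feature set")
  if (k > nrow(X)) stop("k exceeds the number of points")
  km <- NULL
  empty_flag <- FALSE
  n_distinct <- nrow(unique(X))
  if (n_distinct >= k) {
    for (attempt in 0:4) {
      centers <- kmeanspp_centers(X, k, seed = seed + attempt)
      if (anyDuplicated(centers)) next
      km <- tryCatch(
        suppressWarnings(stats::kmeans(X, centers = centers,
                                       iter.max = iter_max,
                                       algorithm = "Lloyd")),
        error = function(e) NULL)
      if (!is.null(km)) {
        if (attempt > 0) empty_flag <- TRUE
        break
      }
    }
  }
  if (is.null(km)) {
    # degenerate features (fewer distinct points than clusters, as with a
    # collapsed embedding): assign identical points together and flag the
    # empty clusters rather than failing
    message("fewer than ", k, " distinct feature points; returning ",
            n_distinct, " clusters (remaining requested clusters empty)")
    uniq <- unique(X)
    key <- function(m) do.call(paste, c(as.data.frame(m), sep = "\r"))
    labels <- match(key(X), key(uniq)) - 1L
    return(structure(list(labels = as.integer(labels), k = as.integer(k),
                          seed = as.integer(seed), inertia = 0,
                          empty_clusters = TRUE, features = features),
                     class = "clustering_result"))
  }
  structure(list(labels = as.integer(km$cluster) - 1L, k = as.integer(k),
                 seed = as.integer(seed), inertia = km$tot.withinss,
                 empty_clusters = empty_flag, features = features),
            class = "clustering_result")
}

#' Evaluate an embedding with all six metrics
#'
#' Clusters the features with K-Means (unless predicted labels are given)
#' and computes ARI, AMI and V-Measure against the ground truth plus the
#' three internal metrics. Following the evaluation protocol, the internal
#' metrics use the ground-truth labels when they exist and the predicted
#' labels otherwise.
#'
#' @param features a [feature_set()] or matrix.
#' @param true_labels ground-truth labels or `NULL` (then only internal
#'   metrics are computed, on the K-Means labels).
#' @param k number of clusters for K-Means; defaults to the number of
#'   distinct ground-truth labels.
#' @param seed integer RNG seed for K-Means.
#' @param pred_labels optional precomputed predicted labels.
#' @return An object of class `metric_report`: list with `ari`, `ami`,
#'   `vm`, `dbs`, `chs`, `ss` (external entries `NA` without ground
#'   truth) and `which_labels_internal`.
#' @export
evaluate_features <- function(features, true_labels = NULL, k = NULL,
                              seed = 1L, pred_labels = NULL) {
  dropped <- attr(features, "dropped")
  if (!is.null(true_labels) && length(dropped) > 0L &&
      length(true_labels) == nrow(as_feature_matrix(features)) +
        length(dropped)) {
    true_labels <- true_labels[-dropped]   # spikes dropped by the embedding
  }
  if (is.null(pred_labels)) {
    if (is.null(k)) {
      if (is.null(true_labels)) stop("need `k` when no ground truth")
      k <- length(unique(true_labels))
    }
    pred_labels <- kmeans_labels(features, k, seed = seed)$labels
  }
  internal_on <- if (!is.null(true_labels)) "ground-truth" else "predicted"
  int_labels <- if (!is.null(true_labels)) true_labels else pred_labels
  safe <- function(f) tryCatch(f, error = function(e) NA_real_)
  structure(list(
    ari = if (!is.null(true_labels))
      adjusted_rand_index(true_labels, pred_labels) else NA_real_,
    ami = if (!is.null(true_labels))
      adjusted_mutual_information(true_labels, pred_labels) else NA_real_,
    vm = if (!is.null(true_labels))
      v_measure(true_labels, pred_labels)$v else NA_real_,
    dbs = safe(davies_bouldin(features, int_labels)),
    chs = safe(calinski_harabasz(features, int_labels)),
    ss = safe(silhouette_score(features, int_labels)),
    which_labels_internal = internal_on),
    class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  cat(sprintf("<metric_report> ARI %.3f AMI %.3f VM %.3f | DBS %.3f CHS %.1f SS %.3f (internal on %s labels)\n",
              x$ari, x$ami, x$vm, x$dbs, x$chs, x$ss,
              x$which_labels_internal))
  invisible(x)
}

#' Borda rank aggregation of a method-by-metric score table
#'
#' Ranks the methods within every metric (respecting each metric's
#' direction; the Davies-Bouldin score is lower-better), converts ranks to
#' Borda points (`n_methods - rank`, ties sharing averaged points) and
#' sums across metrics. The method with the most points ranks first.
#'
#' @param scores numeric matrix or data frame, methods in rows (rownames),
#'   metrics in columns; no missing cells.
#' @param directions named character vector per metric, `"higher"` or
#'   `"lower"`; defaults to higher-is-better for everything except a
#'   column named `dbs`.
#' @return data frame with `method`, `points`, `rank`, ordered best
#'   first.
#' @export
borda_aggregate <- function(scores, directions = NULL) {
  scores <- as.matrix(scores)
  if (anyNA(scores)) stop("missing cells in the score table")
  if (is.null(rownames(scores))) {
    rownames(scores) <- paste0("method", seq_len(nrow(scores)))
  }
  if (is.null(directions)) {
    directions <- ifelse(colnames(scores) == "dbs", "lower", "higher")
    names(directions) <- colnames(scores)
  }
  n <- nrow(scores)
  points <- numeric(n)
  for (j in seq_len(ncol(scores))) {
    dir <- directions[[colnames(scores)[j]]]
    r <- if (identical(dir, "lower")) rank(scores[, j], ties.method = "average")
         else rank(-scores[, j], ties.method = "average")
    points <- points + (n - r)
  }
  out <- data.frame(method = rownames(scores), points = points,
                    rank = rank(-points, ties.method = "min"),
                    row.names = NULL)
  out[order(out$rank), ]
}

#' Bonferroni-corrected paired comparison
#'
#' Paired t-test between two per-dataset score vectors, with the p-value
#' multiplied by the number of comparisons in the family and capped at 1.
#' A zero-variance difference vector is flagged instead of tested.
#'
#' @param scores_a,scores_b paired score vectors (length >= 2).
#' @param n_comparisons Bonferroni family size (1 = no correction).
#' @return list with `statistic`, `p_value`, `p_adjusted`, and
#'   `zero_variance` flag.
#' @export
paired_tests <- function(scores_a, scores_b, n_comparisons = 1L) {
  stopifnot(length(scores_a) == length(scores_b), length(scores_a) >= 2L)
  d <- scores_a - scores_b
  if (stats::sd(d) == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                p_adjusted = NA_real_, zero_variance = TRUE))
  }
  tt <- stats::t.test(scores_a, scores_b, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       p_adjusted = min(1, tt$p.value * n_comparisons),
       zero_variance = FALSE)
}
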