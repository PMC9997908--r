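# Classical 2-D embeddings used as comparison baselines: PCA, ICA and
# Isomap, plus the grid-search protocol for choosing their parameters.

# PCA scores with a deterministic sign convention: each component's
# largest-magnitude loading is made positive, so printed values are stable
# across platforms.
prcomp_signed <- function(X, n_components) {
  pr <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  k <- min(n_components, ncol(pr$rotation))
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    v <- rot[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  sweep(pr$x[, seq_len(k), drop = FALSE], 2L, flip, "*")
}

#' Principal component embedding of spike waveforms
#'
#' Projects the centred waveform matrix onto its top principal
#' components. Deterministic up to component sign, which is fixed by
#' making each component's largest-magnitude loading positive.
#'
#' @param spikes a [spike_set()], [feature_set()] or matrix.
#' @param n_components number of components (default 2).
#' @return a [feature_set()].
#' @export
pca_embed <- function(spikes, n_components = 2L) {
  X <- as_feature_matrix(spikes)
  if (nrow(X) < n_components) stop("fewer spikes than components")
  if (n_components > qr(sweep(X, 2L, colMeans(X)))$rank) {
    stop("n_components exceeds the data rank")
  }
  feature_set(prcomp_signed(X, n_components), method_tag = "pca")
}

#' Independent component embedding (FastICA)
#'
#' Whitens the data by PCA and runs symmetric FastICA with the `logcosh`
#' contrast (the `exp` contrast is also available) to the requested
#' tolerance. Seeded for reproducibility; errors if the iteration cap is
#' reached before convergence.
#'
#' @param spikes a [spike_set()], [feature_set()] or matrix.
#' @param n_components number of components (default 2).
#' @param contrast contrast function, `"logcosh"` or `"exp"`.
#' @param tolerance convergence tolerance on the update (default 1e-5).
#' @param seed integer RNG seed for the unmixing initialisation.
#' @param max_iter iteration cap (default 1000, ample for convergence).
#' @return a [feature_set()].
#' @export
ica_embed <- function(spikes, n_components = 2L, contrast = "logcosh",
                      tolerance = 1e-5, seed = 1L, max_iter = 1000L) {
  contrast <- match.arg(contrast, c("logcosh", "exp"))
  X <- as_feature_matrix(spikes)
  n <- nrow(X)
  if (n < n_components) stop("fewer spikes than components")
  Xc <- sweep(X, 2L, colMeans(X))
  sv <- svd(Xc, nu = n_components, nv = n_components)
  if (sv$d[n_components] < .Machine$double.eps * sv$d[1] * max(dim(X))) {
    stop("data rank below n_components")
  }
  # whitened sources: n x k with identity covariance
  Z <- sv$u[, seq_len(n_components), drop = FALSE] * sqrt(n - 1)
  W <- with_seed(seed, {
    M <- matrix(stats::rnorm(n_components^2), n_components)
    qr.Q(qr(M))
  })
  sym_decorrelate <- function(W) {
    e <- eigen(W %*% t(W), symmetric = TRUE)
    e$vectors %*% diag(1 / sqrt(e$values), n_components) %*%
      t(e$vectors) %*% W
  }
  g <- switch(contrast,
    logcosh = function(u) list(gu = tanh(u), gpu = 1 - tanh(u)^2),
    exp = function(u) {
      eu <- exp(-u^2 / 2)
      list(gu = u * eu, gpu = (1 - u^2) * eu)
    })
  for (it in seq_len(max_iter)) {
    U <- Z %*% t(W)                      # n x k projections
    gg <- g(U)
    W_new <- crossprod(gg$gu, Z) / n - colMeans(gg$gpu) * W
    W_new <- sym_decorrelate(W_new)
    delta <- max(abs(abs(rowSums(W_new * W)) - 1))
    W <- W_new
    if (delta < tolerance) {
      return(feature_set(Z %*% t(W), method_tag = "ica"))
    }
  }
  stop("FastICA did not converge within ", max_iter, " iterations")
}

# Symmetric k-nearest-neighbour graph as a weighted adjacency matrix
# (Inf = no edge), from a full distance matrix.
knn_graph <- function(D, k) {
  n <- nrow(D)
  A <- matrix(Inf, n, n)
  for (i in seq_len(n)) {
    nb <- order(D[i, ])[2:(k + 1L)]
    A[i, nb] <- D[i, nb]
  }
  pmin(A, t(A))                           # union of neighbourhoods
}

# Connected components of a finite-edge adjacency matrix, by BFS.
graph_components <- function(A) {
  n <- nrow(A)
  comp <- integer(n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[[1L]]; queue <- queue[-1L]
      nb <- which(is.finite(A[v, ]) & comp == 0L)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

# All-pairs shortest-path (geodesic) distances on the kNN graph, by
# repeated Dijkstra.
geodesic_distances <- function(D, k) {
  A <- knn_graph(as.matrix(D), k)
  n <- nrow(A)
  G <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    done <- logical(n)
    for (step in seq_len(n)) {
      u <- which.min(ifelse(done, Inf, dist))
      if (!is.finite(dist[u])) break
      done[u] <- TRUE
      nb <- which(is.finite(A[u, ]) & !done)
      if (length(nb) > 0L) {
        dist[nb] <- pmin(dist[nb], dist[u] + A[u, nb])
      }
    }
    G[s, ] <- dist
  }
  G
}

#' Isomap embedding of spike waveforms
#'
#' Classical Isomap: a symmetric k-nearest-neighbour graph is built on the
#' chosen metric, geodesic distances are taken as shortest paths through
#' the graph, and classical multidimensional scaling of the geodesic
#' matrix gives the embedding. If the neighbourhood graph is disconnected
#' the largest connected component is embedded and the dropped spikes are
#' reported via a message; their indices are in `attr(, "dropped")` and
#' the retained rows keep the input order.
#'
#' @param spikes a [spike_set()], [feature_set()] or matrix.
#' @param n_neighbors neighbourhood size k.
#' @param n_components embedding dimension (default 2).
#' @param metric `"minkowski"` (Euclidean, the best-performing choice) or
#'   `"manhattan"`.
#' @return a [feature_set()].
#' @export
isomap_embed <- function(spikes, n_neighbors = 30L, n_components = 2L,
                         metric = "minkowski") {
  metric <- match.arg(metric, c("minkowski", "euclidean", "manhattan"))
  X <- as_feature_matrix(spikes)
  n <- nrow(X)
  if (n_neighbors >= n) stop("n_neighbors must be < n_spikes")
  if (n_neighbors < 1L) stop("n_neighbors must be >= 1")
  D <- as.matrix(stats::dist(X, method = if (metric == "manhattan")
    "manhattan" else "euclidean"))
  A <- knn_graph(D, n_neighbors)
  comp <- graph_components(A)
  keep <- seq_len(n)
  if (max(comp) > 1L) {
    largest <- which.max(tabulate(comp))
    keep <- which(comp == largest)
    message("neighbourhood graph disconnected: embedding largest ",
            "component (", length(keep), "/", n, " spikes)")
    D <- D[keep, keep]
  }
  G <- geodesic_distances(D, min(n_neighbors, length(keep) - 1L))
  pts <- stats::cmdscale(G, k = n_components)
  out <- feature_set(pts, method_tag = sprintf("isomap(k=%d)", n_neighbors))
  attr(out, "dropped") <- setdiff(seq_len(n), keep)
  out
}

#' Grid search over embedding parameters
#'
#' Evaluates every combination of the supplied parameter grid for an
#' embedding method, scoring each by a clustering metric (K-Means labels
#' against ground truth for the external metrics; ground-truth labels for
#' the internal ones, following the evaluation protocol for labeled data),
#' and returns all scores plus the best combination (lowest for the
#' Davies-Bouldin score, highest otherwise).
#'
#' @param method `"pca"`, `"ica"` or `"isomap"`.
#' @param spikes a labeled [spike_set()].
#' @param grid named list of parameter vectors, e.g.
#'   `list(n_neighbors = c(30, 60, 90))`.
#' @param objective one of `"ari"`, `"ami"`, `"vm"`, `"dbs"`, `"chs"`,
#'   `"ss"` (default `"ari"` when ground truth is available, `"ss"`
#'   otherwise).
#' @param k number of clusters for K-Means; defaults to the number of
#'   distinct ground-truth labels.
#' @param seed integer RNG seed (clustering and seeded embeddings).
#' @return An object of class `grid_search_report`: list with `method`,
#'   `grid`, `scores` (one row per combination) and `best` (row of
#'   `scores`).
#' @export
grid_search_embedding <- function(method, spikes, grid, objective = NULL,
                                  k = NULL, seed = 1L) {
  method <- match.arg(method, c("pca", "ica", "isomap"))
  stopifnot(is.list(grid), length(grid) > 0L, !is.null(names(grid)))
  if (is.null(objective)) {
    objective <- if (!is.null(spikes$labels)) "ari" else "ss"
  }
  objective <- match.arg(objective, c("ari", "ami", "vm", "dbs", "chs",
                                      "ss"))
  if (is.null(k) && is.null(spikes$labels)) {
    stop("`k` is required for unlabeled data")
  }
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  scores <- numeric(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    args <- c(list(spikes), as.list(combos[i, , drop = FALSE]))
    if (method == "ica") args$seed <- seed
    fs <- try(do.call(switch(method, pca = pca_embed, ica = ica_embed,
                             isomap = isomap_embed), args), silent = TRUE)
    if (inherits(fs, "try-error")) {
      scores[i] <- NA_real_
      next
    }
    rep <- evaluate_features(fs, spikes$labels, k = k, seed = seed)
    scores[i] <- rep[[objective]]
  }
  tab <- cbind(combos, score = scores)
  direction <- if (objective == "dbs") which.min else which.max
  best_i <- direction(ifelse(is.na(scores),
                             if (objective == "dbs") Inf else -Inf, scores))
  structure(list(method = method, grid = grid, objective = objective,
                 scores = tab, best = tab[best_i, , drop = FALSE]),
            class = "grid_search_report")
}

#' @export
print.grid_search_report <- function(x, ...) {
  cat("<grid_search_report> ", x$method, ", objective ", x$objective,
      ", ", nrow(x$scores), " combinations\n", sep = "")
  cat("best:\n")
  print(x$best)
  invisible(x)
}

#' Serialize a grid-search report to delimited text
#'
#' @param report a `grid_search_report`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_grid_report <- function(report, path) {
  utils::write.table(report$scores, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
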