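# The six validity metrics against independent direct-definition oracles,
# K-Means, Borda aggregation and paired tests.

# --- worked examples ---------------------------------------------------

test_that("worked pair-counting examples reproduce exactly", {
  expect_equal(rand_index(c("a", "a", "b"), c("x", "y", "y")), 1 / 3)
  expect_equal(adjusted_rand_index(c("a", "a", "b"), c("x", "y", "y")),
               -0.5)
  expect_equal(rand_index(1:5, 1:5), 1)
  expect_equal(adjusted_rand_index(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
})

test_that("worked internal-metric examples reproduce exactly", {
  f <- matrix(c(0, 2, 10, 12))
  l <- c(1, 1, 2, 2)
  expect_equal(davies_bouldin(f, l), 0.2)      # s=1, s=1, d=10
  expect_equal(calinski_harabasz(f, l), 50)    # tr(B)=100, tr(W)=4, x2
  expect_equal(silhouette_score(matrix(c(0, 0.1, 10, 10.1)), l),
               0.99, tolerance = 1e-3)
})

test_that("degenerate-case conventions hold", {
  expect_equal(adjusted_rand_index(rep(1, 4), rep(2, 4)), 1)
  expect_equal(adjusted_mutual_information(rep(1, 4), rep(1, 4)), 1)
  expect_equal(adjusted_mutual_information(c(1, 1, 2, 2), rep(7, 4)), 0)
  vm <- v_measure(c(1, 1, 2, 2), rep(1, 4))
  expect_equal(vm$homogeneity, 0)
  expect_equal(vm$completeness, 1)
  expect_equal(v_measure(1:4, 1:4), list(homogeneity = 1,
                                         completeness = 1, v = 1))
  expect_error(davies_bouldin(matrix(c(0, 0, 5, 5)), c(1, 2, 1, 2)),
               "coincident")
  expect_error(calinski_harabasz(matrix(c(0, 0, 5, 5)), c(1, 1, 2, 2)),
               "dispersion")
  expect_error(silhouette_score(matrix(1:4), rep(1, 4)), "2 clusters")
  expect_error(rand_index(1:3, 1:4), "length")
})

# --- oracle equivalence on random instances ----------------------------

test_that("external metrics agree with enumeration/entropy oracles to 1e-9", {
  set.seed(101)
  for (rep in 1:40) {
    n <- sample(5:50, 1)
    a <- random_labels(n, 5); b <- random_labels(n, 5)
    expect_equal(rand_index(a, b), oracle_rand(a, b), tolerance = 1e-9)
    expect_equal(adjusted_rand_index(a, b), oracle_ari(a, b),
                 tolerance = 1e-9)
    expect_equal(mutual_information(a, b), oracle_mi(a, b),
                 tolerance = 1e-9)
    expect_equal(v_measure(a, b)$v, oracle_vm(a, b), tolerance = 1e-9)
  }
})

test_that("internal metrics agree with distance-loop oracles to 1e-9", {
  set.seed(102)
  for (rep in 1:25) {
    n <- sample(8:40, 1); d <- sample(1:4, 1)
    X <- matrix(rnorm(n * d), n, d)
    lab <- random_labels(n, 4)
    if (length(unique(lab)) < 2) next
    expect_equal(silhouette_score(X, lab), oracle_silhouette(X, lab),
                 tolerance = 1e-9)
    expect_equal(davies_bouldin(X, lab), oracle_dbs(X, lab),
                 tolerance = 1e-9)
    expect_equal(calinski_harabasz(X, lab), oracle_chs(X, lab),
                 tolerance = 1e-9)
  }
})

test_that("ARI is chance-centred under random permutations", {
  # oracle: Monte-Carlo permutation null
  set.seed(103)
  lab <- rep(1:4, times = c(10, 6, 5, 9))
  aris <- vapply(1:200, function(i) {
    adjusted_rand_index(lab, sample(lab))
  }, numeric(1))
  expect_lt(abs(mean(aris)), 0.02)
})

test_that("metrics respect their documented ranges on arbitrary inputs", {
  set.seed(104)
  for (rep in 1:60) {
    n <- sample(6:40, 1)
    a <- random_labels(n, 6); b <- random_labels(n, 6)
    expect_gte(adjusted_rand_index(a, b), -1)
    expect_lte(adjusted_rand_index(a, b), 1)
    ami <- adjusted_mutual_information(a, b)
    expect_gte(ami, 0); expect_lte(ami, 1)
    v <- v_measure(a, b)$v
    expect_gte(v, 0); expect_lte(v, 1)
    X <- matrix(rnorm(n * 2), n)
    if (length(unique(a)) >= 2 && length(unique(a)) < n) {
      expect_gte(davies_bouldin(X, a), 0)
      expect_gte(calinski_harabasz(X, a), 0)
      ss <- silhouette_score(X, a)
      expect_gte(ss, -1); expect_lte(ss, 1)
    }
  }
})

test_that("external metrics are label-permutation invariant; internal ones rotation invariant", {
  set.seed(105)
  a <- random_labels(30, 4); b <- random_labels(30, 4)
  relab <- function(x) match(x, sample(unique(x)))
  for (f in list(rand_index, adjusted_rand_index,
                 adjusted_mutual_information,
                 function(u, v) v_measure(u, v)$v)) {
    expect_equal(f(a, b), f(relab(a), relab(b)), tolerance = 1e-12)
  }
  X <- matrix(rnorm(60), 30, 2)
  th <- 0.73
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  lab <- random_labels(30, 3)
  if (length(unique(lab)) >= 2) {
    for (f in list(davies_bouldin, calinski_harabasz, silhouette_score)) {
      expect_equal(f(X, lab), f(X %*% R, lab), tolerance = 1e-9)
      expect_equal(f(X, lab), f(X, relab(lab)), tolerance = 1e-9)
    }
  }
  # DBS is additionally scale invariant (a ratio of distances)
  expect_equal(davies_bouldin(X, lab), davies_bouldin(X * 7.3, lab),
               tolerance = 1e-12)
})

# all permutations of a small vector (for the expected-MI oracle); equal
# elements are treated as distinct so every distinct arrangement appears
# with the same multiplicity and the deduplicated mean stays unbiased
combinat_perms <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in combinat_perms(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

test_that("AMI matches a small exhaustive expected-MI computation", {
  # 2x2 contingency example: direct Eq-style double sum for MI and the
  # exact hypergeometric expectation computed by brute-force enumeration
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 2, 2, 1)
  expect_equal(mutual_information(a, b), oracle_mi(a, b), tolerance = 1e-12)
  # brute-force E[MI]: average MI over all distinct permutations of b
  perms <- unique(combinat_perms(b))
  emi_bf <- mean(vapply(perms, function(p) oracle_mi(a, p), numeric(1)))
  emi <- expected_mutual_information(as.integer(table(a)),
                                     as.integer(table(b)), 6L)
  expect_equal(emi, emi_bf, tolerance = 1e-10)
})

# --- K-Means -----------------------------------------------------------

test_that("K-Means handles the degenerate and separable cases", {
  set.seed(106)
  X <- matrix(rnorm(20), 10, 2)
  res <- kmeans_labels(X, k = 10L, seed = 1L)
  expect_equal(res$inertia, 0)
  expect_equal(sort(unique(res$labels)), 0:9)
  blobs <- rbind(matrix(rnorm(40, 0, 0.2), 20, 2),
                 matrix(rnorm(40, 30, 0.2), 20, 2))
  truth <- rep(1:2, each = 20)
  res2 <- kmeans_labels(blobs, 2L, seed = 1L)
  expect_equal(adjusted_rand_index(truth, res2$labels), 1)
  expect_true(all(res2$labels %in% 0:1))
  expect_error(kmeans_labels(X, 11L), "exceeds")
})

test_that("Lloyd iterations never increase the inertia", {
  # oracle: per-iteration inertia trace from fixed initial centres
  set.seed(107)
  X <- matrix(rnorm(300), 100, 3)
  centers <- kmeanspp_centers(X, 5L, seed = 2L)
  trace <- vapply(1:8, function(iters) {
    suppressWarnings(stats::kmeans(X, centers = centers, iter.max = iters,
                                   algorithm = "Lloyd"))$tot.withinss
  }, numeric(1))
  expect_true(all(diff(trace) <= 1e-9))
})

test_that("K-Means is deterministic per seed and flags collapsed features", {
  set.seed(108)
  X <- matrix(rnorm(80), 40, 2)
  r1 <- kmeans_labels(X, 4L, seed = 9L)
  r2 <- kmeans_labels(X, 4L, seed = 9L)
  expect_identical(r1$labels, r2$labels)
  expect_identical(r1$inertia, r2$inertia)
  collapsed <- matrix(rep(c(1, 2), each = 10), 10, 2)
  expect_message(r3 <- kmeans_labels(collapsed, 4L, seed = 1L), "distinct")
  expect_true(r3$empty_clusters)
  expect_equal(length(unique(r3$labels)), 1L)
})

# --- aggregation -------------------------------------------------------

test_that("Borda aggregation matches manual point counting", {
  scores <- rbind(m1 = c(ari = 0.9, dbs = 0.2),
                  m2 = c(ari = 0.5, dbs = 0.9),
                  m3 = c(ari = 0.7, dbs = 0.5))
  # manual tally: ari ranks m1>m3>m2 -> points 2,0,1; dbs (lower better)
  # ranks m1>m3>m2 -> points 2,0,1; totals m1=4, m2=0, m3=2
  out <- borda_aggregate(scores)
  expect_equal(out$method, c("m1", "m3", "m2"))
  expect_equal(out$points, c(4, 2, 0))
  expect_equal(out$rank, c(1L, 2L, 3L))
  # single metric: aggregate equals that metric's ranking
  out1 <- borda_aggregate(scores[, "ari", drop = FALSE])
  expect_equal(out1$method, c("m1", "m3", "m2"))
  # a method dominating every metric ranks first
  dom <- rbind(a = c(x = 1, y = 1), b = c(x = 0.2, y = 0.1),
               c = c(x = 0.5, y = 0.4))
  expect_equal(borda_aggregate(dom)$method[1], "a")
  # ties share averaged points
  tied <- rbind(a = c(x = 1), b = c(x = 1), c = c(x = 0))
  pts <- borda_aggregate(tied)
  expect_equal(sort(pts$points, decreasing = TRUE), c(1.5, 1.5, 0))
  expect_error(borda_aggregate(rbind(c(1, NA))), "missing")
})

test_that("paired comparisons match the closed-form t statistic", {
  a <- c(0.9, 0.8, 0.95, 0.7, 0.85)
  b <- c(0.6, 0.65, 0.7, 0.6, 0.75)
  res <- paired_tests(a, b, n_comparisons = 3L)
  d <- a - b
  t_manual <- mean(d) / (stats::sd(d) / sqrt(5))
  expect_equal(res$statistic, t_manual, tolerance = 1e-12)
  expect_equal(res$p_adjusted, min(1, res$p_value * 3))
  # no correction case
  res1 <- paired_tests(a, b, n_comparisons = 1L)
  expect_equal(res1$p_adjusted, res1$p_value)
  # cap at 1
  res_big <- paired_tests(a, b, n_comparisons = 1e6)
  expect_lte(res_big$p_adjusted, 1)
  # zero-variance flag
  resz <- paired_tests(c(1, 1, 1), c(0.5, 0.5, 0.5))
  expect_true(resz$zero_variance)
  expect_true(is.na(resz$p_value))
})
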