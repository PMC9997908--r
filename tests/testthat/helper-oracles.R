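# Independent direct-definition oracles for the validity metrics
# (deliberately naive pair/entropy/distance loops).

oracle_rand <- function(a, b) {
  n <- length(a)
  agree <- 0; pairs <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    pairs <- pairs + 1
    same_a <- a[i] == a[j]; same_b <- b[i] == b[j]
    if (same_a == same_b) agree <- agree + 1
  }
  agree / pairs
}

oracle_ari <- function(a, b) {
  # direct contingency-table arithmetic
  ct <- table(a, b)
  c2 <- function(x) x * (x - 1) / 2
  sij <- sum(c2(ct)); sa <- sum(c2(rowSums(ct))); sb <- sum(c2(colSums(ct)))
  e <- sa * sb / c2(length(a))
  mx <- (sa + sb) / 2
  if (mx == e) return(1)
  (sij - e) / (mx - e)
}

oracle_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log(p))
}

oracle_mi <- function(a, b) {
  # explicit double sum over cells
  n <- length(a)
  mi <- 0
  for (u in unique(a)) for (v in unique(b)) {
    nij <- sum(a == u & b == v)
    if (nij > 0) {
      mi <- mi + nij / n * log(n * nij / (sum(a == u) * sum(b == v)))
    }
  }
  mi
}

oracle_vm <- function(a, b) {
  n <- length(a)
  hck <- 0; hkc <- 0
  for (v in unique(b)) {
    sel <- b == v
    for (u in unique(a[sel])) {
      nij <- sum(a[sel] == u)
      hck <- hck - nij / n * log(nij / sum(sel))
    }
  }
  for (u in unique(a)) {
    sel <- a == u
    for (v in unique(b[sel])) {
      nij <- sum(b[sel] == v)
      hkc <- hkc - nij / n * log(nij / sum(sel))
    }
  }
  hc <- oracle_entropy(a); hk <- oracle_entropy(b)
  h <- if (hc == 0) 1 else 1 - hck / hc
  cm <- if (hk == 0) 1 else 1 - hkc / hk
  if (h + cm == 0) 0 else 2 * h * cm / (h + cm)
}

oracle_silhouette <- function(X, lab) {
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  s <- numeric(n)
  for (i in 1:n) {
    own <- which(lab == lab[i] & seq_len(n) != i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(vapply(own, function(j) d(i, j), numeric(1)))
    b <- Inf
    for (l in setdiff(unique(lab), lab[i])) {
      others <- which(lab == l)
      b <- min(b, mean(vapply(others, function(j) d(i, j), numeric(1))))
    }
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

oracle_dbs <- function(X, lab) {
  levs <- sort(unique(lab))
  k <- length(levs)
  cent <- lapply(levs, function(l) colMeans(X[lab == l, , drop = FALSE]))
  s <- vapply(seq_len(k), function(i) {
    pts <- X[lab == levs[i], , drop = FALSE]
    mean(apply(pts, 1, function(p) sqrt(sum((p - cent[[i]])^2))))
  }, numeric(1))
  tot <- 0
  for (i in 1:k) {
    best <- -Inf
    for (j in setdiff(1:k, i)) {
      dij <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      best <- max(best, (s[i] + s[j]) / dij)
    }
    tot <- tot + best
  }
  tot / k
}

oracle_chs <- function(X, lab) {
  levs <- sort(unique(lab)); k <- length(levs); n <- nrow(X)
  grand <- colMeans(X)
  trw <- 0; trb <- 0
  for (l in levs) {
    pts <- X[lab == l, , drop = FALSE]
    cent <- colMeans(pts)
    trw <- trw + sum(apply(pts, 1, function(p) sum((p - cent)^2)))
    trb <- trb + nrow(pts) * sum((cent - grand)^2)
  }
  trb / trw * (n - k) / (k - 1)
}

random_labels <- function(n, kmax) sample.int(sample(2:kmax, 1), n,
                                              replace = TRUE)

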