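# Dense feed-forward core used by the autoencoder variants.
#
# Networks are stored as list(W = list of in x out matrices, b = list of
# bias vectors, acts = activation name per layer). Data flows as row-major
# batches: Z = A %*% W + b. The optimiser is Adam; gradients are exact
# analytic backpropagation, including the Jacobian (contractive) and
# orthogonality/decorrelation penalty terms.

act_fun <- function(z, act) {
  switch(act, relu = pmax(z, 0), tanh = tanh(z), linear = z,
         stop("unknown activation: ", act))
}

act_grad <- function(z, a, act) {
  switch(act, relu = (z > 0) * 1, tanh = 1 - a^2,
         linear = array(1, dim(z)), stop("unknown activation: ", act))
}

glorot_init <- function(widths, seed = NULL) {
  init <- function() {
    L <- length(widths) - 1L
    W <- vector("list", L); b <- vector("list", L)
    for (l in seq_len(L)) {
      lim <- sqrt(6 / (widths[l] + widths[l + 1L]))
      W[[l]] <- matrix(stats::runif(widths[l] * widths[l + 1L], -lim, lim),
                       widths[l], widths[l + 1L])
      b[[l]] <- numeric(widths[l + 1L])
    }
    list(W = W, b = b)
  }
  if (is.null(seed)) init() else with_seed(seed, init())
}

mlp_forward <- function(net, X) {
  L <- length(net$W)
  A <- vector("list", L + 1L); Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- sweep(A[[l]] %*% net$W[[l]], 2L, net$b[[l]], "+")
    A[[l + 1L]] <- act_fun(Z[[l]], net$acts[l])
  }
  list(A = A, Z = Z)
}

# Encoder Jacobian d code / d input for one input row `x` (analytic),
# valid for relu/tanh/linear layer stacks. Layers 1..code_index.
mlp_encoder_jacobian <- function(net, x, code_index) {
  a <- matrix(x, 1L)
  J <- diag(length(x))
  for (l in seq_len(code_index)) {
    z <- drop(a %*% net$W[[l]]) + net$b[[l]]
    a_next <- act_fun(z, net$acts[l])
    g <- drop(act_grad(matrix(z, 1L), matrix(a_next, 1L), net$acts[l]))
    J <- (t(net$W[[l]]) * g) %*% J   # rows scaled by activation derivative
    a <- matrix(a_next, 1L)
  }
  J  # code_size x input_dim
}

# Squared-Frobenius Jacobian penalty and its analytic parameter gradients
# for the encoder stack (ReLU hiddens + tanh code), summed over the batch.
# The ReLU masks' own derivative is zero almost everywhere and is treated
# as constant; the tanh code diagonal is differentiated exactly.
contractive_grads <- function(net, X, code_index) {
  C <- code_index
  w <- lapply(net$W[seq_len(C)], t)          # out x in orientation
  gW <- lapply(net$W[seq_len(C)], function(m) array(0, dim(m)))
  gb <- lapply(net$b[seq_len(C)], function(v) numeric(length(v)))
  penalty <- 0
  d_in <- ncol(X)
  for (i in seq_len(nrow(X))) {
    a <- X[i, ]
    As <- vector("list", C + 1L); As[[1L]] <- a
    masks <- vector("list", C)
    Rs <- vector("list", C)                  # Jacobian of a_{k-1} wrt x
    Rs[[1L]] <- diag(d_in)
    for (k in seq_len(C)) {
      z <- drop(w[[k]] %*% As[[k]]) + net$b[[k]]
      if (k < C) {
        m <- (z > 0) * 1
        masks[[k]] <- m
        As[[k + 1L]] <- z * m
        if (k < C) Rs[[k + 1L]] <- (w[[k]] * m) %*% Rs[[k]]
      } else {
        tcode <- tanh(z)
        dvec <- 1 - tcode^2
        As[[k + 1L]] <- tcode
      }
    }
    M <- w[[C]] %*% Rs[[C]]                  # code x d_in, pre-tanh chain
    g <- rowSums(M^2)
    delta2 <- dvec^2
    penalty <- penalty + sum(delta2 * g)
    DM <- M * delta2                         # diag(d^2) %*% M
    # direct terms, masks and tanh diagonal held fixed
    gw_direct <- vector("list", C)
    gw_direct[[C]] <- 2 * (DM %*% t(Rs[[C]]))
    if (C > 1L) {
      Q <- w[[C]]                            # code x width_{C-1}
      for (k in (C - 1L):1L) {
        QD <- Q * rep(masks[[k]], each = nrow(Q))
        gw_direct[[k]] <- 2 * (t(QD) %*% DM %*% t(Rs[[k]]))
        if (k > 1L) Q <- QD %*% w[[k]]
      }
    }
    # dependence of the tanh derivative on the code pre-activation
    u <- -4 * tcode * delta2 * g
    delta <- u
    for (k in C:1L) {
      gw_direct[[k]] <- gw_direct[[k]] + outer(delta, As[[k]])
      gb[[k]] <- gb[[k]] + delta
      if (k > 1L) delta <- drop(delta %*% w[[k]]) * masks[[k - 1L]]
    }
    for (k in seq_len(C)) gW[[k]] <- gW[[k]] + t(gw_direct[[k]])
  }
  list(penalty = penalty, gW = gW, gb = gb)
}

# One full loss + gradient evaluation on a batch.
# opts: code_index, code_l1, contractive_lambda (0 = off), ortho_w,
# decor_w (0 = off), tied (logical).
mlp_grads <- function(net, X, opts) {
  L <- length(net$W)
  fw <- mlp_forward(net, X)
  A <- fw$A; Z <- fw$Z
  n <- nrow(X); p <- ncol(X)
  out <- A[[L + 1L]]
  code <- A[[opts$code_index + 1L]]
  recon <- mean((out - X)^2)
  loss <- recon + opts$code_l1 * sum(abs(code)) / n
  gW <- vector("list", L); gb <- vector("list", L)
  delta <- (2 * (out - X) / (n * p)) * act_grad(Z[[L]], out, net$acts[L])
  for (l in L:1L) {
    gW[[l]] <- crossprod(A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      dA <- delta %*% t(net$W[[l]])
      if (l - 1L == opts$code_index) {
        dA <- dA + opts$code_l1 * sign(code) / n
        if (opts$decor_w > 0 && n > 1L) {
          cv <- stats::cov(code)
          offdiag <- cv; diag(offdiag) <- 0
          loss <- loss + opts$decor_w * sum(offdiag^2)
          centered <- sweep(code, 2L, colMeans(code))
          dA <- dA + opts$decor_w * (4 / (n - 1)) * (centered %*% offdiag)
        }
      }
      delta <- dA * act_grad(Z[[l - 1L]], A[[l]], net$acts[l - 1L])
    }
  }
  if (opts$ortho_w > 0) {
    for (l in seq_len(L)) {
      dev <- crossprod(net$W[[l]]) - diag(ncol(net$W[[l]]))
      loss <- loss + opts$ortho_w * sum(dev^2)
      gW[[l]] <- gW[[l]] + opts$ortho_w * 4 * (net$W[[l]] %*% dev)
    }
  }
  if (opts$contractive_lambda > 0) {
    cg <- contractive_grads(net, X, opts$code_index)
    loss <- loss + opts$contractive_lambda * cg$penalty
    for (k in seq_along(cg$gW)) {
      gW[[k]] <- gW[[k]] + opts$contractive_lambda * cg$gW[[k]]
      gb[[k]] <- gb[[k]] + opts$contractive_lambda * cg$gb[[k]]
    }
  }
  list(loss = loss, recon = recon, gW = gW, gb = gb)
}

adam_state <- function(net) {
  list(mW = lapply(net$W, function(m) array(0, dim(m))),
       vW = lapply(net$W, function(m) array(0, dim(m))),
       mb = lapply(net$b, function(v) numeric(length(v))),
       vb = lapply(net$b, function(v) numeric(length(v))),
       t = 0L)
}

adam_update <- function(net, st, gW, gb, lr, beta1 = 0.9, beta2 = 0.999,
                        eps = 1e-8, skip_w = integer(0)) {
  st$t <- st$t + 1L
  c1 <- 1 - beta1^st$t; c2 <- 1 - beta2^st$t
  for (l in seq_along(net$W)) {
    if (!(l %in% skip_w)) {
      st$mW[[l]] <- beta1 * st$mW[[l]] + (1 - beta1) * gW[[l]]
      st$vW[[l]] <- beta2 * st$vW[[l]] + (1 - beta2) * gW[[l]]^2
      net$W[[l]] <- net$W[[l]] -
        lr * (st$mW[[l]] / c1) / (sqrt(st$vW[[l]] / c2) + eps)
    }
    st$mb[[l]] <- beta1 * st$mb[[l]] + (1 - beta1) * gb[[l]]
    st$vb[[l]] <- beta2 * st$vb[[l]] + (1 - beta2) * gb[[l]]^2
    net$b[[l]] <- net$b[[l]] -
      lr * (st$mb[[l]] / c1) / (sqrt(st$vb[[l]] / c2) + eps)
  }
  list(net = net, st = st)
}

# Mini-batch Adam training of an autoencoder net on X (targets = inputs).
# Returns list(net, loss_history). Tied nets update encoder weights with
# the summed encoder + transposed-decoder gradients and mirror after every
# step, so the transposition constraint holds throughout training.
mlp_fit <- function(net, X, epochs, lr, batch_size, opts, seed = NULL,
                    on_step = NULL) {
  run <- function() {
    n <- nrow(X)
    L <- length(net$W)
    st <- adam_state(net)
    history <- numeric(epochs)
    mirror <- if (isTRUE(opts$tied)) L + 1L - seq_len(opts$code_index)
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1L, n)]
        gr <- mlp_grads(net, X[idx, , drop = FALSE], opts)
        if (!is.finite(gr$loss)) {
          stop("non-finite loss at epoch ", ep,
               " (learning rate too high or degenerate input)")
        }
        if (isTRUE(opts$tied)) {
          # shared weights receive the encoder + transposed decoder grads
          for (l in seq_len(opts$code_index)) {
            gr$gW[[l]] <- gr$gW[[l]] + t(gr$gW[[mirror[l]]])
          }
        }
        up <- adam_update(net, st, gr$gW, gr$gb, lr,
                          skip_w = if (isTRUE(opts$tied)) mirror
                                   else integer(0))
        net <- up$net; st <- up$st
        if (isTRUE(opts$tied)) {
          for (l in seq_len(opts$code_index)) {
            net$W[[mirror[l]]] <- t(net$W[[l]])
          }
        }
        ep_loss <- ep_loss + gr$loss * length(idx)
        if (!is.null(on_step)) on_step(net)
      }
      history[ep] <- ep_loss / n
    }
    list(net = net, loss_history = history)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
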