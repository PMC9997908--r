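# Stacked-LSTM autoencoder used by the recurrent variant.
#
# Each waveform is treated as a length-T sequence of scalar amplitudes.
# The encoder stacks LSTM layers of decreasing width that return full
# sequences, then a code LSTM whose final hidden state is the latent code.
# The decoder repeats the code at every timestep, runs the mirrored LSTM
# stack, and maps each timestep through a dense tanh output unit. Batches
# are lists of n x d matrices, one per timestep; training is full
# backpropagation through time with Adam.

lstm_layer_init <- function(d_in, units) {
  lim_x <- sqrt(6 / (d_in + 4 * units))
  lim_h <- sqrt(6 / (units + 4 * units))
  b <- numeric(4 * units)
  b[(units + 1L):(2L * units)] <- 1          # forget-gate bias
  list(Wx = matrix(stats::runif(d_in * 4 * units, -lim_x, lim_x),
                   d_in, 4L * units),
       Wh = matrix(stats::runif(units * 4 * units, -lim_h, lim_h),
                   units, 4L * units),
       b = b, units = units)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Forward pass of one LSTM layer over a list-of-timesteps batch.
lstm_forward <- function(layer, Xs) {
  Tt <- length(Xs); n <- nrow(Xs[[1L]]); H <- layer$units
  h <- matrix(0, n, H); cc <- matrix(0, n, H)
  cache <- vector("list", Tt)
  Hs <- vector("list", Tt)
  for (t in seq_len(Tt)) {
    z <- sweep(Xs[[t]] %*% layer$Wx + h %*% layer$Wh, 2L, layer$b, "+")
    i <- sigmoid(z[, 1:H, drop = FALSE])
    f <- sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
    g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
    o <- sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
    c_prev <- cc
    cc <- f * c_prev + i * g
    tc <- tanh(cc)
    h <- o * tc
    cache[[t]] <- list(i = i, f = f, g = g, o = o, c = cc, c_prev = c_prev,
                       tc = tc, x = Xs[[t]], h_prev = if (t > 1L) Hs[[t - 1L]]
                                             else matrix(0, n, H))
    Hs[[t]] <- h
  }
  list(Hs = Hs, cache = cache)
}

# Backward pass; dHs is a list of gradients wrt the layer outputs (NULL
# entries allowed). Returns parameter grads and dXs.
lstm_backward <- function(layer, cache, dHs) {
  Tt <- length(cache); n <- nrow(cache[[1L]]$x); H <- layer$units
  gWx <- array(0, dim(layer$Wx)); gWh <- array(0, dim(layer$Wh))
  gb <- numeric(4 * H)
  dh_next <- matrix(0, n, H); dc_next <- matrix(0, n, H)
  dXs <- vector("list", Tt)
  for (t in Tt:1L) {
    ca <- cache[[t]]
    dh <- dh_next
    if (!is.null(dHs[[t]])) dh <- dh + dHs[[t]]
    do <- dh * ca$tc
    dc <- dh * ca$o * (1 - ca$tc^2) + dc_next
    di <- dc * ca$g
    dg <- dc * ca$i
    df <- dc * ca$c_prev
    dc_next <- dc * ca$f
    dz <- cbind(di * ca$i * (1 - ca$i), df * ca$f * (1 - ca$f),
                dg * (1 - ca$g^2), do * ca$o * (1 - ca$o))
    gWx <- gWx + crossprod(ca$x, dz)
    gWh <- gWh + crossprod(ca$h_prev, dz)
    gb <- gb + colSums(dz)
    dXs[[t]] <- dz %*% t(layer$Wx)
    dh_next <- dz %*% t(layer$Wh)
  }
  list(gWx = gWx, gWh = gWh, gb = gb, dXs = dXs)
}

lstm_ae_init <- function(enc_units, code_size, seed = NULL) {
  build <- function() {
    enc <- list(); d <- 1L
    for (u in enc_units) { enc <- c(enc, list(lstm_layer_init(d, u))); d <- u }
    code_layer <- lstm_layer_init(d, code_size)
    dec <- list(); d <- code_size
    for (u in rev(enc_units)) { dec <- c(dec, list(lstm_layer_init(d, u))); d <- u }
    lim <- sqrt(6 / (d + 1))
    list(enc = enc, code = code_layer, dec = dec,
         Wy = matrix(stats::runif(d, -lim, lim), d, 1L), by = 0)
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

waveforms_to_steps <- function(X) {
  lapply(seq_len(ncol(X)), function(t) X[, t, drop = FALSE])
}

lstm_ae_forward <- function(par, Xs) {
  seqs <- Xs; enc_caches <- vector("list", length(par$enc))
  for (l in seq_along(par$enc)) {
    fw <- lstm_forward(par$enc[[l]], seqs)
    enc_caches[[l]] <- fw$cache
    seqs <- fw$Hs
  }
  cfw <- lstm_forward(par$code, seqs)
  code <- cfw$Hs[[length(cfw$Hs)]]                    # n x code_size
  Tt <- length(Xs)
  dseqs <- rep(list(code), Tt)                        # repeat code
  dec_caches <- vector("list", length(par$dec))
  for (l in seq_along(par$dec)) {
    fw <- lstm_forward(par$dec[[l]], dseqs)
    dec_caches[[l]] <- fw$cache
    dseqs <- fw$Hs
  }
  Ys <- lapply(dseqs, function(h) tanh(sweep(h %*% par$Wy, 2L, par$by, "+")))
  list(code = code, Ys = Ys, enc_caches = enc_caches, code_cache = cfw$cache,
       dec_caches = dec_caches, dec_tops = dseqs)
}

lstm_ae_encode <- function(par, X) {
  lstm_ae_forward(par, waveforms_to_steps(X))$code
}

# Loss and full BPTT gradients for one batch (targets = inputs).
lstm_ae_grads <- function(par, X) {
  Xs <- waveforms_to_steps(X)
  fw <- lstm_ae_forward(par, Xs)
  Tt <- length(Xs); n <- nrow(X)
  loss <- 0
  dTop <- vector("list", Tt)
  gWy <- array(0, dim(par$Wy)); gby <- 0
  for (t in seq_len(Tt)) {
    err <- fw$Ys[[t]] - Xs[[t]]
    loss <- loss + sum(err^2)
    dy <- (2 * err / (n * Tt)) * (1 - fw$Ys[[t]]^2)
    gWy <- gWy + crossprod(fw$dec_tops[[t]], dy)
    gby <- gby + sum(dy)
    dTop[[t]] <- dy %*% t(par$Wy)
  }
  loss <- loss / (n * Tt)
  grads <- list(enc = vector("list", length(par$enc)),
                code = NULL, dec = vector("list", length(par$dec)),
                Wy = gWy, by = gby)
  dseq <- dTop
  for (l in rev(seq_along(par$dec))) {
    bw <- lstm_backward(par$dec[[l]], fw$dec_caches[[l]], dseq)
    grads$dec[[l]] <- bw[c("gWx", "gWh", "gb")]
    dseq <- bw$dXs
  }
  # decoder input was the code repeated at every timestep
  dcode <- Reduce(`+`, dseq)
  dHs_code <- vector("list", Tt)
  dHs_code[[Tt]] <- dcode
  bw <- lstm_backward(par$code, fw$code_cache, dHs_code)
  grads$code <- bw[c("gWx", "gWh", "gb")]
  dseq <- bw$dXs
  for (l in rev(seq_along(par$enc))) {
    bw <- lstm_backward(par$enc[[l]], fw$enc_caches[[l]], dseq)
    grads$enc[[l]] <- bw[c("gWx", "gWh", "gb")]
    dseq <- bw$dXs
  }
  list(loss = loss, grads = grads)
}

# Flatten/unflatten LSTM parameters so the generic Adam loop applies.
lstm_flatten <- function(par) {
  out <- list()
  for (l in seq_along(par$enc)) {
    out[[paste0("enc", l, ".Wx")]] <- par$enc[[l]]$Wx
    out[[paste0("enc", l, ".Wh")]] <- par$enc[[l]]$Wh
    out[[paste0("enc", l, ".b")]] <- par$enc[[l]]$b
  }
  out[["code.Wx"]] <- par$code$Wx
  out[["code.Wh"]] <- par$code$Wh
  out[["code.b"]] <- par$code$b
  for (l in seq_along(par$dec)) {
    out[[paste0("dec", l, ".Wx")]] <- par$dec[[l]]$Wx
    out[[paste0("dec", l, ".Wh")]] <- par$dec[[l]]$Wh
    out[[paste0("dec", l, ".b")]] <- par$dec[[l]]$b
  }
  out[["Wy"]] <- par$Wy
  out[["by"]] <- par$by
  out
}

lstm_apply_flat <- function(par, flat) {
  for (l in seq_along(par$enc)) {
    par$enc[[l]]$Wx <- flat[[paste0("enc", l, ".Wx")]]
    par$enc[[l]]$Wh <- flat[[paste0("enc", l, ".Wh")]]
    par$enc[[l]]$b <- as.numeric(flat[[paste0("enc", l, ".b")]])
  }
  par$code$Wx <- flat[["code.Wx"]]
  par$code$Wh <- flat[["code.Wh"]]
  par$code$b <- as.numeric(flat[["code.b"]])
  for (l in seq_along(par$dec)) {
    par$dec[[l]]$Wx <- flat[[paste0("dec", l, ".Wx")]]
    par$dec[[l]]$Wh <- flat[[paste0("dec", l, ".Wh")]]
    par$dec[[l]]$b <- as.numeric(flat[[paste0("dec", l, ".b")]])
  }
  par$Wy <- flat[["Wy"]]
  par$by <- as.numeric(flat[["by"]])
  par
}

lstm_fit <- function(par, X, epochs, lr, batch_size, seed = NULL) {
  run <- function() {
    n <- nrow(X)
    flat <- lstm_flatten(par)
    m <- lapply(flat, function(x) array(0, dim(as.array(x))))
    v <- m
    tstep <- 0L
    history <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = batch_size)) {
        idx <- perm[start:min(start + batch_size - 1L, n)]
        gr <- lstm_ae_grads(par, X[idx, , drop = FALSE])
        if (!is.finite(gr$loss)) {
          stop("non-finite loss at epoch ", ep, " (LSTM training diverged)")
        }
        gflat <- lstm_flatten(list(
          enc = lapply(gr$grads$enc,
                       function(g) list(Wx = g$gWx, Wh = g$gWh, b = g$gb)),
          code = list(Wx = gr$grads$code$gWx, Wh = gr$grads$code$gWh,
                      b = gr$grads$code$gb),
          dec = lapply(gr$grads$dec,
                       function(g) list(Wx = g$gWx, Wh = g$gWh, b = g$gb)),
          Wy = gr$grads$Wy, by = gr$grads$by))
        flat <- lstm_flatten(par)
        tstep <- tstep + 1L
        c1 <- 1 - 0.9^tstep; c2 <- 1 - 0.999^tstep
        for (nm in names(flat)) {
          g <- as.array(gflat[[nm]])
          m[[nm]] <- 0.9 * m[[nm]] + 0.1 * g
          v[[nm]] <- 0.999 * v[[nm]] + 0.001 * g^2
          upd <- lr * (m[[nm]] / c1) / (sqrt(v[[nm]] / c2) + 1e-8)
          flat[[nm]] <- flat[[nm]] - upd
        }
        par <- lstm_apply_flat(par, flat)
        ep_loss <- ep_loss + gr$loss * length(idx)
      }
      history[ep] <- ep_loss / n
    }
    list(par = par, loss_history = history)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}
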