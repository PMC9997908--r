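# Autoencoder variants: architecture, training, encoding, pretraining,
# contractive and orthogonal penalties.

test_that("variant architectures have the documented shapes", {
  deep <- build_model(ae_config("deep", input_dim = 79))
  expect_equal(n_layers(deep), 17L)            # 8 encoder + code + 8 decoder
  expect_equal(deep$config$encoder_layers,
               c(70L, 60L, 50L, 40L, 30L, 20L, 10L, 5L))
  expect_equal(deep$config$code_size, 2L)
  shallow <- build_model(ae_config("shallow", input_dim = 79))
  expect_equal(shallow$config$encoder_layers, c(60L, 40L, 20L))
  # mirrored, symmetric widths ending back at the input size
  widths <- vapply(shallow$params$W, nrow, integer(1))
  expect_equal(widths, c(79L, 60L, 40L, 20L, 2L, 20L, 40L, 60L))
  expect_equal(ncol(shallow$params$W[[8]]), 79L)
  pca_h <- ae_config("pca_hybrid", input_dim = 79)
  expect_equal(pca_h$encoder_layers, c(70L, 60L, 50L, 40L, 30L))
  expect_equal(pca_h$code_size, 20L)
})

test_that("invalid configurations are rejected", {
  expect_error(ae_config(encoder_layers = c(40, 60), input_dim = 79),
               "decreasing")
  expect_error(ae_config(encoder_layers = c(60, 1), input_dim = 79),
               "code_size")
  expect_error(ae_config(learning_rate = 0), "learning_rate")
  expect_error(ae_config(epochs = 0), "epochs")
})

test_that("tied decoder weights are transposed encoder weights at init and during training", {
  cfg <- ae_config("tied", input_dim = 31, encoder_layers = c(16L, 8L),
                   epochs = 2L, batch_size = 16L)
  m <- build_model(cfg)
  L <- length(m$params$W)
  ci <- length(cfg$encoder_layers) + 1L
  for (l in seq_len(ci)) {
    expect_identical(m$params$W[[L + 1L - l]], t(m$params$W[[l]]))
  }
  # the constraint must hold after every optimiser step, not just at the end
  sp <- prep(easy_spikes(seed = 2L, duration = 30, samples = 31L))
  violations <- 0L
  fit <- with_seed(1L, mlp_fit(
    m$params, sp$waveforms, epochs = 2L,
    lr = 0.001, batch_size = 16L, opts = train_opts(cfg),
    on_step = function(net) {
      for (l in seq_len(ci)) {
        if (!isTRUE(all.equal(net$W[[L + 1L - l]], t(net$W[[l]]))))
          violations <<- violations + 1L
      }
    }))
  expect_equal(violations, 0L)
})

test_that("training reduces the loss and is reproducible per seed", {
  sp <- prep(easy_spikes(seed = 4L, duration = 30, samples = 31L))
  cfg <- ae_config("shallow", input_dim = 31, encoder_layers = c(16L, 8L),
                   epochs = 10L)
  m1 <- train(build_model(cfg), sp, seed = 5L)
  m2 <- train(build_model(cfg), sp, seed = 5L)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_true(all(is.finite(m1$loss_history)))
  expect_lte(min(m1$loss_history), m1$loss_history[1])
  m3 <- train(build_model(cfg), sp, seed = 6L)
  expect_false(identical(m1$loss_history, m3$loss_history))
})

test_that("an autoencoder overfits a single repeated waveform", {
  tmpl <- spike_templates(1L, 31L, seed = 3L)
  w <- matrix(rep(tmpl, 40), 40, byrow = TRUE)
  sp <- scale_unit_interval(spike_set(w, 24000))
  cfg <- ae_config("shallow", input_dim = 31, encoder_layers = c(16L, 8L),
                   epochs = 200L, batch_size = 16L)
  m <- train(build_model(cfg), sp, seed = 1L)
  fw <- mlp_forward(m$params, sp$waveforms)
  rms <- sqrt(mean((fw$A[[length(fw$A)]] - sp$waveforms)^2))
  expect_lt(rms, 0.05)
})

test_that("encoding preserves order, shape, determinism and the tanh range", {
  sp <- prep(easy_spikes(seed = 4L, duration = 30, samples = 31L))
  cfg <- ae_config("shallow", input_dim = 31, encoder_layers = c(16L, 8L),
                   epochs = 5L)
  m <- train(build_model(cfg), sp, seed = 1L)
  f1 <- encode(m, sp)
  expect_equal(nrow(f1$features), n_spikes(sp))
  expect_equal(f1$d, 2L)
  expect_true(all(abs(f1$features) <= 1))
  expect_identical(f1$features, encode(m, sp)$features)
  # row i depends only on spike i
  f_sub <- encode(m, sp[3:5])
  expect_equal(f_sub$features, f1$features[3:5, , drop = FALSE])
  expect_error(encode(build_model(cfg), sp), "trained")
})

test_that("greedy pretraining stages have the documented parameter shapes", {
  cfg <- ae_config("pretrained", input_dim = 79)
  X <- prep(easy_spikes(seed = 6L, duration = 10))$waveforms
  store <- greedy_pretrain(ae_config("pretrained", input_dim = 79,
                                     pretrain_epochs = 2L), X, seed = 1L)
  # first stage: 79x70 encoder weights, 70x79 decoder weights, 70 biases
  expect_equal(dim(store$W[[1]]), c(79L, 70L))
  expect_equal(length(store$b[[1]]), 70L)
  expect_equal(dim(store$W[[length(store$W)]]), c(70L, 79L))
  # stage-1 codes have dimension 70
  codes1 <- act_fun(sweep(X %*% store$W[[1]], 2L, store$b[[1]], "+"),
                    "relu")
  expect_equal(ncol(codes1), 70L)
  # assembled initialisation matches the full model's parameter shapes
  full <- build_model(cfg)
  expect_identical(lapply(store$W, dim), lapply(full$params$W, dim))
  expect_identical(lengths(store$b), lengths(full$params$b))
})

test_that("pretraining lowers the median first-epoch loss across seeds", {
  sp <- prep(easy_spikes(seed = 7L, duration = 60, samples = 31L))
  cfg_r <- ae_config("deep", input_dim = 31,
                     encoder_layers = c(24L, 16L, 8L), epochs = 1L)
  cfg_p <- ae_config("pretrained", input_dim = 31,
                     encoder_layers = c(24L, 16L, 8L), epochs = 1L,
                     pretrain_epochs = 10L)
  first_loss <- function(cfg, seed) {
    train(build_model(cfg), sp, seed = seed)$loss_history[1]
  }
  rand <- vapply(1:5, function(s) first_loss(cfg_r, s), numeric(1))
  pre <- vapply(1:5, function(s) first_loss(cfg_p, s), numeric(1))
  expect_lte(stats::median(pre), stats::median(rand))
})

test_that("a shallow autoencoder recovers well-separated clusters", {
  sp <- prep(easy_spikes(seed = 3L, duration = 200))
  aris <- vapply(1:3, function(s) {
    m <- train(build_model(ae_config("shallow", input_dim = 79,
                                     epochs = 50L)), sp, seed = s)
    evaluate_features(encode(m, sp), sp$labels, seed = s)$ari
  }, numeric(1))
  expect_gte(stats::median(aris), 0.9)
})

test_that("contractive loss reduces to reconstruction loss at lambda 0 and is monotone in lambda", {
  set.seed(8)
  X <- matrix(runif(12), 4, 3)
  R <- X + matrix(rnorm(12, 0, 0.1), 4, 3)
  J <- lapply(1:4, function(i) matrix(rnorm(6), 2, 3))
  base <- contractive_loss(X, R, J, 0)
  expect_equal(base, sum((X - R)^2))
  l1 <- contractive_loss(X, R, J, 0.1)
  l2 <- contractive_loss(X, R, J, 0.2)
  expect_gte(l1, base)
  expect_gte(l2, l1)
  expect_error(contractive_loss(X, R, J, -1), "lambda")
})

test_that("the analytic encoder Jacobian matches finite differences", {
  # oracle: central finite differences of the encoder map
  fd_jacobian <- function(model, x, h = 1e-6) {
    f <- function(v) encode_point(model, v)
    J <- matrix(0, model$config$code_size, length(x))
    for (i in seq_along(x)) {
      xp <- x; xm <- x
      xp[i] <- xp[i] + h; xm[i] <- xm[i] - h
      J[, i] <- (f(xp) - f(xm)) / (2 * h)
    }
    J
  }
  encode_point <- function(model, v) {
    ci <- length(model$config$encoder_layers) + 1L
    a <- matrix(v, 1L)
    for (l in seq_len(ci)) {
      a <- act_fun(sweep(a %*% model$params$W[[l]], 2L,
                         model$params$b[[l]], "+"),
                   model$params$acts[l])
    }
    drop(a)
  }
  set.seed(17)
  for (layers in list(integer(0), c(7L), c(9L, 5L))) {
    cfg <- ae_config("contractive", input_dim = 11,
                     encoder_layers = layers, code_size = 2L, epochs = 1L)
    m <- build_model(cfg)
    for (rep in 1:3) {
      x <- runif(11)
      Ja <- encoder_jacobian(m, x)
      Jn <- fd_jacobian(m, x)
      pen_a <- sum(Ja^2); pen_n <- sum(Jn^2)
      expect_lt(abs(pen_a - pen_n) / max(pen_n, 1e-12), 1e-4)
    }
  }
})

test_that("training shrinks the contractive model's Jacobian norm below the plain model's", {
  sp <- prep(easy_spikes(seed = 5L, duration = 200, samples = 31L))
  mean_j2 <- function(model) {
    idx <- seq(1L, n_spikes(sp), by = 20L)
    mean(vapply(idx, function(i) {
      sum(encoder_jacobian(model, sp$waveforms[i, ])^2)
    }, numeric(1)))
  }
  layers <- c(16L, 8L)
  ratio <- vapply(1:3, function(s) {
    plain <- train(build_model(ae_config("deep", input_dim = 31,
                                         encoder_layers = layers,
                                         epochs = 20L)), sp, seed = s)
    contr <- train(build_model(ae_config("contractive", input_dim = 31,
                                         encoder_layers = layers,
                                         epochs = 20L,
                                         contractive_lambda = 0.01)),
                   sp, seed = s)
    mean_j2(contr) / mean_j2(plain)
  }, numeric(1))
  expect_lt(stats::median(ratio), 1)
})

test_that("orthogonal penalties match explicit matrix arithmetic", {
  # orthonormal columns: zero orthogonality penalty
  Q <- qr.Q(qr(matrix(rnorm(25), 5)))[, 1:3]
  codes <- matrix(rnorm(40), 20, 2)
  p <- orthogonal_penalties(Q, codes)
  expect_lt(p$orthogonality, 1e-20)
  # exactly uncorrelated code columns: zero decorrelation penalty
  u <- scale(matrix(rnorm(20), 10, 2), scale = FALSE)
  u[, 2] <- stats::residuals(stats::lm(u[, 2] ~ u[, 1]))
  expect_lt(orthogonal_penalties(Q, u)$decorrelation, 1e-20)
  # random 5x3 matrix against a direct elementwise computation
  set.seed(9)
  W <- matrix(rnorm(15), 5, 3)
  dev <- t(W) %*% W - diag(3)
  direct <- sum(dev^2)
  expect_equal(orthogonal_penalties(W, codes)$orthogonality, direct)
  cv <- stats::cov(codes)
  expect_equal(orthogonal_penalties(W, codes)$decorrelation,
               sum(cv^2) - sum(diag(cv)^2))
  expect_error(orthogonal_penalties(W, codes[1, , drop = FALSE]),
               "size 1")
})

test_that("the PCA-hybrid postmap yields ordered orthogonal 2-D components", {
  sp <- prep(easy_spikes(seed = 6L, duration = 60, samples = 31L))
  cfg <- ae_config("pca_hybrid", input_dim = 31,
                   encoder_layers = c(20L, 12L), code_size = 8L,
                   epochs = 10L)
  m <- train(build_model(cfg), sp, seed = 2L)
  expect_equal(encode(m, sp)$d, 8L)            # raw code before postmap
  fs <- pca_ae_embed(m, sp)
  expect_equal(fs$d, 2L)
  expect_gte(stats::var(fs$features[, 1]), stats::var(fs$features[, 2]))
  expect_lt(abs(stats::cor(fs$features[, 1], fs$features[, 2])), 1e-8)
})

test_that("the LSTM variant trains, encodes in-range codes and reproduces per seed", {
  sp <- prep(easy_spikes(seed = 2L, duration = 25, n_units = 3L,
                         samples = 31L))
  cfg <- ae_config("lstm", input_dim = 31, encoder_layers = c(12L, 6L),
                   epochs = 3L, batch_size = 32L)
  m1 <- train(build_model(cfg), sp, seed = 1L)
  m2 <- train(build_model(cfg), sp, seed = 1L)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_true(all(diff(m1$loss_history) < 0))  # early epochs keep improving
  f <- encode(m1, sp)
  expect_equal(dim(f$features), c(n_spikes(sp), 2L))
  expect_true(all(abs(f$features) <= 1))
})

test_that("a too-high learning rate reproduces the degenerate-feature failure", {
  sp <- prep(easy_spikes(seed = 3L, duration = 100))
  fs <- extract_features(sp, "deep",
                         config = list(epochs = 20L, learning_rate = 0.1),
                         seed = 1L)
  r <- suppressMessages(evaluate_features(fs, sp$labels, seed = 1L))
  expect_lt(abs(r$ari), 0.05)
})
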