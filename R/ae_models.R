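#' Autoencoder variant registry
#'
#' @return character vector of the recognised autoencoder variant names.
#' @export
ae_variants <- function() {
  c("shallow", "deep", "tied", "pca_hybrid", "pretrained", "lstm",
    "ft", "wft", "orthogonal", "contractive")
}

default_encoder_layers <- function(variant, input_dim, code_size) {
  widths <- switch(variant,
    shallow = c(60L, 40L, 20L),
    lstm = c(60L, 40L, 20L),
    pca_hybrid = c(70L, 60L, 50L, 40L, 30L),
    c(70L, 60L, 50L, 40L, 30L, 20L, 10L, 5L)  # the deep schedule
  )
  # the canonical schedules assume 79-dim input; for narrower inputs
  # (e.g. the Fourier half-spectrum) drop widths that no longer compress
  widths <- widths[widths < input_dim & widths > code_size]
  widths
}

#' Configuration of an autoencoder variant
#'
#' Builds a validated configuration for one of the ten variants. Defaults
#' follow the common specification: mirrored symmetric encoder/decoder,
#' rectifier (ReLU) hidden activations with hyperbolic-tangent code and
#' output layers, L1 regularisation of 1e-7 on the code activations, Adam
#' with learning rate 0.001, mean squared error loss, and 500 training
#' epochs (50 is the fast preset used throughout the examples). The deep
#' schedule is (70,60,50,40,30,20,10,5) down to a code of size 2; the
#' shallow and LSTM schedules are (60,40,20); the PCA-hybrid uses
#' (70,60,50,40,30) to a code of 20 that is later projected to 2 by PCA.
#'
#' @param variant one of [ae_variants()].
#' @param input_dim input dimensionality (waveform length, or Fourier
#'   feature length for the `ft`/`wft` variants, computed automatically
#'   when left `NULL` at training time).
#' @param encoder_layers integer widths of the encoder hidden layers,
#'   strictly decreasing and all greater than `code_size`; `NULL` uses the
#'   variant's canonical schedule.
#' @param code_size latent code width (2 for all variants except the
#'   PCA-hybrid's 20).
#' @param code_l1 L1 coefficient on code activations. The source
#'   convention "10e-7" is read as 1e-7; pass 1e-6 for the literal reading.
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size mini-batch size.
#' @param loss `"mse"` or `"contractive"`.
#' @param contractive_lambda weight of the Jacobian penalty (contractive
#'   variant).
#' @param orthogonality_weight,decorrelation_weight penalty weights of the
#'   orthogonal variant.
#' @param pretrain_epochs epochs per greedy pretraining stage (pretrained
#'   variant).
#' @param fourier_window taper for the `ft`/`wft` input transform
#'   (`"none"` for ft, `"blackman"` for wft; set automatically).
#' @return An object of class `ae_config`.
#' @export
ae_config <- function(variant = "deep", input_dim = 79L,
                      encoder_layers = NULL, code_size = NULL,
                      code_l1 = 1e-7, learning_rate = 0.001,
                      epochs = 500L, batch_size = 64L,
                      loss = NULL, contractive_lambda = 1e-4,
                      orthogonality_weight = 0.01,
                      decorrelation_weight = 0.01,
                      pretrain_epochs = 20L, fourier_window = NULL) {
  variant <- match.arg(variant, ae_variants())
  if (is.null(code_size)) {
    code_size <- if (variant == "pca_hybrid") 20L else 2L
  }
  input_dim <- as.integer(input_dim)
  if (variant %in% c("ft", "wft")) {
    input_dim <- floor(input_dim / 2L) + 1L   # real-part half-spectrum
  }
  if (is.null(encoder_layers)) {
    encoder_layers <- default_encoder_layers(variant, input_dim, code_size)
  }
  encoder_layers <- as.integer(encoder_layers)
  if (length(encoder_layers) > 1L &&
      any(diff(encoder_layers) >= 0L)) {
    stop("encoder_layers must be strictly decreasing")
  }
  if (any(encoder_layers <= code_size)) {
    stop("all encoder_layers must exceed code_size")
  }
  if (code_size < 1L) stop("code_size must be >= 1")
  if (learning_rate <= 0) stop("learning_rate must be > 0")
  if (epochs < 1L) stop("epochs must be >= 1")
  if (contractive_lambda < 0) stop("contractive_lambda must be >= 0")
  if (is.null(loss)) {
    loss <- if (variant == "contractive") "contractive" else "mse"
  }
  loss <- match.arg(loss, c("mse", "contractive"))
  if (is.null(fourier_window)) {
    fourier_window <- if (variant == "wft") "blackman" else "none"
  }
  structure(list(variant = variant, input_dim = input_dim,
                 encoder_layers = encoder_layers,
                 code_size = as.integer(code_size),
                 hidden_activation = "relu",
                 code_and_output_activation = "tanh",
                 code_l1 = code_l1, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), loss = loss,
                 contractive_lambda = contractive_lambda,
                 orthogonality_weight = orthogonality_weight,
                 decorrelation_weight = decorrelation_weight,
                 pretrain_epochs = as.integer(pretrain_epochs),
                 fourier_window = fourier_window),
            class = "ae_config")
}

mlp_widths <- function(config) {
  c(config$input_dim, config$encoder_layers, config$code_size,
    rev(config$encoder_layers), config$input_dim)
}

mlp_acts <- function(config) {
  ne <- length(config$encoder_layers)
  c(rep("relu", ne), "tanh", rep("relu", ne), "tanh")
}

train_opts <- function(config) {
  list(code_index = length(config$encoder_layers) + 1L,
       code_l1 = config$code_l1,
       contractive_lambda = if (config$loss == "contractive")
         config$contractive_lambda else 0,
       ortho_w = if (config$variant == "orthogonal")
         config$orthogonality_weight else 0,
       decor_w = if (config$variant == "orthogonal")
         config$decorrelation_weight else 0,
       tied = config$variant == "tied")
}

#' Build an (untrained) autoencoder model
#'
#' Creates the symmetric encoder/decoder network for the configured
#' variant with Glorot-initialised weights. For the tied variant, every
#' decoder weight matrix is the transpose of its mirrored encoder matrix
#' from initialisation onwards.
#'
#' @param config an [ae_config()].
#' @return An object of class `trained_encoder` with `trained = FALSE`.
#' @export
build_model <- function(config) {
  stopifnot(inherits(config, "ae_config"))
  params <- if (config$variant == "lstm") {
    lstm_ae_init(config$encoder_layers, config$code_size)
  } else {
    net <- glorot_init(mlp_widths(config))
    net$acts <- mlp_acts(config)
    if (config$variant == "tied") {
      L <- length(net$W)
      ci <- length(config$encoder_layers) + 1L
      for (l in seq_len(ci)) net$W[[L + 1L - l]] <- t(net$W[[l]])
    }
    net
  }
  structure(list(config = config, params = params, loss_history = NULL,
                 trained = FALSE, init_store = NULL, input_map = NULL,
                 postmap = NULL),
            class = "trained_encoder")
}

#' @export
print.trained_encoder <- function(x, ...) {
  cfg <- x$config
  cat("<trained_encoder> variant '", cfg$variant, "': ",
      cfg$input_dim, " -> (", paste(cfg$encoder_layers, collapse = ","),
      ") -> code ", cfg$code_size,
      if (x$trained) sprintf("  [trained, %d epochs, final loss %.4g]",
                             length(x$loss_history),
                             x$loss_history[length(x$loss_history)])
      else "  [untrained]",
      "\n", sep = "")
  invisible(x)
}

#' Number of weight-bearing layers of a model
#'
#' Counts the hidden and code layers (the convention under which the deep
#' variant totals 17: 8 encoder + code + 8 decoder).
#'
#' @param model a `trained_encoder`.
#' @return integer layer count.
#' @export
n_layers <- function(model) {
  2L * length(model$config$encoder_layers) + 1L
}

# Inputs the model actually trains on: raw waveforms, or the real part of
# the (optionally Blackman-tapered) half-spectrum for ft/wft, rescaled to
# [0,1] so the tanh output can reconstruct it. The fitted rescaling map is
# reused at encode time.
model_inputs <- function(model, spikes, fit_map = FALSE) {
  X <- as_feature_matrix(spikes)
  cfg <- model$config
  if (cfg$variant %in% c("ft", "wft")) {
    ss <- if (inherits(spikes, "spike_set")) spikes
          else spike_set(X, 1)
    X <- fourier_features(ss, fourier_spec("real",
                                           cfg$fourier_window))$features
    if (fit_map || is.null(model$input_map)) {
      r <- range(X)
      model$input_map <- c(r[1], max(r[2] - r[1], .Machine$double.eps))
    }
    X <- (X - model$input_map[1]) / model$input_map[2]
  }
  if (ncol(X) != cfg$input_dim) {
    stop("input dimension ", ncol(X), " does not match the configured ",
         cfg$input_dim)
  }
  list(X = X, model = model)
}

#' Train an autoencoder on a spike set
#'
#' Runs `config$epochs` full passes of mini-batch Adam over the (scaled)
#' waveforms; labels are never used. Weights are (re-)initialised from
#' `seed` unless the model carries a greedy pretraining initialisation, so
#' a given seed, configuration and dataset reproduce the training loss
#' history exactly. For the pretrained variant the greedy stage-wise
#' initialisation is computed first (see [greedy_pretrain()]).
#'
#' @param model a `trained_encoder` from [build_model()].
#' @param spikes a [spike_set()] (waveforms scaled to the unit interval)
#'   or a numeric matrix.
#' @param seed integer RNG seed governing initialisation and batch order.
#' @return the trained `trained_encoder`, with per-epoch `loss_history`.
#' @export
train <- function(model, spikes, seed = 1L) {
  stopifnot(inherits(model, "trained_encoder"))
  cfg <- model$config
  mi <- model_inputs(model, spikes, fit_map = TRUE)
  X <- mi$X; model <- mi$model
  if (nrow(X) < 1L) stop("empty spike set")
  if (cfg$variant == "lstm") {
    fit <- with_seed(seed, {
      par <- lstm_ae_init(cfg$encoder_layers, cfg$code_size)
      lstm_fit(par, X, cfg$epochs, cfg$learning_rate, cfg$batch_size)
    })
    model$params <- fit$par
  } else {
    fit <- with_seed(seed, {
      if (cfg$variant == "pretrained" && is.null(model$init_store)) {
        model$init_store <- greedy_pretrain(cfg, X,
                                            seed = stats::runif(1, 1, 2^30))
      }
      net <- if (!is.null(model$init_store)) {
        st <- model$init_store
        st$acts <- mlp_acts(cfg)
        st
      } else {
        glorot_init(mlp_widths(cfg))
      }
      if (is.null(net$acts)) net$acts <- mlp_acts(cfg)
      opts <- train_opts(cfg)
      if (isTRUE(opts$tied)) {
        L <- length(net$W)
        for (l in seq_len(opts$code_index)) {
          net$W[[L + 1L - l]] <- t(net$W[[l]])
        }
      }
      mlp_fit(net, X, cfg$epochs, cfg$learning_rate, cfg$batch_size, opts)
    })
    model$params <- fit$net
  }
  model$loss_history <- fit$loss_history
  model$trained <- TRUE
  model
}

#' Extract the latent code of a trained model
#'
#' Deterministically maps each spike through the encoder and returns the
#' code-layer activations, one row per input spike in input order. For the
#' PCA-hybrid variant this is the raw (e.g. 20-dimensional) code; use
#' [pca_ae_embed()] for the final 2-D embedding.
#'
#' @param model a trained `trained_encoder`.
#' @param spikes a [spike_set()] or matrix on the same scale as the
#'   training data.
#' @return a [feature_set()] of dimension `code_size`.
#' @export
encode <- function(model, spikes) {
  stopifnot(inherits(model, "trained_encoder"))
  if (!model$trained) stop("model has not been trained")
  cfg <- model$config
  X <- model_inputs(model, spikes)$X
  codes <- if (cfg$variant == "lstm") {
    lstm_ae_encode(model$params, X)
  } else {
    ci <- length(cfg$encoder_layers) + 1L
    sub <- list(W = model$params$W[seq_len(ci)],
                b = model$params$b[seq_len(ci)],
                acts = model$params$acts[seq_len(ci)])
    mlp_forward(sub, X)$A[[ci + 1L]]
  }
  feature_set(codes, method_tag = paste0("ae:", cfg$variant))
}

#' Greedy layer-wise pretraining
#'
#' Initialises a deep autoencoder stage by stage: a one-hidden-layer
#' autoencoder is trained for the first hidden width, its weights and
#' biases are saved, its codes become the next stage's input, and so on
#' down to the code size; the saved encoder and (mirrored) decoder
#' parameters are then assembled as the full model's initial values. For a
#' 79-dimensional input and first width 70 the first stage holds 79x70
#' encoder weights, 70x79 decoder weights and 70 hidden biases, and its
#' saved codes have dimension 70.
#'
#' @param config an [ae_config()] (any variant; the pretrained variant
#'   calls this automatically inside [train()]).
#' @param spikes a [spike_set()] or matrix of training inputs.
#' @param seed integer RNG seed.
#' @return a parameter store (`list(W, b)`) with exactly the shapes of
#'   [build_model()]'s parameters, with per-stage final losses in
#'   `attr(, "stage_losses")`.
#' @export
greedy_pretrain <- function(config, spikes, seed = 1L) {
  stopifnot(inherits(config, "ae_config"))
  X <- as_feature_matrix(spikes)
  dims <- c(config$input_dim, config$encoder_layers, config$code_size)
  n_stage <- length(dims) - 1L
  L <- 2L * n_stage
  W <- vector("list", L); b <- vector("list", L)
  stage_losses <- numeric(n_stage)
  with_seed(seed, {
    inp <- X
    for (k in seq_len(n_stage)) {
      hidden_act <- if (k == n_stage) "tanh" else "relu"
      net <- glorot_init(c(dims[k], dims[k + 1L], dims[k]))
      net$acts <- c(hidden_act, "linear")
      fit <- mlp_fit(net, inp, config$pretrain_epochs,
                     config$learning_rate, config$batch_size,
                     opts = list(code_index = 1L, code_l1 = 0,
                                 contractive_lambda = 0, ortho_w = 0,
                                 decor_w = 0, tied = FALSE))
      if (!all(is.finite(fit$loss_history))) {
        stop("pretraining stage ", k, " diverged")
      }
      stage_losses[k] <- fit$loss_history[length(fit$loss_history)]
      W[[k]] <- fit$net$W[[1L]]; b[[k]] <- fit$net$b[[1L]]
      W[[L + 1L - k]] <- fit$net$W[[2L]]; b[[L + 1L - k]] <- fit$net$b[[2L]]
      inp <- act_fun(sweep(inp %*% W[[k]], 2L, b[[k]], "+"), hidden_act)
    }
  })
  store <- list(W = W, b = b)
  attr(store, "stage_losses") <- stage_losses
  store
}

#' Contractive autoencoder loss
#'
#' The contractive objective sums, over the batch, the reconstruction
#' error and `lambda` times the squared Frobenius norm of the encoder
#' Jacobian: `sum_x [ L(x, g(f(x))) + lambda * ||J_f(x)||_F^2 ]`, with
#' `L` the per-sample squared error. With `lambda = 0` it reduces exactly
#' to the summed reconstruction loss.
#'
#' @param inputs,reconstructions numeric matrices, one sample per row.
#' @param code_jacobian list of per-sample encoder Jacobians
#'   (`code_size x input_dim`).
#' @param lambda non-negative penalty coefficient.
#' @return scalar loss.
#' @export
contractive_loss <- function(inputs, reconstructions, code_jacobian,
                             lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  inputs <- as.matrix(inputs); reconstructions <- as.matrix(reconstructions)
  stopifnot(all(dim(inputs) == dim(reconstructions)),
            length(code_jacobian) == nrow(inputs))
  recon <- sum((inputs - reconstructions)^2)
  pen <- sum(vapply(code_jacobian, function(J) sum(J^2), numeric(1)))
  recon + lambda * pen
}

#' Analytic encoder Jacobian
#'
#' Jacobian of the code with respect to one input, computed analytically
#' through the encoder stack (exact for the rectifier/tanh layers used
#' here; not defined for the LSTM variant).
#'
#' @param model a `trained_encoder` (trained or freshly built).
#' @param x numeric input vector of length `input_dim`.
#' @return a `code_size x input_dim` matrix.
#' @export
encoder_jacobian <- function(model, x) {
  stopifnot(inherits(model, "trained_encoder"))
  if (model$config$variant == "lstm") {
    stop("encoder_jacobian is not defined for the LSTM variant")
  }
  mlp_encoder_jacobian(model$params, x,
                       length(model$config$encoder_layers) + 1L)
}

#' Orthogonality and decorrelation penalties
#'
#' The orthogonal variant's two regularisers: the summed squared deviation
#' of `t(W) %*% W` from the identity over the given weight matrices, and
#' the summed squared off-diagonal entries of the batch code covariance.
#'
#' @param encoder_weights a list of weight matrices (or a single matrix).
#' @param codes numeric matrix of code activations, one sample per row
#'   (at least 2 rows, otherwise the covariance is undefined).
#' @return named list with elements `orthogonality` and `decorrelation`.
#' @export
orthogonal_penalties <- function(encoder_weights, codes) {
  if (is.matrix(encoder_weights)) encoder_weights <- list(encoder_weights)
  codes <- as.matrix(codes)
  if (nrow(codes) < 2L) {
    stop("decorrelation penalty is undefined for a batch of size 1")
  }
  orth <- sum(vapply(encoder_weights, function(W) {
    dev <- crossprod(W) - diag(ncol(W))
    sum(dev^2)
  }, numeric(1)))
  cv <- stats::cov(codes)
  diag(cv) <- 0
  list(orthogonality = orth, decorrelation = sum(cv^2))
}

#' Project PCA-hybrid codes to two dimensions
#'
#' The PCA-hybrid variant trains a deep autoencoder to a 20-dimensional
#' code and then projects the codes onto their top two principal
#' components.
#'
#' @param model a trained PCA-hybrid `trained_encoder`.
#' @param spikes a [spike_set()] or matrix.
#' @param n_components number of principal components (default 2).
#' @return a [feature_set()] of dimension `n_components`.
#' @export
pca_ae_embed <- function(model, spikes, n_components = 2L) {
  codes <- encode(model, spikes)$features
  if (nrow(codes) < n_components) {
    stop("fewer samples than requested components")
  }
  pr <- prcomp_signed(codes, n_components)
  feature_set(pr, method_tag = "ae:pca_hybrid+pca")
}
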