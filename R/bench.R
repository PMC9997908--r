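# Benchmark orchestration: the preprocessing -> feature extraction ->
# K-Means -> metrics pipeline, run over datasets x methods x seeds, plus
# the alignment experiment, hyperparameter sweeps and variability
# analyses. Ground-truth labels are used only for metric computation and
# for choosing k; they never reach feature extraction or clustering.

#' Registered feature-extraction methods
#'
#' @return character vector of method names usable in [run_benchmark()]
#'   and [extract_features()]: the classical baselines plus the ten
#'   autoencoder variants (prefixed freely, e.g. `"shallow"` or `"ae"`
#'   for the deep variant).
#' @export
feature_methods <- function() {
  c("pca", "ica", "isomap", ae_variants())
}

#' Extract features with a named method
#'
#' One entry point over the classical embeddings and the autoencoder
#' variants. Autoencoder methods train on the (already preprocessed)
#' waveforms with the given seed and return the code-layer embedding
#' (after the PCA postmap for the PCA-hybrid variant).
#'
#' @param spikes a preprocessed [spike_set()] (aligned, scaled to the
#'   unit interval for the autoencoders).
#' @param method one of [feature_methods()] (`"ae"` and `"deep"` are
#'   synonyms).
#' @param config named list of overrides: hyperparameters for
#'   [ae_config()] (`epochs`, `learning_rate`, `encoder_layers`, ...) or
#'   embedding parameters (`n_neighbors`, `n_components`, ...).
#' @param seed integer RNG seed.
#' @return a [feature_set()]; trained autoencoders are attached as
#'   `attr(, "model")`.
#' @export
extract_features <- function(spikes, method, config = list(), seed = 1L) {
  if (method == "ae") method <- "deep"
  method <- match.arg(method, feature_methods())
  if (method == "pca") {
    return(do.call(pca_embed, c(list(spikes), config[names(config) %in%
                                                       "n_components"])))
  }
  if (method == "ica") {
    keep <- intersect(names(config),
                      c("n_components", "contrast", "tolerance", "max_iter"))
    return(do.call(ica_embed, c(list(spikes), config[keep],
                                list(seed = seed))))
  }
  if (method == "isomap") {
    keep <- intersect(names(config),
                      c("n_neighbors", "n_components", "metric"))
    return(do.call(isomap_embed, c(list(spikes), config[keep])))
  }
  cfg_args <- config[names(config) %in% names(formals(ae_config))]
  cfg <- do.call(ae_config, c(list(variant = method,
                                   input_dim = n_samples(spikes)),
                              cfg_args))
  model <- build_model(cfg)
  model <- train(model, spikes, seed = seed)
  fs <- if (method == "pca_hybrid") pca_ae_embed(model, spikes)
        else encode(model, spikes)
  attr(fs, "model") <- model
  fs
}

# Standard preprocessing chain for a benchmark run.
preprocess_spikes <- function(spikes, config = list(), seed = 1L) {
  align <- !isFALSE(config$align)
  scale <- !isFALSE(config$scale)
  shuffle <- !isFALSE(config$shuffle)
  if (align) spikes <- align_spikes(spikes, alignment_spec())
  if (scale) spikes <- scale_unit_interval(spikes)
  if (shuffle) spikes <- shuffle_spikes(spikes, seed = seed)
  spikes
}

bench_log <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S"), " | ", ...)
}

metric_row <- function(dataset, method, seed, rep, note = "") {
  data.frame(dataset = dataset, method = method, seed = seed,
             ari = rep$ari, ami = rep$ami, vm = rep$vm, dbs = rep$dbs,
             chs = rep$chs, ss = rep$ss, note = note,
             stringsAsFactors = FALSE)
}

failed_row <- function(dataset, method, seed, msg) {
  data.frame(dataset = dataset, method = method, seed = seed,
             ari = NA_real_, ami = NA_real_, vm = NA_real_, dbs = NA_real_,
             chs = NA_real_, ss = NA_real_, note = paste0("error: ", msg),
             stringsAsFactors = FALSE)
}

#' Run the method-comparison benchmark
#'
#' For every dataset x method x seed combination: preprocess (align to the
#' middle, scale to the unit interval, shuffle), extract features, cluster
#' with K-Means at k = number of ground-truth clusters (or `config$k` for
#' unlabeled data), and compute the six metrics with the internal ones on
#' the ground-truth labels where available. Failures are recorded in the
#' row's `note` and the run continues. The aggregate Borda ranking is
#' computed from the per-method mean of each metric over datasets and
#' seeds (only when all methods have complete rows).
#'
#' @param datasets named list of [spike_set()] objects (or a single one).
#' @param methods character vector from [feature_methods()].
#' @param config named list: preprocessing switches (`align`, `scale`,
#'   `shuffle`), `k` for unlabeled data, and method hyperparameter
#'   overrides (see [extract_features()]).
#' @param seeds integer vector of seeds.
#' @param verbose log per-stage progress to stderr.
#' @return An object of class `benchmark_table`: list with `rows` (one
#'   data frame row per combination) and `aggregate` (Borda ranking or
#'   `NULL`).
#' @export
run_benchmark <- function(datasets, methods, config = list(), seeds = 1L,
                          verbose = FALSE) {
  if (inherits(datasets, "spike_set")) datasets <- list(dataset1 = datasets)
  if (is.null(names(datasets))) {
    names(datasets) <- paste0("dataset", seq_along(datasets))
  }
  rows <- list()
  for (ds_name in names(datasets)) {
    ds <- datasets[[ds_name]]
    for (seed in seeds) {
      pre <- preprocess_spikes(ds, config, seed = seed)
      k <- if (!is.null(pre$labels)) length(unique(pre$labels))
           else if (!is.null(config$k)) config$k
           else stop("dataset '", ds_name, "' is unlabeled: set config$k")
      for (method in methods) {
        t0 <- Sys.time()
        row <- tryCatch({
          fs <- extract_features(pre, method, config = config, seed = seed)
          rep <- evaluate_features(fs, pre$labels, k = k, seed = seed)
          metric_row(ds_name, method, seed, rep,
                     note = sprintf("%.2fs",
                                    as.numeric(Sys.time() - t0,
                                               units = "secs")))
        }, error = function(e) {
          failed_row(ds_name, method, seed, conditionMessage(e))
        })
        bench_log(verbose, ds_name, " ", method, " seed ", seed, " ",
                  row$note)
        rows[[length(rows) + 1L]] <- row
      }
    }
  }
  rows <- do.call(rbind, rows)
  aggregate <- NULL
  ok <- stats::complete.cases(rows[, c("ari", "ami", "vm", "dbs", "chs",
                                       "ss")])
  if (all(ok)) {
    mean_scores <- stats::aggregate(
      rows[, c("ari", "ami", "vm", "dbs", "chs", "ss")],
      by = list(method = rows$method), FUN = mean)
    m <- as.matrix(mean_scores[, -1L])
    rownames(m) <- mean_scores$method
    aggregate <- borda_aggregate(m)
  }
  structure(list(rows = rows, aggregate = aggregate),
            class = "benchmark_table")
}

#' @export
print.benchmark_table <- function(x, ...) {
  cat("<benchmark_table> ", nrow(x$rows), " rows\n", sep = "")
  print(utils::head(x$rows, 12L))
  if (!is.null(x$aggregate)) {
    cat("Borda aggregate:\n")
    print(x$aggregate)
  }
  invisible(x)
}

#' Serialize a benchmark table to delimited text
#'
#' @param table a `benchmark_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_benchmark_table <- function(table, path) {
  utils::write.table(table$rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Alignment impact experiment
#'
#' Runs the identical pipeline once per alignment condition (including
#' "none") for each method and seed, reporting all six metrics, to
#' quantify how peak alignment changes embedding quality on jittered
#' data.
#'
#' @param dataset a labeled [spike_set()].
#' @param methods character vector of methods.
#' @param align_specs named list of [alignment_spec()] or `NULL` entries
#'   (`NULL` = unaligned); default compares none vs middle alignment.
#' @param seeds integer vector of seeds.
#' @param config method hyperparameter overrides.
#' @return a `benchmark_table` whose `dataset` column names the alignment
#'   condition.
#' @export
alignment_experiment <- function(dataset, methods,
                                 align_specs = list(
                                   unaligned = NULL,
                                   aligned = alignment_spec()),
                                 seeds = 1L, config = list()) {
  stopifnot(!is.null(dataset$labels))
  rows <- list()
  for (cond in names(align_specs)) {
    sp <- align_specs[[cond]]
    ds <- if (is.null(sp)) dataset else align_spikes(dataset, sp)
    cfg <- utils::modifyList(config, list(align = FALSE))
    bt <- run_benchmark(stats::setNames(list(ds), cond), methods,
                        config = cfg, seeds = seeds)
    rows[[cond]] <- bt$rows
  }
  structure(list(rows = do.call(rbind, rows), aggregate = NULL),
            class = "benchmark_table")
}

#' Epoch / learning-rate sweep
#'
#' Runs the full pipeline for one autoencoder variant across a value grid
#' of one hyperparameter axis, tabulating the six metrics per value and
#' seed. Per-value training loss histories are attached as
#' `attr(, "loss_histories")` for loss-curve inspection.
#'
#' @param dataset a labeled [spike_set()].
#' @param variant an autoencoder variant name.
#' @param axis `"epochs"` or `"learning_rate"`.
#' @param values numeric vector of axis values (non-empty).
#' @param seeds integer vector of seeds.
#' @param config further hyperparameter overrides.
#' @return a `benchmark_table`; the `dataset` column names the axis
#'   value.
#' @export
hyperparameter_sweep <- function(dataset, variant, axis, values,
                                 seeds = 1L, config = list()) {
  axis <- match.arg(axis, c("epochs", "learning_rate"))
  stopifnot(length(values) > 0L, !is.null(dataset$labels))
  pre <- preprocess_spikes(dataset, config, seed = seeds[1L])
  k <- length(unique(pre$labels))
  rows <- list(); histories <- list()
  for (v in values) {
    cfg <- utils::modifyList(config, stats::setNames(list(v), axis))
    tag <- paste0(axis, "=", format(v))
    for (seed in seeds) {
      row <- tryCatch({
        fs <- extract_features(pre, variant, config = cfg, seed = seed)
        model <- attr(fs, "model")
        if (!is.null(model)) {
          histories[[paste0(tag, ";seed=", seed)]] <- model$loss_history
        }
        rep <- evaluate_features(fs, pre$labels, k = k, seed = seed)
        metric_row(tag, variant, seed, rep)
      }, error = function(e) {
        failed_row(tag, variant, seed, conditionMessage(e))
      })
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- structure(list(rows = do.call(rbind, rows), aggregate = NULL),
                   class = "benchmark_table")
  attr(out, "loss_histories") <- histories
  out
}

#' Run-to-run variability analysis
#'
#' `stage = "clustering"` re-runs K-Means with `n_runs` different seeds on
#' one fixed embedding, isolating the clustering's own variability;
#' `stage = "full"` re-trains the feature extractor each run as well.
#' Returns per-metric distribution summaries; optionally the unbounded
#' internal scores (Davies-Bouldin, Calinski-Harabasz) are rescaled to
#' `[0, 1]` by their maximum across runs.
#'
#' @param dataset a labeled [spike_set()].
#' @param method a method name.
#' @param n_runs number of repetitions (>= 2).
#' @param stage `"clustering"` or `"full"`.
#' @param config method hyperparameter overrides.
#' @param rescale_internal rescale `dbs`/`chs` by their max across runs.
#' @return list with `runs` (per-run metric data frame) and `summary`
#'   (min/median/mean/max per metric).
#' @export
variability_analysis <- function(dataset, method, n_runs = 10L,
                                 stage = c("clustering", "full"),
                                 config = list(),
                                 rescale_internal = FALSE) {
  stage <- match.arg(stage)
  stopifnot(n_runs >= 2L, !is.null(dataset$labels))
  pre <- preprocess_spikes(dataset, config, seed = 1L)
  k <- length(unique(pre$labels))
  if (stage == "clustering") {
    fs <- extract_features(pre, method, config = config, seed = 1L)
  }
  rows <- lapply(seq_len(n_runs), function(seed) {
    if (stage == "full") {
      fs <- extract_features(pre, method, config = config, seed = seed)
    }
    rep <- evaluate_features(fs, pre$labels, k = k, seed = seed)
    metric_row(stage, method, seed, rep)
  })
  runs <- do.call(rbind, rows)
  metrics <- c("ari", "ami", "vm", "dbs", "chs", "ss")
  if (rescale_internal) {
    for (mcol in c("dbs", "chs")) {
      mx <- max(runs[[mcol]], na.rm = TRUE)
      if (is.finite(mx) && mx > 0) runs[[mcol]] <- runs[[mcol]] / mx
    }
  }
  summary <- do.call(rbind, lapply(metrics, function(mcol) {
    v <- runs[[mcol]]
    data.frame(metric = mcol, min = min(v), median = stats::median(v),
               mean = mean(v), max = max(v))
  }))
  list(runs = runs, summary = summary)
}

#' Read / write a benchmark run configuration
#'
#' Configurations are nested key-value YAML documents covering dataset
#' specs, preprocessing switches, method hyperparameters, seeds and output
#' paths, so that a config file plus a seed list fully determines a
#' benchmark table.
#'
#' @param path YAML file path.
#' @param config named list to write.
#' @return `read_bench_config()` returns the named list;
#'   `write_bench_config()` returns `path` invisibly.
#' @export
read_bench_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_bench_config
#' @export
write_bench_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}
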