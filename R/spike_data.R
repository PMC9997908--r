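#' Labeled spike waveform set
#'
#' Container for a set of extracellular spike waveforms cut to a common
#' length, with the sampling rate and, when available, ground-truth unit
#' labels. Label `0` is reserved for the multi-unit cluster (the composite
#' low-amplitude background activity); single units use positive integers.
#' All sample indices in this package are 1-based, as is usual in R.
#'
#' @param waveforms numeric matrix, one spike per row (amplitude in
#'   arbitrary units); all spikes must have the same number of samples.
#' @param sampling_rate sampling rate in Hz.
#' @param labels optional integer vector of unit labels, one per spike;
#'   non-negative, with 0 reserved for multi-unit activity.
#' @param peak_indices optional integer vector giving the sample index of
#'   each spike's reference peak, in `[1, n_samples]`.
#' @param starts optional integer vector giving the start sample of each
#'   spike's window in the source recording (used to re-cut windows when
#'   aligning against the continuous signal).
#' @param source free-text provenance tag.
#' @return An object of class `spike_set`.
#' @export
spike_set <- function(waveforms, sampling_rate, labels = NULL,
                      peak_indices = NULL, starts = NULL, source = "") {
  if (!is.matrix(waveforms)) waveforms <- matrix(waveforms, nrow = 1L)
  storage.mode(waveforms) <- "double"
  n <- nrow(waveforms)
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop("`sampling_rate` must be a single positive number (Hz)")
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != n) {
      stop("`labels` must have one entry per spike (", n, "), got ",
           length(labels))
    }
    if (anyNA(labels) || any(labels < 0L)) {
      stop("`labels` must be non-negative integers (0 = multi-unit)")
    }
  }
  if (!is.null(peak_indices)) {
    peak_indices <- as.integer(peak_indices)
    if (length(peak_indices) != n) {
      stop("`peak_indices` must have one entry per spike")
    }
    if (any(peak_indices < 1L | peak_indices > ncol(waveforms))) {
      stop("`peak_indices` must lie in [1, n_samples]")
    }
  }
  if (!is.null(starts)) {
    starts <- as.integer(starts)
    if (length(starts) != n) stop("`starts` must have one entry per spike")
  }
  structure(
    list(waveforms = waveforms, sampling_rate = sampling_rate,
         labels = labels, peak_indices = peak_indices, starts = starts,
         source = source),
    class = "spike_set"
  )
}

#' @export
print.spike_set <- function(x, ...) {
  cat("<spike_set> ", nrow(x$waveforms), " spikes x ", ncol(x$waveforms),
      " samples @ ", x$sampling_rate, " Hz\n", sep = "")
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat("  labels: ", length(tab), " units (",
        paste0(names(tab), ":", as.integer(tab), collapse = " "), ")\n",
        sep = "")
  } else {
    cat("  labels: none\n")
  }
  if (nzchar(x$source)) cat("  source: ", x$source, "\n", sep = "")
  invisible(x)
}

#' Number of spikes / samples in a spike set
#' @param x a `spike_set`.
#' @return integer count.
#' @export
n_spikes <- function(x) nrow(x$waveforms)

#' @rdname n_spikes
#' @export
n_samples <- function(x) ncol(x$waveforms)

#' Subset a spike set by spike index
#' @param x a `spike_set`.
#' @param i integer indices of spikes to keep.
#' @param ... unused.
#' @return a `spike_set` with the selected spikes, all per-spike fields
#'   subset consistently.
#' @export
`[.spike_set` <- function(x, i, ...) {
  spike_set(x$waveforms[i, , drop = FALSE], x$sampling_rate,
            labels = if (!is.null(x$labels)) x$labels[i],
            peak_indices = if (!is.null(x$peak_indices)) x$peak_indices[i],
            starts = if (!is.null(x$starts)) x$starts[i],
            source = x$source)
}

#' Simulation specification for synthetic spike data
#'
#' Parameters of the synthetic ground-truth generator, mirroring the
#' statistical structure of the public benchmark simulations: a number of
#' single units with distinct waveform shapes whose per-spike amplitudes
#' follow a normal distribution rescaled into `[amplitude_low,
#' amplitude_high]`, plus one composite multi-unit cluster mixing
#' `multiunit_n_shapes` shapes at the fixed low amplitude
#' `multiunit_amplitude`. Units fire as independent Poisson processes with
#' mean rates drawn between `rate_low` and `rate_high` Hz (each multi-unit
#' component at `multiunit_unit_rate` Hz), and events are thinned so that
#' consecutive spikes are at least `min_separation` seconds apart.
#'
#' @param n_single_units number of single units.
#' @param samples_per_spike samples per waveform (default 79, i.e. ~3.3 ms
#'   at 24 kHz).
#' @param sampling_rate sampling rate in Hz.
#' @param amplitude_low,amplitude_high range the single-unit amplitudes
#'   span (unitless): unit mean amplitudes are spread across this interval
#'   (emulating different distances to the electrode) and per-spike
#'   amplitudes vary normally around them, truncated to the interval.
#' @param amplitude_sd per-spike standard deviation of the normal
#'   amplitude variation around each unit's mean.
#' @param multiunit_amplitude fixed amplitude of multi-unit spikes.
#' @param multiunit_n_shapes number of distinct shapes mixed into the
#'   multi-unit cluster.
#' @param rate_low,rate_high bounds for per-unit mean firing rates (Hz).
#' @param multiunit_unit_rate mean firing rate (Hz) of each multi-unit
#'   component neuron (composite rate = `multiunit_n_shapes` times this).
#' @param min_separation minimum time between consecutive spikes (s).
#' @param duration recording duration (s).
#' @param noise_sd standard deviation of the additive Gaussian background
#'   noise, on the same unitless scale as the amplitudes.
#' @param peak_jitter uniform jitter of the peak position, in samples
#'   (`0` means every waveform peaks exactly at the window middle).
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_single_units = 5L, samples_per_spike = 79L,
                            sampling_rate = 24000, amplitude_low = 0.9,
                            amplitude_high = 2.0, amplitude_sd = 0.05,
                            multiunit_amplitude = 0.5,
                            multiunit_n_shapes = 20L, rate_low = 0.1,
                            rate_high = 2.0, multiunit_unit_rate = 0.25,
                            min_separation = 0.0003, duration = 600,
                            noise_sd = 0.1, peak_jitter = 0L) {
  spec <- list(n_single_units = as.integer(n_single_units),
               samples_per_spike = as.integer(samples_per_spike),
               sampling_rate = sampling_rate,
               amplitude_low = amplitude_low,
               amplitude_high = amplitude_high,
               amplitude_sd = amplitude_sd,
               multiunit_amplitude = multiunit_amplitude,
               multiunit_n_shapes = as.integer(multiunit_n_shapes),
               rate_low = rate_low, rate_high = rate_high,
               multiunit_unit_rate = multiunit_unit_rate,
               min_separation = min_separation, duration = duration,
               noise_sd = noise_sd, peak_jitter = as.integer(peak_jitter))
  class(spec) <- "simulation_spec"
  validate_simulation_spec(spec)
  spec
}

validate_simulation_spec <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$amplitude_low >= spec$amplitude_high) {
    stop("amplitude_low must be < amplitude_high")
  }
  if (spec$min_separation < 0) stop("min_separation must be >= 0")
  if (spec$amplitude_sd < 0) stop("amplitude_sd must be >= 0")
  if (spec$rate_low <= 0 || spec$rate_high <= 0 ||
      spec$multiunit_unit_rate <= 0) {
    stop("all firing rates must be > 0")
  }
  if (spec$rate_low > spec$rate_high) stop("rate_low must be <= rate_high")
  if (spec$samples_per_spike < 3L) stop("samples_per_spike must be >= 3")
  if (spec$n_single_units < 1L) stop("n_single_units must be >= 1")
  if (spec$duration <= 0) stop("duration must be > 0")
  if (spec$noise_sd < 0) stop("noise_sd must be >= 0")
  if (spec$peak_jitter < 0) stop("peak_jitter must be >= 0")
  invisible(spec)
}

#' Continuous extracellular recording
#'
#' A single-channel continuous signal, optionally carrying the ground-truth
#' spike peak positions (sample indices) and unit labels used to generate
#' it.
#'
#' @param signal numeric vector of amplitudes.
#' @param sampling_rate sampling rate in Hz.
#' @param true_spike_times optional strictly increasing integer sample
#'   indices of the true spike peaks.
#' @param true_labels optional integer unit labels, same length as
#'   `true_spike_times`.
#' @return An object of class `spike_recording`.
#' @export
spike_recording <- function(signal, sampling_rate, true_spike_times = NULL,
                            true_labels = NULL) {
  signal <- as.numeric(signal)
  if (!is.null(true_spike_times)) {
    true_spike_times <- as.integer(true_spike_times)
    if (is.unsorted(true_spike_times, strictly = TRUE)) {
      stop("`true_spike_times` must be strictly increasing")
    }
    if (!is.null(true_labels) &&
        length(true_labels) != length(true_spike_times)) {
      stop("`true_labels` must match `true_spike_times` in length")
    }
  }
  structure(list(signal = signal, sampling_rate = sampling_rate,
                 true_spike_times = true_spike_times,
                 true_labels = if (!is.null(true_labels))
                   as.integer(true_labels)),
            class = "spike_recording")
}

#' @export
print.spike_recording <- function(x, ...) {
  cat("<spike_recording> ", length(x$signal), " samples @ ",
      x$sampling_rate, " Hz (", round(length(x$signal) / x$sampling_rate, 2),
      " s)\n", sep = "")
  if (!is.null(x$true_spike_times)) {
    cat("  ground truth: ", length(x$true_spike_times), " spikes\n",
        sep = "")
  }
  invisible(x)
}

#' Low-dimensional feature embedding of a spike set
#'
#' @param features numeric matrix, one row per source spike (order
#'   preserved).
#' @param method_tag provenance string naming the method that produced the
#'   embedding.
#' @return An object of class `feature_set`.
#' @export
feature_set <- function(features, method_tag = "") {
  if (!is.matrix(features)) features <- as.matrix(features)
  storage.mode(features) <- "double"
  structure(list(features = features, d = ncol(features),
                 method_tag = method_tag),
            class = "feature_set")
}

#' @export
print.feature_set <- function(x, ...) {
  cat("<feature_set> ", nrow(x$features), " x ", x$d,
      if (nzchar(x$method_tag)) paste0("  [", x$method_tag, "]"), "\n",
      sep = "")
  invisible(x)
}

# Coerce spike_set / feature_set / matrix to a plain numeric matrix.
as_feature_matrix <- function(x) {
  if (inherits(x, "feature_set")) return(x$features)
  if (inherits(x, "spike_set")) return(x$waveforms)
  as.matrix(x)
}
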