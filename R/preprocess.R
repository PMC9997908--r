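#' Alignment specification
#'
#' Describes how spike waveforms are aligned to a common reference point.
#' The shift of each spike's window follows
#' `new_start = old_start - (index_align - peak)`, where `peak` is the
#' sample index of the chosen reference extremum within the waveform and
#' `index_align` the target index it is moved to. Aligning to the window
#' middle (the default, `floor(n_samples/2) + 1`) retains information about
#' both the pre- and post-peak course of the spike.
#'
#' @param index_align target sample index (1-based); `NULL` means the
#'   window middle of the data being aligned.
#' @param reference which extremum to align: `"maximum"` or `"minimum"`
#'   peak.
#' @param mode `"shift"` moves the waveform within its fixed window,
#'   replicating edge values into vacated samples (usable when only
#'   extracted waveforms exist); `"recut"` re-cuts the window from the
#'   continuous signal, skipping spikes whose shifted window would leave
#'   the signal.
#' @return An object of class `alignment_spec`.
#' @export
alignment_spec <- function(index_align = NULL,
                           reference = c("maximum", "minimum"),
                           mode = c("shift", "recut")) {
  structure(list(index_align = if (!is.null(index_align))
                   as.integer(index_align),
                 reference = match.arg(reference),
                 mode = match.arg(mode)),
            class = "alignment_spec")
}

#' Align spike waveforms to a common reference index
#'
#' Shifts every waveform so that its reference peak sits at
#' `spec$index_align`. Waveform length and labels are preserved. In
#' `"recut"` mode the window is re-cut from `signal` using the stored
#' window starts; spikes whose re-cut window would exceed the signal are
#' skipped (with a message). Flat waveforms with tied extrema use the first
#' occurrence (reported via a message). Aligning already-aligned data is a
#' no-op, so the operation is idempotent.
#'
#' @param spikes a [spike_set()].
#' @param spec an [alignment_spec()].
#' @param signal optional [spike_recording()] required for `mode =
#'   "recut"` (together with `spikes$starts`).
#' @return an aligned [spike_set()] with updated `peak_indices`.
#' @export
align_spikes <- function(spikes, spec = alignment_spec(), signal = NULL) {
  w <- spikes$waveforms
  n <- nrow(w); p <- ncol(w)
  if (n == 0L) return(spikes)
  target <- if (is.null(spec$index_align)) floor(p / 2) + 1L
            else spec$index_align
  if (target < 1L || target > p) {
    stop("index_align must lie in [1, ", p, "]")
  }
  peaks <- if (spec$reference == "maximum") {
    max.col(w, ties.method = "first")
  } else {
    max.col(-w, ties.method = "first")
  }
  ext <- w[cbind(seq_len(n), peaks)]
  n_ties <- sum(rowSums(w == ext) > 1L)
  if (n_ties > 0L) {
    message(n_ties, " waveform(s) with tied extrema; first occurrence used")
  }
  shifts <- target - peaks
  if (spec$mode == "shift" || is.null(signal)) {
    if (spec$mode == "recut") {
      stop("mode = 'recut' requires the continuous `signal` and stored ",
           "window starts")
    }
    for (i in which(shifts != 0L)) w[i, ] <- shift_pad(w[i, ], shifts[i])
    out <- spikes
    out$waveforms <- w
    out$peak_indices <- rep.int(target, n)
    return(out)
  }
  # recut mode: new_start = old_start - (index_align - peak)
  if (is.null(spikes$starts)) {
    stop("mode = 'recut' requires window `starts` on the spike set")
  }
  new_starts <- spikes$starts - shifts
  ok <- new_starts >= 1L & new_starts + p - 1L <= length(signal$signal)
  if (any(!ok)) {
    message(sum(!ok), " spike(s) shifted outside the signal; skipped")
  }
  keep <- which(ok)
  w2 <- t(vapply(new_starts[keep],
                 function(s) signal$signal[s:(s + p - 1L)], numeric(p)))
  if (length(keep) == 0L) w2 <- matrix(numeric(0), 0L, p)
  spike_set(w2, spikes$sampling_rate,
            labels = if (!is.null(spikes$labels)) spikes$labels[keep],
            peak_indices = rep.int(target, length(keep)),
            starts = new_starts[keep], source = spikes$source)
}

#' Scale a spike set to the unit interval
#'
#' Applies a single global min-max affine map so that the whole dataset
#' spans exactly `[0, 1]`. Scaling is global (per dataset) rather than
#' per spike: a per-spike map would destroy the amplitude differences that
#' separate clusters. The fitted map is stored in `attr(, "scale_map")`
#' (`c(offset, range)`) and can be reused to transform further data from
#' the same recording on the same scale.
#'
#' @param spikes a [spike_set()].
#' @param map optional previously fitted map `c(offset, range)` to reuse
#'   instead of fitting.
#' @return the rescaled [spike_set()] with the map attached.
#' @export
scale_unit_interval <- function(spikes, map = NULL) {
  w <- spikes$waveforms
  if (is.null(map)) {
    r <- range(w)
    if (r[1] == r[2]) {
      stop("constant dataset: unit-interval scale is undefined")
    }
    map <- c(offset = r[1], range = r[2] - r[1])
  }
  out <- spikes
  out$waveforms <- (w - map[[1]]) / map[[2]]
  attr(out, "scale_map") <- map
  out
}

#' Randomly shuffle the spikes of a set
#'
#' Permutes waveforms and all per-spike fields by one common random
#' permutation. The benchmark simulations store spikes ordered by cluster,
#' so shuffling is needed before mini-batch training on them; it is a
#' no-op statistically for already unordered data. Deterministic per seed.
#'
#' @param spikes a [spike_set()].
#' @param seed integer RNG seed.
#' @return the permuted [spike_set()].
#' @export
shuffle_spikes <- function(spikes, seed = 1L) {
  perm <- with_seed(seed, sample.int(n_spikes(spikes)))
  spikes[perm]
}

#' Fourier descriptor specification
#'
#' @param part which frequency-domain descriptor to return over the
#'   non-redundant half-spectrum: `"real"`, `"imaginary"`, `"magnitude"`,
#'   `"phase"`, `"power"` (magnitude squared), or `"concatenation"` (real
#'   and imaginary parts stacked).
#' @param window taper applied before the transform: `"none"` or
#'   `"blackman"` (amplifies the centre of the window, where aligned peaks
#'   sit).
#' @return An object of class `fourier_spec`.
#' @export
fourier_spec <- function(part = c("real", "imaginary", "magnitude",
                                  "phase", "power", "concatenation"),
                         window = c("none", "blackman")) {
  structure(list(part = match.arg(part), window = match.arg(window)),
            class = "fourier_spec")
}

#' Fourier-domain features of spike waveforms
#'
#' Computes the discrete Fourier transform of each waveform (after an
#' optional Blackman taper) via the FFT and returns the selected descriptor
#' over the non-redundant half-spectrum (`floor(n/2) + 1` bins). The phase
#' of an exactly zero bin is reported as 0 (R's `Arg(0)` convention).
#'
#' @param spikes a [spike_set()].
#' @param spec a [fourier_spec()].
#' @return a [feature_set()], one row per spike.
#' @export
fourier_features <- function(spikes, spec = fourier_spec()) {
  w <- spikes$waveforms
  p <- ncol(w)
  if (p < 2L) stop("waveform length must be >= 2")
  if (spec$window == "blackman") {
    w <- w * rep(signal::blackman(p), each = nrow(w))
  }
  ft <- stats::mvfft(t(w))              # p x n, spikes in columns
  half <- ft[seq_len(floor(p / 2) + 1L), , drop = FALSE]
  feats <- switch(spec$part,
    real = t(Re(half)),
    imaginary = t(Im(half)),
    magnitude = t(Mod(half)),
    phase = t(Arg(half)),
    power = t(Mod(half)^2),
    concatenation = cbind(t(Re(half)), t(Im(half)))
  )
  feature_set(feats, method_tag = paste0("fourier:", spec$part,
                                         if (spec$window != "none")
                                           paste0("+", spec$window)))
}
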