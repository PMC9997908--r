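#' Detect spikes in a continuous recording
#'
#' Standard amplitude-threshold detection front-end: the signal is band-pass
#' filtered with a bidirectional (forward-backward, zero-phase) Butterworth
#' IIR filter, an amplitude threshold is set at `threshold_k` standard
#' deviations of the filtered signal, and each suprathreshold excursion of
#' the absolute filtered signal yields one detection at its absolute peak,
#' followed by a refractory lockout. A fixed-length window centred on each
#' detected peak is cut from the filtered signal.
#'
#' The default threshold of 4 SD sits in the 3-5 SD range conventional for
#' extracellular recordings; the default lockout equals the generator's
#' default minimum inter-spike separation (0.3 ms).
#'
#' @param rec a [spike_recording()].
#' @param band_low,band_high band-pass corner frequencies in Hz (defaults
#'   300 and 7000).
#' @param filter_order Butterworth order (default 3; applied bidirectionally
#'   the effective order doubles).
#' @param threshold_k threshold in multiples of the filtered signal's SD.
#' @param window window length in samples cut around each detected peak.
#' @param lockout refractory lockout in samples after a detected peak;
#'   default `round(0.0003 * sampling_rate)`.
#' @return an unlabeled [spike_set()] of detected waveforms; detected peak
#'   sample indices are in `attr(, "detected_times")`.
#' @export
detect_spikes <- function(rec, band_low = 300, band_high = 7000,
                          filter_order = 3L, threshold_k = 4,
                          window = 79L, lockout = NULL) {
  fs <- rec$sampling_rate
  if (!(band_low < band_high && band_high < fs / 2)) {
    stop("need band_low < band_high < sampling_rate / 2 (got ",
         band_low, ", ", band_high, " at fs = ", fs, ")")
  }
  if (is.null(lockout)) lockout <- max(1L, round(0.0003 * fs))
  bf <- signal::butter(filter_order, c(band_low, band_high) / (fs / 2),
                       type = "pass")
  filtered <- as.numeric(signal::filtfilt(bf, rec$signal))
  thr <- threshold_k * stats::sd(filtered)
  a <- abs(filtered)
  idx <- which(a > thr)
  peaks <- integer(0)
  if (length(idx) > 0L) {
    # suprathreshold samples separated by more than the lockout belong to
    # distinct events; each event is detected at its absolute peak
    grp <- cumsum(c(1L, diff(idx) > lockout))
    peaks <- vapply(split(idx, grp),
                    function(ii) ii[which.max(a[ii])], integer(1))
    peaks <- unname(peaks)
  }
  out <- cut_windows(spike_recording(filtered, fs), peaks, window)
  out$source <- "detect_spikes"
  # keep detected times only for windows that were actually cut
  kept <- (peaks - floor(window / 2)) %in% out$starts
  attr(out, "detected_times") <- peaks[kept]
  out
}
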