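#' Default variable mapping for benchmark simulation files
#'
#' The public simulation files do not document a single variable layout, so
#' the mapping from roles to MAT variable names is configurable. The
#' defaults below are a documented guess covering the common distribution:
#' either an extracted waveform matrix plus labels, or a continuous trace
#' plus ground-truth spike times and classes.
#'
#' @return named list mapping roles (`waveforms`, `labels`, `signal`,
#'   `spike_times`, `spike_classes`, `sampling_rate`) to variable names.
#' @export
default_field_map <- function() {
  list(waveforms = "spikes", labels = "cluster_class", signal = "data",
       spike_times = "spike_times", spike_classes = "spike_class",
       sampling_rate = "sr")
}

#' Load a benchmark simulation file
#'
#' Reads a MAT-dialect simulation container under a configurable variable
#' mapping. If a waveform matrix is present it is used directly together
#' with its labels; otherwise 79-sample (or `window`-sample) windows are cut
#' from the continuous trace around each ground-truth spike time. The
#' multi-unit class is mapped to label 0 (it already is 0 in the public
#' files). Ground-truth times are interpreted as peak positions with
#' `floor(window/2)` pre-peak samples; windows that would cross the signal
#' edge are skipped and counted in a message.
#'
#' @param path path to the MAT file.
#' @param field_map role-to-variable-name mapping, see
#'   [default_field_map()]; unknown layouts fail with the missing mapped
#'   variable named rather than guessing.
#' @param sampling_rate sampling rate in Hz, used when the file does not
#'   carry one (default 24000, the benchmark simulations' rate).
#' @param window window length when cutting from a continuous trace.
#' @return a labeled [spike_set()].
#' @export
load_simulation <- function(path, field_map = default_field_map(),
                            sampling_rate = 24000, window = 79L) {
  if (!file.exists(path)) stop("file not found: ", path)
  vars <- read_mat(path)
  fm <- utils::modifyList(default_field_map(), field_map)
  unwrap <- function(x) {
    while (is.list(x) && length(x) == 1L) x <- x[[1L]]
    x
  }
  fs <- if (!is.null(vars[[fm$sampling_rate]])) {
    as.numeric(unwrap(vars[[fm$sampling_rate]]))[1L]
  } else sampling_rate
  if (!is.null(vars[[fm$waveforms]])) {
    w <- vars[[fm$waveforms]]
    if (!is.matrix(w)) stop("mapped waveform variable '", fm$waveforms,
                            "' is not a matrix")
    labs <- vars[[fm$labels]]
    if (is.null(labs)) {
      stop("mapped label variable '", fm$labels, "' not found in ", path)
    }
    labs <- unwrap(labs)
    # some distributions store (class, time) columns; take the class column
    if (is.matrix(labs)) labs <- labs[, 1L]
    return(spike_set(w, fs, labels = round(as.numeric(labs)),
                     source = basename(path)))
  }
  sig <- vars[[fm$signal]]
  if (is.null(sig)) {
    stop("neither waveform variable '", fm$waveforms,
         "' nor signal variable '", fm$signal, "' found in ", path)
  }
  tt <- vars[[fm$spike_times]]
  if (is.null(tt)) {
    stop("mapped spike-time variable '", fm$spike_times, "' not found in ",
         path)
  }
  cls <- vars[[fm$spike_classes]]
  if (is.null(cls)) {
    stop("mapped class variable '", fm$spike_classes, "' not found in ",
         path)
  }
  tt <- round(as.numeric(unwrap(tt)))
  cls <- round(as.numeric(unwrap(cls)))
  if (length(tt) != length(cls)) {
    stop("spike times (", length(tt), ") and classes (", length(cls),
         ") differ in length")
  }
  rec <- spike_recording(as.numeric(sig), fs)
  out <- cut_windows(rec, tt, window, labels = cls)
  out$source <- basename(path)
  out
}

#' Read / write spike waveforms as delimited text
#'
#' CSV with one spike per row; when labels are present they occupy a
#' leading `label` column. Integer labels round-trip exactly.
#'
#' @param spikes a [spike_set()].
#' @param path file path.
#' @param sampling_rate sampling rate in Hz to attach on read.
#' @return `write_waveforms_csv()` returns `path` invisibly;
#'   `read_waveforms_csv()` returns a [spike_set()].
#' @export
write_waveforms_csv <- function(spikes, path) {
  df <- as.data.frame(spikes$waveforms)
  names(df) <- paste0("s", seq_len(ncol(df)))
  if (!is.null(spikes$labels)) df <- cbind(label = spikes$labels, df)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_waveforms_csv
#' @export
read_waveforms_csv <- function(path, sampling_rate = 24000) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- as.integer(df$label)
    df$label <- NULL
  }
  spike_set(as.matrix(df), sampling_rate, labels = labels,
            source = basename(path))
}

#' Read / write spike waveforms in a simple binary container
#'
#' Layout (little-endian): magic `"SPKW"`, int32 version, int32 n_spikes,
#' int32 n_samples, int32 has_labels, double sampling_rate, doubles
#' (waveforms, row-major), then int32 labels when present. Integer fields
#' round-trip bit-exactly.
#'
#' @inheritParams write_waveforms_csv
#' @return `write_waveforms_bin()` returns `path` invisibly;
#'   `read_waveforms_bin()` returns a [spike_set()].
#' @export
write_waveforms_bin <- function(spikes, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("SPKW", con, 4L, eos = NULL)
  writeBin(c(1L, nrow(spikes$waveforms), ncol(spikes$waveforms),
             as.integer(!is.null(spikes$labels))), con, size = 4L,
           endian = "little")
  writeBin(as.numeric(spikes$sampling_rate), con, size = 8L,
           endian = "little")
  writeBin(as.numeric(t(spikes$waveforms)), con, size = 8L,
           endian = "little")
  if (!is.null(spikes$labels)) {
    writeBin(spikes$labels, con, size = 4L, endian = "little")
  }
  invisible(path)
}

#' @rdname write_waveforms_bin
#' @export
read_waveforms_bin <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 4L, useBytes = TRUE)
  if (!identical(magic, "SPKW")) stop("not a SPKW container: ", path)
  hdr <- readBin(con, integer(), 4L, size = 4L, endian = "little")
  fs <- readBin(con, numeric(), 1L, size = 8L, endian = "little")
  w <- matrix(readBin(con, numeric(), hdr[2L] * hdr[3L], size = 8L,
                      endian = "little"),
              nrow = hdr[2L], ncol = hdr[3L], byrow = TRUE)
  labels <- if (hdr[4L] == 1L) {
    readBin(con, integer(), hdr[2L], size = 4L, endian = "little")
  }
  spike_set(w, fs, labels = labels, source = basename(path))
}
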