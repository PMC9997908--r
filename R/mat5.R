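# Minimal MAT-file (level 5) reader / writer.
#
# No installed R package reads MAT containers in this stack, so the subset
# of the format needed for benchmark simulation files is implemented here:
# little-endian files, numeric arrays (double/single/int8..uint32), logical,
# char (returned as character), cell arrays (returned as lists), and
# zlib-compressed data elements. Structs and sparse/complex arrays are out
# of scope and raise an error naming the unsupported class.
#
# The writer emits uncompressed little-endian files with double arrays and
# cell arrays of doubles, and round-trips bit-exactly through the reader.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_INT64 <- 12L; MI_UINT64 <- 13L; MI_MATRIX <- 14L; MI_COMPRESSED <- 15L
MI_UTF8 <- 16L

MX_CELL <- 1L; MX_STRUCT <- 2L; MX_OBJECT <- 3L; MX_CHAR <- 4L
MX_SPARSE <- 5L; MX_DOUBLE <- 6L; MX_SINGLE <- 7L; MX_INT8 <- 8L
MX_UINT8 <- 9L; MX_INT16 <- 10L; MX_UINT16 <- 11L; MX_INT32 <- 12L
MX_UINT32 <- 13L

# --- reading -----------------------------------------------------------

mat5_read_numeric <- function(raw, type, nbytes) {
  con <- rawConnection(raw)
  on.exit(close(con))
  switch(as.character(type),
    "1" = readBin(con, integer(), nbytes, size = 1L, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, integer(), nbytes, size = 1L, signed = FALSE,
                  endian = "little"),
    "3" = readBin(con, integer(), nbytes / 2L, size = 2L, signed = TRUE,
                  endian = "little"),
    "4" = readBin(con, integer(), nbytes / 2L, size = 2L, signed = FALSE,
                  endian = "little"),
    "5" = readBin(con, integer(), nbytes / 4L, size = 4L, endian = "little"),
    "6" = readBin(con, numeric(), nbytes / 4L, size = 4L, endian = "little"),
    "7" = readBin(con, numeric(), nbytes / 4L, size = 4L, endian = "little"),
    "9" = readBin(con, numeric(), nbytes / 8L, size = 8L, endian = "little"),
    "16" = rawToChar(raw[seq_len(nbytes)]),
    stop("unsupported MAT data type mi", type)
  )
}

# Parse one tagged data element starting at offset `pos` (1-based) in `raw`.
# Returns list(type, data(raw), next_pos).
mat5_element <- function(raw, pos) {
  tag <- readBin(raw[pos:(pos + 3L)], integer(), 1L, size = 4L,
                 endian = "little")
  small_size <- bitwShiftR(tag, 16L)
  if (small_size > 0L) {           # small data element: data in the tag
    type <- bitwAnd(tag, 65535L)
    data <- raw[(pos + 4L):(pos + 3L + small_size)]
    list(type = type, data = data, nbytes = small_size, next_pos = pos + 8L)
  } else {
    type <- tag
    nbytes <- readBin(raw[(pos + 4L):(pos + 7L)], integer(), 1L, size = 4L,
                      endian = "little")
    data <- if (nbytes > 0L) raw[(pos + 8L):(pos + 7L + nbytes)] else raw(0)
    pad <- (8L - nbytes %% 8L) %% 8L
    list(type = type, data = data, nbytes = nbytes,
         next_pos = pos + 8L + nbytes + pad)
  }
}

# Parse a miMATRIX payload into list(name = , value = ).
mat5_parse_matrix <- function(payload) {
  el <- mat5_element(payload, 1L)                   # array flags
  flags <- readBin(el$data, integer(), 2L, size = 4L, endian = "little")
  class_id <- bitwAnd(flags[1L], 255L)
  el2 <- mat5_element(payload, el$next_pos)         # dimensions
  dims <- mat5_read_numeric(el2$data, el2$type, el2$nbytes)
  el3 <- mat5_element(payload, el2$next_pos)        # name
  name <- if (el3$nbytes > 0L) {
    rawToChar(el3$data[seq_len(el3$nbytes)])
  } else ""
  pos <- el3$next_pos
  if (class_id == MX_CELL) {
    n_cells <- prod(dims)
    cells <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      ci <- mat5_element(payload, pos)
      if (ci$type != MI_MATRIX) stop("malformed cell array element")
      parsed <- mat5_parse_matrix(ci$data)
      cells[[i]] <- parsed$value
      pos <- ci$next_pos
    }
    if (length(dims) == 2L && all(dims == c(1L, 1L)) && n_cells == 1L) {
      return(list(name = name, value = cells[[1L]]))
    }
    dim(cells) <- dims
    return(list(name = name, value = cells))
  }
  if (class_id == MX_CHAR) {
    ce <- mat5_element(payload, pos)
    chars <- if (ce$type == MI_UTF8) {
      mat5_read_numeric(ce$data, ce$type, ce$nbytes)
    } else {
      intToUtf8(mat5_read_numeric(ce$data, ce$type, ce$nbytes),
                multiple = FALSE)
    }
    return(list(name = name, value = chars))
  }
  if (class_id %in% c(MX_DOUBLE, MX_SINGLE, MX_INT8, MX_UINT8, MX_INT16,
                      MX_UINT16, MX_INT32, MX_UINT32)) {
    if (bitwAnd(bitwShiftR(flags[1L], 8L), 8L) != 0L) {
      stop("complex MAT arrays are not supported")
    }
    re <- mat5_element(payload, pos)
    vals <- as.numeric(mat5_read_numeric(re$data, re$type, re$nbytes))
    if (length(dims) == 2L && any(dims == 1L)) {
      return(list(name = name, value = as.numeric(vals)))
    }
    dim(vals) <- dims
    return(list(name = name, value = vals))
  }
  stop("unsupported MAT array class mx", class_id)
}

#' Read a MAT (level 5) file
#'
#' Reads little-endian MAT v5 containers holding numeric arrays, char
#' arrays and cell arrays (including zlib-compressed elements). Vectors
#' (1 x n or n x 1) are simplified to plain numeric vectors; 1 x 1 cell
#' wrappers are unwrapped.
#'
#' @param path file path.
#' @return named list of variables.
#' @export
read_mat <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 128L) stop("not a MAT v5 file (too short): ", path)
  endian <- rawToChar(raw[127:128])
  if (endian != "IM") {
    stop("unsupported MAT file (expected little-endian v5): ", path)
  }
  out <- list()
  pos <- 129L
  while (pos + 7L <= length(raw)) {
    el <- mat5_element(raw, pos)
    payload <- el$data
    type <- el$type
    if (type == MI_COMPRESSED) {
      payload <- memDecompress(payload, type = "gzip")
      inner <- mat5_element(payload, 1L)
      type <- inner$type
      payload <- inner$data
    }
    if (type == MI_MATRIX) {
      parsed <- mat5_parse_matrix(payload)
      out[[parsed$name]] <- parsed$value
    }
    pos <- el$next_pos
  }
  out
}

# --- writing -----------------------------------------------------------

mat5_tag <- function(type, nbytes) {
  c(writeBin(as.integer(type), raw(), size = 4L, endian = "little"),
    writeBin(as.integer(nbytes), raw(), size = 4L, endian = "little"))
}

mat5_pad <- function(bytes) {
  pad <- (8L - length(bytes) %% 8L) %% 8L
  c(bytes, raw(pad))
}

mat5_encode_matrix <- function(value, name) {
  if (is.list(value)) {
    dims <- dim(value)
    if (is.null(dims)) dims <- c(1L, length(value))
    body <- raw(0)
    for (cell in value) body <- c(body, mat5_encode_matrix(cell, ""))
    class_id <- MX_CELL
    data_bytes <- body
  } else {
    m <- value
    if (!is.matrix(m)) m <- matrix(as.numeric(m), nrow = 1L)
    dims <- dim(m)
    payload <- writeBin(as.numeric(m), raw(), size = 8L, endian = "little")
    class_id <- MX_DOUBLE
    data_bytes <- c(mat5_tag(MI_DOUBLE, length(payload)), mat5_pad(payload))
  }
  flags <- c(mat5_tag(MI_UINT32, 8L),
             writeBin(c(class_id, 0L), raw(), size = 4L, endian = "little"))
  dim_el <- c(mat5_tag(MI_INT32, 4L * length(dims)),
              mat5_pad(writeBin(as.integer(dims), raw(), size = 4L,
                                endian = "little")))
  name_raw <- charToRaw(name)
  name_el <- c(mat5_tag(MI_INT8, length(name_raw)), mat5_pad(name_raw))
  body <- c(flags, dim_el, name_el, data_bytes)
  c(mat5_tag(MI_MATRIX, length(body)), body)
}

#' Write variables to a MAT (level 5) file
#'
#' Writes an uncompressed little-endian MAT v5 file. Numeric vectors and
#' matrices are stored as double arrays; lists as cell arrays of double
#' arrays. Round-trips bit-exactly through [read_mat()].
#'
#' @param vars named list of numeric matrices/vectors or lists thereof.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_mat <- function(vars, path) {
  stopifnot(is.list(vars), !is.null(names(vars)), all(nzchar(names(vars))))
  header <- charToRaw(sprintf("MATLAB 5.0 MAT-file, created by spikeAE%s",
                              strrep(" ", 200)))[1:116]
  header <- c(header, raw(8L),
              writeBin(c(0x00L, 0x01L), raw(), size = 1L),  # version 0x0100
              charToRaw("IM"))
  body <- raw(0)
  for (nm in names(vars)) {
    body <- c(body, mat5_encode_matrix(vars[[nm]], nm))
  }
  writeBin(c(header, body), path)
  invisible(path)
}
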