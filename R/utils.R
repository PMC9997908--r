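# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
# The seed promise is forced before the state snapshot: a lazily
# evaluated `seed` argument that itself draws from the RNG (e.g. a
# derived sub-seed) must advance the caller's stream, not be rewound.
with_seed <- function(seed, expr) {
  seed <- as.integer(seed)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Shift a vector by `k` samples (positive = move content right), filling
# vacated positions by replicating the edge value.
shift_pad <- function(x, k) {
  n <- length(x)
  if (k == 0L) return(x)
  if (abs(k) >= n) return(rep(if (k > 0L) x[1L] else x[n], n))
  if (k > 0L) c(rep(x[1L], k), x[seq_len(n - k)])
  else c(x[seq.int(1L - k, n)], rep(x[n], -k))
}

# Min-max rescale `x` into [lo, hi]; a constant vector maps to the
# interval midpoint.
rescale_into <- function(x, lo, hi) {
  r <- range(x)
  if (r[1] == r[2]) return(rep((lo + hi) / 2, length(x)))
  lo + (x - r[1]) / (r[2] - r[1]) * (hi - lo)
}
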