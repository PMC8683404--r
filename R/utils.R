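#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic per-cell substream seed derived from a patch seed and a cell
# index; kept inside the 32-bit signed-integer range R requires.
derive_seed <- function(seed, index) {
  x <- (abs(as.double(seed)) * 69069 + as.double(index) * 40503 + 12345)
  as.integer(x %% 2147483647)
}

# Spike counts per interval; `times` must be sorted ascending.
# [lo, hi): #{t < hi} - #{t < lo}
count_left_closed <- function(times, lo, hi) {
  findInterval(hi, times, left.open = TRUE) -
    findInterval(lo, times, left.open = TRUE)
}
# (lo, hi]: #{t <= hi} - #{t <= lo}
count_right_closed <- function(times, lo, hi) {
  findInterval(hi, times) - findInterval(lo, times)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
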