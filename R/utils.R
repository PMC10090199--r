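#' @keywords internal
"_PACKAGE"

# Run an expression under a fixed RNG seed, restoring the caller's RNG state.
local_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Derive a sub-seed from a base seed and a small stream index, kept within
# 32-bit integer range so set.seed() never overflows.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 1000003 + 97 * as.numeric(stream)) %% 2147483647
}

# Runs of TRUE in a logical vector: data.frame(start, length) in sample units.
true_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  keep <- r$values
  data.frame(start = (ends - r$lengths + 1L)[keep], length = r$lengths[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Apply an IIR filter (coefficients as from signal::butter) causally via two
# C-level stats::filter passes: FIR numerator as convolution, denominator as
# recursion; works on vectors and on matrices (per column). Orders of
# magnitude faster than generic filtering on the multi-hour signals this
# package processes.
iir_filter <- function(flt, x) {
  b <- flt$b / flt$a[1]
  a <- flt$a / flt$a[1]
  k <- length(b)
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  strip <- function(v) {
    v <- unclass(v)
    attr(v, "tsp") <- NULL
    if (is.null(dim(v))) dim(v) <- c(length(v), 1L)
    v
  }
  v <- strip(stats::filter(xm, b, method = "convolution", sides = 1))
  for (i in seq_len(k - 1)) {  # zero-history head left NA by filter()
    v[i, ] <- colSums(b[seq_len(i)] * xm[i:1, , drop = FALSE])
  }
  if (length(a) > 1) {
    v <- strip(stats::filter(v, -a[-1], method = "recursive"))
  }
  if (vec) as.numeric(v) else v
}

# Zero-phase (forward-backward) application of an IIR filter.
iir_filtfilt <- function(flt, x) {
  vec <- is.null(dim(x))
  xm <- if (vec) matrix(x, ncol = 1) else x
  n <- nrow(xm)
  v <- iir_filter(flt, xm)
  v <- iir_filter(flt, v[n:1, , drop = FALSE])[n:1, , drop = FALSE]
  if (vec) as.numeric(v) else v
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
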