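# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. seed = NULL runs unseeded.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic 32-bit sub-seed derived from a parent seed and an index.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483587)
}

# Unit-sum 1-D Gaussian kernel; radius 4 SD.
gauss_kernel <- function(sigma) {
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Shift matrix rows (margin 1) or columns (margin 2) by s, zero fill.
shift_fill0 <- function(m, s, margin) {
  n <- dim(m)[margin]
  if (abs(s) >= n) return(matrix(0, nrow(m), ncol(m)))
  out <- matrix(0, nrow(m), ncol(m))
  if (s == 0) return(m)
  if (margin == 1L) {
    if (s > 0) out[(1 + s):n, ] <- m[1:(n - s), ] else out[1:(n + s), ] <- m[(1 - s):n, ]
  } else {
    if (s > 0) out[, (1 + s):n] <- m[, 1:(n - s)] else out[, 1:(n + s)] <- m[, (1 - s):n]
  }
  out
}

# Separable zero-padded Gaussian convolution of a matrix.
smooth_gauss2d <- function(m, sigma) {
  if (sigma <= 0) return(m)
  k <- gauss_kernel(sigma)
  r <- (length(k) - 1L) / 2L
  for (margin in 1:2) {
    acc <- matrix(0, nrow(m), ncol(m))
    for (j in seq_along(k)) acc <- acc + k[j] * shift_fill0(m, j - r - 1L, margin)
    m <- acc
  }
  m
}

# Maximal runs of TRUE in a logical vector (NA treated as FALSE).
# Returns data.frame(start, end) of index ranges, possibly empty.
true_runs <- function(v) {
  v[is.na(v)] <- FALSE
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}

`%||%` <- function(a, b) if (is.null(a)) b else a
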