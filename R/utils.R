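# Internal numeric helpers shared across modules.

# Truncated sliding-window sum over a matrix: at (i, j) the sum of m over
# rows i-wr..i+wr and columns j-wc..j+wc, clipped to the array (out-of-bounds
# positions contribute zero). Works for numeric and complex matrices.
box_sum <- function(m, wr, wc) {
  nr <- nrow(m)
  nc <- ncol(m)
  cs <- rbind(m[1, , drop = FALSE] * 0,
              matrix(apply(m, 2, cumsum), nrow = nr, ncol = nc))
  hi <- pmin(seq_len(nr) + wr, nr)
  lo <- pmax(seq_len(nr) - wr, 1L)
  rows <- cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]
  cs2 <- cbind(rows[, 1, drop = FALSE] * 0, t(
    matrix(apply(rows, 1, cumsum), nrow = nc, ncol = nr)))
  hj <- pmin(seq_len(nc) + wc, nc)
  lj <- pmax(seq_len(nc) - wc, 1L)
  cs2[, hj + 1L, drop = FALSE] - cs2[, lj, drop = FALSE]
}

# Separable Gaussian blur of a matrix (reflecting borders), sigma in pixels.
# sigma of 0 is the identity.
gauss_blur <- function(m, sigma_r, sigma_c) {
  blur1 <- function(x, sigma) {
    if (sigma <= 0) return(x)
    hw <- max(1L, ceiling(3 * sigma))
    k <- stats::dnorm(seq(-hw, hw), sd = sigma)
    k <- k / sum(k)
    n <- nrow(x)
    idx <- outer(seq_len(n), seq(-hw, hw), "+")
    idx[idx < 1L] <- 1L
    idx[idx > n] <- n
    out <- x * 0
    for (s in seq_along(k)) out <- out + k[s] * x[idx[, s], , drop = FALSE]
    out
  }
  m <- blur1(m, sigma_r)
  t(blur1(t(m), sigma_c))
}

# Running mean along a vector with window half-width hw, truncated at ends.
run_mean <- function(x, hw) {
  if (hw <= 0) return(x)
  n <- length(x)
  cs <- c(0, cumsum(x))
  hi <- pmin(seq_len(n) + hw, n)
  lo <- pmax(seq_len(n) - hw, 1L)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be > 0", name), call. = FALSE)
  invisible(x)
}
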