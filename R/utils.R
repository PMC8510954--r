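# Internal numerical helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so deterministic operations do not
#' disturb the caller's RNG stream.
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Sample moments; both return 0 for constant input (degenerate maps are
# zero-filled rather than propagating NaN into the feature table).
.skewness <- function(x) {
  n <- length(x); s <- stats::sd(x)
  if (n < 2L || !is.finite(s) || s == 0) return(0)
  mean((x - mean(x))^3) / s^3
}

.kurtosis <- function(x) {
  n <- length(x); s <- stats::sd(x)
  if (n < 2L || !is.finite(s) || s == 0) return(0)
  mean((x - mean(x))^4) / s^4 - 3
}

# Shannon entropy (bits) of an equal-width histogram.
.hist_entropy <- function(x, nbins = 16L) {
  r <- range(x)
  if (r[1] == r[2]) return(0)
  b <- pmin(nbins, pmax(1L, ceiling((x - r[1]) / (r[2] - r[1]) * nbins)))
  p <- tabulate(b, nbins) / length(x)
  p <- p[p > 0]
  -sum(p * log2(p))
}

.finite_or_zero <- function(x) {
  x[!is.finite(x)] <- 0
  x
}

# --- small image-processing primitives ------------------------------------

gauss_kernel_1d <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

# Separable Gaussian smoothing of a 3-D array, reflecting at the borders.
smooth_gauss_3d <- function(a, sigma) {
  if (length(sigma) == 1L) sigma <- rep(sigma, 3L)
  d <- dim(a)
  for (ax in 1:3) {
    if (sigma[ax] <= 0) next
    k <- gauss_kernel_1d(sigma[ax])
    a <- .conv_along_axis(a, k, ax)
  }
  a
}

.conv_along_axis <- function(a, k, axis) {
  d <- dim(a)
  r <- (length(k) - 1L) / 2L
  n <- d[axis]
  # reflect-pad index vector
  idx <- c(rev(seq_len(min(r, n))), seq_len(n), n + 1L - rev(seq_len(min(r, n))))
  if (r > n) { # degenerate: tile
    idx <- rep(seq_len(n), length.out = n + 2L * r)
  }
  perm <- c(axis, setdiff(1:3, axis))
  ap <- aperm(a, perm)
  dp <- dim(ap)
  m <- matrix(ap, nrow = dp[1])
  mp <- m[idx, , drop = FALSE]
  out <- matrix(0, nrow = dp[1], ncol = ncol(m))
  for (j in seq_along(k)) {
    out <- out + k[j] * mp[seq_len(dp[1]) + (j - 1L), , drop = FALSE]
  }
  dim(out) <- dp
  aperm(out, order(perm))
}

# 2-D 'same' convolution via FFT with reflect padding; kernel FFTs cached by
# (tag, padded size) because filter banks are re-applied to many slices.
.fft_cache <- new.env(parent = emptyenv())

conv2_fft <- function(img, kern, tag = NULL) {
  di <- dim(img); dk <- dim(kern)
  rk <- (dk - 1L) %/% 2L
  # reflect-pad image by kernel half-width
  pr <- pmin(rk, di - 1L)
  ri <- c(rev(seq_len(pr[1]) + 1L), seq_len(di[1]), di[1] - seq_len(pr[1]))
  ci <- c(rev(seq_len(pr[2]) + 1L), seq_len(di[2]), di[2] - seq_len(pr[2]))
  imgp <- img[ri, ci, drop = FALSE]
  dp <- dim(imgp)
  n1 <- dp[1] + dk[1] - 1L
  n2 <- dp[2] + dk[2] - 1L
  key <- if (!is.null(tag)) paste0(tag, "_", n1, "x", n2) else NULL
  if (!is.null(key) && !is.null(.fft_cache[[key]])) {
    K <- .fft_cache[[key]]
  } else {
    kp <- matrix(0, n1, n2)
    kp[seq_len(dk[1]), seq_len(dk[2])] <- kern
    K <- stats::fft(kp)
    if (!is.null(key)) .fft_cache[[key]] <- K
  }
  ip <- matrix(0, n1, n2)
  ip[seq_len(dp[1]), seq_len(dp[2])] <- imgp
  full <- Re(stats::fft(stats::fft(ip) * K, inverse = TRUE)) / (n1 * n2)
  # centre of the full convolution, then un-pad
  out <- full[rk[1] + seq_len(dp[1]), rk[2] + seq_len(dp[2]), drop = FALSE]
  out[pr[1] + seq_len(di[1]), pr[2] + seq_len(di[2]), drop = FALSE]
}

# complex-valued frequency-domain filtering of a single slice (used by the
# monogenic / Riesz machinery, where the filter is defined on the FFT grid)
fft_freq_grid <- function(n1, n2) {
  u <- c(seq(0, floor(n1 / 2)), seq(-ceiling(n1 / 2) + 1, -1)) / n1
  v <- c(seq(0, floor(n2 / 2)), seq(-ceiling(n2 / 2) + 1, -1)) / n2
  list(u = matrix(u, n1, n2), v = matrix(v, n1, n2, byrow = TRUE))
}
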