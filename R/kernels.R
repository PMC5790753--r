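#' Truncated, unit-sum 1-D Gaussian kernel
#'
#' Weights proportional to `exp(-k^2 / (2 sigma^2))` at integer offsets
#' `k = -(size-1)/2 ... (size-1)/2`, renormalized to sum to one, so that
#' convolution leaves constant signals unchanged.
#'
#' @param size Odd kernel length (5 for the spatial filter, 3 for the
#'   temporal filter).
#' @param sigma Gaussian SD in sample units.
#' @return Numeric vector of `size` weights summing to 1.
#' @export
#' @examples
#' gaussian_kernel_1d(5, 1)
gaussian_kernel_1d <- function(size, sigma) {
  if (size < 1 || size %% 2 == 0) stop("kernel size must be odd and >= 1")
  if (sigma <= 0) stop("sigma must be > 0")
  h <- (size - 1L) / 2L
  w <- exp(-((-h:h)^2) / (2 * sigma^2))
  w / sum(w)
}

# Renormalized 1-D convolution along one dimension of a 3-D array.
# At the borders the kernel is renormalized over its in-bounds support,
# which preserves constants everywhere (no padding assumption).
smooth_along_dim <- function(x, dim, w) {
  d <- dim(x)
  n <- d[dim]
  h <- (length(w) - 1L) %/% 2L
  perm <- c(dim, setdiff(seq_along(d), dim))
  m <- matrix(aperm(x, perm), nrow = n)
  num <- matrix(0, nrow = n, ncol = ncol(m))
  den <- numeric(n)
  for (j in seq_along(w)) {
    k <- j - h - 1L
    t0 <- max(1L, 1L - k); t1 <- min(n, n - k)
    if (t0 > t1) next
    num[t0:t1, ] <- num[t0:t1, ] + w[j] * m[(t0 + k):(t1 + k), , drop = FALSE]
    den[t0:t1] <- den[t0:t1] + w[j]
  }
  res <- num / den
  aperm(array(res, d[perm]), order(perm))
}

# Spatial (rows then columns; separable, so per-axis border renormalization
# equals full 2-D renormalization) followed by temporal smoothing.
smooth_stack <- function(x, spatial_size = 5L, spatial_sigma = 1,
                         temporal_size = 3L, temporal_sigma = 1) {
  ws <- gaussian_kernel_1d(spatial_size, spatial_sigma)
  wt <- gaussian_kernel_1d(temporal_size, temporal_sigma)
  x <- smooth_along_dim(x, 2L, ws)
  x <- smooth_along_dim(x, 3L, ws)
  smooth_along_dim(x, 1L, wt)
}
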