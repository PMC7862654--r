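# Shared numerical helpers: Gaussian kernels, symmetric-boundary convolution
# operators and bilinear resampling. Everything here is deterministic and
# boundary conventions are fixed once so that the deconvolution adjoint,
# post-filter flux conservation and sub-pixel localization all agree.

# Conversion between full width at half maximum and Gaussian sigma.
FWHM_SIGMA <- 2.3548

#' Convert a Gaussian FWHM to sigma
#'
#' Beam widths in ion imaging are quoted as full width at half maximum; all
#' internal kernels are parameterized by sigma with `sigma = fwhm / 2.3548`.
#'
#' @param fwhm Full width at half maximum (any length unit).
#' @return Sigma in the same unit.
#' @export
fwhm_to_sigma <- function(fwhm) fwhm / FWHM_SIGMA

#' Convert a Gaussian sigma to FWHM
#' @param sigma Gaussian sigma.
#' @return Full width at half maximum in the same unit.
#' @export
sigma_to_fwhm <- function(sigma) sigma * FWHM_SIGMA

# Normalized 1D Gaussian kernel sampled at integer pixel offsets.
# Support is +/- max(1, ceiling(4 sigma)) pixels; the kernel sums to 1 exactly.
gaussian_kernel_1d <- function(sigma_px) {
  if (sigma_px <= 1e-6) return(1)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-((-r:r)^2) / (2 * sigma_px^2))
  k / sum(k)
}

# Index map for half-sample symmetric ("reflect including edge") extension of
# 1:n to positions idx (any integers). x[-1] -> x[1], x[0] -> x[1] is wrong for
# half-sample: convention used everywhere here is x[0] -> x[1], x[-1] -> x[2],
# x[n+1] -> x[n], x[n+2] -> x[n-1]. Repeated reflection handles large offsets.
reflect_index <- function(idx, n) {
  if (n == 1L) return(rep(1L, length(idx)))
  period <- 2L * n
  j <- (idx - 1L) %% period
  j <- ifelse(j < 0L, j + period, j)
  ifelse(j < n, j + 1L, period - j)
}

# Dense 1D convolution operator (n x n matrix) for a symmetric-extension
# boundary. Row i gives the weights producing output pixel i. With a symmetric
# kernel this matrix is symmetric, which makes the Lucy-Richardson correlation
# step an exact adjoint of the convolution step (exact flux conservation).
conv_operator_1d <- function(kernel, n) {
  r <- (length(kernel) - 1L) %/% 2L
  A <- matrix(0, n, n)
  for (i in seq_len(n)) {
    src <- reflect_index((i - r):(i + r), n)
    for (m in seq_along(kernel)) {
      A[i, src[m]] <- A[i, src[m]] + kernel[m]
    }
  }
  A
}

# Separable 2D convolution with symmetric boundary extension via the dense 1D
# operators. img is (rows y, cols x); ky acts on rows, kx on columns.
conv2_sep <- function(img, ky, kx) {
  Ay <- conv_operator_1d(ky, nrow(img))
  Ax <- conv_operator_1d(kx, ncol(img))
  Ay %*% img %*% t(Ax)
}

# Gaussian blur of a 2D image, sigma in pixels (scalar or c(sy, sx)).
gaussian_blur <- function(img, sigma_px) {
  sigma_px <- rep(sigma_px, length.out = 2)
  conv2_sep(img, gaussian_kernel_1d(sigma_px[1]), gaussian_kernel_1d(sigma_px[2]))
}

# Bilinear interpolation of matrix img at fractional (row, col) positions
# (1-based, pixel-center convention). Out-of-range queries clamp to the edge
# when clamp = TRUE, otherwise return `fill`.
bilinear_interp <- function(img, yi, xi, clamp = TRUE, fill = 0) {
  ny <- nrow(img); nx <- ncol(img)
  inside <- yi >= 1 & yi <= ny & xi >= 1 & xi <= nx
  if (clamp) {
    yi <- pmin(pmax(yi, 1), ny)
    xi <- pmin(pmax(xi, 1), nx)
  }
  y0 <- pmin(floor(yi), ny - 1L); y0 <- pmax(y0, 1L)
  x0 <- pmin(floor(xi), nx - 1L); x0 <- pmax(x0, 1L)
  fy <- yi - y0; fx <- xi - x0
  v <- (1 - fy) * (1 - fx) * img[cbind(y0, x0)] +
    (1 - fy) * fx * img[cbind(y0, x0 + 1L)] +
    fy * (1 - fx) * img[cbind(y0 + 1L, x0)] +
    fy * fx * img[cbind(y0 + 1L, x0 + 1L)]
  if (!clamp) v[!inside] <- fill
  v
}

# Shift a 2D image by (dy, dx) pixels using bilinear interpolation; pixels
# sampled from outside the field are zero-filled. Positive dy/dx move content
# toward larger row/column indices. Bilinear (rather than spline) interpolation
# keeps shifted count images non-negative.
shift_image <- function(img, dy, dx, fill = 0) {
  ny <- nrow(img); nx <- ncol(img)
  grid <- expand.grid(y = seq_len(ny), x = seq_len(nx))
  v <- bilinear_interp(img, grid$y - dy, grid$x - dx, clamp = FALSE, fill = fill)
  matrix(v, ny, nx)
}

# Exact sub-pixel translation by a Fourier phase ramp. Unlike interpolation
# this does not smooth the image, so registration never trades sharpness for
# alignment. Wrapped-around margins are zeroed (out-of-field pixels carry no
# counts) and small negative ringing is clamped to keep counts non-negative.
fourier_shift <- function(img, dy, dx) {
  ny <- nrow(img); nx <- ncol(img)
  fy <- c(0:floor((ny - 1) / 2), -(ceiling((ny - 1) / 2):1)) / ny
  fx <- c(0:floor((nx - 1) / 2), -(ceiling((nx - 1) / 2):1)) / nx
  ph <- exp(-2i * pi * (outer(fy, rep(1, nx)) * dy +
                        outer(rep(1, ny), fx) * dx))
  out <- Re(stats::fft(stats::fft(img) * ph, inverse = TRUE)) / (ny * nx)
  if (dy > 0) out[seq_len(min(ny, ceiling(dy))), ] <- 0
  if (dy < 0) out[seq(ny - min(ny, ceiling(-dy)) + 1, ny), ] <- 0
  if (dx > 0) out[, seq_len(min(nx, ceiling(dx)))] <- 0
  if (dx < 0) out[, seq(nx - min(nx, ceiling(-dx)) + 1, nx)] <- 0
  pmax(out, 0)
}

# Median absolute deviation without the consistency constant (raw MAD),
# used for robust per-slice / per-block thresholds.
raw_mad <- function(x) stats::median(abs(x - stats::median(x)))

# Local maxima of a 2D image over the 8-neighborhood (at least as large as
# every neighbor; edge pixels compared against available neighbors only).
# Tied plateaus are collapsed to one representative so that a peak landing
# exactly between pixel centers is still reported once. Returns a two-column
# matrix (row, col).
local_maxima <- function(img, threshold = -Inf) {
  ny <- nrow(img); nx <- ncol(img)
  if (ny < 1 || nx < 1) return(matrix(numeric(0), 0, 2))
  pad <- matrix(-Inf, ny + 2, nx + 2)
  pad[2:(ny + 1), 2:(nx + 1)] <- img
  is_max <- matrix(TRUE, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0 && dx == 0) next
    nb <- pad[(2 + dy):(ny + 1 + dy), (2 + dx):(nx + 1 + dx)]
    is_max <- is_max & (img >= nb)
  }
  is_max <- is_max & (img > threshold)
  cand <- which(is_max, arr.ind = TRUE)
  if (nrow(cand) < 2) return(cand)
  # collapse adjacent equal-valued candidates (plateaus) to the first found
  keep <- rep(TRUE, nrow(cand))
  vals <- img[cand]
  ord <- order(cand[, 1], cand[, 2])
  cand <- cand[ord, , drop = FALSE]; vals <- vals[ord]
  for (k in seq (2, nrow(cand))) {
    if (!keep[k]) next
    prev <- which(keep[seq_len(k - 1)])
    close <- prev[abs(cand[prev, 1] - cand[k, 1]) <= 1 &
                  abs(cand[prev, 2] - cand[k, 2]) <= 1 &
                  vals[prev] == vals[k]]
    if (length(close)) keep[k] <- FALSE
  }
  cand[keep, , drop = FALSE]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
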