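# Depth binning, SNR measurement and fiducial-based drift registration.

#' Sliding-window depth binning
#'
#' Output slice `t` is the elementwise sum of input slices `t .. t + n - 1`,
#' advanced one slice at a time, so a stack of length `L` becomes one of
#' length `L - n + 1`: signal-to-noise improves with `n` while axial sampling
#' is preserved. Channels are binned independently; total counts per output
#' window are conserved exactly.
#'
#' @param stack An [ion_stack()].
#' @param n Window size, `1 <= n <= n_slices(stack)`; `n = 1` is the identity.
#' @return A binned [ion_stack()].
#' @export
sliding_window_sum <- function(stack, n) {
  stopifnot(inherits(stack, "ion_stack"))
  L <- n_slices(stack)
  n <- as.integer(n)
  if (n < 1 || n > L) stop("window size must satisfy 1 <= n <= ", L)
  d <- dim(stack$counts)
  out <- array(0, dim = c(L - n + 1L, d[2], d[3], d[4]))
  # cumulative sum along z gives each window sum in O(1)
  cs <- apply(stack$counts, c(2, 3, 4), cumsum)       # (z, ch, y, x)
  for (t in seq_len(L - n + 1L)) {
    hi <- cs[t + n - 1L, , , , drop = FALSE]
    lo <- if (t == 1L) 0 else cs[t - 1L, , , , drop = FALSE]
    out[t, , , ] <- hi - lo
  }
  # integer counts stay integer (binning is exact integer arithmetic)
  if (is.integer(stack$counts) && max(out) <= .Machine$integer.max)
    storage.mode(out) <- "integer"
  st <- ion_stack(out, stack$geometry, channel_labels = stack$channel_labels,
                  provenance = stack$provenance)
  log_provenance(st, sprintf("sliding_window_sum(n=%d)", n))
}

#' Signal-to-noise ratio of an image region, in dB
#'
#' `snr_db = 20 log10( mu_signal / rms_background )` where `rms_background`
#' is the root-mean-square deviation of the background pixels about their
#' mean. Note the deviation term is squared: the mean (unsquared) deviation is
#' identically zero, so the RMS form is the only reading that yields finite
#' decibel values.
#'
#' @param image A 2D matrix of counts.
#' @param signal_mask,background_mask Logical matrices of the same shape;
#'   disjoint, non-empty, background with at least 2 pixels.
#' @return A list with `snr_db`, `mu_signal`, `mu_background`, `n_background`
#'   and `background_values`.
#' @export
snr_db <- function(image, signal_mask, background_mask) {
  stopifnot(is.matrix(image), identical(dim(image), dim(signal_mask)),
            identical(dim(image), dim(background_mask)))
  if (any(signal_mask & background_mask))
    stop("signal and background masks must be disjoint")
  if (!any(signal_mask)) stop("empty signal mask")
  B <- image[background_mask]
  if (length(B) < 2) stop("background mask needs at least 2 pixels")
  mu_s <- mean(image[signal_mask])
  mu_b <- mean(B)
  rms <- sqrt(sum((B - mu_b)^2) / length(B))
  if (rms == 0) stop("undefined SNR: background deviation is zero")
  list(snr_db = 20 * log10(mu_s / rms), mu_signal = mu_s, mu_background = mu_b,
       n_background = length(B), background_values = B)
}

# Sub-pixel translation between two images by FFT cross-correlation with
# quadratic interpolation of the correlation peak. Returns c(dy, dx): the
# shift that maps `ref` onto `img`.
xcorr_shift <- function(img, ref) {
  ny <- nrow(img); nx <- ncol(img)
  F1 <- stats::fft(img - mean(img))
  F2 <- stats::fft(ref - mean(ref))
  cc <- Re(stats::fft(F1 * Conj(F2), inverse = TRUE))
  pk <- which(cc == max(cc), arr.ind = TRUE)[1, ]
  # quadratic sub-pixel refinement along each axis (circular indexing)
  refine <- function(m, i, n, get) {
    c0 <- get(i); cm <- get(((i - 2) %% n) + 1); cp <- get((i %% n) + 1)
    den <- cm - 2 * c0 + cp
    if (den >= 0) 0 else max(-0.5, min(0.5, 0.5 * (cm - cp) / den))
  }
  dyf <- refine(cc, pk[1], ny, function(i) cc[i, pk[2]])
  dxf <- refine(cc, pk[2], nx, function(j) cc[pk[1], j])
  wrap <- function(i, n) { v <- i - 1; if (v > n / 2) v - n else v }
  c(wrap(pk[1], ny) + dyf, wrap(pk[2], nx) + dxf)
}

#' Estimate per-slice drift from a fiducial channel
#'
#' Offsets are estimated per slice by maximizing the cross-correlation against
#' slice 1 (sub-pixel via quadratic peak interpolation). Slices with a flat
#' fiducial image get offsets interpolated from their neighbors and are
#' flagged. The same trace applies to every channel of the acquisition.
#'
#' @param stack An [ion_stack()].
#' @param fiducial_channel Channel index or label carrying the fiducial.
#' @param subpixel If `FALSE`, offsets are rounded to integers.
#' @return A [drift_trace()]; flat slices are listed in attribute
#'   `"interpolated_slices"`.
#' @export
estimate_drift <- function(stack, fiducial_channel = "fiducial",
                           subpixel = TRUE) {
  stopifnot(inherits(stack, "ion_stack"))
  L <- n_slices(stack)
  ref <- get_slice(stack, 1, fiducial_channel)
  if (stats::sd(ref) == 0) stop("reference slice 1 has a flat fiducial image")
  dx <- numeric(L); dy <- numeric(L); flat <- logical(L)
  for (s in seq(2, length.out = L - 1)) {
    img <- get_slice(stack, s, fiducial_channel)
    if (stats::sd(img) == 0) { flat[s] <- TRUE; next }
    sh <- xcorr_shift(img, ref)
    dy[s] <- sh[1]; dx[s] <- sh[2]
  }
  if (any(flat)) {
    ok <- which(!flat)
    for (s in which(flat)) {
      dy[s] <- stats::approx(ok, dy[ok], s, rule = 2)$y
      dx[s] <- stats::approx(ok, dx[ok], s, rule = 2)$y
    }
  }
  if (!subpixel) { dx <- round(dx); dy <- round(dy) }
  tr <- drift_trace(dx_px = dx, dy_px = dy)
  attr(tr, "interpolated_slices") <- which(flat)
  tr
}

#' Undo estimated drift on every channel of a stack
#'
#' Shifts each slice by the negated trace using an exact Fourier phase-ramp
#' translation (no interpolation smoothing); wrapped margins are zero-filled
#' and negative ringing is clamped at zero. The same trace is applied to
#' every channel.
#'
#' @param stack An [ion_stack()].
#' @param trace A [drift_trace()] as returned by [estimate_drift()].
#' @return A registered [ion_stack()].
#' @export
apply_correction <- function(stack, trace) {
  stopifnot(inherits(stack, "ion_stack"), inherits(trace, "drift_trace"))
  if (nrow(trace) != n_slices(stack))
    stop("trace length must equal number of slices")
  counts <- stack$counts
  for (s in seq_len(n_slices(stack))) {
    dy <- -trace$dy_px[s]; dx <- -trace$dx_px[s]
    if (abs(dy) < 1e-12 && abs(dx) < 1e-12) next
    for (ch in seq_len(n_channels(stack))) {
      counts[s, ch, , ] <- fourier_shift(counts[s, ch, , ], dy, dx)
    }
  }
  st <- ion_stack(counts, stack$geometry,
                  channel_labels = stack$channel_labels,
                  provenance = stack$provenance)
  log_provenance(st, "apply_correction")
}
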