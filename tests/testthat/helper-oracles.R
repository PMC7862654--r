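# Literal transcription of the multiplicative-update deconvolution step used
# as an independent oracle: nested loops, symmetric boundary indexing, flipped
# kernel for the correlation step.
lr_literal <- function(image, sigma_px, n_iter) {
  kk <- iontomo:::gaussian_kernel_1d(sigma_px)
  r <- (length(kk) - 1) / 2
  ref <- function(i, n) iontomo:::reflect_index(i, n)
  conv <- function(m, flip) {
    ny <- nrow(m); nx <- ncol(m); out <- m * 0
    s <- if (flip) -1 else 1
    for (i in 1:ny) for (j in 1:nx) {
      acc <- 0
      for (a in -r:r) for (b in -r:r) {
        acc <- acc + kk[a + r + 1] * kk[b + r + 1] *
          m[ref(i - s * a, ny), ref(j - s * b, nx)]
      }
      out[i, j] <- acc
    }
    out
  }
  est <- image
  for (it in seq_len(n_iter)) {
    blurred <- conv(est, flip = FALSE)
    est <- est * conv(image / pmax(blurred, 1e-12), flip = TRUE)
  }
  est
}
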