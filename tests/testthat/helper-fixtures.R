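# Shared builders for small test fixtures. Everything is generated in code;
# no data files are read.

# 50 nm pixels, 3.2 x 3.2 um field, 100 nm beam.
small_geom <- function(z_step_nm = 5) {
  acq_geometry(3.2, 3.2, n_pixels_x = 64L, beam_width_nm = 100,
               z_step_nm = z_step_nm)
}

# Tiny integer stack with reproducible counts.
tiny_stack <- function(n_slices = 3, n_channels = 2, n_px = 8, seed = 1) {
  set.seed(seed)
  g <- acq_geometry(n_px * 0.05, n_px * 0.05, n_pixels_x = n_px,
                    beam_width_nm = 100, z_step_nm = 5)
  counts <- array(rpois(n_slices * n_channels * n_px * n_px, 7),
                  dim = c(n_slices, n_channels, n_px, n_px))
  ion_stack(counts, g, channel_labels = paste0("ch", seq_len(n_channels)))
}

# Single persistent point source at a given physical position.
point_object <- function(x_nm, y_nm, rate = 1000, z_nm = NA_real_) {
  object_volume(points = data.frame(x_nm = x_nm, y_nm = y_nm, z_nm = z_nm,
                                    rate = rate, channel = 1L))
}

# Count local maxima above a fraction of the max along a profile.
profile_maxima <- function(prof, frac = 0.5) {
  pk <- which(diff(sign(diff(prof))) == -2) + 1
  pk[prof[pk] > max(prof) * frac]
}

# Count 2D local maxima above a fraction of the image max, after an optional
# light Gaussian smoothing (smoothing can merge maxima but never create them).
image_maxima <- function(img, frac = 0.5, smooth_px = 0) {
  if (smooth_px > 0) img <- iontomo:::gaussian_blur(img, smooth_px)
  iontomo:::local_maxima(img, threshold = max(img) * frac)
}

# Rand index between two hard clusterings.
rand_index <- function(a, b) {
  n <- length(a)
  same_a <- outer(a, a, "==")
  same_b <- outer(b, b, "==")
  agree <- same_a == same_b
  (sum(agree) - n) / (n^2 - n)
}
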