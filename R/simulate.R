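# Forward model: detected image = efficiency * (object content in the axial
# window, convolved with the lateral beam Gaussian) * multiplicative gamma
# factors, optionally sampled to integer counts. The simulator generates every
# fixture the rest of the package is tested on.

#' Ground-truth object volume
#'
#' Describes true source distributions: point emitters, uniform-density
#' spheres (nanotags) and uniform half-plane layers (edge targets). A point
#' with `z_nm = NA` is present at every depth (a column-like persistent
#' source). Rates and densities must be non-negative.
#'
#' @param points Data frame with columns `x_nm, y_nm, z_nm, rate, channel`.
#' @param spheres Data frame with columns `x_nm, y_nm, z_nm, diameter_nm,
#'   density, channel`; `density` is the emission rate per nanometre of depth
#'   intersected by the axial window.
#' @param halfplanes Data frame with columns `edge_x_nm, rate, channel`; each
#'   describes a uniform layer covering `x >= edge_x_nm` at every depth.
#' @param n_channels Number of emission channels.
#' @return An object of class `object_volume`.
#' @export
object_volume <- function(points = NULL, spheres = NULL, halfplanes = NULL,
                          n_channels = 1) {
  chk <- function(df, rate_col) {
    if (!is.null(df) && nrow(df) && min(df[[rate_col]]) < 0)
      stop("negative emission rates are not allowed")
  }
  chk(points, "rate"); chk(spheres, "density"); chk(halfplanes, "rate")
  structure(list(points = points, spheres = spheres, halfplanes = halfplanes,
                 n_channels = as.integer(n_channels)),
            class = "object_volume")
}

#' Beam point-spread function model
#'
#' Separable PSF: Gaussian laterally (width given as FWHM), uniform box
#' axially over `axial_extent_nm` — each raster scan collects ions from the
#' etch plane down to the stated penetration depth.
#'
#' @param lateral_fwhm_nm Lateral FWHM in nanometres (> 0).
#' @param axial_extent_nm Depth over which sub-surface ions contribute;
#'   default 100 nm.
#' @return An object of class `psf_model`.
#' @export
psf_model <- function(lateral_fwhm_nm, axial_extent_nm = 100) {
  stopifnot(lateral_fwhm_nm > 0, axial_extent_nm > 0)
  structure(list(lateral_fwhm_nm = lateral_fwhm_nm,
                 axial_extent_nm = axial_extent_nm),
            class = "psf_model")
}

#' Detector noise model
#'
#' Multiplicative gamma factors with mean pinned to 1 (shape `k`, scale
#' `1/k`), an ion extraction efficiency, an optional uniform dark-count floor,
#' and an optional Poisson ion-counting stage. The Poisson stage draws integer
#' counts with the model mean, reproducing the sparse stochastic pixel values
#' characteristic of low-current ion imaging; it preserves the expected image
#' and can be disabled for a purely multiplicative model.
#'
#' @param gamma_shape Gamma shape `k` (> 0); `Inf` disables the gamma factor.
#' @param extraction_efficiency Fraction of emitted material registered as
#'   counts, in (0, 1]; about 0.03 for the instruments modeled here.
#' @param seed Integer seed; simulation is a pure function of inputs and seed.
#' @param counting If `TRUE` (default), sample integer counts from a Poisson
#'   with the model mean.
#' @param dark_count Uniform background mean added before counting (default 0).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(gamma_shape = 3, extraction_efficiency = 0.03,
                        seed = 1, counting = TRUE, dark_count = 0) {
  stopifnot(gamma_shape > 0, extraction_efficiency > 0,
            extraction_efficiency <= 1, dark_count >= 0)
  structure(list(gamma_shape = gamma_shape,
                 extraction_efficiency = extraction_efficiency,
                 seed = as.integer(seed), counting = isTRUE(counting),
                 dark_count = dark_count),
            class = "noise_model")
}

#' Per-slice lateral drift trace
#'
#' @param dx_px,dy_px Real-valued per-slice offsets in pixels; slice 1 must be
#'   (0, 0) by convention.
#' @return An object of class `drift_trace` (data frame with `dx_px, dy_px`).
#' @export
drift_trace <- function(dx_px, dy_px) {
  stopifnot(length(dx_px) == length(dy_px), length(dx_px) >= 1)
  if (abs(dx_px[1]) > 1e-12 || abs(dy_px[1]) > 1e-12)
    stop("slice 1 offset must be (0, 0)")
  structure(data.frame(dx_px = dx_px, dy_px = dy_px),
            class = c("drift_trace", "data.frame"))
}

# ---- rasterization -------------------------------------------------------

# Bilinear splat of a point emitter onto pixel centers. Pixel j center is at
# (j - 0.5) * dx, so continuous pixel coordinate of x_nm is x_nm / dx + 0.5.
splat_point <- function(mat, geom, x_nm, y_nm, rate) {
  px <- pixel_size_nm(geom)
  xi <- x_nm / px$dx_nm + 0.5
  yi <- y_nm / px$dy_nm + 0.5
  x0 <- floor(xi); y0 <- floor(yi)
  fx <- xi - x0; fy <- yi - y0
  for (dd in list(c(0, 0, (1 - fy) * (1 - fx)), c(0, 1, (1 - fy) * fx),
                  c(1, 0, fy * (1 - fx)), c(1, 1, fy * fx))) {
    r <- y0 + dd[1]; c <- x0 + dd[2]
    if (r >= 1 && r <= nrow(mat) && c >= 1 && c <= ncol(mat))
      mat[r, c] <- mat[r, c] + rate * dd[3]
  }
  mat
}

# Rasterize the content of one sphere within an axial window [z0, z1) as the
# per-pixel chord length (nm) times density, averaged over a 3x3 sub-pixel
# grid (anti-aliasing).
raster_sphere_slab <- function(mat, geom, cx, cy, cz, r, density, z0, z1) {
  px <- pixel_size_nm(geom)
  jmin <- max(1L, floor((cx - r) / px$dx_nm))
  jmax <- min(ncol(mat), ceiling((cx + r) / px$dx_nm + 1))
  imin <- max(1L, floor((cy - r) / px$dy_nm))
  imax <- min(nrow(mat), ceiling((cy + r) / px$dy_nm + 1))
  if (jmin > jmax || imin > imax) return(mat)
  sub <- c(-1, 0, 1) / 3
  for (i in imin:imax) for (j in jmin:jmax) {
    acc <- 0
    for (sy in sub) for (sx in sub) {
      x <- (j - 0.5 + sx) * px$dx_nm
      y <- (i - 0.5 + sy) * px$dy_nm
      rho2 <- (x - cx)^2 + (y - cy)^2
      if (rho2 < r^2) {
        h <- sqrt(r^2 - rho2)
        acc <- acc + max(0, min(z1, cz + h) - max(z0, cz - h))
      }
    }
    mat[i, j] <- mat[i, j] + density * acc / 9
  }
  mat
}

# Object content (before blur/noise) for channel `ch` in axial window [z0, z1).
object_slab <- function(obj, geom, ch, z0, z1) {
  mat <- matrix(0, geom$n_pixels_y, geom$n_pixels_x)
  pts <- obj$points
  if (!is.null(pts) && nrow(pts)) {
    pts <- pts[pts$channel == ch, , drop = FALSE]
    for (k in seq_len(nrow(pts))) {
      z <- pts$z_nm[k]
      if (is.na(z) || (z >= z0 && z < z1))
        mat <- splat_point(mat, geom, pts$x_nm[k], pts$y_nm[k], pts$rate[k])
    }
  }
  sph <- obj$spheres
  if (!is.null(sph) && nrow(sph)) {
    sph <- sph[sph$channel == ch, , drop = FALSE]
    for (k in seq_len(nrow(sph))) {
      mat <- raster_sphere_slab(mat, geom, sph$x_nm[k], sph$y_nm[k],
                                sph$z_nm[k], sph$diameter_nm[k] / 2,
                                sph$density[k], z0, z1)
    }
  }
  hp <- obj$halfplanes
  if (!is.null(hp) && nrow(hp)) {
    px <- pixel_size_nm(geom)
    hp <- hp[hp$channel == ch, , drop = FALSE]
    for (k in seq_len(nrow(hp))) {
      # fraction of each pixel column lying at x >= edge
      right_edges <- seq_len(geom$n_pixels_x) * px$dx_nm
      cov <- pmin(pmax((right_edges - hp$edge_x_nm[k]) / px$dx_nm, 0), 1)
      mat <- mat + hp$rate[k] * matrix(cov, geom$n_pixels_y, geom$n_pixels_x,
                                       byrow = TRUE)
    }
  }
  mat
}

# ---- forward simulation --------------------------------------------------

#' Simulate a multi-depth ion image stack
#'
#' For each slice the object content within the axial collection window
#' `[z_s, z_s + axial_extent)` (etch plane `z_s = (s - 1) * z_step`) is
#' convolved with the lateral beam Gaussian, scaled by the extraction
#' efficiency, multiplied by i.i.d. unit-mean gamma factors and, if enabled,
#' sampled to integer counts. Deterministic given the noise seed.
#'
#' @param obj An [object_volume()].
#' @param psf A [psf_model()].
#' @param noise A [noise_model()], or `NULL` for a noiseless expectation image
#'   at efficiency `efficiency`.
#' @param geom An [acq_geometry()].
#' @param n_slices Number of depth slices (>= 1).
#' @param efficiency Extraction efficiency used when `noise` is `NULL`.
#' @param channel_labels Optional channel labels.
#' @return An [ion_stack()].
#' @export
simulate_stack <- function(obj, psf, noise, geom, n_slices,
                           efficiency = 0.03, channel_labels = NULL) {
  stopifnot(inherits(obj, "object_volume"), inherits(psf, "psf_model"),
            inherits(geom, "acq_geometry"), n_slices >= 1)
  px <- pixel_size_nm(geom)
  if (px$dx_nm > psf$lateral_fwhm_nm || px$dy_nm > psf$lateral_fwhm_nm)
    warning("pixel size exceeds PSF width: the object is undersampled")
  eff <- if (is.null(noise)) efficiency else noise$extraction_efficiency
  sx <- fwhm_to_sigma(psf$lateral_fwhm_nm) / px$dx_nm
  sy <- fwhm_to_sigma(psf$lateral_fwhm_nm) / px$dy_nm
  kx <- gaussian_kernel_1d(sx); ky <- gaussian_kernel_1d(sy)
  nc <- obj$n_channels
  counts <- array(0, dim = c(n_slices, nc, geom$n_pixels_y, geom$n_pixels_x))
  if (!is.null(noise)) set.seed(noise$seed)
  for (s in seq_len(n_slices)) {
    z0 <- (s - 1) * geom$z_step_nm
    z1 <- z0 + psf$axial_extent_nm
    for (ch in seq_len(nc)) {
      slab <- object_slab(obj, geom, ch, z0, z1)
      img <- eff * conv2_sep(slab, ky, kx)
      if (!is.null(noise)) {
        if (is.finite(noise$gamma_shape)) {
          g <- matrix(stats::rgamma(length(img), shape = noise$gamma_shape,
                                    scale = 1 / noise$gamma_shape),
                      nrow(img), ncol(img))
          img <- img * g
        }
        img <- img + noise$dark_count
        if (noise$counting)
          img <- matrix(stats::rpois(length(img), lambda = img),
                        nrow(img), ncol(img))
      }
      counts[s, ch, , ] <- img
    }
  }
  st <- ion_stack(counts, geom, channel_labels = channel_labels)
  log_provenance(st, sprintf(
    "simulate_stack(n_slices=%d, psf_fwhm=%g, eff=%g, seed=%s)",
    n_slices, psf$lateral_fwhm_nm, eff,
    if (is.null(noise)) "none" else noise$seed))
}

# ---- fixtures ------------------------------------------------------------

#' Default geometry for the six-molecule validation fixture
#'
#' 50 nm pixels (6.4 x 3.2 um field at 128 x 64 px) with a 120 nm beam: the
#' sampling used for the simulated validation of the deconvolution pipeline.
#' @return An [acq_geometry()].
#' @export
six_point_geometry <- function() {
  acq_geometry(6.4, 3.2, n_pixels_x = 128L, n_pixels_y = 64L,
               beam_width_nm = 120, z_step_nm = 5)
}

#' Six-molecule validation array
#'
#' Six equal-rate collinear point sources separated by 200 nm, centered in the
#' field and present at every depth. The canonical synthetic target for
#' validating binning + deconvolution: the reconstruction should recover six
#' distinct maxima at 200 nm spacing.
#'
#' @param geom An [acq_geometry()]; the field must be wide enough for the
#'   1000 nm array plus a beam-width margin on each side.
#' @param rate Per-slice emission rate of each source.
#' @return An [object_volume()] with one channel.
#' @export
six_point_fixture <- function(geom, rate = 2000) {
  stopifnot(inherits(geom, "acq_geometry"))
  width_nm <- 1000 * geom$scan_area_x_um
  need <- 5 * 200 + 2 * geom$beam_width_nm
  if (width_nm < need)
    stop("field too small for the six-point array (needs >= ", need, " nm)")
  cx <- width_nm / 2
  cy <- 1000 * geom$scan_area_y_um / 2
  object_volume(points = data.frame(
    x_nm = cx + (seq_len(6) - 3.5) * 200,
    y_nm = cy, z_nm = NA_real_, rate = rate, channel = 1L
  ))
}

#' Sharp-edge resolution target
#'
#' A uniform half-plane source covering `x >= edge_x_nm` at all depths,
#' emulating a metal/silicon interface used for edge-spread resolution
#' estimation.
#'
#' @param geom An [acq_geometry()].
#' @param edge_x_nm Edge position in nanometres (default: field center).
#' @param rate Per-slice emission rate per fully covered pixel.
#' @return An [object_volume()] with one channel.
#' @export
edge_fixture <- function(geom, edge_x_nm = 500 * geom$scan_area_x_um,
                         rate = 1000) {
  object_volume(halfplanes = data.frame(edge_x_nm = edge_x_nm, rate = rate,
                                        channel = 1L))
}

#' Isotope-doped nanotag field
#'
#' Non-overlapping spheres with normally distributed diameters (truncated at
#' zero), emitting identically in every channel: a perfectly co-localized
#' multi-channel ground truth.
#'
#' @param geom An [acq_geometry()].
#' @param n_tags Number of tags to place.
#' @param mean_d_nm,sd_d_nm Diameter distribution (defaults 109.8 and 17.6 nm).
#' @param channels Number of co-localized channels (default 2).
#' @param density Emission density per nanometre of intersected depth; the
#'   default puts the expected peak pixel near 9 counts for a mean-diameter
#'   tag at 3% efficiency and 50 nm pixels (the sub-10-counts regime).
#' @param z_nm Depth of all tag centers (default 150 nm).
#' @param seed Integer seed for placement.
#' @param min_sep_nm Minimum center-to-center separation; defaults to the sum
#'   of radii (non-overlap). Larger values give isolated tags.
#' @param max_tries Rejection-sampling attempts before giving up.
#' @return An [object_volume()].
#' @export
nanotag_fixture <- function(geom, n_tags, mean_d_nm = 109.8, sd_d_nm = 17.6,
                            channels = 2, density = 9, z_nm = 150,
                            seed = 1, min_sep_nm = NULL, max_tries = 2000) {
  stopifnot(n_tags >= 1)
  set.seed(seed)
  wx <- 1000 * geom$scan_area_x_um
  wy <- 1000 * geom$scan_area_y_um
  d <- numeric(0)
  while (length(d) < n_tags) {
    cand <- stats::rnorm(n_tags - length(d), mean_d_nm, sd_d_nm)
    d <- c(d, cand[cand > 0])
  }
  margin <- max(d) / 2 + geom$beam_width_nm
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0
  while (length(xs) < n_tags) {
    tries <- tries + 1
    if (tries > max_tries)
      stop("could not place ", n_tags, " non-overlapping tags after ",
           max_tries, " tries")
    x <- stats::runif(1, margin, wx - margin)
    y <- stats::runif(1, margin, wy - margin)
    k <- length(xs) + 1
    ok <- TRUE
    if (length(xs)) {
      min_sep <- pmax((d[seq_along(xs)] + d[k]) / 2, min_sep_nm %||% 0)
      ok <- all(sqrt((xs - x)^2 + (ys - y)^2) >= min_sep)
    }
    if (ok) { xs <- c(xs, x); ys <- c(ys, y) }
  }
  sph <- do.call(rbind, lapply(seq_len(channels), function(ch) {
    data.frame(x_nm = xs, y_nm = ys, z_nm = z_nm, diameter_nm = d,
               density = density, channel = ch)
  }))
  object_volume(spheres = sph, n_channels = channels)
}

#' Close nanotag pair
#'
#' Two identical small spheres at a given center spacing along x, emitting in
#' every channel: the target used to demonstrate that localization-based
#' reconstruction separates pairs closer than the beam width.
#'
#' @param geom An [acq_geometry()].
#' @param spacing_nm Center-to-center spacing.
#' @param diameter_nm Sphere diameter (default 40 nm).
#' @param channels Number of channels (default 2).
#' @param density Emission density per nanometre of depth.
#' @param z_nm Depth of the pair centers.
#' @return An [object_volume()].
#' @export
nanotag_pair_fixture <- function(geom, spacing_nm, diameter_nm = 40,
                                 channels = 2, density = 60, z_nm = 150) {
  cx <- 500 * geom$scan_area_x_um
  cy <- 500 * geom$scan_area_y_um
  sph <- do.call(rbind, lapply(seq_len(channels), function(ch) {
    data.frame(x_nm = cx + c(-0.5, 0.5) * spacing_nm, y_nm = cy, z_nm = z_nm,
               diameter_nm = diameter_nm, density = density, channel = ch)
  }))
  object_volume(spheres = sph, n_channels = channels)
}

#' Two-channel pulse-chase fixture
#'
#' Random persistent point sources where a fraction of positions is shared
#' between the two channels, emulating short-chase (high overlap) versus
#' long-chase (low overlap) double-labeling experiments.
#'
#' @param geom An [acq_geometry()].
#' @param n_sources Sources per channel.
#' @param shared_frac Fraction of channel-2 sources co-located with channel 1.
#' @param rate Per-slice emission rate.
#' @param seed Integer placement seed.
#' @return An [object_volume()] with two channels.
#' @export
pulse_chase_fixture <- function(geom, n_sources = 40, shared_frac = 0.8,
                                rate = 800, seed = 1) {
  stopifnot(shared_frac >= 0, shared_frac <= 1)
  set.seed(seed)
  wx <- 1000 * geom$scan_area_x_um
  wy <- 1000 * geom$scan_area_y_um
  m <- geom$beam_width_nm
  x1 <- stats::runif(n_sources, m, wx - m)
  y1 <- stats::runif(n_sources, m, wy - m)
  n_shared <- round(shared_frac * n_sources)
  x2 <- c(x1[seq_len(n_shared)], stats::runif(n_sources - n_shared, m, wx - m))
  y2 <- c(y1[seq_len(n_shared)], stats::runif(n_sources - n_shared, m, wy - m))
  object_volume(points = rbind(
    data.frame(x_nm = x1, y_nm = y1, z_nm = NA_real_, rate = rate, channel = 1L),
    data.frame(x_nm = x2, y_nm = y2, z_nm = NA_real_, rate = rate, channel = 2L)
  ), n_channels = 2)
}

#' Apply lateral drift (and optionally inject a fiducial bead) to a stack
#'
#' Each slice is shifted by its per-slice offset using bilinear interpolation
#' (sub-pixel shifts supported; out-of-field pixels are zero-filled). If a
#' bead diameter is given, a uniform bright disc is first injected into a
#' dedicated `"fiducial"` channel so the drift can later be estimated from it.
#'
#' @param stack An [ion_stack()].
#' @param trace A [drift_trace()] with one row per slice.
#' @param fiducial_diameter_um Optional bead diameter in micrometres.
#' @param fiducial_value Counts per pixel inside the bead disc (default 50).
#' @return A drifted [ion_stack()].
#' @export
apply_drift <- function(stack, trace, fiducial_diameter_um = NULL,
                        fiducial_value = 50) {
  stopifnot(inherits(stack, "ion_stack"), inherits(trace, "drift_trace"))
  L <- n_slices(stack)
  if (nrow(trace) != L) stop("trace length must equal number of slices")
  g <- stack$geometry
  if (max(abs(trace$dx_px)) >= g$n_pixels_x ||
      max(abs(trace$dy_px)) >= g$n_pixels_y)
    stop("drift larger than the field")
  counts <- stack$counts
  labels <- stack$channel_labels
  if (!is.null(fiducial_diameter_um)) {
    px <- pixel_size_nm(g)
    r_nm <- 500 * fiducial_diameter_um
    cx <- 0.25 * 1000 * g$scan_area_x_um
    cy <- 0.25 * 1000 * g$scan_area_y_um
    xs <- pixel_center_x_nm(g, seq_len(g$n_pixels_x))
    ys <- pixel_center_y_nm(g, seq_len(g$n_pixels_y))
    disc <- outer(ys, xs, function(y, x) (x - cx)^2 + (y - cy)^2 <= r_nm^2)
    d <- dim(counts)
    new_counts <- array(0, dim = c(d[1], d[2] + 1, d[3], d[4]))
    new_counts[, seq_len(d[2]), , ] <- counts
    for (s in seq_len(L)) new_counts[s, d[2] + 1, , ] <- fiducial_value * disc
    counts <- new_counts
    labels <- c(labels, "fiducial")
  }
  for (s in seq_len(L)) {
    if (abs(trace$dx_px[s]) < 1e-12 && abs(trace$dy_px[s]) < 1e-12) next
    for (ch in seq_len(dim(counts)[2])) {
      counts[s, ch, , ] <- shift_image(counts[s, ch, , ],
                                       trace$dy_px[s], trace$dx_px[s])
    }
  }
  st <- ion_stack(counts, g, channel_labels = labels,
                  provenance = stack$provenance)
  log_provenance(st, sprintf("apply_drift(max_dx=%g, max_dy=%g%s)",
                             max(abs(trace$dx_px)), max(abs(trace$dy_px)),
                             if (is.null(fiducial_diameter_um)) ""
                             else ", fiducial"))
}
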