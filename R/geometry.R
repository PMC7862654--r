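#' Acquisition geometry of an ion-beam raster scan
#'
#' Describes the physical scan extent, pixel raster, nominal beam width, etch
#' step and beam current of a depth-scan series. The derived pixel sizes are
#' `dx = 1000 * scan_area_x_um / n_pixels_x` nanometres (and similarly `dy`);
#' sampling satisfies the Nyquist-style criterion for ion imaging when both
#' pixel sizes are at most the beam width.
#'
#' @param scan_area_x_um,scan_area_y_um Physical scan extent in micrometres.
#'   `scan_area_y_um` defaults to the x extent (square field).
#' @param n_pixels_x,n_pixels_y Integer pixel counts; `n_pixels_y` defaults to
#'   `n_pixels_x`.
#' @param beam_width_nm Nominal lateral ion-beam width (FWHM) in nanometres.
#' @param z_step_nm Nominal etch depth per raster scan in nanometres.
#' @param beam_current_pA Recorded beam current in picoamperes.
#' @param dwell_ms Dwell time per pixel in milliseconds.
#' @return An object of class `acq_geometry`.
#' @examples
#' g <- acq_geometry(20, n_pixels_x = 256)
#' pixel_size_nm(g)
#' @export
acq_geometry <- function(scan_area_x_um, scan_area_y_um = scan_area_x_um,
                         n_pixels_x, n_pixels_y = n_pixels_x,
                         beam_width_nm = 100, z_step_nm = 5,
                         beam_current_pA = 1, dwell_ms = 1000) {
  stopifnot(
    is.numeric(scan_area_x_um), length(scan_area_x_um) == 1, scan_area_x_um > 0,
    is.numeric(scan_area_y_um), length(scan_area_y_um) == 1, scan_area_y_um > 0,
    beam_width_nm > 0, z_step_nm > 0, beam_current_pA > 0, dwell_ms > 0
  )
  n_pixels_x <- as.integer(n_pixels_x)
  n_pixels_y <- as.integer(n_pixels_y)
  if (is.na(n_pixels_x) || is.na(n_pixels_y) || n_pixels_x < 1 || n_pixels_y < 1)
    stop("invalid geometry: pixel counts must be strictly positive integers")
  structure(
    list(
      scan_area_x_um = scan_area_x_um, scan_area_y_um = scan_area_y_um,
      n_pixels_x = n_pixels_x, n_pixels_y = n_pixels_y,
      beam_width_nm = beam_width_nm, z_step_nm = z_step_nm,
      beam_current_pA = beam_current_pA, dwell_ms = dwell_ms
    ),
    class = "acq_geometry"
  )
}

#' Pixel size and Nyquist check for an acquisition geometry
#'
#' Returns the exact lateral pixel sizes in nanometres together with a
#' `nyquist_ok` flag that is `TRUE` iff both pixel sizes are at most the
#' nominal beam width. Values are unrounded; display rounding to integer
#' nanometres happens only in `print` methods.
#'
#' @param geometry An [acq_geometry()] object.
#' @return A list with elements `dx_nm`, `dy_nm` and `nyquist_ok`.
#' @examples
#' pixel_size_nm(acq_geometry(20, n_pixels_x = 256))  # 78.125 nm
#' @export
pixel_size_nm <- function(geometry) {
  stopifnot(inherits(geometry, "acq_geometry"))
  dx <- 1000 * geometry$scan_area_x_um / geometry$n_pixels_x
  dy <- 1000 * geometry$scan_area_y_um / geometry$n_pixels_y
  list(
    dx_nm = dx, dy_nm = dy,
    nyquist_ok = dx <= geometry$beam_width_nm && dy <= geometry$beam_width_nm
  )
}

#' @export
print.acq_geometry <- function(x, ...) {
  px <- pixel_size_nm(x)
  cat(sprintf(
    "<acq_geometry> %g x %g um, %d x %d px (pixel %.0f x %.0f nm, Nyquist %s)\n",
    x$scan_area_x_um, x$scan_area_y_um, x$n_pixels_x, x$n_pixels_y,
    px$dx_nm, px$dy_nm, if (px$nyquist_ok) "ok" else "violated"
  ))
  cat(sprintf(
    "  beam %g nm FWHM, z-step %g nm, current %g pA, dwell %g ms\n",
    x$beam_width_nm, x$z_step_nm, x$beam_current_pA, x$dwell_ms
  ))
  invisible(x)
}

# Physical pixel-center coordinates (nm) of 1-based pixel indices.
# Column j center is at (j - 0.5) * dx; row i center at (i - 0.5) * dy.
pixel_center_x_nm <- function(geometry, j) {
  (j - 0.5) * (1000 * geometry$scan_area_x_um / geometry$n_pixels_x)
}
pixel_center_y_nm <- function(geometry, i) {
  (i - 0.5) * (1000 * geometry$scan_area_y_um / geometry$n_pixels_y)
}
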