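#' Ion-count data cube
#'
#' The central container of the package: a 4D array of non-negative ion counts
#' indexed `(slice z, channel c, row y, col x)` together with the acquisition
#' geometry, unique mass-channel labels and a free-form provenance log. All
#' channels share one geometry. Coordinates are pixel-center: the physical
#' position of pixel `(i, j)` (row, column, 1-based) is
#' `((j - 0.5) * dx, (i - 0.5) * dy)` nanometres.
#'
#' @param counts 4D numeric array `(z, channel, y, x)` with `counts >= 0`, or a
#'   3D array `(z, y, x)` for a single channel.
#' @param geometry An [acq_geometry()]; its pixel raster must match `dim(counts)`.
#' @param channel_labels Character vector of unique mass-channel labels, e.g.
#'   `c("127I", "81Br")`.
#' @param provenance Optional character vector describing operations applied.
#' @return An object of class `ion_stack`.
#' @export
ion_stack <- function(counts, geometry, channel_labels = NULL,
                      provenance = character()) {
  stopifnot(inherits(geometry, "acq_geometry"))
  if (length(dim(counts)) == 3) {
    counts <- array(counts, dim = c(dim(counts)[1], 1L, dim(counts)[2:3]))
  }
  d <- dim(counts)
  if (length(d) != 4) stop("counts must be a 4D (z, channel, y, x) array")
  if (d[1] < 1) stop("ion_stack needs at least one slice")
  if (is.null(channel_labels)) channel_labels <- paste0("ch", seq_len(d[2]))
  if (length(channel_labels) != d[2]) stop("one label per channel required")
  if (anyDuplicated(channel_labels)) stop("channel_labels must be unique")
  if (d[3] != geometry$n_pixels_y || d[4] != geometry$n_pixels_x)
    stop("counts dimensions do not match geometry pixel raster")
  if (anyNA(counts)) stop("counts must not contain NA")
  if (min(counts) < 0) stop("counts must be non-negative")
  structure(
    list(counts = counts, channel_labels = channel_labels,
         geometry = geometry, provenance = provenance),
    class = "ion_stack"
  )
}

#' @export
print.ion_stack <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<ion_stack> %d slices x %d channels x %d x %d px [%s]\n",
              d[1], d[2], d[3], d[4], paste(x$channel_labels, collapse = ", ")))
  print(x$geometry)
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " | "), "\n")
  invisible(x)
}

#' Number of depth slices in a stack
#' @param stack An [ion_stack()].
#' @return Integer slice count.
#' @export
n_slices <- function(stack) dim(stack$counts)[1]

#' Number of mass channels in a stack
#' @param stack An [ion_stack()].
#' @return Integer channel count.
#' @export
n_channels <- function(stack) dim(stack$counts)[2]

#' Extract one slice image from a stack
#'
#' @param stack An [ion_stack()].
#' @param z Slice index (1-based).
#' @param channel Channel index or label.
#' @return A `(ny, nx)` matrix of counts.
#' @export
get_slice <- function(stack, z, channel = 1) {
  if (is.character(channel)) channel <- match(channel, stack$channel_labels)
  if (is.na(channel)) stop("unknown channel")
  stack$counts[z, channel, , , drop = TRUE]
}

# Append a provenance entry, returning the modified stack.
log_provenance <- function(stack, entry) {
  stack$provenance <- c(stack$provenance, entry)
  stack
}
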