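# TIFF + JSON-sidecar I/O. Dialect: one multi-page grayscale TIFF per mass
# channel plus one JSON sidecar holding the acquisition geometry, channel
# labels, random seed and per-channel encoding. Integer counts (the native
# detector output) round-trip bit-exactly as 16-bit unsigned pages; non-integer
# stacks (e.g. deconvolved images) are stored as scaled 16-bit with the scale
# recorded in the sidecar, which is quantized and flagged as such.

SIDECAR_VERSION <- "iontomo-1"

#' Write an ion stack as per-channel TIFFs plus a JSON sidecar
#'
#' @param stack An [ion_stack()].
#' @param dir Output directory (created if missing).
#' @param name Base name for the files; channel `L` is written to
#'   `<name>_<L>.tif` and the sidecar to `<name>.json`.
#' @param seed Optional integer seed recorded in the sidecar for provenance.
#' @return Invisibly, the sidecar path.
#' @export
write_stack <- function(stack, dir, name = "stack", seed = NULL) {
  stopifnot(inherits(stack, "ion_stack"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  g <- stack$geometry
  channels <- list()
  for (c in seq_len(n_channels(stack))) {
    label <- stack$channel_labels[c]
    fname <- paste0(name, "_", gsub("[^A-Za-z0-9_-]", "_", label), ".tif")
    dat <- stack$counts[, c, , , drop = FALSE]
    integer_valued <- max(abs(dat - round(dat))) == 0
    if (integer_valued && max(dat) <= 65535) {
      mode <- "uint16"; scale <- 1
    } else {
      mode <- "scaled16"
      scale <- max(dat) / 65535
      if (scale == 0) scale <- 1
      warning(sprintf(
        "channel %s has non-integer or >16-bit counts; stored as scaled 16-bit (lossy)",
        label
      ))
    }
    pages <- lapply(seq_len(n_slices(stack)), function(z) {
      m <- matrix(dat[z, 1, , ], dim(dat)[3], dim(dat)[4])
      if (mode == "uint16") m / 65535 else m / (scale * 65535)
    })
    tiff::writeTIFF(pages, file.path(dir, fname), bits.per.sample = 16,
                    compression = "none")
    channels[[label]] <- list(file = fname, mode = mode, scale = scale)
  }
  sidecar <- list(
    version = SIDECAR_VERSION,
    scan_area_um = c(g$scan_area_x_um, g$scan_area_y_um),
    n_pixels = c(g$n_pixels_x, g$n_pixels_y),
    beam_width_nm = g$beam_width_nm,
    z_step_nm = g$z_step_nm,
    beam_current_pA = g$beam_current_pA,
    dwell_ms = g$dwell_ms,
    channels = channels,
    n_slices = n_slices(stack),
    seed = seed,
    provenance = as.list(stack$provenance)
  )
  path <- file.path(dir, paste0(name, ".json"))
  jsonlite::write_json(sidecar, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Read an ion stack written by [write_stack()]
#'
#' Geometry is taken from the sidecar and is never guessed: a missing or
#' field-incomplete sidecar is an error. Channel pages must all share one
#' shape.
#'
#' @param sidecar Path to the JSON sidecar.
#' @return An [ion_stack()]; the sidecar seed (if any) is attached as
#'   attribute `"seed"`.
#' @export
read_stack <- function(sidecar) {
  if (!file.exists(sidecar)) stop("sidecar not found: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  required <- c("scan_area_um", "n_pixels", "beam_width_nm", "z_step_nm",
                "beam_current_pA", "dwell_ms", "channels")
  missing <- setdiff(required, names(meta))
  if (length(missing))
    stop("sidecar is missing required fields: ", paste(missing, collapse = ", "))
  geom <- acq_geometry(
    scan_area_x_um = meta$scan_area_um[1], scan_area_y_um = meta$scan_area_um[2],
    n_pixels_x = meta$n_pixels[1], n_pixels_y = meta$n_pixels[2],
    beam_width_nm = meta$beam_width_nm, z_step_nm = meta$z_step_nm,
    beam_current_pA = meta$beam_current_pA, dwell_ms = meta$dwell_ms
  )
  dir <- dirname(sidecar)
  labels <- names(meta$channels)
  arrays <- lapply(labels, function(label) {
    ch <- meta$channels[[label]]
    pages <- tiff::readTIFF(file.path(dir, ch$file), all = TRUE, as.is = TRUE)
    shapes <- vapply(pages, function(p) paste(dim(p), collapse = "x"), "")
    if (length(unique(shapes)) != 1)
      stop("format error: page shapes differ within channel ", label)
    a <- simplify2array(pages)        # (y, x, z)
    a <- aperm(a, c(3, 1, 2))         # (z, y, x)
    if (identical(ch$mode, "uint16")) a else a * ch$scale
  })
  shapes <- vapply(arrays, function(a) paste(dim(a), collapse = "x"), "")
  if (length(unique(shapes)) != 1)
    stop("format error: channels have different shapes")
  d <- dim(arrays[[1]])
  counts <- array(if (all(vapply(arrays, is.integer, TRUE))) 0L else 0,
                  dim = c(d[1], length(arrays), d[2], d[3]))
  for (c in seq_along(arrays)) counts[, c, , ] <- arrays[[c]]
  st <- ion_stack(counts, geom, channel_labels = labels,
                  provenance = unlist(meta$provenance) %||% character())
  attr(st, "seed") <- meta$seed
  st
}
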