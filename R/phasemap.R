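## Phase maps: 2D grids of optical phase on a named projection plane.

#' Construct a phase map
#'
#' A phase map is a uniform 2D grid of phase values (radians) on one of the
#' coordinate projection planes. Rows index the first plane axis, columns the
#' second (e.g. on plane `"xz"`, `values[i, j]` is the phase at
#' `x = origin[1] + (i-1) * pixel_size`, `z = origin[2] + (j-1) * pixel_size`).
#'
#' @param values numeric matrix of phase (rad).
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @param pixel_size pixel pitch (um), equal in both directions.
#' @param origin coordinates of the center of pixel `[1, 1]` (um).
#' @param wrapped logical; `TRUE` when values lie in the principal interval
#'   (-pi, pi].
#' @param wavelength vacuum wavelength (um).
#' @return an object of class `phase_map`.
#' @export
phase_map <- function(values, plane, pixel_size, origin = NULL,
                      wrapped = FALSE, wavelength = 0.488) {
  stopifnot(is.matrix(values), pixel_size > 0, wavelength > 0)
  plane <- match.arg(plane, c("xy", "xz", "yz"))
  if (is.null(origin))
    origin <- -pixel_size * (dim(values) - 1) / 2
  if (wrapped && (max(values) > pi + 1e-9 || min(values) <= -pi - 1e-9))
    stop("wrapped phase values must lie in (-pi, pi]")
  structure(list(values = values, plane = plane,
                 pixel_size = pixel_size, origin = as.numeric(origin),
                 wrapped = isTRUE(wrapped), wavelength = wavelength),
            class = "phase_map")
}

#' @export
print.phase_map <- function(x, ...) {
  cat(sprintf("phase map (%s): %d x %d px, pixel %.4g um, %s, range [%.3g, %.3g] rad\n",
              x$plane, nrow(x$values), ncol(x$values), x$pixel_size,
              if (x$wrapped) "wrapped" else "unwrapped",
              min(x$values), max(x$values)))
  invisible(x)
}

## the two in-plane axis names and the projection axis
plane_axes <- function(plane)
  switch(plane, xy = c("x", "y", "z"), xz = c("x", "z", "y"),
         yz = c("y", "z", "x"))

#' Pixel center coordinates of a phase or thickness map
#'
#' @param map a `phase_map` or `thickness_map`.
#' @return list with `u` and `v`, the physical coordinates (um) of pixel rows
#'   and columns along the plane's first and second axis.
#' @export
map_coords <- function(map) {
  list(u = map$origin[1] + (seq_len(nrow(map$values)) - 1) * map$pixel_size,
       v = map$origin[2] + (seq_len(ncol(map$values)) - 1) * map$pixel_size)
}

#' Construct a thickness map
#'
#' A 2D grid of axial physical thickness of one compartment.
#'
#' @param values numeric matrix of thickness (um), non-negative.
#' @param plane,pixel_size,origin as in [phase_map()].
#' @param compartment compartment label, e.g. `"nucleus"`.
#' @return an object of class `thickness_map`.
#' @export
thickness_map_obj <- function(values, plane, pixel_size, origin = NULL,
                              compartment = "nucleus") {
  stopifnot(is.matrix(values), all(values >= -1e-12), pixel_size > 0)
  plane <- match.arg(plane, c("xy", "xz", "yz"))
  if (is.null(origin))
    origin <- -pixel_size * (dim(values) - 1) / 2
  structure(list(values = pmax(values, 0), plane = plane,
                 pixel_size = pixel_size, origin = as.numeric(origin),
                 compartment = compartment), class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf("thickness map (%s, %s): %d x %d px, max %.3g um\n",
              x$compartment, x$plane, nrow(x$values), ncol(x$values),
              max(x$values)))
  invisible(x)
}

## ---- map I/O --------------------------------------------------------------

.map_sidecar <- function(map, extra = list()) {
  c(list(plane = map$plane, pixel_size = map$pixel_size,
         origin = map$origin), extra)
}

#' Read and write phase maps
#'
#' `write_phase_map` stores the grid as a single-page TIFF (values scaled to
#' `[0, 1]`; the affine scale and offset are recorded in a YAML sidecar next
#' to the file) or as a plain-text matrix, together with a sidecar
#' `<path>.yml` carrying plane, pixel size, origin, wavelength and the wrapped
#' flag. `read_phase_map` reverses this.
#'
#' @param map a `phase_map`.
#' @param path output file path (`.tif` or `.txt`).
#' @param format `"tiff"` or `"text"`; guessed from the extension by default.
#' @return `read_phase_map` returns a `phase_map`; `write_phase_map` returns
#'   `path` invisibly.
#' @export
write_phase_map <- function(map, path, format = NULL) {
  stopifnot(inherits(map, "phase_map"))
  if (is.null(format))
    format <- if (grepl("\\.tiff?$", path, ignore.case = TRUE)) "tiff" else "text"
  meta <- .map_sidecar(map, list(wavelength = map$wavelength,
                                 wrapped = map$wrapped))
  if (format == "tiff") {
    lo <- min(map$values); hi <- max(map$values)
    scale <- if (hi > lo) hi - lo else 1
    tiff::writeTIFF((map$values - lo) / scale, path, bits.per.sample = 32L,
                    compression = "none")
    meta$tiff_offset <- lo
    meta$tiff_scale <- scale
  } else {
    utils::write.table(map$values, path, row.names = FALSE, col.names = FALSE)
  }
  yaml::write_yaml(meta, paste0(path, ".yml"), precision = 15)
  invisible(path)
}

#' @rdname write_phase_map
#' @export
read_phase_map <- function(path) {
  meta <- yaml::read_yaml(paste0(path, ".yml"))
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    v <- tiff::readTIFF(path)
    v <- v * meta$tiff_scale + meta$tiff_offset
  } else {
    v <- as.matrix(utils::read.table(path))
    dimnames(v) <- NULL
  }
  phase_map(v, plane = meta$plane, pixel_size = meta$pixel_size,
            origin = unlist(meta$origin), wrapped = isTRUE(meta$wrapped),
            wavelength = meta$wavelength)
}
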