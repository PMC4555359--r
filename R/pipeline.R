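## End-to-end characterization: scene -> orthogonal phase maps -> interface
## contours -> reconciled center -> reconstructed nucleus -> shape report.

#' Simulate the two orthogonal views of a scene
#'
#' @param scene an `ri_scene`.
#' @param pixel_size pixel pitch (um).
#' @param wavelength vacuum wavelength (um).
#' @param field field of view (um).
#' @return list with unwrapped `phase_map`s `xy` and `xz`.
#' @export
simulate_views <- function(scene, pixel_size = 0.0625, wavelength = 0.488,
                           field = 16) {
  list(xy = project_phase(scene, "xy", pixel_size, wavelength, field),
       xz = project_phase(scene, "xz", pixel_size, wavelength, field))
}

#' Characterize the nucleus from two orthogonal phase images
#'
#' Runs the full reconstruction: inflexion-curve contour extraction on the
#' x-y and x-z unwrapped phase maps, phase-center determination (contour
#' centroid, with the restricted extremum reported alongside), cross-view
#' reconciliation of the shared x coordinate, surface reconstruction from
#' the two nucleus outlines, and an axis-aligned ellipsoid fit.
#'
#' @param scene an `ri_scene` to simulate (or `NULL` when maps are given).
#' @param map_xy,map_xz unwrapped `phase_map`s of the x-y and x-z views;
#'   generated from `scene` when omitted. Wrapped maps are unwrapped with the
#'   quality method.
#' @param pixel_size,wavelength,field simulation settings used when `scene`
#'   is given.
#' @param smoothing_sigma Gaussian scale for the inflexion response (um);
#'   default one pixel.
#' @param reconstruction `"merge"` (elliptical cross-sections from both
#'   outlines, default) or `"rotate"` (literal revolution of the x-y
#'   outline).
#' @param tol shared-x consistency tolerance (um) for [reconcile_centers()].
#' @return object of class `cell_characterization`: list with `report`
#'   (a `nucleus_report`), `center`, `centers` (per-view centroid/extremum),
#'   `contours`, `mesh` and `maps`.
#' @examples
#' \donttest{
#' cc <- characterize_nucleus(build_monocyte_edward(), pixel_size = 0.125)
#' cc$report
#' }
#' @export
characterize_nucleus <- function(scene = NULL, map_xy = NULL, map_xz = NULL,
                                 pixel_size = 0.0625, wavelength = 0.488,
                                 field = 16, smoothing_sigma = NULL,
                                 reconstruction = c("merge", "rotate"),
                                 tol = 0.2) {
  reconstruction <- match.arg(reconstruction)
  if (is.null(map_xy) || is.null(map_xz)) {
    if (is.null(scene)) stop("need either a scene or both phase maps")
    views <- simulate_views(scene, pixel_size, wavelength, field)
    map_xy <- views$xy; map_xz <- views$xz
  }
  if (map_xy$wrapped) map_xy <- unwrap2d(map_xy, "quality")
  if (map_xz$wrapped) map_xz <- unwrap2d(map_xz, "quality")
  stopifnot(map_xy$plane == "xy", map_xz$plane == "xz")

  resp_xy <- inflexion_field(map_xy, smoothing_sigma)
  resp_xz <- inflexion_field(map_xz, smoothing_sigma)
  ct_xy <- extract_contours(resp_xy, map_xy, require_nucleus = TRUE)
  ct_xz <- extract_contours(resp_xz, map_xz, require_nucleus = TRUE)

  cen_xy <- phase_center_centroid(ct_xy$nucleus)
  cen_xz <- phase_center_centroid(ct_xz$nucleus)
  ext_xy <- phase_center_extremum(map_xy, ct_xy$nucleus)
  ext_xz <- phase_center_extremum(map_xz, ct_xz$nucleus)
  center <- reconcile_centers(cen_xy, cen_xz, tol = tol)

  mesh <- if (reconstruction == "merge") {
    merge_orthogonal(ct_xy$nucleus, ct_xz$nucleus)
  } else {
    ## the revolved outline is built about its own plane; place it at the
    ## reconciled out-of-plane center
    m <- rotate_outline(ct_xy$nucleus, axis = "u", level = center[["y"]])
    m$vertices[, 3] <- m$vertices[, 3] + center[["z"]]
    m
  }
  report <- fit_ellipsoid(mesh, center = center)

  structure(list(report = report, center = center,
                 centers = list(centroid_xy = cen_xy, centroid_xz = cen_xz,
                                extremum_xy = ext_xy, extremum_xz = ext_xz),
                 contours = list(xy = ct_xy, xz = ct_xz),
                 mesh = mesh,
                 maps = list(xy = map_xy, xz = map_xz)),
            class = "cell_characterization")
}

#' @export
print.cell_characterization <- function(x, ...) {
  cat("orthogonal-phase cell characterization\n")
  print(x$report)
  invisible(x)
}

#' Random nucleated-cell scenes for recovery studies
#'
#' Draws axis-aligned ellipsoidal nuclei (semi-axes uniform in
#' `semi_range`, centers uniform within `center_range` of the origin in each
#' coordinate) embedded in the default two-half-ellipsoid membrane, keeping
#' only draws whose nucleus lies inside the membrane with at least
#' `clearance` margin so the two interfaces stay resolvable.
#'
#' @param n number of scenes.
#' @param seed RNG seed.
#' @param semi_range range of nucleus semi-axes (um).
#' @param center_range half-width of the center distribution (um).
#' @param clearance minimum nucleus-membrane margin (um).
#' @return list of `n` elements, each with `scene`, `semi_axes`, `center`.
#' @export
random_nucleus_scenes <- function(n, seed = 1L, semi_range = c(2, 4),
                                  center_range = 2, clearance = 0.4) {
  set.seed(seed)
  mem_top <- c(6.0, 6.0, 6.5); mem_bot <- c(6.0, 6.0, 3.5)
  shrunk_top <- mem_top - clearance
  shrunk_bot <- mem_bot - clearance
  out <- vector("list", n)
  got <- 0L
  while (got < n) {
    semi <- stats::runif(3, semi_range[1], semi_range[2])
    cen <- stats::runif(3, -center_range, center_range)
    nuc <- part_ellipsoid(semi, center = cen)
    pts <- part_surface_points(nuc, 400L)
    ins <- ifelse(pts[, 3] >= 0,
                  rowSums(sweep(pts, 2, shrunk_top, "/")^2) <= 1,
                  rowSums(sweep(pts, 2, shrunk_bot, "/")^2) <= 1)
    if (!all(ins)) next
    got <- got + 1L
    out[[got]] <- list(
      scene = build_monocyte_edward(nucleus_semiaxes = semi,
                                    nucleus_center = cen),
      semi_axes = semi, center = cen)
  }
  out
}

#' Wrapped-phase gallery of the built-in cell models
#'
#' Renders the wrapped x-y phase maps of the six built-in blood-cell models
#' and summarizes their fringe structure: the number of 2 pi discontinuities
#' along the central row (fringe count, growing with peak optical path) and
#' the maximum unwrapped phase.
#'
#' @param pixel_size pixel pitch (um).
#' @param dir optional directory; when given, one PNG per model is written.
#' @return data frame with model, max unwrapped phase (rad) and fringe count;
#'   the wrapped maps are attached as attribute `"maps"`.
#' @export
wrapped_gallery <- function(pixel_size = 0.0625, dir = NULL) {
  models <- cell_models()
  maps <- list()
  res <- data.frame(model = names(models), max_phase = NA_real_,
                    fringe_count = NA_integer_)
  for (i in seq_along(models)) {
    pm <- project_phase(models[[i]](), "xy", pixel_size = pixel_size)
    w <- wrap_phase(pm)
    maps[[names(models)[i]]] <- w
    res$max_phase[i] <- max(pm$values)
    mid <- w$values[, ceiling(ncol(w$values) / 2)]
    res$fringe_count[i] <- sum(abs(diff(mid)) > pi)
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      grDevices::png(file.path(dir, paste0(names(models)[i], "_wrapped.png")),
                     width = 600, height = 600)
      plot_boundaries(w, main = paste(names(models)[i], "(wrapped)"))
      grDevices::dev.off()
    }
  }
  attr(res, "maps") <- maps
  res
}
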