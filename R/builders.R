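## Parametric blood-cell scene builders.
##
## The white-blood-cell models share a 12.0 um outer sphere (the membrane)
## with nuclear material of a cell-type-specific shape inside; the red blood
## cell is a biconcave disc. Indices default to cytoplasm 1.37, nucleus 1.39
## and medium 1.003; dimensions not fixed by the model descriptions (lobe
## semi-axes, tube radii) are configurable defaults chosen to match the
## relative nuclear size of the real cells.

.wbc_membrane <- function(diameter, n1)
  part_sphere(diameter / 2, index = n1, priority = 1L, label = "membrane")

.check_nucleus_inside <- function(parts, membrane_parts, what = "nucleus") {
  inside_union <- function(pts) {
    ins <- rep(FALSE, nrow(pts))
    for (m in membrane_parts) ins <- ins | part_contains(m, pts)
    ins
  }
  for (p in parts) {
    pts <- part_surface_points(p, 500L)
    if (!all(inside_union(pts)))
      stop(what, " geometry extends outside the membrane")
  }
  invisible(TRUE)
}

#' Red blood cell model
#'
#' Axisymmetric biconcave disc; the thickness profile is a cosine series
#' constrained to the center thickness, the interior maximum (edge) thickness
#' and zero thickness at the rim.
#'
#' @param diameter disc diameter (um).
#' @param center_thickness axial thickness on the axis (um).
#' @param edge_thickness maximum axial thickness, attained at an interior
#'   radius (um).
#' @param index interior refractive index.
#' @param medium_index refractive index of the surrounding medium.
#' @return an `ri_scene`.
#' @examples
#' rbc <- build_rbc()
#' @export
build_rbc <- function(diameter = 7.7, center_thickness = 1.0,
                      edge_thickness = 2.0, index = 1.40,
                      medium_index = 1.003) {
  if (diameter <= 0 || center_thickness <= 0)
    stop("dimensions must be positive")
  ri_scene(list(part_biconcave(diameter, center_thickness, edge_thickness,
                               index = index, priority = 1L, label = "cell")),
           medium_index = medium_index)
}

#' White blood cell models
#'
#' Five nuclear-type models sharing a 12.0 um spherical membrane:
#' eccentric double spheres (lymphocyte), two internal spheroid lobes
#' (eosinophil), four internal spheroids in two connected pairs (neutrophil),
#' an internal U-shaped swept tube (monocyte), and an internal S-shaped swept
#' tube (basophil).
#'
#' @param membrane_diameter outer sphere diameter (um).
#' @param nucleus_radius lymphocyte nucleus radius (um).
#' @param nucleus_center lymphocyte nucleus center (um).
#' @param lobe_semi_axes spheroid lobe semi-axes (um); the long axis is
#'   oriented along y.
#' @param lobe_centers matrix of lobe centers, one row per lobe (um).
#' @param arc_radius centerline arc radius of the U/S tube (um).
#' @param tube_radius tube radius of the U/S nucleus (um).
#' @param n1,n2,nm cytoplasm, nucleus and medium refractive indices.
#' @return an `ri_scene`.
#' @name wbc-models
NULL

#' @rdname wbc-models
#' @export
build_lymphocyte <- function(membrane_diameter = 12.0, nucleus_radius = 4.0,
                             nucleus_center = c(0, 0, 1.2),
                             n1 = 1.37, n2 = 1.39, nm = 1.003) {
  mem <- .wbc_membrane(membrane_diameter, n1)
  nuc <- part_sphere(nucleus_radius, center = nucleus_center, index = n2)
  nuc$priority <- 2L; nuc$label <- "nucleus"
  .check_nucleus_inside(list(nuc), list(mem))
  ri_scene(list(mem, nuc), medium_index = nm)
}

#' @rdname wbc-models
#' @export
build_eosinophil <- function(membrane_diameter = 12.0,
                             lobe_semi_axes = c(2.5, 2.0, 2.0),
                             lobe_centers = rbind(c(-2.2, 0, 0),
                                                  c(2.2, 0, 0)),
                             n1 = 1.37, n2 = 1.39, nm = 1.003) {
  mem <- .wbc_membrane(membrane_diameter, n1)
  lobes <- lapply(seq_len(nrow(lobe_centers)), function(i)
    part_ellipsoid(lobe_semi_axes, center = lobe_centers[i, ], index = n2,
                   priority = 2L, label = "nucleus", orient = c(z = 90)))
  .check_nucleus_inside(lobes, list(mem))
  ri_scene(c(list(mem), lobes), medium_index = nm)
}

#' @rdname wbc-models
#' @export
build_neutrophil <- function(membrane_diameter = 12.0,
                             lobe_semi_axes = c(2.5, 2.0, 2.0),
                             lobe_centers = rbind(c(-2.3, -1.3, 0),
                                                  c(-2.3, 1.3, 0),
                                                  c(2.3, -1.3, 0),
                                                  c(2.3, 1.3, 0)),
                             n1 = 1.37, n2 = 1.39, nm = 1.003) {
  mem <- .wbc_membrane(membrane_diameter, n1)
  lobes <- lapply(seq_len(nrow(lobe_centers)), function(i)
    part_ellipsoid(lobe_semi_axes, center = lobe_centers[i, ], index = n2,
                   priority = 2L, label = "nucleus", orient = c(z = 90)))
  .check_nucleus_inside(lobes, list(mem))
  ri_scene(c(list(mem), lobes), medium_index = nm)
}

#' @rdname wbc-models
#' @export
build_monocyte_fig1 <- function(membrane_diameter = 12.0, arc_radius = 3.0,
                                tube_radius = 1.5, n1 = 1.37, n2 = 1.39,
                                nm = 1.003) {
  mem <- .wbc_membrane(membrane_diameter, n1)
  u <- part_swept_tube(list(list(center = c(0, 0, 0), radius = arc_radius,
                                 theta = c(180, 360))),
                       tube_radius = tube_radius, index = n2,
                       priority = 2L, label = "nucleus")
  .check_nucleus_inside(list(u), list(mem))
  ri_scene(list(mem, u), medium_index = nm)
}

#' @rdname wbc-models
#' @export
build_basophil <- function(membrane_diameter = 12.0, arc_radius = 1.5,
                           tube_radius = 1.5, n1 = 1.37, n2 = 1.39,
                           nm = 1.003) {
  mem <- .wbc_membrane(membrane_diameter, n1)
  s <- part_swept_tube(list(list(center = c(0, arc_radius, 0),
                                 radius = arc_radius, theta = c(-90, 90)),
                            list(center = c(0, -arc_radius, 0),
                                 radius = arc_radius, theta = c(90, 270))),
                       tube_radius = tube_radius, index = n2,
                       priority = 2L, label = "nucleus")
  .check_nucleus_inside(list(s), list(mem))
  ri_scene(list(mem, s), medium_index = nm)
}

#' Monocyte model with half-ellipsoid membrane and ellipsoidal nucleus
#'
#' The membrane consists of two half-ellipsoids sharing the z = 0 equatorial
#' plane (equal equatorial semi-axes, different polar semi-axes); the nucleus
#' is an axis-aligned ellipsoid. Defaults reproduce the verification presets:
#' nucleus semi-axes 3.40/3.70/3.00 um at (0, 0, 3.00) um, cytoplasm 1.37,
#' nucleus 1.39, medium 1.003.
#'
#' @param membrane_semiaxes_top semi-axes (a, b, c) of the upper (z >= 0)
#'   half-ellipsoid (um).
#' @param membrane_semiaxes_bottom semi-axes of the lower half (um); a and b
#'   must match the top half.
#' @param nucleus_semiaxes nucleus semi-axes along x, y, z (um).
#' @param nucleus_center nucleus center (um).
#' @param n1,n2,nm cytoplasm, nucleus and medium refractive indices.
#' @return an `ri_scene`.
#' @examples
#' mono <- build_monocyte_edward()
#' index_at(mono, c(0, 0, 3))   # 1.39 (nucleus)
#' @export
build_monocyte_edward <- function(membrane_semiaxes_top = c(6.0, 6.0, 6.5),
                                  membrane_semiaxes_bottom = c(6.0, 6.0, 3.5),
                                  nucleus_semiaxes = c(3.40, 3.70, 3.00),
                                  nucleus_center = c(0, 0, 3.00),
                                  n1 = 1.37, n2 = 1.39, nm = 1.003) {
  if (any(membrane_semiaxes_top[1:2] != membrane_semiaxes_bottom[1:2]))
    stop("the two half-ellipsoids must share equatorial semi-axes")
  top <- part_half_ellipsoid(membrane_semiaxes_top, half = "+", index = n1,
                             priority = 1L, label = "membrane")
  bot <- part_half_ellipsoid(membrane_semiaxes_bottom, half = "-", index = n1,
                             priority = 1L, label = "membrane")
  nuc <- part_ellipsoid(nucleus_semiaxes, center = nucleus_center, index = n2,
                        priority = 2L, label = "nucleus")
  .check_nucleus_inside(list(nuc), list(top, bot))
  ri_scene(list(top, bot, nuc), medium_index = nm)
}

#' Generic two-ellipsoid nuclear-type model
#'
#' An ellipsoidal membrane with an ellipsoidal nucleus inside.
#'
#' @param membrane_semiaxes membrane semi-axes (um).
#' @param nucleus_semiaxes nucleus semi-axes (um).
#' @param nucleus_center nucleus center (um).
#' @param n1,n2,nm cytoplasm, nucleus and medium refractive indices.
#' @return an `ri_scene`.
#' @export
build_two_ellipsoid <- function(membrane_semiaxes = c(6.0, 6.0, 5.0),
                                nucleus_semiaxes = c(3.0, 3.0, 2.5),
                                nucleus_center = c(0, 0, 1.0),
                                n1 = 1.37, n2 = 1.39, nm = 1.003) {
  mem <- part_ellipsoid(membrane_semiaxes, index = n1, priority = 1L,
                        label = "membrane")
  nuc <- part_ellipsoid(nucleus_semiaxes, center = nucleus_center, index = n2,
                        priority = 2L, label = "nucleus")
  .check_nucleus_inside(list(nuc), list(mem))
  ri_scene(list(mem, nuc), medium_index = nm)
}

#' Built-in cell model catalogue
#'
#' @return named list of zero-argument builder functions for the six built-in
#'   blood-cell models.
#' @export
cell_models <- function() {
  list(rbc = build_rbc, lymphocyte = build_lymphocyte,
       eosinophil = build_eosinophil, neutrophil = build_neutrophil,
       monocyte = build_monocyte_fig1, basophil = build_basophil)
}
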