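## Nucleus surface reconstruction from orthogonal interface outlines, shape
## reporting, and outer-surface recovery by phase subtraction.

.new_mesh <- function(vertices, faces, label = "nucleus") {
  structure(list(vertices = vertices, faces = faces, label = label),
            class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat(sprintf("surface mesh (%s): %d vertices, %d faces, volume %.3f um^3\n",
              x$label, nrow(x$vertices), nrow(x$faces), mesh_volume(x)))
  invisible(x)
}

#' Mesh volume by the divergence theorem
#'
#' @param mesh a `surface_mesh` (closed, consistently oriented).
#' @return enclosed volume (um^3).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c3[, 3] - b[, 3] * c3[, 2],
              b[, 3] * c3[, 1] - b[, 1] * c3[, 3],
              b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  abs(sum(a * cr) / 6)
}

#' Check that a mesh is watertight
#'
#' @param mesh a `surface_mesh`.
#' @return logical: every edge is shared by exactly two faces.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

## interval [lo, hi] of a closed polygon along its second coordinate at
## abscissa x (crossings of edges); NA when x is outside the polygon
.polygon_vrange <- function(pts, x) {
  p <- pts
  if (!all(p[1, ] == p[nrow(p), ])) p <- rbind(p, p[1, ])
  x1 <- p[-nrow(p), 1]; y1 <- p[-nrow(p), 2]
  x2 <- p[-1, 1]; y2 <- p[-1, 2]
  vapply(x, function(xx) {
    hit <- (x1 <= xx & x2 > xx) | (x2 <= xx & x1 > xx)
    if (!any(hit)) return(c(NA_real_, NA_real_))
    t <- (xx - x1[hit]) / (x2[hit] - x1[hit])
    yy <- y1[hit] + t * (y2[hit] - y1[hit])
    c(min(yy), max(yy))
  }, c(0, 0))
}

## build a closed triangulated surface from per-slice elliptical sections
## sections: list(x, yc, zc, wy, wz) vectors; slices ordered in x
.sections_to_mesh <- function(x, yc, zc, wy, wz, n_theta, label) {
  K <- length(x)
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-(n_theta + 1)]
  verts <- matrix(0, K * n_theta + 2, 3)
  for (k in seq_len(K))
    verts[(k - 1) * n_theta + seq_len(n_theta), ] <-
      cbind(x[k], yc[k] + wy[k] * cos(th), zc[k] + wz[k] * sin(th))
  p0 <- K * n_theta + 1L   # pole at low x
  p1 <- K * n_theta + 2L
  dx0 <- x[2] - x[1]
  verts[p0, ] <- c(x[1] - dx0 / 2, yc[1], zc[1])
  verts[p1, ] <- c(x[K] + dx0 / 2, yc[K], zc[K])
  fc <- list()
  idx <- function(k, t) (k - 1L) * n_theta + ((t - 1L) %% n_theta) + 1L
  ## cap fans
  f0 <- t(vapply(seq_len(n_theta), function(t)
    c(p0, idx(1L, t + 1L), idx(1L, t)), integer(3)))
  f1 <- t(vapply(seq_len(n_theta), function(t)
    c(p1, idx(K, t), idx(K, t + 1L)), integer(3)))
  ## side quads
  fs <- matrix(0L, 2L * (K - 1L) * n_theta, 3)
  r <- 1L
  for (k in seq_len(K - 1L)) for (t in seq_len(n_theta)) {
    a <- idx(k, t); b <- idx(k, t + 1L)
    c2 <- idx(k + 1L, t); d <- idx(k + 1L, t + 1L)
    fs[r, ] <- c(a, b, d); fs[r + 1L, ] <- c(a, d, c2)
    r <- r + 2L
  }
  m <- .new_mesh(verts, rbind(f0, fs, f1), label)
  m
}

#' Surface of revolution from one outline
#'
#' Sweeps a closed outline about an in-plane axis: each abscissa's half-width
#' becomes the radius of a circular cross-section (rotating the outline 180
#' degrees and completing the other half by mirror symmetry). The outline
#' must cross the axis line at exactly two abscissae (a two-branch outline);
#' otherwise the revolution is ambiguous and an error is raised.
#'
#' @param outline a `boundary_contour`.
#' @param axis in-plane axis direction to revolve about, `"u"` (first plane
#'   axis, default) or `"v"`; the axis line passes through `level`.
#' @param level coordinate of the axis line along the other in-plane axis;
#'   defaults to the outline centroid.
#' @param n_steps angular facets of the full surface.
#' @param n_slices cross-sections along the axis.
#' @return a watertight `surface_mesh`. The revolution axis is placed along
#'   the world axis matching the outline's plane.
#' @examples
#' th <- seq(0, 2 * pi, length.out = 181)
#' circ <- structure(list(points = cbind(3 * cos(th), 3 * sin(th)),
#'                        plane = "xy", label = "nucleus", method = "synthetic"),
#'                   class = "boundary_contour")
#' m <- rotate_outline(circ)
#' mesh_volume(m) / (4 / 3 * pi * 27)
#' @export
rotate_outline <- function(outline, axis = c("u", "v"), level = NULL,
                           n_steps = 180L, n_slices = 120L) {
  stopifnot(inherits(outline, "boundary_contour"))
  axis <- match.arg(axis)
  pts <- outline$points
  if (axis == "v") pts <- pts[, c(2, 1)]
  if (is.null(level)) level <- .polygon_centroid(outline$points)[if (axis == "u") 2 else 1]
  ## outline must have exactly two crossings of the axis line
  side <- sign(pts[, 2] - level)
  side <- side[side != 0]
  crossings <- sum(diff(side) != 0) + as.integer(side[1] != side[length(side)])
  if (crossings > 2)
    stop("outline crosses the revolution axis at more than 2 points; ",
         "ambiguous surface of revolution")
  xr <- range(pts[, 1])
  xs <- seq(xr[1], xr[2], length.out = n_slices + 2L)[2:(n_slices + 1L)]
  vr <- .polygon_vrange(pts, xs)
  w <- (vr[2, ] - vr[1, ]) / 2
  w[is.na(w)] <- 0
  m <- .sections_to_mesh(xs, rep(level, length(xs)), rep(0, length(xs)),
                         w, w, n_steps, outline$label)
  ## embed in 3D world coordinates according to the outline plane
  .orient_mesh(m, outline$plane, swap = (axis == "v"))
}

## map mesh built in (x = slice axis, y, z-local) coordinates into world axes
.orient_mesh <- function(mesh, plane, swap = FALSE) {
  v <- mesh$vertices
  ax <- plane_axes(plane)
  u_ax <- if (swap) ax[2] else ax[1]
  v_ax <- if (swap) ax[1] else ax[2]
  w_ax <- ax[3]
  out <- matrix(0, nrow(v), 3)
  out[, axis_id(u_ax)] <- v[, 1]
  out[, axis_id(v_ax)] <- v[, 2]
  out[, axis_id(w_ax)] <- v[, 3]
  mesh$vertices <- out
  if (mesh_signed_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c3 <- v[f[, 3], , drop = FALSE]
  cr <- cbind(b[, 2] * c3[, 3] - b[, 3] * c3[, 2],
              b[, 3] * c3[, 1] - b[, 1] * c3[, 3],
              b[, 1] * c3[, 2] - b[, 2] * c3[, 1])
  sum(a * cr) / 6
}

#' Merge two orthogonal outlines into a closed surface
#'
#' Generalizes the outline revolution to both views: at every shared x the
#' cross-section normal to x is an ellipse whose semi-axes are the local
#' half-widths of the x-y and x-z outlines, centered at their local
#' mid-lines. When the two outlines are congruent this reduces to
#' [rotate_outline()].
#'
#' @param outline_xy nucleus contour on plane `"xy"` (a `boundary_contour`).
#' @param outline_xz nucleus contour on plane `"xz"`.
#' @param n_theta angular facets.
#' @param n_slices cross-sections along x.
#' @return a watertight `surface_mesh` in world coordinates.
#' @export
merge_orthogonal <- function(outline_xy, outline_xz, n_theta = 90L,
                             n_slices = 120L) {
  stopifnot(inherits(outline_xy, "boundary_contour"),
            inherits(outline_xz, "boundary_contour"))
  r1 <- range(outline_xy$points[, 1])
  r2 <- range(outline_xz$points[, 1])
  lo <- max(r1[1], r2[1]); hi <- min(r1[2], r2[2])
  if (hi <= lo) stop("outlines share no x interval")
  xs <- seq(lo, hi, length.out = n_slices + 2L)[2:(n_slices + 1L)]
  vy <- .polygon_vrange(outline_xy$points, xs)
  vz <- .polygon_vrange(outline_xz$points, xs)
  yc <- (vy[1, ] + vy[2, ]) / 2; wy <- (vy[2, ] - vy[1, ]) / 2
  zc <- (vz[1, ] + vz[2, ]) / 2; wz <- (vz[2, ] - vz[1, ]) / 2
  ok <- !(is.na(wy) | is.na(wz))
  if (sum(ok) < 3) stop("outlines share no usable x interval")
  fill <- function(a) { a[!ok] <- stats::approx(xs[ok], a[ok], xs[!ok],
                                                rule = 2)$y; a }
  if (any(!ok)) { yc <- fill(yc); zc <- fill(zc); wy <- fill(wy); wz <- fill(wz)
                  wy[!ok] <- 0; wz[!ok] <- 0 }
  m <- .sections_to_mesh(xs, yc, zc, wy, wz, n_theta,
                         outline_xy$label)
  ## sections are built in (x, y, z): matches world for the xy/xz view pair
  if (mesh_signed_volume(m) < 0) m$faces <- m$faces[, c(1, 3, 2)]
  m
}

#' Fit an axis-aligned ellipsoid and report nucleus shape
#'
#' Least-squares fit of an axis-aligned ellipsoid about a given center to a
#' reconstructed surface; reports fitted semi-axes, equivalent volume
#' (4/3 pi a b c), the ellipsoidal degree (pairwise semi-axis ratios b/a,
#' c/a, c/b plus the fit residual) and the mesh volume.
#'
#' @param mesh a `surface_mesh` (or `NULL` when `contours` given).
#' @param center 3-vector, the reconciled nucleus center (um); defaults to
#'   the vertex centroid.
#' @param contours optional list with contours `xy` and `xz` used to build
#'   the mesh via [merge_orthogonal()] when `mesh` is `NULL`.
#' @return object of class `nucleus_report`.
#' @export
fit_ellipsoid <- function(mesh = NULL, center = NULL, contours = NULL) {
  if (is.null(mesh)) {
    if (is.null(contours)) stop("need a mesh or a contour pair")
    mesh <- merge_orthogonal(contours$xy, contours$xz)
  }
  v <- mesh$vertices
  if (is.null(center)) center <- colMeans(v)
  q <- sweep(v, 2, center)
  A <- q^2
  coefs <- solve(crossprod(A), colSums(A))   # LS for u x^2 + v y^2 + w z^2 = 1
  if (any(coefs <= 0)) stop("degenerate surface: ellipsoid fit failed")
  semi <- 1 / sqrt(coefs)
  rr <- sqrt(rowSums(q^2))
  dir <- q / pmax(rr, 1e-12)
  r_ell <- 1 / sqrt(rowSums(sweep(dir, 2, semi, "/")^2))
  residual <- mean(abs(rr - r_ell))
  if (residual > 0.1 * mean(semi))
    warning("non-ellipsoidal nucleus: fit residual exceeds 10% of the mean semi-axis")
  structure(list(center = center,
                 semi_axes = stats::setNames(as.numeric(semi), c("a", "b", "c")),
                 equivalent_volume = 4 / 3 * pi * prod(semi),
                 mesh_volume = mesh_volume(mesh),
                 ellipsoidal_degree = c(b_over_a = semi[[2]] / semi[[1]],
                                        c_over_a = semi[[3]] / semi[[1]],
                                        c_over_b = semi[[3]] / semi[[2]]),
                 residual = residual), class = "nucleus_report")
}

#' @export
print.nucleus_report <- function(x, ...) {
  cat("nucleus report\n")
  cat(sprintf("  center          : (%.3f, %.3f, %.3f) um\n",
              x$center[1], x$center[2], x$center[3]))
  cat(sprintf("  semi-axes       : a=%.3f b=%.3f c=%.3f um\n",
              x$semi_axes[1], x$semi_axes[2], x$semi_axes[3]))
  cat(sprintf("  equiv. volume   : %.2f um^3 (mesh %.2f um^3)\n",
              x$equivalent_volume, x$mesh_volume))
  cat(sprintf("  ellipsoidal deg.: b/a=%.3f c/a=%.3f c/b=%.3f (residual %.4f um)\n",
              x$ellipsoidal_degree[1], x$ellipsoidal_degree[2],
              x$ellipsoidal_degree[3], x$residual))
  invisible(x)
}

#' Convert a nucleus report to a data frame / write it out
#'
#' @param report a `nucleus_report`.
#' @param path output path (`.json` or `.csv`).
#' @return `as.data.frame`: one-row data frame; `write_nucleus_report`:
#'   `path` invisibly.
#' @export
write_nucleus_report <- function(report, path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                         digits = NA)
  } else {
    utils::write.csv(as.data.frame(report), path, row.names = FALSE)
  }
  invisible(path)
}

#' @export
as.data.frame.nucleus_report <- function(x, ...) {
  data.frame(cx = x$center[1], cy = x$center[2], cz = x$center[3],
             a = x$semi_axes[1], b = x$semi_axes[2], c = x$semi_axes[3],
             equivalent_volume = x$equivalent_volume,
             mesh_volume = x$mesh_volume,
             b_over_a = x$ellipsoidal_degree[1],
             c_over_a = x$ellipsoidal_degree[2],
             c_over_b = x$ellipsoidal_degree[3],
             residual = x$residual)
}

## all z-crossings of mesh triangles above (x, y) points; returns a list of
## (zmin, zmax) per point, NA when the vertical ray misses the mesh.
## Assumes the mesh has convex cross-sections along the chosen axis.
.mesh_axis_range <- function(mesh, uv, axis = "z") {
  ai <- axis_id(axis)
  ui <- setdiff(1:3, ai)
  v <- mesh$vertices; f <- mesh$faces
  n <- nrow(uv)
  lo <- rep(NA_real_, n); hi <- rep(NA_real_, n)
  ## bucket query points on a grid keyed by triangle bounding boxes
  for (t in seq_len(nrow(f))) {
    tri <- v[f[t, ], , drop = FALSE]
    u1 <- tri[, ui[1]]; u2 <- tri[, ui[2]]; w <- tri[, ai]
    sel <- which(uv[, 1] >= min(u1) - 1e-12 & uv[, 1] <= max(u1) + 1e-12 &
                 uv[, 2] >= min(u2) - 1e-12 & uv[, 2] <= max(u2) + 1e-12)
    if (length(sel) == 0L) next
    d <- (u2[2] - u2[3]) * (u1[1] - u1[3]) + (u1[3] - u1[2]) * (u2[1] - u2[3])
    if (abs(d) < 1e-14) next
    l1 <- ((u2[2] - u2[3]) * (uv[sel, 1] - u1[3]) +
             (u1[3] - u1[2]) * (uv[sel, 2] - u2[3])) / d
    l2 <- ((u2[3] - u2[1]) * (uv[sel, 1] - u1[3]) +
             (u1[1] - u1[3]) * (uv[sel, 2] - u2[3])) / d
    l3 <- 1 - l1 - l2
    inb <- l1 >= -1e-9 & l2 >= -1e-9 & l3 >= -1e-9
    if (!any(inb)) next
    zz <- l1[inb] * w[1] + l2[inb] * w[2] + l3[inb] * w[3]
    ss <- sel[inb]
    lo[ss] <- pmin(lo[ss], zz, na.rm = TRUE)
    hi[ss] <- pmax(hi[ss], zz, na.rm = TRUE)
  }
  list(lo = lo, hi = hi)
}

#' Thickness map of a reconstructed mesh
#'
#' Per-pixel chord length through a watertight mesh along the projection
#' axis of the chosen plane.
#'
#' @param mesh a watertight `surface_mesh` with convex cross-sections along
#'   the projection axis.
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @param pixel_size pixel pitch (um).
#' @param field,center field of view (um).
#' @return a `thickness_map`.
#' @export
nucleus_thickness_from_mesh <- function(mesh, plane = "xy",
                                        pixel_size = 0.0625, field = 16,
                                        center = c(0, 0)) {
  stopifnot(inherits(mesh, "surface_mesh"))
  if (!mesh_is_watertight(mesh)) stop("mesh is not watertight")
  plane <- match.arg(plane, c("xy", "xz", "yz"))
  g <- .projection_grid(plane, pixel_size, field, center)
  ax <- plane_axes(plane)
  gg <- expand.grid(u = g$u, v = g$v)
  ## plane axes are alphabetical, matching .mesh_axis_range's column order
  uv <- cbind(gg$u, gg$v)
  rng <- .mesh_axis_range(mesh, uv, axis = ax[3])
  th <- ifelse(is.na(rng$lo), 0, rng$hi - rng$lo)
  thickness_map_obj(matrix(th, g$np, g$np), plane = plane,
                    pixel_size = pixel_size, origin = g$origin,
                    compartment = mesh$label)
}

#' Outer-surface thickness by phase subtraction
#'
#' Removes the nucleus contribution from the unwrapped whole-cell phase and
#' converts the remainder to the physical thickness of the outer surface:
#' `h1 = (lambda * phi / (2 pi) - (n2 - n1) * h2) / (n1 - nm)`, clipped at 0.
#'
#' @param map unwrapped whole-cell `phase_map`.
#' @param h2 nucleus `thickness_map` on the same grid.
#' @param n1,n2,nm cytoplasm, nucleus and medium refractive indices.
#' @param wavelength vacuum wavelength (um); defaults to the map's.
#' @return a `thickness_map` of the outer surface.
#' @export
outer_surface_thickness <- function(map, h2, n1, n2, nm,
                                    wavelength = map$wavelength) {
  stopifnot(inherits(map, "phase_map"), inherits(h2, "thickness_map"))
  if (map$wrapped) stop("need an unwrapped phase map")
  if (n1 <= nm) stop("n1 must exceed the medium index nm")
  if (!all(dim(map$values) == dim(h2$values)) ||
      map$pixel_size != h2$pixel_size)
    stop("phase map and thickness map must share the same grid")
  h1 <- (wavelength * map$values / (2 * pi) - (n2 - n1) * h2$values) / (n1 - nm)
  thickness_map_obj(pmax(h1, 0), plane = map$plane,
                    pixel_size = map$pixel_size, origin = map$origin,
                    compartment = "cell")
}

#' Assemble the whole cell from membrane and nucleus surfaces
#'
#' Verifies that the nucleus mesh lies inside the membrane mesh and returns
#' the pair of labeled surfaces.
#'
#' @param outer membrane `surface_mesh` (e.g. from [merge_orthogonal()] on
#'   the cell contours).
#' @param nucleus nucleus `surface_mesh`.
#' @param center optional reconciled nucleus center; when given the nucleus
#'   mesh is translated so its vertex centroid sits there.
#' @return list with elements `membrane` and `nucleus`.
#' @export
assemble_cell <- function(outer, nucleus, center = NULL) {
  stopifnot(inherits(outer, "surface_mesh"), inherits(nucleus, "surface_mesh"))
  if (!is.null(center)) {
    shift <- as.numeric(center) - colMeans(nucleus$vertices)
    nucleus$vertices <- sweep(nucleus$vertices, 2, shift, "+")
  }
  rng <- .mesh_axis_range(outer, nucleus$vertices[, 1:2, drop = FALSE], "z")
  z <- nucleus$vertices[, 3]
  viol <- pmax(z - rng$hi, rng$lo - z, 0)
  viol[is.na(rng$lo)] <- Inf
  if (any(viol > 1e-6)) {
    mx <- max(viol[is.finite(viol)], 0)
    stop(sprintf("nucleus protrudes outside the membrane (max violation %.3f um)",
                 if (any(!is.finite(viol))) Inf else mx))
  }
  outer$label <- "membrane"; nucleus$label <- "nucleus"
  list(membrane = outer, nucleus = nucleus)
}

## ---- mesh export ----------------------------------------------------------

#' Write a mesh to PLY or OBJ
#'
#' ASCII export of a triangulated surface.
#'
#' @param mesh a `surface_mesh`.
#' @param path output path ending in `.ply` or `.obj`.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  if (grepl("\\.ply$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("ply", "format ascii 1.0",
                 paste("element vertex", nrow(v)),
                 "property float x", "property float y", "property float z",
                 paste("element face", nrow(f)),
                 "property list uchar int vertex_indices", "end_header"), con)
    utils::write.table(format(v, digits = 9, trim = TRUE), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(cbind(3L, f - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else if (grepl("\\.obj$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    utils::write.table(cbind("v", format(v, digits = 9, trim = TRUE)), con,
                       row.names = FALSE, col.names = FALSE, quote = FALSE)
    utils::write.table(cbind("f", f), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else stop("unsupported mesh format: ", path)
  invisible(path)
}
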