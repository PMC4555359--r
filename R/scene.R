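## Refractive-index scenes: ordered collections of homogeneous parts in a
## surrounding medium, queryable at any point and projectable into phase maps.

#' Build a refractive-index scene
#'
#' Assembles geometric parts into a scene. The index at any point is that of
#' the highest-priority part containing the point, or the medium index outside
#' all parts. The scene records the containment structure of its parts
#' (which compartment sits inside which), used by the fast analytic
#' projection path.
#'
#' @param parts list of `phase_part` objects (see [part_ellipsoid()]).
#' @param medium_index refractive index of the surrounding medium.
#' @param bbox optional 2x3 matrix (rows `lo`, `hi`) bounding the scene (um);
#'   computed from the parts when omitted.
#' @return an object of class `ri_scene`.
#' @examples
#' sc <- ri_scene(list(part_sphere(6, index = 1.37)), medium_index = 1.003)
#' index_at(sc, c(0, 0, 0))
#' @export
ri_scene <- function(parts, medium_index = 1.003, bbox = NULL) {
  stopifnot(is.list(parts), all(vapply(parts, inherits, TRUE, "phase_part")))
  if (medium_index <= 0) stop("medium_index must be positive")
  if (is.null(bbox) && length(parts) > 0) {
    bbs <- lapply(parts, part_bbox)
    lo <- apply(do.call(rbind, lapply(bbs, function(b) b["lo", ])), 2, min)
    hi <- apply(do.call(rbind, lapply(bbs, function(b) b["hi", ])), 2, max)
    bbox <- rbind(lo = lo - 0.5, hi = hi + 0.5)
  }
  if (is.null(bbox)) bbox <- rbind(lo = c(-8, -8, -8), hi = c(8, 8, 8))
  colnames(bbox) <- c("x", "y", "z")
  sc <- structure(list(parts = parts, medium_index = medium_index,
                       bbox = bbox), class = "ri_scene")
  sc$structure <- .scene_structure(sc)
  sc
}

#' @export
print.ri_scene <- function(x, ...) {
  cat("refractive-index scene:", length(x$parts), "part(s), medium index",
      x$medium_index, "\n")
  for (p in x$parts)
    cat(sprintf("  %-14s %-9s n=%.4g priority=%d\n", p$kind, p$label,
                p$index, p$priority))
  invisible(x)
}

#' Refractive index at points
#'
#' @param scene an `ri_scene`.
#' @param points a 3-vector or an n x 3 matrix of world coordinates (um).
#' @return numeric vector of refractive indices.
#' @export
index_at <- function(scene, points) {
  stopifnot(inherits(scene, "ri_scene"))
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  stopifnot(all(is.finite(points)))
  out <- rep(scene$medium_index, nrow(points))
  ord <- order(vapply(scene$parts, `[[`, 1L, "priority"))
  for (p in scene$parts[ord]) out[part_contains(p, points)] <- p$index
  out
}

## Quasi-uniform points on a part surface, used for containment analysis.
part_surface_points <- function(part, n = 400L) {
  gr <- (1 + sqrt(5)) / 2
  i <- seq_len(n) - 0.5
  th <- 2 * pi * i / gr
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(1 - z^2, 0))
  unit <- cbind(r * cos(th), r * sin(th), z)
  q <- switch(part$kind,
    sphere = ,
    ellipsoid = sweep(unit, 2, part$semi, "*"),
    half_ellipsoid = {
      s <- if (part$half == "+") 1 else -1
      u <- unit
      u[, 3] <- s * abs(u[, 3])         # fold onto the kept half
      pts <- sweep(u, 2, part$semi, "*")
      ## add the equatorial face
      m <- ceiling(sqrt(n))
      g <- seq(-1, 1, length.out = m)
      fg <- as.matrix(expand.grid(g, g))
      fg <- fg[rowSums(fg^2) <= 1, , drop = FALSE]
      rbind(pts, cbind(fg[, 1] * part$semi[1], fg[, 2] * part$semi[2], 0))
    },
    biconcave = {
      m <- ceiling(sqrt(n / 2))
      rho <- seq(0, 1, length.out = m)
      ang <- seq(0, 2 * pi, length.out = 2 * m + 1)[-1]
      g <- expand.grid(rho = rho, ang = ang)
      rr <- g$rho * part$diameter / 2
      h <- biconcave_profile(part, rr)
      rbind(cbind(rr * cos(g$ang), rr * sin(g$ang), h / 2),
            cbind(rr * cos(g$ang), rr * sin(g$ang), -h / 2))
    },
    swept_tube = {
      pts <- NULL
      m <- max(8L, ceiling(n / (16 * length(part$arcs))))
      for (a in part$arcs) {
        th0 <- a$theta[1] * pi / 180; th1 <- a$theta[2] * pi / 180
        tt <- seq(th0, th1, length.out = 4 * m)
        ph <- seq(0, 2 * pi, length.out = 17)[-1]
        for (phi in ph) {
          nx <- cos(tt); ny <- sin(tt)
          px <- a$center[1] + (a$radius + part$tube_radius * cos(phi)) * nx
          py <- a$center[2] + (a$radius + part$tube_radius * cos(phi)) * ny
          pz <- a$center[3] + part$tube_radius * sin(phi)
          pts <- rbind(pts, cbind(px, py, pz))
        }
      }
      pts
    })
  sweep(q %*% t(part$rot), 2, part$center, "+")
}

## Group parts by compartment (label, index, priority) and resolve which group
## contains which; marks whether the strictly-nested fast projection path is
## valid.
.scene_structure <- function(scene) {
  parts <- scene$parts
  if (length(parts) == 0L)
    return(list(groups = list(), nested = TRUE))
  key <- vapply(parts, function(p)
    paste(p$label, p$index, p$priority, sep = "|"), "")
  ug <- unique(key)
  groups <- lapply(ug, function(k) which(key == k))
  prio <- vapply(groups, function(g) parts[[g[1]]]$priority, 1L)
  names(groups) <- vapply(groups, function(g) parts[[g[1]]]$label, "")
  ord <- order(prio)
  groups <- groups[ord]; prio <- prio[ord]
  parent <- rep(NA_integer_, length(groups))   # index into groups, NA = medium
  nested <- TRUE
  in_union <- function(gidx, pts) {
    ins <- rep(FALSE, nrow(pts))
    for (j in groups[[gidx]]) ins <- ins | part_contains(parts[[j]], pts)
    ins
  }
  for (gi in seq_along(groups)) {
    cands <- which(prio < prio[gi])
    if (length(cands) == 0L) next
    pts <- do.call(rbind, lapply(groups[[gi]],
                                 function(j) part_surface_points(parts[[j]], 300L)))
    found <- FALSE
    for (ci in rev(cands)) {          # innermost candidate first
      if (all(in_union(ci, pts))) { parent[gi] <- ci; found <- TRUE; break }
      if (any(in_union(ci, pts))) { nested <- FALSE }  # straddles a boundary
    }
    if (!found && !is.na(parent[gi])) found <- TRUE
  }
  ## sibling groups sharing a parent must not overlap for the fast path
  for (gi in seq_along(groups)) for (gj in seq_along(groups)) {
    if (gj <= gi) next
    if (identical(parent[gi], parent[gj]) && prio[gi] == prio[gj]) {
      pts <- do.call(rbind, lapply(groups[[gj]],
                                   function(j) part_surface_points(parts[[j]], 200L)))
      if (any(in_union(gi, pts))) nested <- FALSE
    }
  }
  list(groups = groups, priority = prio, parent = parent, nested = nested)
}

## index of the compartment surrounding a group (medium if top level)
.group_background_index <- function(scene, gi) {
  pa <- scene$structure$parent[gi]
  if (is.na(pa)) scene$medium_index
  else scene$parts[[scene$structure$groups[[pa]][1]]]$index
}

## ---- scene configuration files -------------------------------------------

#' Read and write scene configuration files
#'
#' Scenes serialize to a flat YAML document with one section per part; reading
#' it back reproduces the scene (`read_scene_config(write_scene_config(s))`
#' round-trips).
#'
#' @param scene an `ri_scene`.
#' @param path file path.
#' @return `read_scene_config` returns an `ri_scene`; `write_scene_config`
#'   returns `path` invisibly.
#' @export
write_scene_config <- function(scene, path) {
  stopifnot(inherits(scene, "ri_scene"))
  ser_part <- function(p) {
    out <- list(kind = p$kind, center = p$center, index = p$index,
                priority = p$priority, label = p$label)
    if (!is.null(p$orient)) out$orient <- as.list(p$orient)
    out <- c(out, switch(p$kind,
      sphere = list(radius = p$semi[1]),
      ellipsoid = ,
      half_ellipsoid = list(semi_axes = p$semi),
      biconcave = list(diameter = p$diameter, center_thickness = p$tc,
                       edge_thickness = p$te),
      swept_tube = list(tube_radius = p$tube_radius,
                        arcs = lapply(p$arcs, function(a)
                          list(center = a$center, radius = a$radius,
                               theta = a$theta)))))
    if (p$kind == "half_ellipsoid") out$half <- p$half
    out
  }
  doc <- list(medium_index = scene$medium_index,
              bbox = list(lo = unname(scene$bbox["lo", ]),
                          hi = unname(scene$bbox["hi", ])),
              parts = lapply(scene$parts, ser_part))
  yaml::write_yaml(doc, path, precision = 15)
  invisible(path)
}

#' @rdname write_scene_config
#' @export
read_scene_config <- function(path) {
  doc <- yaml::read_yaml(path)
  de_part <- function(s) {
    orient <- if (!is.null(s$orient)) unlist(s$orient) else NULL
    common <- list(center = unlist(s$center), index = s$index,
                   priority = s$priority, label = s$label, orient = orient)
    switch(s$kind,
      sphere = part_sphere(s$radius, center = common$center, index = s$index,
                           priority = s$priority, label = s$label),
      ellipsoid = do.call(part_ellipsoid,
                          c(list(semi_axes = unlist(s$semi_axes)), common)),
      half_ellipsoid = do.call(part_half_ellipsoid,
                               c(list(semi_axes = unlist(s$semi_axes),
                                      half = s$half), common)),
      biconcave = do.call(part_biconcave,
                          c(list(diameter = s$diameter,
                                 center_thickness = s$center_thickness,
                                 edge_thickness = s$edge_thickness), common)),
      swept_tube = do.call(part_swept_tube,
                           c(list(arcs = lapply(s$arcs, function(a)
                                    list(center = unlist(a$center),
                                         radius = a$radius,
                                         theta = unlist(a$theta))),
                                  tube_radius = s$tube_radius), common)),
      stop("unknown part kind in config: ", s$kind))
  }
  bbox <- NULL
  if (!is.null(doc$bbox))
    bbox <- rbind(lo = unlist(doc$bbox$lo), hi = unlist(doc$bbox$hi))
  ri_scene(lapply(doc$parts, de_part), medium_index = doc$medium_index,
           bbox = bbox)
}

## ---- voxelization ---------------------------------------------------------

#' Voxelize a scene to a 3D refractive-index grid
#'
#' @param scene an `ri_scene`.
#' @param step voxel pitch (um).
#' @param bbox optional bounding box; defaults to the scene's.
#' @return list with `index` (3D array, x by y by z), `x`, `y`, `z` voxel
#'   center coordinates.
#' @export
voxelize_scene <- function(scene, step = 0.1, bbox = scene$bbox) {
  stopifnot(step > 0)
  ax <- lapply(1:3, function(i) seq(bbox["lo", i] + step / 2, bbox["hi", i],
                                    by = step))
  g <- as.matrix(expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]]))
  v <- index_at(scene, g)
  list(index = array(v, vapply(ax, length, 1L)),
       x = ax[[1]], y = ax[[2]], z = ax[[3]])
}

#' Export a voxelized scene
#'
#' Writes the index grid as a multi-page 32-bit float TIFF (one page per z
#' slice) or as plain-text matrix slices.
#'
#' @param vox result of [voxelize_scene()].
#' @param path output file (TIFF) or directory (text slices).
#' @param format `"tiff"` or `"text"`.
#' @return `path`, invisibly.
#' @export
write_voxels <- function(vox, path, format = c("tiff", "text")) {
  format <- match.arg(format)
  if (format == "tiff") {
    slices <- lapply(seq_along(vox$z), function(k) vox$index[, , k])
    tiff::writeTIFF(slices, path, bits.per.sample = 32L,
                    reduce = FALSE)
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    for (k in seq_along(vox$z))
      utils::write.table(vox$index[, , k],
                         file.path(path, sprintf("slice_%04d.txt", k)),
                         row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}
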