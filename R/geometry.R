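## Geometric primitives for piecewise-constant refractive-index scenes.
## All lengths in micrometres; world frame is right-handed with z the optical
## axis of the x-y view.

#' Rotation matrix from named axis angles
#'
#' Builds the world-from-part rotation matrix by composing rotations about the
#' named coordinate axes in the order given.
#'
#' @param orient named numeric vector of angles in degrees, names in
#'   `c("x","y","z")`, e.g. `c(z = 90)`. `NULL` or empty means identity.
#' @return 3x3 rotation matrix.
#' @keywords internal
rotation_matrix <- function(orient = NULL) {
  R <- diag(3)
  if (is.null(orient) || length(orient) == 0L) return(R)
  stopifnot(!is.null(names(orient)), all(names(orient) %in% c("x", "y", "z")))
  for (i in seq_along(orient)) {
    a <- orient[[i]] * pi / 180
    ca <- cos(a); sa <- sin(a)
    Ri <- switch(names(orient)[i],
      x = matrix(c(1, 0, 0, 0, ca, sa, 0, -sa, ca), 3, 3),
      y = matrix(c(ca, 0, -sa, 0, 1, 0, sa, 0, ca), 3, 3),
      z = matrix(c(ca, sa, 0, -sa, ca, 0, 0, 0, 1), 3, 3))
    R <- Ri %*% R
  }
  R
}

new_part <- function(kind, center, index, priority, label, orient = NULL, ...) {
  stopifnot(length(center) == 3, all(is.finite(center)))
  if (index <= 1.0) stop("refractive index must exceed 1.0")
  p <- c(list(kind = kind, center = as.numeric(center), orient = orient,
              index = as.numeric(index), priority = as.integer(priority),
              label = label), list(...))
  p$rot <- rotation_matrix(orient)
  class(p) <- "phase_part"
  p
}

#' Geometric scene parts
#'
#' Constructors for the homogeneous compartments a refractive-index scene is
#' assembled from. Within a scene, the index at a point is that of the
#' highest-priority part containing it (nucleus over cytoplasm over medium).
#'
#' @param semi_axes semi-axis lengths along the part's x, y, z axes (um).
#' @param center part center in world coordinates (um).
#' @param index refractive index of the compartment (dimensionless, > 1).
#' @param priority integer; larger wins where parts overlap.
#' @param label compartment label, e.g. `"membrane"` or `"nucleus"`.
#' @param orient named angles (degrees) rotating the part about world axes,
#'   e.g. `c(z = 90)`; applied in the order given.
#' @param radius sphere or tube radius (um).
#' @param diameter biconcave disc diameter (um).
#' @param center_thickness,edge_thickness biconcave axial thickness at the
#'   center and its interior maximum (um); the profile is a cosine series
#'   constrained to these values and to zero thickness at the rim.
#' @param half which half of the ellipsoid to keep, `"+"` (part z >= 0) or
#'   `"-"`.
#' @param arcs list of circular arcs in the part x-y plane, each a list with
#'   `center` (3-vector), `radius`, and `theta` (two angles, degrees).
#' @param tube_radius radius of the tube swept along the arcs (um).
#' @return an object of class `phase_part`.
#' @name scene-parts
NULL

#' @rdname scene-parts
#' @export
part_ellipsoid <- function(semi_axes, center = c(0, 0, 0), index = 1.39,
                           priority = 2L, label = "nucleus", orient = NULL) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0))
  new_part("ellipsoid", center, index, priority, label, orient,
           semi = as.numeric(semi_axes))
}

#' @rdname scene-parts
#' @export
part_sphere <- function(radius, center = c(0, 0, 0), index = 1.37,
                        priority = 1L, label = "membrane") {
  stopifnot(radius > 0)
  new_part("sphere", center, index, priority, label, NULL,
           semi = rep(as.numeric(radius), 3))
}

#' @rdname scene-parts
#' @export
part_half_ellipsoid <- function(semi_axes, center = c(0, 0, 0), half = "+",
                                index = 1.37, priority = 1L,
                                label = "membrane", orient = NULL) {
  stopifnot(length(semi_axes) == 3, all(semi_axes > 0), half %in% c("+", "-"))
  new_part("half_ellipsoid", center, index, priority, label, orient,
           semi = as.numeric(semi_axes), half = half)
}

#' @rdname scene-parts
#' @export
part_biconcave <- function(diameter, center_thickness, edge_thickness,
                           center = c(0, 0, 0), index = 1.40, priority = 1L,
                           label = "cell", orient = NULL) {
  if (!(edge_thickness >= center_thickness && center_thickness > 0))
    stop("need edge_thickness >= center_thickness > 0")
  if (diameter <= 0) stop("diameter must be positive")
  co <- biconcave_coefficients(center_thickness, edge_thickness)
  new_part("biconcave", center, index, priority, label, orient,
           diameter = diameter, tc = center_thickness, te = edge_thickness,
           coef = co)
}

#' @rdname scene-parts
#' @export
part_swept_tube <- function(arcs, tube_radius, center = c(0, 0, 0),
                            index = 1.39, priority = 2L, label = "nucleus",
                            orient = NULL) {
  stopifnot(tube_radius > 0, length(arcs) >= 1)
  for (a in arcs)
    stopifnot(length(a$center) == 3, a$radius > 0, length(a$theta) == 2)
  new_part("swept_tube", center, index, priority, label, orient,
           arcs = arcs, tube_radius = tube_radius)
}

## Cosine-series biconcave profile h(rho) = A + B cos(pi rho) + C cos(2 pi rho)
## constrained to h(0) = tc, h(1) = 0 and interior maximum te.
biconcave_coefficients <- function(tc, te) {
  B <- tc / 2
  disc <- (tc / 2 - te)^2 - tc^2 / 4
  if (disc < 0) stop("no biconcave profile with these thicknesses")
  roots <- ((tc / 2 - te) + c(1, -1) * sqrt(disc)) / 4
  ok <- abs(-B / (4 * roots)) < 1          # interior stationary point
  if (!any(ok)) stop("no biconcave profile with these thicknesses")
  C <- roots[ok][which.max(abs(roots[ok]))]
  c(A = tc / 2 - C, B = B, C = C)
}

#' Biconcave disc thickness profile
#'
#' Axial thickness of a biconcave disc part as a function of radial distance
#' from its axis.
#'
#' @param part a `phase_part` of kind `"biconcave"`.
#' @param r radial distances (um).
#' @return thickness values (um), zero beyond the rim.
#' @export
biconcave_profile <- function(part, r) {
  stopifnot(inherits(part, "phase_part"), part$kind == "biconcave")
  rho <- 2 * r / part$diameter
  h <- part$coef[["A"]] + part$coef[["B"]] * cos(pi * rho) +
    part$coef[["C"]] * cos(2 * pi * rho)
  h[rho > 1] <- 0
  pmax(h, 0)
}

## points: n x 3 matrix in world coordinates -> logical vector
part_contains <- function(part, points) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3)
  q <- sweep(points, 2, part$center) %*% part$rot  # world -> part frame
  switch(part$kind,
    sphere = ,
    ellipsoid = {
      rowSums(sweep(q, 2, part$semi, "/")^2) <= 1
    },
    half_ellipsoid = {
      inside <- rowSums(sweep(q, 2, part$semi, "/")^2) <= 1
      if (part$half == "+") inside & q[, 3] >= 0 else inside & q[, 3] <= 0
    },
    biconcave = {
      r <- sqrt(q[, 1]^2 + q[, 2]^2)
      h <- biconcave_profile(part, r)
      r <= part$diameter / 2 & abs(q[, 3]) <= h / 2
    },
    swept_tube = {
      d <- rep(Inf, nrow(q))
      for (a in part$arcs) d <- pmin(d, .arc_distance(a, q))
      d <= part$tube_radius
    },
    stop("unknown part kind"))
}

## distance from part-frame points to a circular arc in the part x-y plane
.arc_distance <- function(arc, q) {
  dx <- q[, 1] - arc$center[1]
  dy <- q[, 2] - arc$center[2]
  dz <- q[, 3] - arc$center[3]
  th0 <- arc$theta[1] * pi / 180
  span <- (arc$theta[2] - arc$theta[1]) * pi / 180
  stopifnot(span > 0, span <= 2 * pi + 1e-9)
  ang <- atan2(dy, dx)
  rel <- (ang - th0) %% (2 * pi)
  on_arc <- rel <= span
  ## nearest arc point at the same azimuth
  rr <- sqrt(dx^2 + dy^2)
  d_arc <- sqrt((rr - arc$radius)^2 + dz^2)
  ## endpoint distances
  th1 <- th0 + span
  d1 <- sqrt((dx - arc$radius * cos(th0))^2 + (dy - arc$radius * sin(th0))^2 + dz^2)
  d2 <- sqrt((dx - arc$radius * cos(th1))^2 + (dy - arc$radius * sin(th1))^2 + dz^2)
  ifelse(on_arc, d_arc, pmin(d1, d2))
}

## world-frame axis-aligned bounding box, rows = (lo, hi), cols = x,y,z
part_bbox <- function(part) {
  r <- switch(part$kind,
    sphere = ,
    ellipsoid = ,
    half_ellipsoid = {
      ## support of |R diag(semi)| in each world direction
      apply(abs(part$rot %*% diag(part$semi)), 1, function(v) sqrt(sum(v^2)))
    },
    biconcave = {
      s <- c(part$diameter / 2, part$diameter / 2, part$te / 2)
      apply(abs(part$rot %*% diag(s)), 1, function(v) sqrt(sum(v^2)))
    },
    swept_tube = {
      m <- 0
      for (a in part$arcs)
        m <- max(m, sqrt(sum(a$center^2)) + a$radius)
      rep(m + part$tube_radius, 3)
    })
  rbind(lo = part$center - r, hi = part$center + r)
}

axis_id <- function(axis) match(axis, c("x", "y", "z"))

## Entry/exit of rays along a world coordinate axis for convex analytic parts.
## origins: n x 3 world points on the rays (the axis coordinate is ignored);
## returns list(t0, t1) with NA for rays that miss. Only for convex kinds.
part_interval_analytic <- function(part, origins, axis) {
  ai <- axis_id(axis)
  d <- c(0, 0, 0); d[ai] <- 1
  o <- origins; o[, ai] <- 0
  oq <- sweep(o, 2, part$center) %*% part$rot
  dq <- as.numeric(matrix(d, 1, 3) %*% part$rot)
  s <- part$semi
  A <- sum((dq / s)^2)
  Bv <- 2 * (oq %*% (dq / s^2))[, 1]
  Cv <- rowSums(sweep(oq, 2, s, "/")^2) - 1
  disc <- Bv^2 - 4 * A * Cv
  hit <- disc > 0
  t0 <- t1 <- rep(NA_real_, nrow(o))
  sq <- sqrt(pmax(disc, 0))
  t0[hit] <- ((-Bv - sq) / (2 * A))[hit]
  t1[hit] <- ((-Bv + sq) / (2 * A))[hit]
  if (part$kind == "half_ellipsoid") {
    ## intersect with halfspace sign * z_part >= 0 (linear in t)
    sgn <- if (part$half == "+") 1 else -1
    a0 <- sgn * oq[, 3]
    b0 <- sgn * dq[3]
    if (abs(b0) < 1e-12) {
      drop <- a0 < 0
      t0[drop] <- NA; t1[drop] <- NA
    } else {
      tb <- -a0 / b0
      if (b0 > 0) t0 <- pmax(t0, tb) else t1 <- pmin(t1, tb)
      drop <- !is.na(t0) & t0 >= t1
      t0[drop] <- NA; t1[drop] <- NA
    }
  }
  list(t0 = t0, t1 = t1)
}

## Numeric interval finder for one ray through a non-convex part.
## Returns a k x 2 matrix of (t_in, t_out); step is the scan step in um.
part_intervals_numeric <- function(part, origin, axis, step = 0.02) {
  ai <- axis_id(axis)
  bb <- part_bbox(part)
  lo <- bb["lo", ai] - step
  hi <- bb["hi", ai] + step
  if (hi <= lo) return(matrix(numeric(0), 0, 2))
  ts <- seq(lo, hi, by = step)
  pts <- matrix(rep(origin, each = length(ts)), ncol = 3)
  pts[, ai] <- ts
  ins <- part_contains(part, pts)
  if (!any(ins)) return(matrix(numeric(0), 0, 2))
  dd <- diff(c(FALSE, ins, FALSE))
  starts <- which(dd == 1L)          # first inside sample
  ends <- which(dd == -1L) - 1L      # last inside sample
  refine <- function(t_out, t_in) {  # bisect boundary between outside/inside
    for (i in 1:30) {
      tm <- (t_out + t_in) / 2
      pm <- origin; pm[ai] <- tm
      if (part_contains(part, matrix(pm, 1, 3))) t_in <- tm else t_out <- tm
    }
    (t_out + t_in) / 2
  }
  n_int <- length(starts)
  out <- matrix(0, n_int, 2)
  for (k in seq_len(n_int)) {
    t_in_lo <- ts[starts[k]]
    out[k, 1] <- if (starts[k] == 1L) t_in_lo else refine(ts[starts[k] - 1L], t_in_lo)
    t_in_hi <- ts[ends[k]]
    out[k, 2] <- if (ends[k] == length(ts)) t_in_hi else refine(ts[ends[k] + 1L], t_in_hi)
  }
  out
}

## TRUE when rays along every coordinate axis meet the part in one interval
part_is_convex <- function(part)
  part$kind %in% c("sphere", "ellipsoid", "half_ellipsoid")
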