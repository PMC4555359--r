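## Inflexion-curve boundary extraction.
##
## At the projected silhouette of a homogeneous compartment the chord-length
## profile has a square-root kink, so the phase surface's curvature diverges
## to minus infinity just inside the interface ("phase mutation"). The
## response field used here is the clipped negative principal curvature of
## the Gaussian-smoothed phase: single-signed at every interface, independent
## of the local gradient direction. Interfaces are traced radially as ridges
## of this response; sub-pixel peak positions are corrected by the
## (universal) offset of the smoothed square-root-kink peak, computed once
## from the 1D edge model.

.gauss_kernel <- function(sigma, order = 0L) {
  r <- max(1L, ceiling(4 * sigma))
  u <- (-r):r
  g <- exp(-u^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
         "0" = g,
         "1" = -u / sigma^2 * g,                 # odd: zero-sum by symmetry
         "2" = {
           g2 <- (u^2 - sigma^2) / sigma^4 * g
           g2 - mean(g2)                         # exact zero response on constants
         })
}

## separable convolution with replicate padding
.conv_sep <- function(m, kx, ky) {
  n1 <- nrow(m); n2 <- ncol(m)
  rx <- (length(kx) - 1) / 2; ry <- (length(ky) - 1) / 2
  mp <- m[c(rep(1, rx), 1:n1, rep(n1, rx)), , drop = FALSE]
  out <- apply(mp, 2, function(col) stats::filter(col, rev(kx), sides = 2))
  out <- out[(rx + 1):(rx + n1), , drop = FALSE]
  mp <- out[, c(rep(1, ry), 1:n2, rep(n2, ry)), drop = FALSE]
  out2 <- t(apply(mp, 1, function(row) stats::filter(row, rev(ky), sides = 2)))
  out2[, (ry + 1):(ry + n2), drop = FALSE]
}

.bilin <- function(m, xi, yi) {
  i0 <- floor(xi); j0 <- floor(yi)
  di <- xi - i0; dj <- yi - j0
  i0 <- pmin(pmax(i0, 1), nrow(m) - 1)
  j0 <- pmin(pmax(j0, 1), ncol(m) - 1)
  m[cbind(i0, j0)] * (1 - di) * (1 - dj) +
    m[cbind(i0 + 1, j0)] * di * (1 - dj) +
    m[cbind(i0, j0 + 1)] * (1 - di) * dj +
    m[cbind(i0 + 1, j0 + 1)] * di * dj
}

## Peak offset (in pixels, measured into the compartment) of the smoothed
## negative-curvature response at a sqrt(u) edge; universal given sigma.
.kink_cache <- new.env(parent = emptyenv())
.kink_offset_px <- function(sigma_px) {
  key <- sprintf("%.6g", sigma_px)
  if (!is.null(.kink_cache[[key]])) return(.kink_cache[[key]])
  du <- 0.005
  u <- seq(-30, 60, by = du)
  f <- sqrt(pmax(u, 0))
  s <- sigma_px / du
  r <- ceiling(5 * s)
  uu <- (-r):r
  g2 <- (uu^2 - s^2) / s^4 * exp(-uu^2 / (2 * s^2))
  g2 <- g2 - mean(g2)
  fp <- c(rep(0, r), f, rep(f[length(f)], r))
  d2 <- stats::filter(fp, rev(g2), sides = 2)[(r + 1):(r + length(u))]
  off <- u[which.max(-d2)]
  .kink_cache[[key]] <- off
  off
}

#' Curvature response field of an unwrapped phase map
#'
#' Computes the interface-detection response: the clipped negative principal
#' curvature (largest negative eigenvalue of the Hessian, sign-flipped) of
#' the Gaussian-smoothed phase, in pixel units. Connected ridges of the
#' response trace the projected interfaces between compartments of different
#' refractive index. A variant projecting the second derivative onto the
#' local gradient direction is available for comparison.
#'
#' @param map an unwrapped `phase_map`.
#' @param smoothing_sigma Gaussian scale in um; defaults to one pixel.
#' @param response `"curvature"` (negative principal curvature, default) or
#'   `"gradient"` (second directional derivative along the local gradient,
#'   sign-flipped and clipped).
#' @return a matrix of class `inflexion_field` with attributes `plane`,
#'   `pixel_size`, `origin` and `sigma_px`.
#' @export
inflexion_field <- function(map, smoothing_sigma = NULL,
                            response = c("curvature", "gradient")) {
  stopifnot(inherits(map, "phase_map"))
  if (map$wrapped) stop("inflexion_field needs an unwrapped map")
  response <- match.arg(response)
  sig <- if (is.null(smoothing_sigma)) 1 else smoothing_sigma / map$pixel_size
  if (sig < 0) stop("smoothing_sigma must be >= 0")
  sig <- max(sig, 0.5)
  g0 <- .gauss_kernel(sig, 0L)
  g1 <- .gauss_kernel(sig, 1L)
  g2 <- .gauss_kernel(sig, 2L)
  phi <- map$values
  fxx <- .conv_sep(phi, g2, g0)
  fyy <- .conv_sep(phi, g0, g2)
  fxy <- .conv_sep(phi, g1, g1)
  if (response == "curvature") {
    tr2 <- (fxx + fyy) / 2
    dd <- sqrt(((fxx - fyy) / 2)^2 + fxy^2)
    R <- pmax(-(tr2 - dd), 0)           # -lambda_min, clipped
  } else {
    fx <- .conv_sep(phi, g1, g0)
    fy <- .conv_sep(phi, g0, g1)
    num <- fxx * fx^2 + 2 * fxy * fx * fy + fyy * fy^2
    R <- pmax(-num / (fx^2 + fy^2 + 1e-12), 0)
  }
  structure(R, class = "inflexion_field", plane = map$plane,
            pixel_size = map$pixel_size, origin = map$origin,
            sigma_px = sig)
}

## physical (u, v) -> fractional pixel indices of a field/map
.to_px <- function(obj, u, v) {
  org <- if (inherits(obj, "inflexion_field")) attr(obj, "origin") else obj$origin
  ps <- if (inherits(obj, "inflexion_field")) attr(obj, "pixel_size") else obj$pixel_size
  list(i = (u - org[1]) / ps + 1, j = (v - org[2]) / ps + 1)
}

.ray_profile <- function(R, center, theta, rmax, dr) {
  rad <- seq(dr, rmax, by = dr)
  px <- .to_px(R, center[1] + rad * cos(theta), center[2] + rad * sin(theta))
  ok <- px$i >= 1 & px$i <= nrow(R) & px$j >= 1 & px$j <= ncol(R)
  v <- rep(0, length(rad))
  if (any(ok)) v[ok] <- .bilin(unclass(R), px$i[ok], px$j[ok])
  list(rad = rad, v = v)
}

.subpix_peak <- function(rad, v, k, dr) {
  r0 <- rad[k]
  if (k > 1 && k < length(v)) {
    den <- v[k - 1] - 2 * v[k] + v[k + 1]
    if (den < 0) r0 <- r0 + (v[k - 1] - v[k + 1]) / (2 * den) * dr
  }
  r0
}

.polygon_centroid <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  if (!all(pts[1, ] == pts[nrow(pts), ])) { x <- c(x, x[1]); y <- c(y, y[1]) }
  n <- length(x)
  cr <- x[-1] * y[-n] - x[-n] * y[-1]
  A <- sum(cr) / 2
  if (abs(A) < 1e-12) stop("degenerate (zero-area) contour")
  c(sum((x[-1] + x[-n]) * cr) / (6 * A), sum((y[-1] + y[-n]) * cr) / (6 * A))
}

.polygon_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  if (!all(pts[1, ] == pts[nrow(pts), ])) { x <- c(x, x[1]); y <- c(y, y[1]) }
  n <- length(x)
  abs(sum(x[-1] * y[-n] - x[-n] * y[-1]) / 2)
}

.new_contour <- function(pts, plane, label, method) {
  pts <- rbind(pts, pts[1, ])        # close
  structure(list(points = pts, plane = plane, label = label,
                 method = method), class = "boundary_contour")
}

#' Construct a boundary contour
#'
#' An ordered closed planar curve (physical units) labeling one detected
#' interface on a projection plane. The first and last points are identical;
#' the constructor closes an open point list.
#'
#' @param points n x 2 matrix of (u, v) coordinates in um along the plane's
#'   two axes.
#' @param plane `"xy"`, `"xz"` or `"yz"`.
#' @param label `"nucleus"` or `"cell"`.
#' @param method provenance tag.
#' @return a `boundary_contour`.
#' @export
boundary_contour <- function(points, plane = "xy", label = "nucleus",
                             method = "manual") {
  points <- as.matrix(points)
  stopifnot(ncol(points) == 2, nrow(points) >= 3)
  plane <- match.arg(plane, c("xy", "xz", "yz"))
  if (all(points[1, ] == points[nrow(points), ]))
    points <- points[-nrow(points), , drop = FALSE]
  .new_contour(points, plane, label, method)
}

#' @export
print.boundary_contour <- function(x, ...) {
  cat(sprintf("boundary contour (%s, %s): %d points, area %.3g um^2\n",
              x$label, x$plane, nrow(x$points) - 1, .polygon_area(x$points)))
  invisible(x)
}

## per-angle radius of a closed contour around a center (linear interp)
.contour_radius_fun <- function(pts, center, theta) {
  tc <- atan2(pts[, 2] - center[2], pts[, 1] - center[1])
  rc <- sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2)
  o <- order(tc)
  tc <- tc[o]; rc <- rc[o]
  th <- ifelse(theta > pi, theta - 2 * pi, theta)
  stats::approx(c(tc[1] - 1e-9, tc, tc[1] + 2 * pi), c(rc[length(rc)], rc, rc[1]),
                xout = th, rule = 2)$y
}

.extract_outer <- function(R, center, n_angles, dr, offs, rmax) {
  th <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  r <- vapply(th, function(t) {
    pr <- .ray_profile(R, center, t, rmax, dr)
    k <- which.max(pr$v)
    .subpix_peak(pr$rad, pr$v, k, dr) + offs
  }, 0)
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

## strict interior local maxima of a profile (indices)
.local_maxima <- function(v) {
  n <- length(v)
  if (n < 3L) return(integer(0))
  which(v[2:(n - 1)] > 0 & v[2:(n - 1)] >= v[1:(n - 2)] &
          v[2:(n - 1)] >= v[3:n]) + 1L
}

.extract_inner <- function(R, center, outer_pts, n_angles, dr, offs,
                           thr_frac = 0.25, min_coverage = 0.85,
                           iterations = 3L) {
  sig <- attr(R, "sigma_px") * attr(R, "pixel_size")
  th <- seq(0, 2 * pi, length.out = n_angles + 1)[-(n_angles + 1)]
  ## one radial sweep: returns per-angle interior candidate peaks (strict
  ## local maxima whose radius stays clear of the cell rim's own peak zone)
  sweep_rays <- function(center) {
    rcell <- .contour_radius_fun(outer_pts, center, th)
    profs <- lapply(seq_along(th), function(i)
      .ray_profile(R, center, th[i], max(rcell[i] - 2 * dr, 0.2), dr))
    cand <- lapply(seq_along(th), function(i) {
      ks <- .local_maxima(profs[[i]]$v)
      ks[profs[[i]]$rad[ks] < rcell[i] - 3 * sig]   # not the rim itself
    })
    list(profs = profs, cand = cand, rcell = rcell)
  }
  peak_floor <- function(sw) {
    strongest <- vapply(seq_along(th), function(i) {
      if (length(sw$cand[[i]]) == 0L) return(NA_real_)
      max(sw$profs[[i]]$v[sw$cand[[i]]])
    }, 0)
    if (all(is.na(strongest))) return(NA_real_)
    thr_frac * stats::median(strongest, na.rm = TRUE)
  }
  ## seed: response-weighted centroid of all interior candidate peaks seen
  ## from the cell centroid (the given center may sit far off the nucleus,
  ## or on its rim, where ray tracing alone misbehaves)
  sw <- sweep_rays(center)
  floorv <- peak_floor(sw)
  if (is.na(floorv)) return(NULL)
  cl <- do.call(rbind, lapply(seq_along(th), function(i) {
    ks <- sw$cand[[i]]
    ks <- ks[sw$profs[[i]]$v[ks] >= floorv]
    if (length(ks) == 0L) return(NULL)
    cbind(center[1] + sw$profs[[i]]$rad[ks] * cos(th[i]),
          center[2] + sw$profs[[i]]$rad[ks] * sin(th[i]),
          sw$profs[[i]]$v[ks])
  }))
  if (is.null(cl) || nrow(cl) < 0.3 * n_angles) return(NULL)
  center <- c(sum(cl[, 1] * cl[, 3]), sum(cl[, 2] * cl[, 3])) / sum(cl[, 3])
  pts <- NULL; ok <- NULL
  for (iter in seq_len(iterations)) {
    sw <- sweep_rays(center)
    floorv <- peak_floor(sw)
    if (is.na(floorv)) return(NULL)
    pts <- t(vapply(seq_along(th), function(i) {
      pr <- sw$profs[[i]]
      ks <- sw$cand[[i]][pr$v[sw$cand[[i]]] >= floorv]
      if (length(ks) == 0L) return(c(NA_real_, NA_real_))
      k <- ks[1]                                  # innermost significant peak
      win <- which(pr$rad >= pr$rad[k] - 0.1 & pr$rad <= pr$rad[k] + 0.15)
      k <- win[which.max(pr$v[win])]
      r0 <- .subpix_peak(pr$rad, pr$v, k, dr) + offs
      c(center[1] + r0 * cos(th[i]), center[2] + r0 * sin(th[i]))
    }, c(0, 0)))
    ## angular-consistency filter, once the center has converged (early
    ## iterations may sit close to the ridge itself, where the legitimate
    ## radius function varies quickly)
    if (iter == iterations) {
      rr <- sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2)
      rfill <- rr
      rfill[is.na(rfill)] <- stats::median(rr, na.rm = TRUE)
      rmed <- stats::runmed(c(rfill, rfill, rfill), 15)[n_angles + seq_len(n_angles)]
      drop <- is.na(rr) | abs(rr - rmed) > max(0.3, 5 * dr)
      pts[drop, ] <- NA_real_
    }
    ok <- !is.na(pts[, 1])
    need <- if (iter < iterations) 0.5 else min_coverage
    if (sum(ok) < need * n_angles) return(NULL)
    center <- .polygon_centroid(pts[ok, , drop = FALSE])
  }
  ## a "nucleus" tracing the cell rim itself is no nucleus
  rin <- sqrt((pts[ok, 1] - center[1])^2 + (pts[ok, 2] - center[2])^2)
  rc <- .contour_radius_fun(outer_pts, center, th[ok])
  if (mean(rc - rin) < 4 * sig) return(NULL)
  list(points = pts[ok, , drop = FALSE], center = center)
}

#' Extract interface contours from a curvature response field
#'
#' Traces closed interface contours as ridges of the inflexion response,
#' assuming nested, star-shaped interfaces (one cell outline, optionally one
#' nucleus outline inside it). The cell/medium interface is located first as
#' the per-angle response maximum from the phase-weighted map center; the
#' nucleus/cytoplasm interface is then the innermost interior ridge peak
#' above an adaptive threshold, iterating the nucleus center to the contour
#' centroid. Sub-pixel radii come from a quadratic fit across the ridge plus
#' the calibrated kink offset.
#'
#' @param response an `inflexion_field`.
#' @param map the unwrapped `phase_map` the response was computed from.
#' @param n_angles angular sampling of each contour.
#' @param require_nucleus error (rather than return only the cell contour)
#'   when no closed nucleus ridge is found.
#' @return list of `boundary_contour` objects, labeled `"cell"` and (when
#'   detected) `"nucleus"`; the nucleus contour lies inside the cell contour.
#' @export
extract_contours <- function(response, map, n_angles = 360L,
                             require_nucleus = FALSE) {
  stopifnot(inherits(response, "inflexion_field"), inherits(map, "phase_map"))
  if (max(response) <= 1e-8)    # rounding floor: real interfaces are >> this
    stop("no closed contour found (response field is empty)")
  ps <- attr(response, "pixel_size")
  dr <- ps / 2
  offs <- .kink_offset_px(attr(response, "sigma_px")) * ps
  cc <- map_coords(map)
  ## phase-weighted seed center
  wsum <- sum(map$values)
  seed <- c(sum(outer(cc$u, rep(1, length(cc$v))) * map$values),
            sum(outer(rep(1, length(cc$u)), cc$v) * map$values)) / wsum
  rmax <- max(diff(range(cc$u)), diff(range(cc$v))) * 0.7
  outer_pts <- .extract_outer(response, seed, n_angles, dr, offs, rmax)
  outer_pts <- .extract_outer(response, colMeans(outer_pts), n_angles, dr,
                              offs, rmax)
  cell <- .new_contour(outer_pts, map$plane, "cell", "inflexion-ridge")
  inner <- .extract_inner(response, .polygon_centroid(outer_pts), outer_pts,
                          n_angles, dr, offs)
  if (is.null(inner)) {
    if (require_nucleus)
      stop("no closed contour found for the nucleus")
    return(list(cell = cell))
  }
  nuc <- .new_contour(inner$points, map$plane, "nucleus", "inflexion-ridge")
  list(cell = cell, nucleus = nuc)
}

## ---- phase centers --------------------------------------------------------

.point_in_polygon <- function(px, py, poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- nrow(poly)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (y[i] > py) != (y[j] > py)
    xi <- x[i] + (py - y[i]) / (y[j] - y[i] + 1e-300) * (x[j] - x[i])
    flip <- cross & (px < xi)
    inside[flip] <- !inside[flip]
    j <- i
  }
  inside
}

#' Phase center by extremum search
#'
#' Locates the extremum of the (unwrapped) phase inside the nucleus contour;
#' the projection of the nucleus center onto the map plane. Ties are broken
#' by the centroid of the argmax set.
#'
#' @param map a `phase_map`; a wrapped map is unwrapped first (quality
#'   method), since the extremum of a wrapped map is ill-defined beyond one
#'   fringe.
#' @param contour optional `boundary_contour` restricting the search (the
#'   nucleus contour); without it the global extremum is returned.
#' @return object of class `phase_center`: list with `plane`, `coordinates`
#'   (um) and `method`.
#' @export
phase_center_extremum <- function(map, contour = NULL) {
  stopifnot(inherits(map, "phase_map"))
  if (map$wrapped) map <- unwrap2d(map, method = "quality")
  cc <- map_coords(map)
  v <- map$values
  if (!is.null(contour)) {
    g <- expand.grid(u = cc$u, v = cc$v)
    keep <- .point_in_polygon(g$u, g$v, contour$points)
    v[!matrix(keep, nrow(v))] <- -Inf
  }
  mx <- max(v)
  sel <- which(v >= mx - 1e-9, arr.ind = TRUE)
  structure(list(plane = map$plane,
                 coordinates = c(mean(cc$u[sel[, 1]]), mean(cc$v[sel[, 2]])),
                 method = "extremum"), class = "phase_center")
}

#' Phase center as contour centroid
#'
#' Area centroid of a closed interface contour, the geometric reading of the
#' projected nucleus center.
#'
#' @param contour a `boundary_contour`.
#' @return a `phase_center`.
#' @export
phase_center_centroid <- function(contour) {
  stopifnot(inherits(contour, "boundary_contour"))
  structure(list(plane = contour$plane,
                 coordinates = .polygon_centroid(contour$points),
                 method = "centroid"), class = "phase_center")
}

#' @export
print.phase_center <- function(x, ...) {
  cat(sprintf("phase center (%s, %s): (%.3f, %.3f) um\n", x$plane, x$method,
              x$coordinates[1], x$coordinates[2]))
  invisible(x)
}

#' Merge phase centers from two orthogonal views
#'
#' The x-y and x-z views share the x axis; a real nucleus must project to
#' the same x in both. The merged 3D center uses the mean of the two x
#' estimates, y from the x-y view and z from the x-z view. When the x
#' estimates disagree beyond `tol` the detection is rejected ("no consistent
#' nucleus").
#'
#' @param center_xy a `phase_center` on plane `"xy"`.
#' @param center_xz a `phase_center` on plane `"xz"`.
#' @param tol shared-axis consistency tolerance (um).
#' @return named numeric 3-vector (x, y, z) in um.
#' @export
reconcile_centers <- function(center_xy, center_xz, tol = 0.2) {
  stopifnot(inherits(center_xy, "phase_center"),
            inherits(center_xz, "phase_center"))
  if (center_xy$plane != "xy" || center_xz$plane != "xz")
    stop("need one center on plane xy and one on plane xz")
  dx <- abs(center_xy$coordinates[1] - center_xz$coordinates[1])
  if (dx > tol)
    stop(sprintf(paste0("no nucleus detected: x estimates differ by %.3f um ",
                        "(> tol = %.3f um) across views"), dx, tol))
  c(x = mean(c(center_xy$coordinates[1], center_xz$coordinates[1])),
    y = center_xy$coordinates[2], z = center_xz$coordinates[2])
}

## ---- export / diagnostics -------------------------------------------------

#' Write contours to CSV
#'
#' @param contours list of `boundary_contour` objects.
#' @param path output CSV path; columns plane, label, u, v (um).
#' @return `path`, invisibly.
#' @export
write_contours_csv <- function(contours, path) {
  rows <- do.call(rbind, lapply(contours, function(ct)
    data.frame(plane = ct$plane, label = ct$label,
               u = ct$points[, 1], v = ct$points[, 2])))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Plot a phase map with contour overlays
#'
#' @param map a `phase_map`.
#' @param contours optional list of `boundary_contour` objects.
#' @param main plot title.
#' @return invisibly, `NULL`.
#' @export
plot_boundaries <- function(map, contours = NULL, main = NULL) {
  cc <- map_coords(map)
  ax <- plane_axes(map$plane)
  graphics::image(cc$u, cc$v, map$values, asp = 1, col = grDevices::hcl.colors(64),
                  xlab = paste0(ax[1], " (um)"), ylab = paste0(ax[2], " (um)"),
                  main = if (is.null(main)) sprintf("phase (%s)", map$plane) else main,
                  useRaster = TRUE)
  if (!is.null(contours))
    for (ct in contours)
      graphics::lines(ct$points[, 1], ct$points[, 2], lwd = 2,
                      col = if (ct$label == "nucleus") "red" else "white")
  invisible(NULL)
}
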