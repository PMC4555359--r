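## Forward projection: scene -> unwrapped/wrapped phase maps and thickness
## maps, under the projection (ray-integral) approximation: the phase at a
## pixel is (2 pi / lambda) * integral of (n(s) - n_medium) along the
## projection axis.

## wrap to the principal interval (-pi, pi]
.wrap_values <- function(x) x - 2 * pi * ceiling(x / (2 * pi) - 0.5)

## merge a k x 2 matrix of intervals into disjoint intervals
.merge_intervals <- function(iv) {
  if (nrow(iv) <= 1L) return(iv)
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (k in 2:nrow(iv)) {
    m <- nrow(out)
    if (iv[k, 1] <= out[m, 2]) out[m, 2] <- max(out[m, 2], iv[k, 2])
    else out <- rbind(out, iv[k, , drop = FALSE])
  }
  out
}

## TRUE when the world `axis` maps onto the part's own +-z axis
.axis_is_part_z <- function(part, axis) {
  d <- c(0, 0, 0); d[axis_id(axis)] <- 1
  dq <- as.numeric(matrix(d, 1, 3) %*% part$rot)
  abs(abs(dq[3]) - 1) < 1e-12
}

## Interval providers: a part contributes one or more single-interval ray
## intersectors (vectorized over origins), or NULL when only the sampled
## fallback applies. Convex parts give one; an axis-aligned biconcave disc
## gives one; a swept tube with arcs normal to the ray gives one per arc.
.part_providers <- function(part, origins, axis) {
  if (part_is_convex(part))
    return(list(part_interval_analytic(part, origins, axis)))
  if (!.axis_is_part_z(part, axis)) return(NULL)
  o <- origins; o[, axis_id(axis)] <- 0
  q <- sweep(o, 2, part$center) %*% part$rot
  dz <- as.numeric(matrix(replace(c(0, 0, 0), axis_id(axis), 1), 1, 3) %*% part$rot)[3]
  if (part$kind == "biconcave") {
    r <- sqrt(q[, 1]^2 + q[, 2]^2)
    h <- biconcave_profile(part, r)
    t0 <- t1 <- rep(NA_real_, nrow(q))
    hit <- h > 0
    ## part-frame z interval is [-h/2, h/2] around -q_z; map back to ray t
    t0[hit] <- ((-h[hit] / 2) - q[hit, 3]) / dz
    t1[hit] <- ((h[hit] / 2) - q[hit, 3]) / dz
    sw <- !is.na(t0) & t0 > t1
    tmp <- t0[sw]; t0[sw] <- t1[sw]; t1[sw] <- tmp
    return(list(list(t0 = t0, t1 = t1)))
  }
  if (part$kind == "swept_tube") {
    out <- vector("list", length(part$arcs))
    for (k in seq_along(part$arcs)) {
      a <- part$arcs[[k]]
      dx <- q[, 1] - a$center[1]; dy <- q[, 2] - a$center[2]
      th0 <- a$theta[1] * pi / 180
      span <- (a$theta[2] - a$theta[1]) * pi / 180
      rel <- (atan2(dy, dx) - th0) %% (2 * pi)
      rr <- sqrt(dx^2 + dy^2)
      th1 <- th0 + span
      d1 <- sqrt((dx - a$radius * cos(th0))^2 + (dy - a$radius * sin(th0))^2)
      d2 <- sqrt((dx - a$radius * cos(th1))^2 + (dy - a$radius * sin(th1))^2)
      hdist <- ifelse(rel <= span, abs(rr - a$radius), pmin(d1, d2))
      hw2 <- part$tube_radius^2 - hdist^2
      t0 <- t1 <- rep(NA_real_, nrow(q))
      hit <- hw2 > 0
      hw <- sqrt(pmax(hw2, 0))
      zc <- a$center[3]
      t0[hit] <- ((zc - hw[hit]) - q[hit, 3]) / dz
      t1[hit] <- ((zc + hw[hit]) - q[hit, 3]) / dz
      sw <- !is.na(t0) & t0 > t1
      tmp <- t0[sw]; t0[sw] <- t1[sw]; t1[sw] <- tmp
      out[[k]] <- list(t0 = t0, t1 = t1)
    }
    return(out)
  }
  NULL
}

## per-pixel union chord length of a set of parts along a world axis.
## origins: n x 3 matrix. Returns a numeric vector.
.group_union_chord <- function(parts, origins, axis, step = 0.02) {
  n <- nrow(origins)
  prov <- list()
  ok <- TRUE
  for (p in parts) {
    pr <- .part_providers(p, origins, axis)
    if (is.null(pr)) { ok <- FALSE; break }
    prov <- c(prov, pr)
  }
  if (ok) {
    len <- rep(0, n)
    for (v in prov) len <- len + ifelse(is.na(v$t0), 0, v$t1 - v$t0)
    if (length(prov) > 1L) {
      for (i in seq_along(prov)) for (j in seq_along(prov)) {
        if (j <= i) next
        a <- prov[[i]]; b <- prov[[j]]
        ov <- pmin(a$t1, b$t1) - pmax(a$t0, b$t0)
        ov[is.na(ov) | ov < 0] <- 0
        len <- len - ov
      }
    }
    return(pmax(len, 0))
  }
  ## numeric path: loop over pixels inside the union of part bounding boxes
  ai <- axis_id(axis)
  ui <- setdiff(1:3, ai)
  len <- rep(0, n)
  cand <- rep(FALSE, n)
  for (p in parts) {
    bb <- part_bbox(p)
    cand <- cand | (origins[, ui[1]] >= bb["lo", ui[1]] &
                    origins[, ui[1]] <= bb["hi", ui[1]] &
                    origins[, ui[2]] >= bb["lo", ui[2]] &
                    origins[, ui[2]] <= bb["hi", ui[2]])
  }
  idx <- which(cand)
  for (k in idx) {
    iv <- do.call(rbind, lapply(parts, part_intervals_numeric,
                                origin = origins[k, ], axis = axis,
                                step = step))
    if (nrow(iv) == 0L) next
    iv <- .merge_intervals(iv)
    len[k] <- sum(iv[, 2] - iv[, 1])
  }
  len
}

## generic per-pixel priority sweep (used when the scene is not strictly
## nested); returns the optical path length integral of (n - nm) per pixel
.sweep_opl <- function(scene, origins, axis, step = 0.02) {
  parts <- scene$parts
  nm <- scene$medium_index
  n <- nrow(origins)
  convex <- vapply(parts, part_is_convex, TRUE)
  ivs <- vector("list", length(parts))
  for (pi in seq_along(parts))
    if (convex[pi])
      ivs[[pi]] <- part_interval_analytic(parts[[pi]], origins, axis)
  opl <- rep(0, n)
  for (k in seq_len(n)) {
    segs <- NULL
    for (pi in seq_along(parts)) {
      if (convex[pi]) {
        t0 <- ivs[[pi]]$t0[k]
        if (is.na(t0)) next
        segs <- rbind(segs, c(t0, ivs[[pi]]$t1[k], pi))
      } else {
        m <- part_intervals_numeric(parts[[pi]], origins[k, ], axis, step)
        if (nrow(m) > 0L) segs <- rbind(segs, cbind(m, pi))
      }
    }
    if (is.null(segs)) next
    bp <- sort(unique(c(segs[, 1], segs[, 2])))
    mid <- (bp[-1] + bp[-length(bp)]) / 2
    wl <- diff(bp)
    for (s in seq_along(mid)) {
      best <- NA_integer_; bprio <- -Inf
      for (r in seq_len(nrow(segs))) {
        if (mid[s] >= segs[r, 1] && mid[s] <= segs[r, 2]) {
          pr <- parts[[segs[r, 3]]]$priority
          if (pr > bprio) { bprio <- pr; best <- segs[r, 3] }
        }
      }
      if (!is.na(best)) opl[k] <- opl[k] + (parts[[best]]$index - nm) * wl[s]
    }
  }
  opl
}

.projection_grid <- function(plane, pixel_size, field, center = c(0, 0)) {
  np <- round(field / pixel_size)
  u <- center[1] - field / 2 + (seq_len(np) - 0.5) * pixel_size
  v <- center[2] - field / 2 + (seq_len(np) - 0.5) * pixel_size
  list(u = u, v = v, np = np,
       origin = c(u[1], v[1]))
}

.projection_origins <- function(plane, u, v) {
  ax <- plane_axes(plane)
  g <- expand.grid(u = u, v = v)
  o <- matrix(0, nrow(g), 3)
  o[, axis_id(ax[1])] <- g$u
  o[, axis_id(ax[2])] <- g$v
  o
}

#' Project a scene into an unwrapped phase map
#'
#' Integrates the refractive-index excess over the medium along the projection
#' axis of the chosen plane: `phi = (2 pi / lambda) * integral (n(s) - nm) ds`.
#' Chords through spheres, ellipsoids and half-ellipsoids are evaluated in
#' closed form; biconcave discs and swept tubes are sampled adaptively with
#' bisection-refined boundaries. Pixels whose ray misses every part are
#' exactly zero.
#'
#' @param scene an `ri_scene`.
#' @param plane projection plane, `"xy"`, `"xz"` or `"yz"` (the integral runs
#'   along the remaining axis).
#' @param pixel_size pixel pitch (um).
#' @param wavelength vacuum wavelength (um).
#' @param field side length of the square field of view (um), centered on
#'   `center`.
#' @param center in-plane coordinates of the field center (um).
#' @return an unwrapped `phase_map`.
#' @examples
#' mono <- build_monocyte_edward()
#' pm <- project_phase(mono, "xy", pixel_size = 0.125)
#' @export
project_phase <- function(scene, plane = c("xy", "xz", "yz"),
                          pixel_size = 0.0625, wavelength = 0.488,
                          field = 16, center = c(0, 0)) {
  stopifnot(inherits(scene, "ri_scene"), pixel_size > 0, wavelength > 0)
  plane <- match.arg(plane)
  g <- .projection_grid(plane, pixel_size, field, center)
  origins <- .projection_origins(plane, g$u, g$v)
  ax <- plane_axes(plane)[3]
  st <- scene$structure
  if (length(scene$parts) == 0L) {
    opl <- rep(0, nrow(origins))
  } else if (st$nested) {
    opl <- rep(0, nrow(origins))
    for (gi in seq_along(st$groups)) {
      prts <- scene$parts[st$groups[[gi]]]
      dn <- prts[[1]]$index - .group_background_index(scene, gi)
      if (dn == 0) next
      opl <- opl + dn * .group_union_chord(prts, origins, ax)
    }
  } else {
    opl <- .sweep_opl(scene, origins, ax)
  }
  vals <- matrix(2 * pi * opl / wavelength, g$np, g$np)
  phase_map(vals, plane = plane, pixel_size = pixel_size, origin = g$origin,
            wrapped = FALSE, wavelength = wavelength)
}

#' Chord length of a ray through a part
#'
#' Total length of the intersection of a coordinate-axis-aligned ray with a
#' scene part (closed form for spheres/ellipsoids, sampled and
#' bisection-refined otherwise).
#'
#' @param part a `phase_part`.
#' @param origin a 3-vector on the ray (the coordinate along `axis` is
#'   ignored).
#' @param axis `"x"`, `"y"` or `"z"`.
#' @return chord length (um); 0 when the ray misses the part.
#' @examples
#' nuc <- part_ellipsoid(c(3.4, 3.7, 3.0))
#' chord_length(nuc, c(0, 0, 0), "z")   # 6
#' @export
chord_length <- function(part, origin, axis = "z") {
  stopifnot(inherits(part, "phase_part"), axis %in% c("x", "y", "z"))
  if (part_is_convex(part)) {
    v <- part_interval_analytic(part, matrix(origin, 1, 3), axis)
    if (is.na(v$t0)) 0 else v$t1 - v$t0
  } else {
    iv <- part_intervals_numeric(part, origin, axis)
    if (nrow(iv) == 0L) 0 else sum(iv[, 2] - iv[, 1])
  }
}

#' Axial thickness map of one compartment
#'
#' Per-pixel chord length through the union of the parts carrying the given
#' compartment label.
#'
#' @param scene an `ri_scene`.
#' @param plane projection plane (thickness runs along the remaining axis).
#' @param pixel_size pixel pitch (um).
#' @param compartment label of the compartment (e.g. `"nucleus"`).
#' @param field,center field of view (um).
#' @return a `thickness_map`.
#' @export
thickness_map <- function(scene, plane = c("xy", "xz", "yz"),
                          pixel_size = 0.0625, compartment = "nucleus",
                          field = 16, center = c(0, 0)) {
  stopifnot(inherits(scene, "ri_scene"))
  plane <- match.arg(plane)
  labs <- vapply(scene$parts, `[[`, "", "label")
  sel <- which(labs == compartment)
  if (length(sel) == 0L)
    stop("no parts labeled '", compartment, "' in the scene")
  g <- .projection_grid(plane, pixel_size, field, center)
  origins <- .projection_origins(plane, g$u, g$v)
  ax <- plane_axes(plane)[3]
  len <- .group_union_chord(scene$parts[sel], origins, ax)
  thickness_map_obj(matrix(len, g$np, g$np), plane = plane,
                    pixel_size = pixel_size, origin = g$origin,
                    compartment = compartment)
}

#' Wrap a phase map to the principal interval
#'
#' Reduces phase values to (-pi, pi]; the difference to the input is an
#' integer multiple of 2 pi at every pixel. Idempotent.
#'
#' @param map a `phase_map`.
#' @return a wrapped `phase_map`.
#' @export
wrap_phase <- function(map) {
  stopifnot(inherits(map, "phase_map"))
  out <- map
  out$values <- .wrap_values(map$values)
  out$wrapped <- TRUE
  out
}

#' Add Gaussian phase noise
#'
#' @param map a `phase_map`.
#' @param sigma noise standard deviation (rad), >= 0.
#' @param seed optional integer seed; when given, the global RNG state is
#'   left untouched and the result is reproducible.
#' @return a `phase_map` with i.i.d. Gaussian noise added (re-wrapped when the
#'   input was wrapped).
#' @export
add_noise <- function(map, sigma, seed = NULL) {
  stopifnot(inherits(map, "phase_map"), sigma >= 0)
  if (sigma == 0) return(map)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  out <- map
  out$values <- map$values + matrix(stats::rnorm(length(map$values), 0, sigma),
                                    nrow(map$values))
  if (map$wrapped) out$values <- .wrap_values(out$values)
  out
}

#' Brute-force ray phase integral
#'
#' Reference line integration of the refractive-index excess along a ray,
#' sampling `index_at` at `n_samples` midpoints across the scene bounding
#' box. Independent of the analytic chord machinery; intended for
#' verification.
#'
#' @param scene an `ri_scene`.
#' @param origin 3-vector on the ray (coordinate along `axis` ignored).
#' @param axis `"x"`, `"y"` or `"z"`.
#' @param wavelength vacuum wavelength (um).
#' @param n_samples number of midpoint samples.
#' @param refine bisect the index transitions between adjacent samples (the
#'   integrand is piecewise constant, so this removes the midpoint-rule
#'   boundary error); default `TRUE`.
#' @return phase (rad).
#' @export
ray_phase_integral <- function(scene, origin, axis = "z", wavelength = 0.488,
                               n_samples = 1e4, refine = TRUE) {
  ai <- axis_id(axis)
  lo <- scene$bbox["lo", ai]; hi <- scene$bbox["hi", ai]
  ds <- (hi - lo) / n_samples
  ts <- lo + (seq_len(n_samples) - 0.5) * ds
  pts <- matrix(rep(as.numeric(origin), each = n_samples), ncol = 3)
  pts[, ai] <- ts
  v <- index_at(scene, pts) - scene$medium_index
  total <- sum(v) * ds
  if (refine) {
    jumps <- which(diff(v) != 0)
    for (i in jumps) {
      a <- ts[i]; b <- ts[i + 1]
      va <- v[i]
      probe <- function(t) {
        p <- as.numeric(origin); p[ai] <- t
        index_at(scene, matrix(p, 1, 3)) - scene$medium_index
      }
      for (k in 1:40) {
        m <- (a + b) / 2
        if (probe(m) == va) a <- m else b <- m
      }
      tstar <- (a + b) / 2
      ## the midpoint rule placed the transition at the sample-cell boundary
      total <- total + (v[i] - v[i + 1]) * (tstar - (ts[i] + ds / 2))
    }
  }
  2 * pi * total / wavelength
}
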