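## Profile diagnostics for simulated cells.

#' Axial thickness and refractive-index profiles of a scene
#'
#' Plots, for a line through `point` along the chosen axis: the whole-cell
#' physical thickness profile (chord length of all parts, per position along
#' the orthogonal in-plane axis) and the refractive-index distribution along
#' the axis itself.
#'
#' @param scene an `ri_scene`.
#' @param axis profile axis, `"x"`, `"y"` or `"z"`.
#' @param point 3-vector the profile line passes through (um).
#' @param n samples per profile.
#' @return invisibly, a list with the sampled profiles.
#' @export
plot_cell_profiles <- function(scene, axis = "y", point = c(0, 0, 0),
                               n = 400L) {
  stopifnot(inherits(scene, "ri_scene"))
  ai <- axis_id(axis)
  lo <- scene$bbox["lo", ai]; hi <- scene$bbox["hi", ai]
  ts <- seq(lo, hi, length.out = n)
  ## index along the axis
  pts <- matrix(rep(as.numeric(point), each = n), ncol = 3)
  pts[, ai] <- ts
  idx <- index_at(scene, pts)
  ## thickness along z as a function of position on this axis
  thick <- vapply(ts, function(t) {
    o <- as.numeric(point); o[ai] <- t
    sum(vapply(scene$parts, function(p) {
      if (p$priority == min(vapply(scene$parts, `[[`, 1L, "priority")))
        chord_length(p, o, "z") else 0
    }, 0))
  }, 0)
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(ts, thick, type = "l", lwd = 2,
                 xlab = paste0(axis, " (um)"), ylab = "thickness (um)",
                 main = "axial physical thickness")
  graphics::plot(ts, idx, type = "s", lwd = 2,
                 xlab = paste0(axis, " (um)"), ylab = "refractive index",
                 main = "refractive index along the axis")
  invisible(list(position = ts, thickness = thick, index = idx))
}
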