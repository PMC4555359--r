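## Two-dimensional phase unwrapping.
##
## Two methods are provided. "itoh" is the classic line-scan: exact whenever
## every pixel-to-pixel phase step along its scan paths is below pi in
## magnitude (noise-free, adequately sampled maps); it refuses maps that carry
## residues, because path-following is then inconsistent. "quality" is a
## reliability-guided congruent merge (second-difference edge weights on the
## 8-neighbor graph, union-find with 2*pi offsets, plus a congruent
## relaxation pass); it tolerates noise and is the default.

#' Residue map of a wrapped phase image
#'
#' Sums the wrapped phase differences around every 2x2 pixel loop; nonzero
#' entries (in units of 2 pi) mark points where path-following unwrapping is
#' path-dependent.
#'
#' @param map a wrapped `phase_map` (a plain matrix is accepted).
#' @return integer matrix of residue charges, dimension `(n-1) x (m-1)`.
#' @export
phase_residues <- function(map) {
  w <- if (inherits(map, "phase_map")) map$values else map
  n1 <- nrow(w); n2 <- ncol(w)
  r <- .wrap_values(w[2:n1, 1:(n2 - 1)] - w[1:(n1 - 1), 1:(n2 - 1)]) +
       .wrap_values(w[2:n1, 2:n2] - w[2:n1, 1:(n2 - 1)]) +
       .wrap_values(w[1:(n1 - 1), 2:n2] - w[2:n1, 2:n2]) +
       .wrap_values(w[1:(n1 - 1), 1:(n2 - 1)] - w[1:(n1 - 1), 2:n2])
  matrix(as.integer(round(r / (2 * pi))), n1 - 1, n2 - 1)
}

.itoh_unwrap <- function(w) {
  u <- w
  d <- .wrap_values(diff(u[, 1]))
  u[, 1] <- u[1, 1] + c(0, cumsum(d))
  ## row-wise cumulated wrapped differences
  dd <- .wrap_values(w[, -1, drop = FALSE] - w[, -ncol(w), drop = FALSE])
  u[, -1] <- u[, 1] + t(apply(dd, 1, cumsum))
  u
}

#' Unwrap a wrapped phase map
#'
#' Recovers continuous phase from a wrapped map. The output minus the input
#' is an integer multiple of 2 pi at every pixel; the global 2 pi offset is
#' fixed so that the median over a 5-pixel border (assumed background) is
#' zero.
#'
#' @param map a wrapped `phase_map`.
#' @param method `"quality"` (reliability-guided merge, default) or `"itoh"`
#'   (line scan; noise-free reference, errors out when the map carries
#'   residues).
#' @param relax_sweeps congruent relaxation sweeps after the quality merge.
#' @return an unwrapped `phase_map`.
#' @examples
#' ramp <- phase_map(matrix(seq(0, 30, length.out = 64), 64, 64),
#'                   "xy", pixel_size = 0.25)
#' rt <- unwrap2d(wrap_phase(ramp), method = "itoh")
#' max(abs(rt$values - ramp$values))
#' @export
unwrap2d <- function(map, method = c("quality", "itoh"), relax_sweeps = 20L) {
  stopifnot(inherits(map, "phase_map"))
  if (!map$wrapped) stop("input map is not wrapped")
  method <- match.arg(method)
  w <- map$values
  if (method == "itoh") {
    if (any(phase_residues(w) != 0L))
      stop("wrapped map carries residues; Itoh path-following is ",
           "inconsistent (undersampled phase gradients). ",
           "Use method = 'quality' or sample finer.")
    u <- .itoh_unwrap(w)
  } else {
    u <- .mst_unwrap_cpp(w, as.integer(relax_sweeps))
  }
  ## fix the global 2 pi offset from the border
  n1 <- nrow(u); n2 <- ncol(u)
  b <- c(u[1:min(5, n1), ], u[max(1, n1 - 4):n1, ],
         u[, 1:min(5, n2)], u[, max(1, n2 - 4):n2])
  u <- u - 2 * pi * round(stats::median(b) / (2 * pi))
  out <- map
  out$values <- u
  out$wrapped <- FALSE
  out
}
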