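## Shared fixtures and small oracles for the test suite. Everything is
## generated in code; no stored data.

K_CYTO <- 2 * pi * (1.37 - 1.003) / 0.488   # rad per um of cytoplasm chord
K_NUC <- 2 * pi * (1.39 - 1.37) / 0.488

## cached monocyte views at full (0.0625 um) and half (0.125 um) resolution
.fix <- new.env()
monocyte_views <- function(pixel_size = 0.0625) {
  key <- sprintf("mono_%g", pixel_size)
  if (is.null(.fix[[key]]))
    .fix[[key]] <- simulate_views(build_monocyte_edward(),
                                  pixel_size = pixel_size)
  .fix[[key]]
}

## free-center axis-aligned ellipse fit: x^2 = c0 + c1 x + c2 v + c3 v^2
fit_ellipse2d <- function(pts) {
  fit <- stats::lm(I(pts[, 1]^2) ~ pts[, 1] + pts[, 2] + I(pts[, 2]^2))
  co <- stats::coef(fit)
  uc <- co[[2]] / 2
  B <- -co[[4]]
  vc <- co[[3]] / (2 * B)
  a2 <- co[[1]] + uc^2 + B * vc^2
  c(uc = uc, vc = vc, a = sqrt(a2), b = sqrt(a2 / B))
}

## analytic closed contour (ellipse) as a boundary_contour
ellipse_contour <- function(a, b, center = c(0, 0), plane = "xy",
                            label = "nucleus", n = 180) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  boundary_contour(cbind(center[1] + a * cos(th), center[2] + b * sin(th)),
                   plane = plane, label = label, method = "synthetic")
}

## remove the global 2*pi*k offset that best aligns u with reference
strip_2pi_offset <- function(u, ref)
  u - 2 * pi * round(stats::median(u - ref) / (2 * pi))
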