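test_that("projection of a homogeneous sphere matches the closed-form chord phase", {
  sc <- ri_scene(list(part_sphere(6, index = 1.37)), medium_index = 1.003)
  pm <- project_phase(sc, "xy")
  cc <- map_coords(pm)
  i0 <- which.min(abs(cc$u)); j0 <- which.min(abs(cc$v))
  want <- 2 * pi / 0.488 * (1.37 - 1.003) *
    2 * sqrt(36 - cc$u[i0]^2 - cc$v[j0]^2)
  expect_equal(pm$values[i0, j0], want, tolerance = 1e-10)
  expect_equal(2 * pi / 0.488 * 0.367 * 12, 56.70, tolerance = 1e-4)
  expect_identical(pm$values[1, 1], 0)                # far field exactly zero
  expect_identical(pm$values[10, 250], 0)
})

test_that("the whole-cell phase composes cytoplasm and nucleus contributions", {
  pm <- monocyte_views()$xy
  cc <- map_coords(pm)
  i0 <- which.min(abs(cc$u)); j0 <- which.min(abs(cc$v))
  x <- cc$u[i0]; y <- cc$v[j0]
  h1 <- (6.5 + 3.5) * sqrt(1 - (x^2 + y^2) / 36)
  h2 <- 2 * 3.0 * sqrt(1 - x^2 / 3.4^2 - y^2 / 3.7^2)
  expect_equal(h2, 6.0, tolerance = 1e-3)
  expect_equal(pm$values[i0, j0], K_CYTO * h1 + K_NUC * h2, tolerance = 1e-8)
})

test_that("chord_length handles hits, misses and oblique chords", {
  nuc <- part_ellipsoid(c(3.4, 3.7, 3.0))
  expect_equal(chord_length(nuc, c(0, 0, 0), "z"), 6.0)
  expect_equal(chord_length(nuc, c(3.4, 0, 0), "z"), 0)
  expect_equal(chord_length(nuc, c(1.7, 0, 0), "z"),
               2 * 3.0 * sqrt(1 - 0.25), tolerance = 1e-12)
  ## dense numerical sampling as cross-check
  zs <- seq(-4, 4, by = 1e-4)
  ins <- (1.7 / 3.4)^2 + (zs / 3)^2 <= 1
  expect_equal(chord_length(nuc, c(1.7, 0, 0), "z"), sum(ins) * 1e-4,
               tolerance = 1e-3)
})

test_that("wrap_phase maps to (-pi, pi] and is idempotent", {
  mk <- function(v) phase_map(matrix(v, 1, 1), "xy", 1)
  expect_equal(wrap_phase(mk(0))$values[1, 1], 0)
  expect_equal(wrap_phase(mk(56.70))$values[1, 1], 56.70 - 18 * pi)
  expect_equal(wrap_phase(mk(pi))$values[1, 1], pi)
  expect_equal(wrap_phase(mk(pi + 0.01))$values[1, 1], -pi + 0.01)
  set.seed(1)
  m <- phase_map(matrix(stats::runif(1e4, -60, 60), 100), "xy", 0.1)
  w1 <- wrap_phase(m)
  expect_true(all(w1$values > -pi & w1$values <= pi))
  expect_equal(wrap_phase(w1)$values, w1$values)       # idempotent
  k <- (w1$values - m$values) / (2 * pi)
  expect_equal(k, round(k), tolerance = 1e-9)          # 2 pi congruence
})

test_that("nucleus thickness map integrates to the ellipsoid volume", {
  tm <- thickness_map(build_monocyte_edward(), "xy", compartment = "nucleus")
  cc <- map_coords(tm)
  i0 <- which.min(abs(cc$u)); j0 <- which.min(abs(cc$v))
  expect_equal(tm$values[i0, j0], 6.0, tolerance = 1e-2)
  expect_identical(tm$values[1, 1], 0)
  vol <- sum(tm$values) * tm$pixel_size^2
  expect_equal(vol, 4 / 3 * pi * 3.4 * 3.7 * 3.0, tolerance = 0.01)
  expect_error(thickness_map(build_rbc(), "xy", compartment = "nucleus"),
               "no parts labeled")
})

test_that("add_noise is calibrated, seeded and leaves sigma = 0 untouched", {
  pm <- phase_map(matrix(0, 1000, 1000), "xy", 0.01)
  expect_identical(add_noise(pm, 0)$values, pm$values)
  n1 <- add_noise(pm, 0.05, seed = 7)
  n2 <- add_noise(pm, 0.05, seed = 7)
  expect_identical(n1$values, n2$values)
  expect_equal(stats::var(as.vector(n1$values - pm$values)), 0.05^2,
               tolerance = 0.02)
})

test_that("analytic projection agrees with refined brute-force line integration", {
  set.seed(11)
  for (nm in c("rbc", "neutrophil", "basophil")) {
    sc <- cell_models()[[nm]]()
    pm <- project_phase(sc, "xy", pixel_size = 0.125, field = 14)
    cc <- map_coords(pm)
    for (k in 1:8) {
      i <- sample(seq_along(cc$u), 1); j <- sample(seq_along(cc$v), 1)
      bf <- ray_phase_integral(sc, c(cc$u[i], cc$v[j], 0), "z")
      expect_lt(abs(bf - pm$values[i, j]), 1e-3)
    }
  }
})

test_that("two-part phase equals the sum of single-part phases minus overlap", {
  ## neutrophil lobe pair: union chord = sum of chords - overlap chord
  sc <- build_neutrophil()
  pair <- Filter(function(p) p$label == "nucleus" && p$center[1] < 0, sc$parts)
  pm_union <- thickness_map(sc, "xy", pixel_size = 0.125,
                            compartment = "nucleus")
  cc <- map_coords(pm_union)
  i0 <- which.min(abs(cc$u + 2.3)); j0 <- which.min(abs(cc$v))
  o <- c(cc$u[i0], cc$v[j0], 0)
  c1 <- chord_length(pair[[1]], o, "z")
  c2 <- chord_length(pair[[2]], o, "z")
  zs <- seq(-3, 3, by = 1e-4)
  both <- part_contains(pair[[1]], cbind(o[1], o[2], zs)) &
          part_contains(pair[[2]], cbind(o[1], o[2], zs))
  expect_equal(pm_union$values[i0, j0], c1 + c2 - sum(both) * 1e-4,
               tolerance = 1e-3)
})

test_that("orthogonal views peak at the same shared-x position", {
  v <- monocyte_views()
  cc <- map_coords(v$xy)
  j_y0 <- which.min(abs(cc$v - 0))
  j_z3 <- which.min(abs(map_coords(v$xz)$v - 3))
  prof_xy <- v$xy$values[, j_y0]
  prof_xz <- v$xz$values[, j_z3]
  expect_lt(abs(cc$u[which.max(prof_xy)] - map_coords(v$xz)$u[which.max(prof_xz)]),
            2 * v$xy$pixel_size)
})

test_that("phase maps survive TIFF and text round trips with sidecar metadata", {
  pm <- wrap_phase(monocyte_views(0.125)$xy)
  for (ext in c(".tif", ".txt")) {
    f <- withr::local_tempfile(fileext = ext)
    write_phase_map(pm, f)
    back <- read_phase_map(f)
    expect_equal(back$values, pm$values, tolerance = 1e-6)
    expect_identical(back$plane, pm$plane)
    expect_equal(back$pixel_size, pm$pixel_size)
    expect_true(back$wrapped)
  }
})
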