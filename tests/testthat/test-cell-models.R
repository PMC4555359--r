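test_that("index_at resolves compartments by priority and falls back to the medium", {
  mono <- build_monocyte_edward()
  expect_equal(index_at(mono, c(0, 0, 3)), 1.39)     # nucleus center
  expect_equal(index_at(mono, c(0, 0, 6.01)), 1.37)  # just past the nucleus pole
  expect_equal(index_at(mono, c(7.9, 0, 0)), 1.003)  # outside the cell
  empty <- ri_scene(list(), medium_index = 1.21)
  expect_equal(index_at(empty, c(1, 2, 3)), 1.21)
})

test_that("index_at agrees with a direct point-in-solid evaluation on a grid", {
  mono <- build_monocyte_edward()
  g <- as.matrix(expand.grid(x = seq(-7, 7, by = 0.5),
                             y = seq(-7, 7, by = 0.5),
                             z = seq(-4.5, 7, by = 0.5)))
  got <- index_at(mono, g)
  in_nuc <- g[, 1]^2 / 3.4^2 + g[, 2]^2 / 3.7^2 + (g[, 3] - 3)^2 / 3^2 <= 1
  in_mem <- ifelse(g[, 3] >= 0,
                   g[, 1]^2 / 36 + g[, 2]^2 / 36 + g[, 3]^2 / 6.5^2 <= 1,
                   g[, 1]^2 / 36 + g[, 2]^2 / 36 + g[, 3]^2 / 3.5^2 <= 1)
  want <- ifelse(in_nuc, 1.39, ifelse(in_mem, 1.37, 1.003))
  expect_equal(got, want)
})

test_that("biconcave disc matches its three defining thicknesses", {
  rbc <- build_rbc()
  disc <- rbc$parts[[1]]
  expect_equal(biconcave_profile(disc, 0), 1.0)
  prof <- biconcave_profile(disc, seq(0, 3.85, by = 0.001))
  expect_equal(max(prof), 2.0, tolerance = 1e-6)
  expect_gt(which.max(prof), 1)                       # interior maximum
  expect_equal(biconcave_profile(disc, 3.85), 0)
  expect_equal(biconcave_profile(disc, 5), 0)         # outside the disc
  expect_equal(chord_length(disc, c(5, 0, 0), "z"), 0)
  expect_equal(chord_length(disc, c(0, 0, 0), "z"), 1.0)
})

test_that("biconcave disc volume matches the frozen quadrature constant", {
  ## 2 pi * integral of h(r) r dr computed by midpoint quadrature (200k steps)
  v_ref <- 47.772836
  tm <- thickness_map(build_rbc(), "xy", pixel_size = 0.0625,
                      compartment = "cell", field = 10)
  expect_equal(sum(tm$values) * tm$pixel_size^2, v_ref, tolerance = 0.01)
})

test_that("white-cell builders give a 12 um membrane with nuclear parts inside", {
  models <- cell_models()
  for (nm in setdiff(names(models), "rbc")) {
    sc <- models[[nm]]()
    expect_equal(index_at(sc, c(5.99, 0, 0)), 1.37, info = nm)
    expect_equal(index_at(sc, c(6.01, 0, 0)), 1.003, info = nm)
    nuc_parts <- Filter(function(p) p$label == "nucleus", sc$parts)
    expect_gt(length(nuc_parts), 0)
    for (p in nuc_parts) {
      probe <- if (p$kind == "swept_tube")
        p$arcs[[1]]$center + c(p$arcs[[1]]$radius, 0, 0) else p$center
      expect_equal(index_at(sc, probe), 1.39, info = nm)
    }
  }
  expect_equal(chord_length(build_monocyte_edward()$parts[[3]],
                            c(0, 0, 0), "z"), 6.0)
})

test_that("every nucleus voxel lies inside the membrane (containment invariant)", {
  for (nm in setdiff(names(cell_models()), "rbc")) {
    sc <- cell_models()[[nm]]()
    g <- as.matrix(expand.grid(x = seq(-6.2, 6.2, by = 0.35),
                               y = seq(-6.2, 6.2, by = 0.35),
                               z = seq(-6.2, 6.2, by = 0.35)))
    v <- index_at(sc, g)
    nuc <- v == 1.39
    expect_true(all(rowSums(g[nuc, , drop = FALSE]^2) <= 36), info = nm)
  }
})

test_that("the neutrophil nucleus union has exactly two connected components", {
  sc <- build_neutrophil()
  step <- 0.1
  ax <- seq(-4.6, 4.6, by = step)
  ay <- seq(-4.0, 4.0, by = step)
  az <- seq(-2.2, 2.2, by = step)
  g <- as.matrix(expand.grid(x = ax, y = ay, z = az))
  mask <- array(index_at(sc, g) == 1.39, c(length(ax), length(ay), length(az)))
  ## 26-connected flood fill by repeated masked dilation (independent oracle)
  shift3 <- function(m, s) {
    d <- dim(m)
    out <- array(FALSE, d)
    src <- lapply(1:3, function(i) max(1, 1 - s[i]):min(d[i], d[i] - s[i]))
    dst <- lapply(1:3, function(i) src[[i]] + s[i])
    out[dst[[1]], dst[[2]], dst[[3]]] <- m[src[[1]], src[[2]], src[[3]]]
    out
  }
  dil <- function(m) {
    d <- m
    for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
      if (sx == 0 && sy == 0 && sz == 0) next
      d <- d | shift3(m, c(sx, sy, sz))
    }
    d
  }
  n_comp <- 0
  remaining <- mask
  while (any(remaining)) {
    n_comp <- n_comp + 1
    seedidx <- which(remaining, arr.ind = TRUE)[1, ]
    comp <- array(FALSE, dim(mask))
    comp[seedidx[1], seedidx[2], seedidx[3]] <- TRUE
    repeat {
      grown <- dil(comp) & mask
      if (sum(grown) == sum(comp)) break
      comp <- grown
    }
    remaining <- remaining & !comp
  }
  expect_equal(n_comp, 2L)
})

test_that("builders reject geometry that violates containment or positivity", {
  expect_error(build_monocyte_edward(nucleus_center = c(0, 0, 5)),
               "outside the membrane")
  expect_error(build_two_ellipsoid(nucleus_semiaxes = c(7, 3, 3)),
               "outside the membrane")
  expect_error(build_rbc(center_thickness = -1), "positive|thickness")
  expect_error(part_ellipsoid(c(3, 3, 3), index = 0.9), "exceed 1.0")
})

test_that("axisymmetric projections are invariant under rotation about the optical axis", {
  rbc <- build_rbc()
  rot <- ri_scene(list(part_biconcave(7.7, 1.0, 2.0, index = 1.40,
                                      orient = c(z = 37))),
                  medium_index = 1.003)
  p1 <- project_phase(rbc, "xy", pixel_size = 0.125, field = 10)
  p2 <- project_phase(rot, "xy", pixel_size = 0.125, field = 10)
  expect_equal(p1$values, p2$values, tolerance = 1e-8)
})

test_that("scene configuration round-trips through YAML", {
  for (sc in list(build_monocyte_edward(), build_basophil(), build_rbc())) {
    f <- withr::local_tempfile(fileext = ".yml")
    write_scene_config(sc, f)
    sc2 <- read_scene_config(f)
    expect_equal(sc2$medium_index, sc$medium_index)
    expect_equal(length(sc2$parts), length(sc$parts))
    set.seed(42)
    pts <- matrix(stats::runif(300, -7, 7), ncol = 3)
    expect_equal(index_at(sc2, pts), index_at(sc, pts))
  }
})

test_that("voxelization exports an index grid consistent with index_at", {
  sc <- build_two_ellipsoid()
  vox <- voxelize_scene(sc, step = 0.5)
  i <- 7L; j <- 9L; k <- 11L
  expect_equal(vox$index[i, j, k],
               index_at(sc, c(vox$x[i], vox$y[j], vox$z[k])))
  d <- withr::local_tempdir()
  write_voxels(vox, file.path(d, "vox"), format = "text")
  sl <- as.matrix(utils::read.table(file.path(d, "vox", "slice_0011.txt")))
  dimnames(sl) <- NULL
  expect_equal(sl, vox$index[, , 11])
})
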