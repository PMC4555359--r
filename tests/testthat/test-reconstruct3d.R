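test_that("revolving a circle about its diameter gives a sphere", {
  circ <- ellipse_contour(3, 3)
  m <- rotate_outline(circ, n_steps = 180L)
  expect_true(mesh_is_watertight(m))
  expect_equal(mesh_volume(m), 36 * pi, tolerance = 0.01)
})

test_that("revolving an ellipse about its major axis gives a prolate spheroid", {
  ell <- ellipse_contour(3.4, 3.0)
  m <- rotate_outline(ell, n_steps = 180L)
  expect_equal(mesh_volume(m), 4 / 3 * pi * 3.4 * 3.0^2, tolerance = 0.01)
})

test_that("an outline crossing the axis more than twice is rejected", {
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  wavy <- boundary_contour(cbind(3 * cos(th), 3 * sin(3 * th)), "xy")
  expect_error(rotate_outline(wavy, level = 0), "more than 2 points")
})

test_that("merging congruent circular outlines reduces to the revolution", {
  circ_xy <- ellipse_contour(3, 3, plane = "xy")
  circ_xz <- ellipse_contour(3, 3, plane = "xz")
  mm <- merge_orthogonal(circ_xy, circ_xz, n_theta = 180L)
  mr <- rotate_outline(circ_xy, n_steps = 180L)
  expect_equal(mesh_volume(mm), mesh_volume(mr), tolerance = 1e-9)
  expect_equal(mm$vertices, mr$vertices, tolerance = 1e-9)
})

test_that("merging ellipse outlines (a,b) and (a,c) gives the (a,b,c) ellipsoid", {
  a <- 3.4; b <- 3.7; c3 <- 3.0
  mm <- merge_orthogonal(ellipse_contour(a, b, plane = "xy"),
                         ellipse_contour(a, c3, plane = "xz"))
  expect_true(mesh_is_watertight(mm))
  expect_equal(mesh_volume(mm), 4 / 3 * pi * a * b * c3, tolerance = 0.01)
  expect_error(merge_orthogonal(ellipse_contour(1, 1, center = c(-5, 0)),
                                ellipse_contour(1, 1, center = c(5, 0),
                                                plane = "xz")),
               "share no x interval")
})

test_that("fit_ellipsoid recovers exact ellipsoid meshes and flags non-ellipsoids", {
  mm <- merge_orthogonal(ellipse_contour(3.4, 3.7, plane = "xy"),
                         ellipse_contour(3.4, 3.0, plane = "xz"))
  rep <- fit_ellipsoid(mm, center = c(0, 0, 0))
  expect_equal(unname(rep$semi_axes), c(3.4, 3.7, 3.0), tolerance = 1e-3)
  expect_equal(rep$equivalent_volume, 158.06, tolerance = 1e-3)
  expect_lt(rep$residual, 1e-3)

  sph <- rotate_outline(ellipse_contour(1, 1))
  rep1 <- fit_ellipsoid(sph, center = c(0, 0, 0))
  expect_equal(unname(rep1$semi_axes), c(1, 1, 1), tolerance = 1e-3)
  expect_equal(unname(rep1$ellipsoidal_degree), c(1, 1, 1), tolerance = 1e-3)

  ## a dumbbell of revolution is far from any ellipsoid: the fit must warn
  th <- seq(0, 2 * pi, length.out = 181)[-181]
  r <- 2 + 1.6 * cos(2 * th)
  dumb <- boundary_contour(cbind(r * cos(th), r * sin(th)), "xy")
  dm <- rotate_outline(dumb, level = 0)
  expect_warning(fit_ellipsoid(dm, center = c(0, 0, 0)), "non-ellipsoidal")
})

test_that("mesh thickness maps match chords and integrate to the mesh volume", {
  sph <- rotate_outline(ellipse_contour(3, 3), n_steps = 120L)
  tm <- nucleus_thickness_from_mesh(sph, "xy", pixel_size = 0.0625, field = 8)
  cc <- map_coords(tm)
  i0 <- which.min(abs(cc$u)); j0 <- which.min(abs(cc$v))
  expect_equal(tm$values[i0, j0], 6.0, tolerance = 0.01)
  expect_identical(tm$values[1, 1], 0)
  expect_equal(sum(tm$values) * tm$pixel_size^2, mesh_volume(sph),
               tolerance = 0.01)
})

test_that("outer-surface thickness inverts the phase composition exactly", {
  n1 <- 1.37; n2 <- 1.39; nm <- 1.003; lam <- 0.488
  set.seed(9)
  h1 <- matrix(stats::runif(64^2, 0, 10), 64)
  h2 <- matrix(stats::runif(64^2, 0, 5), 64)
  h2 <- pmin(h2, h1)
  phi <- 2 * pi * ((n1 - nm) * h1 + (n2 - n1) * h2) / lam
  pm <- phase_map(phi, "xy", 0.25, wavelength = lam)
  h2m <- thickness_map_obj(h2, "xy", 0.25)
  got <- outer_surface_thickness(pm, h2m, n1, n2, nm)
  expect_lt(max(abs(got$values - h1)), 1e-6)
  ## single-compartment limit: h2 = 0
  zero <- thickness_map_obj(matrix(0, 64, 64), "xy", 0.25)
  got0 <- outer_surface_thickness(pm, zero, n1, n2, nm)
  expect_equal(got0$values, lam * phi / (2 * pi * (n1 - nm)), tolerance = 1e-9)
  expect_error(outer_surface_thickness(pm, h2m, n1 = 1.0, n2, nm = 1.003),
               "exceed")
})

test_that("outer-surface thickness of the monocyte matches the membrane chord", {
  pm <- monocyte_views()$xy
  mesh <- merge_orthogonal(ellipse_contour(3.4, 3.7, plane = "xy"),
                           ellipse_contour(3.4, 3.0, center = c(0, 3),
                                           plane = "xz"))
  h2 <- nucleus_thickness_from_mesh(mesh, "xy", pm$pixel_size, field = 16)
  h1 <- outer_surface_thickness(pm, h2, 1.37, 1.39, 1.003)
  cc <- map_coords(h1)
  i0 <- which.min(abs(cc$u)); j0 <- which.min(abs(cc$v))
  want <- (6.5 + 3.5) * sqrt(1 - (cc$u[i0]^2 + cc$v[j0]^2) / 36)
  expect_equal(h1$values[i0, j0], want, tolerance = 0.02)
})

test_that("assemble_cell verifies containment and names the violation", {
  cc <- characterize_nucleus(build_monocyte_edward(), pixel_size = 0.125)
  membrane <- merge_orthogonal(cc$contours$xy$cell, cc$contours$xz$cell)
  pair <- assemble_cell(membrane, cc$mesh, center = cc$center)
  expect_named(pair, c("membrane", "nucleus"))
  ## membrane volume against the closed-form half-ellipsoid union volume
  v_true <- 2 / 3 * pi * 6 * 6 * (6.5 + 3.5)
  expect_equal(mesh_volume(pair$membrane), v_true, tolerance = 0.02)
  ## doubled nucleus must protrude
  big <- cc$mesh
  big$vertices <- sweep(sweep(big$vertices, 2, cc$center), 2, c(2, 2, 2), "*")
  big$vertices <- sweep(big$vertices, 2, cc$center, "+")
  expect_error(assemble_cell(membrane, big), "protrudes")
})

test_that("fitted, mesh and thickness-integral volumes agree within 2%", {
  cc <- characterize_nucleus(build_monocyte_edward(), pixel_size = 0.125)
  tm <- nucleus_thickness_from_mesh(cc$mesh, "xy", 0.0625, field = 16)
  v_int <- sum(tm$values) * tm$pixel_size^2
  expect_equal(cc$report$mesh_volume, cc$report$equivalent_volume,
               tolerance = 0.02)
  expect_equal(v_int, cc$report$mesh_volume, tolerance = 0.02)
})

test_that("meshes export to PLY and OBJ", {
  m <- rotate_outline(ellipse_contour(2, 1), n_steps = 24L, n_slices = 16L)
  fp <- withr::local_tempfile(fileext = ".ply")
  fo <- withr::local_tempfile(fileext = ".obj")
  write_mesh(m, fp); write_mesh(m, fo)
  ply <- readLines(fp)
  expect_identical(ply[1], "ply")
  expect_true(any(grepl(paste("element vertex", nrow(m$vertices)), ply)))
  obj <- readLines(fo)
  expect_equal(sum(grepl("^f ", obj)), nrow(m$faces))
})
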