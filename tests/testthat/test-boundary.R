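test_that("the response field is zero for a constant map and rejects wrapped input", {
  flat <- phase_map(matrix(1.5, 64, 64), "xy", 0.25)
  expect_lt(max(abs(inflexion_field(flat))), 1e-9)
  expect_error(extract_contours(inflexion_field(flat), flat), "no closed contour")
  w <- wrap_phase(monocyte_views(0.125)$xy)
  expect_error(inflexion_field(w), "unwrapped")
})

test_that("the curvature ridge localizes a homogeneous ellipsoid silhouette to < 1 px", {
  sc <- ri_scene(list(part_ellipsoid(c(4.2, 3.1, 2.5), index = 1.37,
                                     priority = 1L, label = "cell")),
                 medium_index = 1.003)
  pm <- project_phase(sc, "xy")
  ct <- extract_contours(inflexion_field(pm), pm)
  expect_length(ct, 1L)
  expect_identical(ct$cell$label, "cell")
  pts <- ct$cell$points
  ## radial mismatch: scale each point onto the true silhouette ellipse
  s <- sqrt((pts[, 1] / 4.2)^2 + (pts[, 2] / 3.1)^2)
  r_got <- sqrt(rowSums(pts^2))
  expect_lt(max(abs(r_got * (1 - 1 / s))), pm$pixel_size)
})

test_that("the monocyte yields two nested contours with the preset nucleus ellipse", {
  pm <- monocyte_views()$xy
  ct <- extract_contours(inflexion_field(pm), pm, require_nucleus = TRUE)
  expect_setequal(names(ct), c("cell", "nucleus"))
  ## nesting: every nucleus point strictly inside the cell polygon
  inside <- phasecell:::.point_in_polygon(ct$nucleus$points[, 1],
                                          ct$nucleus$points[, 2],
                                          ct$cell$points)
  expect_true(all(inside))
  f <- fit_ellipse2d(ct$nucleus$points[-nrow(ct$nucleus$points), ])
  expect_equal(unname(f["a"]), 3.4, tolerance = 0.02)
  expect_equal(unname(f["b"]), 3.7, tolerance = 0.02)
  expect_lt(max(abs(f[c("uc", "vc")])), 0.05)
})

test_that("a homogeneous sphere has no nucleus signature", {
  sc <- ri_scene(list(part_sphere(6, index = 1.37, label = "cell")),
                 medium_index = 1.003)
  pm <- project_phase(sc, "xy")
  ct <- extract_contours(inflexion_field(pm), pm)
  expect_length(ct, 1L)
  expect_error(extract_contours(inflexion_field(pm), pm,
                                require_nucleus = TRUE),
               "no closed contour found")
})

test_that("the two-ellipsoid model shows nucleus and cell contours on both planes", {
  sc <- build_two_ellipsoid()
  for (pl in c("xy", "xz")) {
    pm <- project_phase(sc, pl)
    ct <- extract_contours(inflexion_field(pm), pm, require_nucleus = TRUE)
    expect_setequal(names(ct), c("cell", "nucleus"))
    expect_gte(nrow(ct$nucleus$points), 17)      # closed, >= 16 distinct points
    expect_true(all(ct$nucleus$points[1, ] == ct$nucleus$points[nrow(ct$nucleus$points), ]))
  }
})

test_that("extremum phase centers match a brute-force restricted argmax", {
  v <- monocyte_views()
  for (pl in c("xy", "xz")) {
    pm <- v[[pl]]
    ct <- extract_contours(inflexion_field(pm), pm, require_nucleus = TRUE)
    pc <- phase_center_extremum(pm, ct$nucleus)
    ## oracle: direct argmax over pixels inside the polygon
    cc <- map_coords(pm)
    g <- expand.grid(u = cc$u, v = cc$v)
    keep <- phasecell:::.point_in_polygon(g$u, g$v, ct$nucleus$points)
    vals <- ifelse(keep, as.vector(pm$values), -Inf)
    k <- which.max(vals)
    expect_equal(pc$coordinates, c(g$u[k], g$v[k]),
                 tolerance = pm$pixel_size + 1e-9)
  }
  ## on the x-y view the extremum sits at the preset center
  pcxy <- phase_center_extremum(v$xy)
  expect_lt(max(abs(pcxy$coordinates)), v$xy$pixel_size)
})

test_that("the extremum of a symmetric model is the exact center of symmetry", {
  sc <- build_two_ellipsoid(nucleus_center = c(0, 0, 0))
  pm <- project_phase(sc, "xy")
  pc <- phase_center_extremum(pm)
  expect_equal(pc$coordinates, c(0, 0), tolerance = 1e-9)   # argmax-set centroid
  ct <- extract_contours(inflexion_field(pm), pm, require_nucleus = TRUE)
  cen <- phase_center_centroid(ct$nucleus)
  expect_lt(max(abs(cen$coordinates - pc$coordinates)), 2 * pm$pixel_size)
})

test_that("contour centroids reproduce closed-form polygon centroids", {
  ell <- ellipse_contour(2.5, 1.5, center = c(0, 3), plane = "xz")
  expect_equal(phase_center_centroid(ell)$coordinates, c(0, 3),
               tolerance = 1e-9)
  sq <- boundary_contour(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1)),
                         plane = "xy", label = "cell")
  expect_equal(phase_center_centroid(sq)$coordinates, c(0.5, 0.5))
  degen <- boundary_contour(rbind(c(0, 0), c(1, 0), c(2, 0)), plane = "xy")
  expect_error(phase_center_centroid(degen), "degenerate")
})

test_that("reconcile_centers merges consistent views and rejects inconsistent x", {
  a <- structure(list(plane = "xy", coordinates = c(0.05, 1.0),
                      method = "centroid"), class = "phase_center")
  b <- structure(list(plane = "xz", coordinates = c(0.05, 3.0),
                      method = "centroid"), class = "phase_center")
  expect_equal(reconcile_centers(a, b), c(x = 0.05, y = 1.0, z = 3.0))
  b$coordinates[1] <- 1.05
  expect_error(reconcile_centers(a, b, tol = 0.2), "no nucleus")
})

test_that("nucleus recovery is sub-2-pixel across random placements", {
  cases <- random_nucleus_scenes(10, seed = 42)
  px <- 0.0625
  for (cs in cases) {
    pm <- project_phase(cs$scene, "xy")
    ct <- extract_contours(inflexion_field(pm), pm, require_nucleus = TRUE)
    f <- fit_ellipse2d(ct$nucleus$points[-nrow(ct$nucleus$points), ])
    expect_lt(abs(f[["uc"]] - cs$center[1]), 2 * px)
    expect_lt(abs(f[["vc"]] - cs$center[2]), 2 * px)
    expect_lt(abs(f[["a"]] - cs$semi_axes[1]), 2 * px)
    expect_lt(abs(f[["b"]] - cs$semi_axes[2]), 2 * px)
  }
})

test_that("contour nesting is preserved under a 90-degree map rotation", {
  pm <- monocyte_views(0.125)$xy
  rot <- phase_map(t(pm$values)[nrow(pm$values):1, ], "xy",
                   pm$pixel_size, wrapped = FALSE,
                   wavelength = pm$wavelength)
  ct <- extract_contours(inflexion_field(rot), rot, require_nucleus = TRUE)
  inside <- phasecell:::.point_in_polygon(ct$nucleus$points[, 1],
                                          ct$nucleus$points[, 2],
                                          ct$cell$points)
  expect_true(all(inside))
  ## semi-axes swap under the rotation
  f <- fit_ellipse2d(ct$nucleus$points[-nrow(ct$nucleus$points), ])
  expect_equal(sort(unname(f[c("a", "b")])), c(3.4, 3.7), tolerance = 0.05)
})

test_that("contours export to CSV", {
  ct <- list(ellipse_contour(2, 1), ellipse_contour(4, 3, label = "cell"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_contours_csv(ct, f)
  d <- utils::read.csv(f)
  expect_setequal(unique(d$label), c("nucleus", "cell"))
  expect_true(all(c("plane", "u", "v") %in% names(d)))
})
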