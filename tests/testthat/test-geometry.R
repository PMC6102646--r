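test_that("profile evaluation matches the closed-form endpoints", {
  g <- reference_geometry()
  # apex: sin = 1, cos = 0
  apex <- evaluate_profile(g, pi / 2)
  expect_equal(unlist(apex), c(rho_epi = 0, zeta_epi = 0, rho_end = 0,
                               zeta_end = g$H))
  # equator: shape factor is exactly 1
  eq <- evaluate_profile(g, 0)
  expect_equal(unlist(eq), c(rho_epi = g$R_b, zeta_epi = g$Z,
                             rho_end = g$R_b - g$L, zeta_end = g$Z))
  # dilated-ventricle table row: endocardial equatorial radius R_b - L
  g2 <- lv_geometry(R_b = 40, Z = 53, L = 10, H = 5.9, e = 0.65,
                    psi0 = -75 * pi / 180)
  expect_equal(evaluate_profile(g2, 0)$rho_end, 30)
  expect_error(evaluate_profile(g, g$psi0 - 0.1), "psi outside")
  # wall thickness factor is nonnegative along the whole profile
  psi <- seq(g$psi0, pi / 2, length.out = 101)
  pr <- evaluate_profile(g, psi)
  expect_true(all(pr$rho_epi - pr$rho_end >= 0))
})

test_that("the transmural chart blends the two profiles linearly", {
  g <- reference_geometry()
  psi <- c(g$psi0, -0.3, 0.4, 1.2)
  pr <- evaluate_profile(g, psi)
  p_endo <- lv_point(g, psi, 0, 0)
  p_epi <- lv_point(g, psi, 1, 0)
  expect_equal(p_endo[, "x"], pr$rho_end, tolerance = 1e-12)
  expect_equal(p_endo[, "z"], pr$zeta_end, tolerance = 1e-12)
  expect_equal(p_epi[, "x"], pr$rho_epi, tolerance = 1e-12)
  expect_equal(p_epi[, "z"], pr$zeta_epi, tolerance = 1e-12)
  mid <- lv_point(g, 0, 0.5, 0)
  expect_equal(unname(mid[1, "x"]), g$R_b - g$L / 2)
  expect_error(lv_point(g, 0, 1.5, 0), "t outside")
})

test_that("volumes reduce to ellipsoid closed forms in the e = 1 limit", {
  g <- ellipsoid_geometry()
  v_cav <- 4 / 3 * pi * (g$R_b - g$L)^2 * (g$Z - g$H) / 1000
  v_wall <- 4 / 3 * pi * (g$R_b^2 * g$Z - (g$R_b - g$L)^2 * (g$Z - g$H)) / 1000
  expect_equal(cavity_volume(g), v_cav, tolerance = 1e-6)
  expect_equal(wall_volume(g), v_wall, tolerance = 1e-6)
})

test_that("cavity volume shrinks as the wall thickens", {
  g <- reference_geometry()
  vols <- sapply(c(6, 9, 12, 15), function(L)
    cavity_volume(lv_geometry(g$R_b, g$Z, L, g$H, g$e, g$psi0)))
  expect_true(all(diff(vols) < 0))
})

test_that("quadrature weights integrate to the wall volume", {
  g <- reference_geometry()
  q <- lv_quadrature(g)  # default 24 x 8 x 24
  expect_true(all(q$weights > 0))
  expect_equal(sum(q$weights) / 1000, wall_volume(g), tolerance = 5e-3)
})

test_that("fiber frames are orthonormal and follow the helix-angle rule", {
  g <- reference_geometry()
  q <- lv_quadrature(g, 12, 6, 8)
  fr <- q$frames
  expect_lt(max(abs(rowSums(fr$f^2) - 1)), 1e-10)
  expect_lt(max(abs(rowSums(fr$s^2) - 1)), 1e-10)
  expect_lt(max(abs(rowSums(fr$n^2) - 1)), 1e-10)
  expect_lt(max(abs(rowSums(fr$f * fr$s))), 1e-10)
  expect_lt(max(abs(rowSums(fr$f * fr$n))), 1e-10)
  # right-handedness: n = f x s
  cross <- cbind(fr$f[, 2] * fr$s[, 3] - fr$f[, 3] * fr$s[, 2],
                 fr$f[, 3] * fr$s[, 1] - fr$f[, 1] * fr$s[, 3],
                 fr$f[, 1] * fr$s[, 2] - fr$f[, 2] * fr$s[, 1])
  expect_lt(max(abs(cross - fr$n)), 1e-10)
  # endocardium: fully longitudinal fiber (no circumferential component)
  fr0 <- fiber_frame(g, 0, 0, 0)
  expect_lt(abs(fr0$f[1, 2]), 1e-12)   # e_circ at theta=0 is +y
  # alpha = 0 at t = 0.6: purely circumferential
  fr06 <- fiber_frame(g, 0, 0.6, 0)
  expect_equal(fr06$f[1, ], c(0, 1, 0), tolerance = 1e-9)
  # epicardium: alpha = -60 degrees from circumferential
  fr1 <- fiber_frame(g, 0, 1, 0)
  expect_equal(unname(fr1$f[1, 2]), cos(-60 * pi / 180), tolerance = 1e-9)
})

test_that("voxelization agrees with analytic volumes at fine spacing", {
  g <- reference_geometry()
  img <- voxelize(g, spacing = c(0.5, 0.5, 0.5))
  vv <- prod(img$spacing)
  expect_equal(sum(img$voxels == 2L) * vv / 1000, wall_volume(g),
               tolerance = 0.01)
  expect_equal(sum(img$voxels == 1L) * vv / 1000, cavity_volume(g),
               tolerance = 0.01)
  # Richardson check: error shrinks with spacing
  err <- sapply(c(2, 1, 0.5), function(h) {
    im <- voxelize(g, spacing = rep(h, 3))
    abs(sum(im$voxels == 2L) * h^3 / 1000 - wall_volume(g))
  })
  expect_true(err[3] < err[1])
})

test_that("voxelization respects pose, extent and grid contracts", {
  g <- ellipsoid_geometry(R_b = 20, Z = 25, L = 5, H = 4)
  img <- voxelize(g, spacing = c(2, 2, 2))
  # whole-voxel translation on an aligned grid preserves label counts
  pose <- rigid_pose(translation = c(2, -4, 6))
  img2 <- voxelize(g, pose = pose, spacing = c(2, 2, 2))
  expect_equal(table(img2$voxels), table(img$voxels))
  # grid far away from the geometry: all zeros
  far <- voxelize(g, grid = list(dim = c(8, 8, 8), spacing = c(2, 2, 2),
                                 origin = c(500, 500, 500)))
  expect_true(all(far$voxels == 0L))
  # grid clipping the geometry: error
  expect_error(voxelize(g, grid = list(dim = c(10, 10, 10),
                                       spacing = c(2, 2, 2),
                                       origin = c(0, 0, 0))),
               "too small")
})

test_that("label images survive a NIfTI round trip", {
  g <- ellipsoid_geometry(R_b = 18, Z = 20, L = 5, H = 4)
  img <- voxelize(g, spacing = c(2, 2, 4))
  path <- tempfile(fileext = ".nii.gz")
  write_label_image(img, path)
  back <- read_label_image(path)
  expect_equal(back$voxels, img$voxels, ignore_attr = TRUE)
  expect_equal(back$spacing, img$spacing, tolerance = 1e-6)
  expect_equal(unname(back$origin), img$origin, tolerance = 1e-4)
})

test_that("region masks select the requested wall band", {
  g <- reference_geometry()
  q <- lv_quadrature(g, 16, 8, 16)
  expect_equal(region_mask(q, c(0, 1), c(0, 1)), seq_len(nrow(q$points)))
  expect_error(region_mask(q, c(1.1, 1.2)), "within")
  sel <- region_mask(q)
  expect_gt(length(sel), 0)
  frac <- length(sel) / nrow(q$points)
  expect_gt(frac, 0.004)
  expect_lt(frac, 0.08)
  expect_true(all(q$points$t[sel] >= 0.4 & q$points$t[sel] <= 0.6))
})
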