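test_that("the cavity-and-wall similarity matches hand-counted overlaps", {
  mk <- function(v) label_image(array(v, c(4, 4, 1)), c(1, 1, 1))
  a <- mk(c(rep(1L, 4), rep(2L, 4), rep(0L, 8)))
  expect_equal(similarity_j(a, a), 0)
  # shift the labels so both classes overlap on half their union:
  # cavity A = {1..4}, cavity B = {3..6} -> Jaccard 2/6 = 1/3; same for wall
  b <- mk(c(0L, 0L, 1L, 1L, 1L, 1L, 2L, 2L, 2L, 2L, rep(0L, 6)))
  expect_equal(similarity_j(a, b), 1 - 0.5 * (2 / 6 + 2 / 6))
  expect_equal(similarity_j(a, b), similarity_j(b, a))
  # fully disjoint
  d <- mk(c(rep(0L, 8), rep(1L, 4), rep(2L, 4)))
  expect_equal(similarity_j(a, d), 1)
  expect_error(similarity_j(a, label_image(array(0L, c(3, 3, 1)), 1)),
               "share")
  expect_warning(expect_warning(
    j <- similarity_j(mk(rep(0L, 16)), mk(rep(0L, 16))),
    "label 1"), "label 2")
  expect_equal(j, 1)
})

test_that("wall Dice agrees with an independent point-sampling oracle", {
  g1 <- ellipsoid_geometry(R_b = 34, Z = 40, L = 9, H = 7)
  g2 <- ellipsoid_geometry(R_b = 38, Z = 44, L = 12, H = 9)
  expect_equal(dice_score(g1, g1), 1)
  d <- dice_score(g1, g2, spacing = 0.5)
  # oracle: uniform random points classified by the closed-form ellipsoid
  # inequalities (wall = inside outer, outside inner shell)
  in_wall <- function(g, x, y, z) {
    outer_ <- (x^2 + y^2) / g$R_b^2 + (z - g$Z)^2 / g$Z^2 <= 1
    inner <- (x^2 + y^2) / (g$R_b - g$L)^2 +
      (z - g$Z)^2 / (g$Z - g$H)^2 < 1
    outer_ & !inner
  }
  set.seed(42)
  n <- 2e5
  x <- runif(n, -40, 40); y <- runif(n, -40, 40); z <- runif(n, -2, 90)
  w1 <- in_wall(g1, x, y, z); w2 <- in_wall(g2, x, y, z)
  d_mc <- 2 * sum(w1 & w2) / (sum(w1) + sum(w2))
  expect_equal(d, d_mc, tolerance = 0.02)
})

test_that("the long axis is recovered from slice centroids", {
  g <- reference_geometry()
  img <- voxelize(g, spacing = c(2, 2, 4))
  ax <- estimate_long_axis(img)
  expect_gt(abs(ax$direction[3]), cos(1 * pi / 180))
  # base -> apex points toward decreasing z in canonical pose
  expect_lt(ax$direction[3], 0)
  # rotated image: axis follows
  th <- 30 * pi / 180
  R <- matrix(c(1, 0, 0, 0, cos(th), sin(th), 0, -sin(th), cos(th)), 3, 3)
  img_r <- voxelize(g, pose = rigid_pose(rotation = R), spacing = c(2, 2, 4))
  ax_r <- estimate_long_axis(img_r)
  target <- drop(R %*% c(0, 0, -1))
  expect_gt(abs(sum(ax_r$direction * target)), cos(2 * pi / 180))
  # single-slice image is rejected
  one <- label_image(array(1L, c(4, 4, 1)), c(1, 1, 8))
  expect_error(estimate_long_axis(one), "2 non-empty")
})

test_that("surface fitting is a round trip on in-family clouds", {
  g <- lv_geometry(R_b = 37, Z = 50, L = 10.5, H = 6.3, e = 0.72,
                   psi0 = -68 * pi / 180)
  epi <- sample_surface(g, "epi")
  endo <- sample_surface(g, "endo")
  init <- lv_geometry(33, 46, 9, 5.5, 0.8, -60 * pi / 180)
  fit <- fit_to_surfaces(epi, endo, init)
  expect_equal(as.numeric(fit), as.numeric(g), tolerance = 1e-3)
  # epi-only: thickness parameters keep their initial values
  fit_epi <- fit_to_surfaces(epi, NULL, init)
  expect_equal(fit_epi$L, init$L)
  expect_equal(fit_epi$H, init$H)
  expect_equal(fit_epi$R_b, g$R_b, tolerance = 1e-2)
  # the monolithic variant reaches the same shape
  fit_mono <- fit_to_surfaces(epi, endo, init, monolithic = TRUE)
  expect_equal(as.numeric(fit_mono), as.numeric(g), tolerance = 5e-3)
})

test_that("image fitting recovers a known geometry", {
  g <- lv_geometry(R_b = 36, Z = 50, L = 10, H = 7, e = 0.72,
                   psi0 = -65 * pi / 180)
  img <- voxelize(g, spacing = c(2, 2, 2))
  # initialized at the truth the similarity is already essentially zero
  fit0 <- fit_to_image(img, init = g, restarts = 0, maxit = 50)
  expect_lt(fit0$J, 0.03)
  # from the population mean: lengths within one (2 mm) voxel; the
  # truncation angle is the least identifiable parameter at this spacing
  fit <- fit_to_image(img)
  v <- as.numeric(fit$geometry); truth <- as.numeric(g)
  expect_lt(max(abs(v[1:4] - truth[1:4])), 2)
  expect_lt(abs(v[5] - truth[5]), 0.05)
  expect_lt(abs(v[6] - truth[6]), 6 * pi / 180)
  expect_lt(fit$J, 0.05)
  expect_true(fit$converged)
})

test_that("synthetic segmentations are seeded and boundary-noisy", {
  g <- reference_geometry()
  clean <- generate_label_image(g, spacing = c(2, 2, 6), label_noise_rate = 0)
  ref <- voxelize(g, spacing = c(2, 2, 6))
  expect_identical(clean$voxels, ref$voxels)
  n1 <- generate_label_image(g, spacing = c(2, 2, 6), label_noise_rate = 0.2,
                             seed = 7)
  n2 <- generate_label_image(g, spacing = c(2, 2, 6), label_noise_rate = 0.2,
                             seed = 7)
  expect_identical(n1$voxels, n2$voxels)
  expect_false(identical(n1$voxels, clean$voxels))
  # flips are restricted to boundary-adjacent voxels
  j <- similarity_j(n1, clean)
  expect_gt(j, 0)
  expect_lt(j, 0.5)
})
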