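test_that("lesion membership matches its set definition", {
  g <- infarct_baseline()
  q <- lv_quadrature(g, 16, 6, 24)
  none <- infarct_spec(0.5, 0, 0.5, 0)
  expect_false(any(lesion_membership(g, none, q$points$psi, q$points$t,
                                     q$points$theta)))
  # half-circumference, full length and depth: exactly half the wall
  half <- infarct_spec(0.5, pi, 1, 1)
  iv <- infarct_volume(g, half)
  expect_equal(iv$fraction, 0.5, tolerance = 1e-9)
  expect_equal(iv$volume, wall_volume(g) / 2, tolerance = 5e-3)
})

test_that("lesion volume agrees with a Monte-Carlo membership oracle", {
  g <- infarct_baseline()
  spec <- infarct_spec(0.43, 1.22, 0.40, 0.40)
  iv <- infarct_volume(g, spec)
  set.seed(8)
  n <- 4e5
  psi <- runif(n, g$psi0, pi / 2)
  t <- runif(n, 0, 1)
  theta <- runif(n, 0, 2 * pi)
  p <- lvmech:::chart_partials(g, psi, t)
  w <- abs(p$rho * (p$rho_t * p$zeta_psi - p$rho_psi * p$zeta_t))
  member <- lesion_membership(g, spec, psi, t, theta)
  frac_mc <- sum(w[member]) / sum(w)
  expect_equal(iv$fraction, frac_mc, tolerance = 0.02)
})

test_that("bigger lesions occupy more wall and scale linearly in angle", {
  g <- infarct_baseline()
  small <- infarct_volume(g, infarct_spec(0.43, 1.22, 0.40, 0.40))
  large <- infarct_volume(g, infarct_spec(0.79, 1.57, 0.46, 1.0))
  expect_gt(large$volume, small$volume)
  v1 <- infarct_volume(g, infarct_spec(0.5, 0.6, 0.4, 0.5))$volume
  v2 <- infarct_volume(g, infarct_spec(0.5, 1.2, 0.4, 0.5))$volume
  v3 <- infarct_volume(g, infarct_spec(0.5, 2.4, 0.4, 0.5))$volume
  expect_equal(v2 / v1, 2, tolerance = 1e-6)
  expect_equal(v3 / v1, 4, tolerance = 1e-6)
})

test_that("the calibrated cycle hits both stroke-volume anchors", {
  g <- infarct_baseline()
  mat <- material("usyk")
  hemo <- cached("hemo_usyk", calibrate_elastance(g, mat))
  base <- simulate_cycle(g, mat, NULL, hemo)
  expect_equal(base$SV, 49, tolerance = 1e-6)
  expect_equal(base$SV, base$EDV - base$ESV)
  worst <- simulate_cycle(g, mat, infarct_spec(0.5, pi, 1, 1), hemo)
  expect_equal(worst$SV, 21, tolerance = 1e-6)
  # PV loop encloses a nonnegative area equal in width to the stroke volume
  expect_true(all(base$pv$volume >= hemo$V0 - 1e-9))
  expect_equal(diff(range(base$pv$volume)), base$SV, tolerance = 1e-9)
})

test_that("stroke volume depends on the lesion only through its fraction", {
  g <- infarct_baseline()
  mat <- material("usyk")
  hemo <- cached("hemo_usyk", calibrate_elastance(g, mat))
  # two lesions at different locations scaled in angle to the same fraction
  spec_a <- infarct_spec(0.3, 1.0, 0.5, 0.6)
  f_a <- infarct_volume(g, spec_a)$fraction
  f_b_unit <- infarct_volume(g, infarct_spec(0.7, 1.0, 0.5, 0.6))$fraction
  spec_b <- infarct_spec(0.7, 1.0 * f_a / f_b_unit, 0.5, 0.6)
  a <- simulate_cycle(g, mat, spec_a, hemo)
  b <- simulate_cycle(g, mat, spec_b, hemo)
  expect_equal(a$infarct_fraction, b$infarct_fraction, tolerance = 1e-9)
  expect_equal(a$SV, b$SV, tolerance = 1e-9)
  # monotone non-increasing in each extension parameter
  sv_depth <- sapply(c(0.2, 0.5, 0.8), function(d)
    simulate_cycle(g, mat, infarct_spec(0.5, 1.5, 0.5, d), hemo)$SV)
  sv_circ <- sapply(c(0.5, 1.5, 2.5), function(dc)
    simulate_cycle(g, mat, infarct_spec(0.5, dc, 0.5, 0.6), hemo)$SV)
  sv_long <- sapply(c(0.2, 0.5, 0.8), function(dl)
    simulate_cycle(g, mat, infarct_spec(0.5, 1.5, dl, 0.6), hemo)$SV)
  expect_true(all(diff(sv_depth) < 0))
  expect_true(all(diff(sv_circ) < 0))
  expect_true(all(diff(sv_long) < 0))
})

test_that("the infarct study table is complete, bounded and seeded", {
  tab <- full_infarct_study()
  expect_equal(nrow(tab), 40)
  expect_true(all(tab$SV >= 0 & tab$SV <= 49 + 1e-9))
  expect_true(all(tab$infarct_fraction >= 0 & tab$infarct_fraction <= 0.5 + 1e-9))
  tab2 <- run_infarct_study(n = 40, seed = 1)
  expect_identical(tab2$SV, tab$SV)
})

test_that("the SV emulator is smooth and dominated by depth and angle", {
  tab <- full_infarct_study()
  gp <- train_sv_surrogate(tab, seed = 1)
  pr <- gp_surrogate_predict(gp, as.matrix(
    tab[, c("long_pos", "d_circ", "d_long", "depth")]))
  expect_true(all(abs(drop(pr$mean) - tab$SV) < 3))
  axes <- c("long_pos", "d_circ", "d_long", "depth")
  pairs <- utils::combn(axes, 2, simplify = FALSE)
  maps <- lapply(pairs, function(ax) slice_map(gp, ax, n_grid = 12))
  expect_length(maps, 6)
  expect_true(all(vapply(maps, function(m) all(is.finite(m$SV)), logical(1))))
  # single-axis sweeps: SV range largest along depth or d_circ
  sweep_range <- sapply(axes, function(ax) {
    X <- matrix(rep(c(0.5, pi / 2, 0.5, 0.5), each = 21), 21, 4,
                dimnames = list(NULL, axes))
    lim <- if (ax == "d_circ") c(0, pi) else c(0, 1)
    X[, ax] <- seq(lim[1], lim[2], length.out = 21)
    diff(range(gp_surrogate_predict(gp, X)$mean))
  })
  expect_true(which.max(sweep_range) %in% which(axes %in% c("depth", "d_circ")))
  expect_gt(min(sweep_range[c("depth", "d_circ")]), sweep_range["long_pos"])
})

test_that("cross-validation is near-exact on a linear response surface", {
  X <- lhs_uniform(30, infarct_box(), seed = 9)
  tab <- as.data.frame(X)
  tab$SV <- 50 - 5 * tab$long_pos - 4 * tab$d_circ - 3 * tab$d_long -
    6 * tab$depth
  err <- kfold_cv(tab, k = 5, seed = 3)
  expect_lt(as.numeric(err), 0.5)
  expect_length(attr(err, "folds"), 5)
})
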