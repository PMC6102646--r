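test_that("fixed-point unloading inverts the forward inflation", {
  g_u <- lv_geometry(R_b = 38, Z = 50, L = 10, H = 6.5, e = 0.7,
                     psi0 = -65 * pi / 180)
  mat <- material("whog")
  target <- inflate(g_u, mat, 1)$xi_deformed
  res <- fixed_point_unload(target, 1, mat)
  tolv <- 3 * c(0.1, 0.1, 0.1, 0.1, 0.005, 0.5 * pi / 180)
  expect_true(all(abs(as.numeric(res$xi_unloaded) - as.numeric(g_u)) <= tolv))
  expect_lte(res$n_iterations, 10)
  # the reloaded shape matches the target to the residual tolerance
  expect_true(all(abs(as.numeric(res$xi_reloaded) - as.numeric(target)) <=
                    c(0.1, 0.1, 0.1, 0.1, 0.005, 0.5 * pi / 180)))
})

test_that("zero-pressure unloading returns the target in one iteration", {
  g <- reference_geometry()
  res <- fixed_point_unload(g, 0, material("usyk"))
  expect_equal(res$n_iterations, 1)
  expect_equal(as.numeric(res$xi_unloaded), as.numeric(g))
})

test_that("training sets bookkeep records, pressures and failures", {
  st <- population_stats("BoD")
  samples <- lhs_normal(8, st, seed = 31)
  feas <- vapply(samples, function(g) isTRUE(as.logical(is_feasible(g))),
                 logical(1))
  good <- samples[feas][1:3]
  # inject a geometry that fails the feasibility screen
  bad <- lv_geometry(R_b = 22, Z = 40, L = 16.5, H = 6, e = 0.5,
                     psi0 = -80 * pi / 180)
  ts <- build_training_set(c(good, list(bad)), material("whow"),
                           pressures = c(1, 2))
  expect_named(ts, c("1", "2"))
  expect_equal(nrow(ts[["1"]]), 3)
  expect_equal(nrow(ts[["2"]]), 3)
  expect_match(attr(ts[["1"]], "log"), "dropped", all = FALSE)
  # loaded cavity grows with the conditioning pressure
  v1 <- geometry_from_row(stats::setNames(
    as.list(ts[["1"]][1, paste0("l_", c("R_b", "L", "Z", "H", "e", "psi0"))]),
    c("R_b", "L", "Z", "H", "e", "psi0")))
  v2 <- geometry_from_row(stats::setNames(
    as.list(ts[["2"]][1, paste0("l_", c("R_b", "L", "Z", "H", "e", "psi0"))]),
    c("R_b", "L", "Z", "H", "e", "psi0")))
  expect_gt(cavity_volume(v2), cavity_volume(v1))
})

test_that("stretch-conditioned records hit the stretch target", {
  st <- population_stats("BoD")
  samples <- lhs_normal(6, st, seed = 57)
  feas <- vapply(samples, function(g) isTRUE(as.logical(is_feasible(g))),
                 logical(1))
  good <- samples[feas][1:4]
  ts <- build_training_set(good, material("usyk"), stretch_targets = 1.10,
                           P_max = 5)
  tab <- ts[["1.1"]]
  expect_true(all(abs(tab$lambda - 1.10) <= 0.005))
  expect_true(all(tab$P > 0))
  # stretch-conditioned surrogate predicts the located pressure jointly
  un <- train_unloader(ts, seed = 4)
  nm <- c("R_b", "Z", "L", "H", "e", "psi0")
  loaded <- geometry_from_row(stats::setNames(
    as.list(tab[1, paste0("l_", nm)]), nm))
  pred <- predict_unloaded(un, loaded, 1.10)
  expect_true(is.finite(pred$pressure))
  expect_lt(abs(pred$pressure - tab$P[1]), 0.5)
})

test_that("trained surrogates reproduce training pairs and check conditioning", {
  st <- population_stats("BoD")
  samples <- lhs_normal(14, st, seed = 41)
  feas <- vapply(samples, function(g) isTRUE(as.logical(is_feasible(g))),
                 logical(1))
  good <- samples[feas]
  ts <- build_training_set(good, material("whow"), pressures = 1)
  un <- train_unloader(ts, seed = 2)
  tab <- ts[["1"]]
  nm <- c("R_b", "Z", "L", "H", "e", "psi0")
  loaded <- geometry_from_row(stats::setNames(
    as.list(tab[1, paste0("l_", nm)]), nm))
  pred <- predict_unloaded(un, loaded, 1)
  expect_lt(max(abs(as.numeric(pred$xi_unloaded) -
                    unlist(tab[1, paste0("u_", nm)])) /
                c(1, 1, 1, 1, 0.05, 0.02)), 1)
  expect_length(pred$sd, 6)
  expect_error(predict_unloaded(un, loaded, 1.5), "no trained model")
})

test_that("stretch-mode unloading is invariant to homogeneous stiffness scaling", {
  # scaling the whole energy functional (material coefficients together with
  # the incompressibility and basal-clamp penalty weights, which stand in
  # for exact, scale-invariant constraints) rescales the pressure-stretch
  # curve but leaves the shape trajectory unchanged
  g_u <- lv_geometry(R_b = 39, Z = 51, L = 9.8, H = 6.0, e = 0.68,
                     psi0 = -70 * pi / 180)
  mat1 <- material("usyk")
  co2 <- mat1$coefficients; co2$C <- 2 * co2$C
  mat2 <- material_model("fung_usyk", co2, label = "usyk_x2")
  opt1 <- list()
  opt2 <- list(kappa = 800, clamp_k = 400)
  traj1 <- inflation_sweep(g_u, mat1, P_max = 3, dP = 0.25, options = opt1)
  traj2 <- inflation_sweep(g_u, mat2, P_max = 3, dP = 0.25, options = opt2)
  p1 <- pressure_at_stretch(traj1, 1.10)
  p2 <- pressure_at_stretch(traj2, 1.10)
  expect_equal(p2, 2 * p1, tolerance = 0.02)
  # loaded shapes at the respective stretch pressures coincide
  s1 <- inflate(g_u, mat1, p1, options = opt1)
  s2 <- inflate(g_u, mat2, p2, options = opt2)
  expect_lt(max(abs(as.numeric(s1$xi_deformed) - as.numeric(s2$xi_deformed)) /
                c(0.2, 0.2, 0.2, 0.2, 0.01, 0.02)), 1)
  expect_gt(dice_score(s1$xi_deformed, s2$xi_deformed), 0.985)
  # and so do the fixed-point unloaded shapes of a common loaded target
  fp1 <- fixed_point_unload(s1$xi_deformed, p1, mat1, options = opt1)
  fp2 <- fixed_point_unload(s1$xi_deformed, p2, mat2, options = opt2)
  expect_gt(dice_score(fp1$xi_unloaded, fp2$xi_unloaded), 0.985)
})
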