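test_that("the in-family deformation gradient has the exact limits", {
  g <- reference_geometry()
  q <- data.frame(psi = c(-0.5, 0.2, 1.0), t = c(0.3, 0.5, 0.8),
                  theta = c(0, 1, 4))
  F_id <- deformation_gradient(g, g, q$psi, q$t, q$theta)
  for (i in 1:3) expect_equal(F_id[i, , ], diag(3), tolerance = 1e-8)
  # similarity map: all lengths scaled by k gives F = k I everywhere
  k <- 1.17
  g2 <- lv_geometry(k * g$R_b, k * g$Z, k * g$L, k * g$H, g$e, g$psi0)
  F_k <- deformation_gradient(g, g2, q$psi, q$t, q$theta)
  for (i in 1:3) expect_equal(F_k[i, , ], k * diag(3), tolerance = 1e-8)
})

test_that("det F matches an independent finite-difference volume ratio", {
  g <- reference_geometry()
  g2 <- lv_geometry(46, 51, 8.3, 4.9, 0.62, -77 * pi / 180)
  psi <- 0.3; t <- 0.45; theta <- 0.8
  F <- deformation_gradient(g, g2, psi, t, theta)
  # 6-point stencil volume elements in each configuration
  vol_elem <- function(geom) {
    h <- 1e-4
    dpsi <- (lv_point(geom, psi + h, t, theta) -
             lv_point(geom, psi - h, t, theta)) / (2 * h)
    dt <- (lv_point(geom, psi, t + h, theta) -
           lv_point(geom, psi, t - h, theta)) / (2 * h)
    dth <- (lv_point(geom, psi, t, theta + h) -
            lv_point(geom, psi, t, theta - h)) / (2 * h)
    abs(det(rbind(dpsi, dt, dth)))
  }
  expect_equal(det(F), vol_elem(g2) / vol_elem(g), tolerance = 1e-6)
})

test_that("the Ritz functional behaves like a potential energy", {
  g <- reference_geometry()
  mat <- material("usyk")
  # at rest the Fung energy vanishes (no clamp offset, no pressure work)
  expect_equal(potential_energy(g, g, mat, 0), 0, tolerance = 1e-9)
  # at 5 kPa, moving toward a slightly larger cavity releases energy
  g_out <- lv_geometry(g$R_b + 0.4, g$Z, g$L - 0.1, g$H, g$e, g$psi0)
  expect_lt(potential_energy(g, g_out, mat, 5), potential_energy(g, g, mat, 5))
})

test_that("the volumetric penalty controls incompressibility", {
  g <- reference_geometry()
  mat <- material("whog")
  # pointwise Jacobian deviation sampled over the wall interior
  psi <- rep(seq(g$psi0 + 0.1, 1.3, length.out = 8), times = 4)
  t <- rep(c(0.2, 0.4, 0.6, 0.8), each = 8)
  mean_jdev <- sapply(c(125, 250, 500), function(kap) {
    s <- inflate(g, mat, 2, options = list(kappa = kap))
    F <- deformation_gradient(g, s$xi_deformed, psi, t, 0)
    mean(abs(apply(F, 1, det) - 1))
  })
  expect_true(all(diff(mean_jdev) < 0))
  s <- inflate(g, mat, 2)
  expect_lt(abs(s$wall_vol - wall_volume(g)) / wall_volume(g), 0.02)
})

test_that("inflation is the identity at zero pressure and deterministic", {
  g <- reference_geometry()
  mat <- material("whow")
  s0 <- inflate(g, mat, 0)
  expect_equal(as.numeric(s0$xi_deformed), as.numeric(g), tolerance = 1e-6)
  expect_equal(s0$lambda_ff_midwall, 1, tolerance = 1e-9)
  s_a <- inflate(g, mat, 1)
  s_b <- inflate(g, mat, 1)
  expect_identical(as.numeric(s_a$xi_deformed), as.numeric(s_b$xi_deformed))
})

test_that("pressurization thins the wall and dilates the cavity", {
  g <- reference_geometry()
  mat <- material("usyk")
  s5 <- inflate(g, mat, 5)
  expect_lt(s5$xi_deformed$L, g$L)
  expect_lt(s5$xi_deformed$H, g$H)
  expect_lt(abs(s5$wall_vol - wall_volume(g)) / wall_volume(g), 0.02)
  traj <- inflation_sweep(g, mat, P_max = 5, dP = 1)
  vols <- sapply(traj$states, `[[`, "cavity_vol")
  expect_true(all(diff(c(cavity_volume(g), vols)) > 0))
  lams <- sapply(traj$states, `[[`, "lambda_ff_midwall")
  expect_true(all(diff(c(1, lams)) > 0))
})

test_that("sweeps produce the requested pressure ladder", {
  g <- reference_geometry()
  traj <- inflation_sweep(g, material("whow"), P_max = 2, dP = 0.5)
  expect_length(traj$states, 4)
  expect_equal(sapply(traj$states, `[[`, "pressure"), c(0.5, 1, 1.5, 2))
  tab <- trajectory_table(traj)
  expect_equal(nrow(tab), 4)
  path <- tempfile(fileext = ".csv")
  write_trajectory(traj, path)
  expect_equal(nrow(utils::read.csv(path)), 4)
})

test_that("midwall fiber stretch reports homogeneous stretch exactly", {
  g <- reference_geometry()
  k <- 1.08
  g2 <- lv_geometry(k * g$R_b, k * g$Z, k * g$L, k * g$H, g$e, g$psi0)
  state <- structure(list(xi_unloaded = g, xi_deformed = g2),
                     class = "lv_loaded_state")
  expect_equal(midwall_fiber_stretch(state), k, tolerance = 1e-9)
})

test_that("pressure interpolation at a stretch target inverts the sweep", {
  fake_state <- function(P, lam) structure(
    list(pressure = P, lambda_ff_midwall = lam), class = "lv_loaded_state")
  traj <- structure(list(states = lapply(seq(0.5, 5, by = 0.5), function(P)
    fake_state(P, 1 + 0.05 * P))), class = "inflation_trajectory")
  expect_equal(pressure_at_stretch(traj, 1), 0)
  expect_equal(pressure_at_stretch(traj, 1.10), 2.0, tolerance = 1e-9)
  expect_error(pressure_at_stretch(traj, 2.0), "unreachable")
  expect_error(pressure_at_stretch(traj, 0.9), ">= 1")
})
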