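# Reduced-order forward model of passive inflation.
#
# The deformed configuration is constrained to the same six-parameter shape
# family as the reference: quasi-static equilibrium is found by minimizing the
# total potential energy (elastic strain energy + volumetric penalty - pressure
# work) over the family parameters, with the basal plane height held fixed
# (the axial basal constraint of the full 3-D problem). Because both reference
# and deformed configurations are axisymmetric and share the material chart,
# all strain quantities are theta-independent and quadrature reduces to a
# single meridional plane with circumferential weight 2*pi.

default_solver_options <- function() {
  list(n_psi = 12, n_t = 5, kappa = 400, dP = 0.25,
       maxit = 200, factr = 2e8,
       clamp_k = 200, clamp_band = 3)
}

# batched 3x3 linear algebra on n x 9 column-major matrices ---------------

batch_mm <- function(A, B) {
  C <- matrix(0, nrow(A), 9)
  for (j in 1:3) {
    jb <- 3 * (j - 1)
    for (i in 1:3) {
      C[, i + jb] <- A[, i] * B[, 1 + jb] + A[, i + 3] * B[, 2 + jb] +
        A[, i + 6] * B[, 3 + jb]
    }
  }
  C
}

batch_tmm <- function(A, B) {  # t(A) %*% B
  C <- matrix(0, nrow(A), 9)
  for (j in 1:3) {
    jb <- 3 * (j - 1)
    for (i in 1:3) {
      ia <- 3 * (i - 1)
      C[, i + jb] <- A[, 1 + ia] * B[, 1 + jb] + A[, 2 + ia] * B[, 2 + jb] +
        A[, 3 + ia] * B[, 3 + jb]
    }
  }
  C
}

batch_det <- function(A) {
  A[, 1] * (A[, 5] * A[, 9] - A[, 8] * A[, 6]) -
    A[, 4] * (A[, 2] * A[, 9] - A[, 8] * A[, 3]) +
    A[, 7] * (A[, 2] * A[, 6] - A[, 5] * A[, 3])
}

batch_inv <- function(A) {
  d <- batch_det(A)
  I <- matrix(0, nrow(A), 9)
  I[, 1] <- (A[, 5] * A[, 9] - A[, 8] * A[, 6]) / d
  I[, 2] <- -(A[, 2] * A[, 9] - A[, 8] * A[, 3]) / d
  I[, 3] <- (A[, 2] * A[, 6] - A[, 5] * A[, 3]) / d
  I[, 4] <- -(A[, 4] * A[, 9] - A[, 7] * A[, 6]) / d
  I[, 5] <- (A[, 1] * A[, 9] - A[, 7] * A[, 3]) / d
  I[, 6] <- -(A[, 1] * A[, 6] - A[, 4] * A[, 3]) / d
  I[, 7] <- (A[, 4] * A[, 8] - A[, 7] * A[, 5]) / d
  I[, 8] <- -(A[, 1] * A[, 8] - A[, 7] * A[, 2]) / d
  I[, 9] <- (A[, 1] * A[, 5] - A[, 4] * A[, 2]) / d
  I
}

# chart Jacobian at the theta = 0 meridional plane as an n x 9 matrix
meridional_jacobian <- function(geom, psi, t) {
  p <- chart_partials(geom, psi, t)
  n <- length(psi)
  J <- matrix(0, n, 9)
  J[, 1] <- p$rho_psi   # d x / d psi
  J[, 3] <- p$zeta_psi  # d z / d psi
  J[, 4] <- p$rho_t     # d x / d t
  J[, 6] <- p$zeta_t    # d z / d t
  J[, 8] <- p$rho       # d y / d theta
  J
}

# precomputed reference data for the Ritz solver
inflation_setup <- function(xi_u, mat, options = list()) {
  opt <- utils::modifyList(default_solver_options(), options)
  gp <- gauss_rule(opt$n_psi, xi_u$psi0, pi / 2)
  gt <- gauss_rule(opt$n_t, 0, 1)
  psi <- rep(gp$x, times = opt$n_t)
  t <- rep(gt$x, each = opt$n_psi)
  w_par <- rep(gp$w, times = opt$n_t) * rep(gt$w, each = opt$n_psi) * 2 * pi
  Ju <- meridional_jacobian(xi_u, psi, t)
  detJu <- batch_det(Ju)
  w <- w_par * abs(detJu)                 # reference volume weights, mm^3
  fr <- fiber_frame(xi_u, psi, t, rep(0, length(psi)))
  M <- cbind(fr$f, fr$s, fr$n)            # n x 9 column-major [f s n]
  # epicardial material points within clamp_band mm below the base, tethered
  # to their reference positions (the basal epicardial clamp of the full
  # 3-D problem, reproduced as a quadratic penalty)
  zb <- basal_height(xi_u)
  psi_c <- numeric(0)
  if (opt$clamp_k > 0) {
    s_lo <- 1 - max(0, zb - opt$clamp_band) / xi_u$Z
    psi_hi <- asin(min(1, max(sin(xi_u$psi0), s_lo)))
    psi_c <- seq(xi_u$psi0, max(xi_u$psi0, psi_hi), length.out = 3)
  }
  clamp_ref <- if (length(psi_c)) {
    pr <- evaluate_profile(xi_u, psi_c)
    cbind(pr$rho_epi, pr$zeta_epi)
  } else NULL
  list(xi_u = xi_u, mat = mat, opt = opt, psi = psi, t = t,
       w = w, Ju_inv = batch_inv(Ju), detJu = detJu, M = M,
       zeta_base = zb, V_u = cavity_volume(xi_u),
       psi_clamp = psi_c, clamp_ref = clamp_ref)
}

# candidate free parameters, internal order (R_b, e, L, H, psi0);
# Z recovered from the fixed basal plane height
candidate_geometry <- function(x, zeta_base) {
  psi0 <- x[5]
  Z <- zeta_base / (1 - sin(psi0))
  if (!(x[1] > x[3] && x[3] > 0 && Z > x[4] && x[4] > 0 &&
        x[2] >= 0 && x[2] <= 1))
    return(NULL)
  tryCatch(lv_geometry(x[1], Z, x[3], x[4], x[2], psi0),
           error = function(e) NULL)
}

BIG_ENERGY <- 1e10

# total potential energy (kPa mm^3) of a candidate parameter vector
ritz_energy <- function(x, setup, P) {
  geom <- candidate_geometry(x, setup$zeta_base)
  if (is.null(geom)) return(BIG_ENERGY)
  Jd <- meridional_jacobian(geom, setup$psi, setup$t)
  F <- batch_mm(Jd, setup$Ju_inv)
  detF <- batch_det(Jd) / setup$detJu
  if (any(detF <= 1e-8)) return(BIG_ENERGY)
  C <- batch_tmm(F, F)
  scale <- detF^(-2 / 3)                          # isochoric split
  Cb <- C * scale
  Cl <- batch_tmm(setup$M, batch_mm(Cb, setup$M)) # fiber-frame components
  W <- strain_energy_components(setup$mat, Cl[, 1], Cl[, 5], Cl[, 9],
                                Cl[, 4], Cl[, 7], Cl[, 8])
  elast <- sum(setup$w * (W + setup$opt$kappa / 2 * (detF - 1)^2))
  if (!is.null(setup$clamp_ref)) {
    # family formulas extend smoothly below the deformed truncation angle,
    # so the reference psi labels are valid material coordinates here
    g <- profile_shape(geom$e, setup$psi_clamp)
    drho <- geom$R_b * g - setup$clamp_ref[, 1]
    dzeta <- geom$Z * (1 - sin(setup$psi_clamp)) - setup$clamp_ref[, 2]
    elast <- elast + setup$opt$clamp_k * sum(drho^2 + dzeta^2)
  }
  Vd <- tryCatch(cavity_volume(geom), error = function(e) NA_real_)
  if (!is.finite(Vd)) return(BIG_ENERGY)
  out <- elast - P * (Vd - setup$V_u) * 1000      # ml -> mm^3
  if (!is.finite(out)) return(BIG_ENERGY)         # exp overflow at extreme strain
  out
}

free_params <- function(geom) {
  c(geom$R_b, geom$e, geom$L, geom$H, geom$psi0)
}

solver_bounds <- function(xi_u) {
  lower <- c(0.6 * xi_u$R_b, max(0.02, xi_u$e - 0.35),
             0.2 * xi_u$L, 0.2 * xi_u$H,
             max(-87 * pi / 180, xi_u$psi0 - 30 * pi / 180))
  upper <- c(2.0 * xi_u$R_b, min(1, xi_u$e + 0.35),
             1.4 * xi_u$L, 1.4 * xi_u$H,
             min(-6 * pi / 180, xi_u$psi0 + 30 * pi / 180))
  list(lower = lower, upper = upper)
}

# single equilibrium solve at pressure P, warm-started from parameter vector x0
equilibrium_solve <- function(setup, P, x0) {
  b <- solver_bounds(setup$xi_u)
  x0 <- pmin(pmax(x0, b$lower + 1e-9), b$upper - 1e-9)
  parscale <- c(setup$xi_u$R_b / 10, 0.05, setup$xi_u$L / 10,
                setup$xi_u$H / 10, 0.03)
  fn <- function(x) ritz_energy(x, setup, P)
  res <- tryCatch(
    stats::optim(x0, fn, method = "L-BFGS-B",
                 lower = b$lower, upper = b$upper,
                 control = list(maxit = setup$opt$maxit,
                                factr = setup$opt$factr,
                                parscale = parscale)),
    error = function(e) list(par = x0, value = fn(x0), convergence = 53L))
  if (res$convergence != 0 && res$convergence != 52) {
    # line-search failures fall back to a simplex polish
    res2 <- stats::optim(res$par, fn, method = "Nelder-Mead",
                         control = list(maxit = 500,
                                        parscale = parscale,
                                        reltol = 1e-10))
    if (res2$value <= res$value) res <- res2
  }
  res
}

state_from_params <- function(setup, P, x) {
  geom <- candidate_geometry(x, setup$zeta_base)
  structure(list(
    pressure = P,
    xi_unloaded = setup$xi_u,
    xi_deformed = geom,
    lambda_ff_midwall = midwall_lambda(setup$xi_u, geom),
    cavity_vol = cavity_volume(geom),
    wall_vol = wall_volume(geom)),
    class = "lv_loaded_state")
}

#' @export
print.lv_loaded_state <- function(x, ...) {
  cat(sprintf(
    "Loaded state at P = %.2f kPa: cavity %.1f ml, wall %.1f ml, midwall lambda_ff %.4f\n",
    x$pressure, x$cavity_vol, x$wall_vol, x$lambda_ff_midwall))
  invisible(x)
}

#' Passive inflation of an unloaded geometry
#'
#' Quasi-static pressurization of the endocardial surface at pressure `P`,
#' solved by minimizing total potential energy over the shape family with the
#' basal plane height held fixed. The solver proceeds by continuation in
#' pressure increments of at most `options$dP` (default 0.25 kPa), each step
#' warm-started from the previous equilibrium.
#'
#' @param xi_u Unloaded `lv_geometry`.
#' @param mat A `material_model`.
#' @param P Intraventricular pressure, kPa (non-negative).
#' @param options Solver options overriding the defaults
#'   (n_psi = 12, n_t = 5 quadrature; kappa = 250 kPa volumetric penalty;
#'   dP = 0.25 kPa continuation step).
#' @return An `lv_loaded_state`: pressure, deformed geometry, midwall fiber
#'   stretch, cavity and wall volumes.
#' @export
inflate <- function(xi_u, mat, P, options = list()) {
  if (P < 0) stop("inflate: pressure must be non-negative")
  feas <- is_feasible(xi_u)
  if (!feas)
    stop(sprintf("inflate: infeasible geometry (%s): %s",
                 attr(feas, "reason"),
                 paste(sprintf("%.3g", as.numeric(xi_u)), collapse = " ")))
  setup <- inflation_setup(xi_u, mat, options)
  if (P == 0) return(state_from_params(setup, 0, free_params(xi_u)))
  x <- free_params(xi_u)
  steps <- pressure_steps(P, setup$opt$dP)
  for (p in steps) {
    res <- equilibrium_solve(setup, p, x)
    if (!is.finite(res$value) || res$value >= BIG_ENERGY / 2)
      stop(sprintf("inflate: solver failed at P = %.2f kPa for geometry %s",
                   p, paste(sprintf("%.3g", as.numeric(xi_u)), collapse = " ")))
    x <- res$par
  }
  state_from_params(setup, P, x)
}

pressure_steps <- function(P, dP) {
  n <- ceiling(P / dP - 1e-9)
  seq_len(n) * P / n
}

#' Pressure sweep producing an inflation trajectory
#'
#' Equilibria at P = dP, 2 dP, ..., P_max (defaults give exactly 100 loaded
#' configurations at 0.05 kPa increments up to 5 kPa), each warm-started
#' from the previous state.
#'
#' @inheritParams inflate
#' @param P_max Maximum pressure, kPa.
#' @param dP Pressure increment, kPa.
#' @return An `inflation_trajectory`: list with the unloaded geometry, the
#'   material, and a list of `lv_loaded_state`s at increasing pressure.
#' @export
inflation_sweep <- function(xi_u, mat, P_max = 5, dP = 0.05, options = list()) {
  if (dP <= 0) stop("inflation_sweep: dP must be positive")
  setup <- inflation_setup(xi_u, mat, options)
  pressures <- seq(dP, P_max + 1e-12, by = dP)
  x <- free_params(xi_u)
  states <- vector("list", length(pressures))
  for (i in seq_along(pressures)) {
    res <- equilibrium_solve(setup, pressures[i], x)
    if (!is.finite(res$value) || res$value >= BIG_ENERGY / 2)
      stop(sprintf("inflation_sweep: solver failed at P = %.2f kPa", pressures[i]))
    x <- res$par
    states[[i]] <- state_from_params(setup, pressures[i], x)
  }
  structure(list(unloaded = xi_u, material = mat, states = states),
            class = "inflation_trajectory")
}

#' @export
print.inflation_trajectory <- function(x, ...) {
  n <- length(x$states)
  cat(sprintf("Inflation trajectory (%s): %d states, P in [%.2f, %.2f] kPa\n",
              x$material$label, n, x$states[[1]]$pressure,
              x$states[[n]]$pressure))
  invisible(x)
}

#' Trajectory summary table
#'
#' @param traj An `inflation_trajectory`.
#' @return Data frame with one row per state: pressure, the six deformed
#'   parameters, midwall fiber stretch and volumes.
#' @export
trajectory_table <- function(traj) {
  do.call(rbind, lapply(traj$states, function(s) {
    v <- as.numeric(s$xi_deformed)
    data.frame(P = s$pressure, R_b = v[1], Z = v[2], L = v[3], H = v[4],
               e = v[5], psi0 = v[6], lambda_ff_midwall = s$lambda_ff_midwall,
               cavity_vol = s$cavity_vol, wall_vol = s$wall_vol)
  }))
}

#' Deformation gradient of the in-family map
#'
#' Gradient of the map taking the reference (unloaded) configuration to the
#' deformed configuration at matched material coordinates, from the analytic
#' chart Jacobians: F = J_d(q) J_u(q)^-1.
#'
#' @param xi_u,xi_d Reference and deformed `lv_geometry`.
#' @param psi,t,theta Material coordinates (vectors of common length).
#' @return For a single point a 3 x 3 matrix; otherwise an n x 3 x 3 array.
#' @export
deformation_gradient <- function(xi_u, xi_d, psi, t, theta = 0) {
  n <- max(length(psi), length(t), length(theta))
  psi <- rep_len(psi, n); t <- rep_len(t, n); theta <- rep_len(theta, n)
  Ju <- full_jacobian(xi_u, psi, t, theta)
  Jd <- full_jacobian(xi_d, psi, t, theta)
  F <- batch_mm(Jd, batch_inv(Ju))
  if (n == 1) return(matrix(F[1, ], 3, 3))
  out <- array(0, c(n, 3, 3))
  for (j in 1:3) for (i in 1:3) out[, i, j] <- F[, i + 3 * (j - 1)]
  out
}

full_jacobian <- function(geom, psi, t, theta) {
  J <- chart_jacobian(geom, psi, t, theta)
  cbind(J$j11, J$j21, J$j31, J$j12, J$j22, J$j32, J$j13, J$j23, J$j33)
}

#' Total potential energy of a candidate deformed configuration
#'
#' Ritz functional: strain energy (isochoric part plus volumetric penalty)
#' integrated over the reference wall, minus the pressure work done by the
#' cavity volume change.
#'
#' @inheritParams inflate
#' @param xi_d Candidate deformed `lv_geometry`.
#' @return Energy, mJ.
#' @export
potential_energy <- function(xi_u, xi_d, mat, P, options = list()) {
  setup <- inflation_setup(xi_u, mat, options)
  Jd <- full_jacobian(xi_d, setup$psi, setup$t, rep(0, length(setup$psi)))
  F <- batch_mm(Jd, setup$Ju_inv)
  detF <- batch_det(Jd) / setup$detJu
  if (any(detF <= 0)) return(Inf)
  C <- batch_tmm(F, F)
  Cb <- C * detF^(-2 / 3)
  Cl <- batch_tmm(setup$M, batch_mm(Cb, setup$M))
  W <- strain_energy_components(mat, Cl[, 1], Cl[, 5], Cl[, 9],
                                Cl[, 4], Cl[, 7], Cl[, 8])
  elast <- sum(setup$w * (W + setup$opt$kappa / 2 * (detF - 1)^2))
  (elast - P * (cavity_volume(xi_d) - setup$V_u) * 1000) / 1000
}

# midwall fiber stretch on a fixed evaluation lattice: t in the 40-60%
# thickness band, heights in the 45-55% apex-base band
midwall_lattice <- function(geom, n_long = 5, n_thick = 3) {
  t <- seq(0.42, 0.58, length.out = n_thick)
  frac <- seq(0.455, 0.545, length.out = n_long)
  zb <- basal_height(geom)
  out <- expand.grid(frac = frac, t = t)
  z_t <- geom$Z - geom$H + out$t * geom$H
  s <- 1 - (out$frac * zb - (1 - out$t) * geom$H) / z_t
  s <- pmin(1 - 1e-9, pmax(sin(geom$psi0) + 1e-9, s))
  data.frame(psi = asin(s), t = out$t)
}

midwall_lambda <- function(xi_u, xi_d) {
  lat <- midwall_lattice(xi_u)
  n <- nrow(lat)
  Ju <- full_jacobian(xi_u, lat$psi, lat$t, rep(0, n))
  Jd <- full_jacobian(xi_d, lat$psi, lat$t, rep(0, n))
  F <- batch_mm(Jd, batch_inv(Ju))
  C <- batch_tmm(F, F)
  fr <- fiber_frame(xi_u, lat$psi, lat$t, rep(0, n))
  f <- fr$f
  cf1 <- C[, 1] * f[, 1] + C[, 4] * f[, 2] + C[, 7] * f[, 3]
  cf2 <- C[, 2] * f[, 1] + C[, 5] * f[, 2] + C[, 8] * f[, 3]
  cf3 <- C[, 3] * f[, 1] + C[, 6] * f[, 2] + C[, 9] * f[, 3]
  mean(sqrt(f[, 1] * cf1 + f[, 2] * cf2 + f[, 3] * cf3))
}

#' Midwall fiber stretch of a loaded state
#'
#' Unweighted mean of \eqn{\sqrt{f \cdot C f}} over a midwall evaluation
#' lattice spanning 40-60% of the wall thickness and 45-55% of the
#' apex-base distance.
#'
#' @param state An `lv_loaded_state`.
#' @return Midwall fiber stretch, dimensionless.
#' @export
midwall_fiber_stretch <- function(state) {
  if (is.null(state$xi_deformed)) stop("midwall_fiber_stretch: no deformed geometry")
  midwall_lambda(state$xi_unloaded, state$xi_deformed)
}

#' Pressure at which a trajectory reaches a target midwall stretch
#'
#' Linear interpolation of pressure against midwall fiber stretch at the
#' first crossing of the target.
#'
#' @param traj An `inflation_trajectory`.
#' @param target Target midwall fiber stretch (>= 1).
#' @return Pressure, kPa (0 when `target` is 1).
#' @export
pressure_at_stretch <- function(traj, target) {
  if (target < 1) stop("pressure_at_stretch: target must be >= 1")
  if (target == 1) return(0)
  P <- vapply(traj$states, function(s) s$pressure, numeric(1))
  lam <- vapply(traj$states, function(s) s$lambda_ff_midwall, numeric(1))
  P <- c(0, P); lam <- c(1, lam)
  idx <- which(lam >= target)
  if (length(idx) == 0)
    stop(sprintf("pressure_at_stretch: stretch target %.3f unreachable by %.2f kPa",
                 target, max(P)))
  i <- idx[1]
  if (i == 1) return(P[1])
  P[i - 1] + (target - lam[i - 1]) / (lam[i] - lam[i - 1]) * (P[i] - P[i - 1])
}

#' Write / read an inflation trajectory as CSV
#'
#' @param traj An `inflation_trajectory`.
#' @param path CSV path.
#' @return The path (write) or the summary data frame (read).
#' @export
write_trajectory <- function(traj, path) {
  utils::write.csv(trajectory_table(traj), path, row.names = FALSE)
  invisible(path)
}
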