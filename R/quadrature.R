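#' Rule-based myofiber frame at a material point
#'
#' Local orthonormal frame (fiber f, sheet s, sheet-normal n) following the
#' rule-based helix-angle assignment: the fiber angle with respect to the
#' local circumferential direction varies linearly across the wall from
#' +90 degrees at the endocardium (longitudinally aligned) to -60 degrees at
#' the epicardium.
#'
#' @param geom An `lv_geometry`.
#' @param psi,t,theta Material coordinates (vectors of common length).
#' @return A list with n x 3 matrices `f`, `s`, `n` (unit vectors, canonical
#'   pose Cartesian components).
#' @export
fiber_frame <- function(geom, psi, t, theta) {
  n <- max(length(psi), length(t), length(theta))
  psi <- rep_len(psi, n); t <- rep_len(t, n); theta <- rep_len(theta, n)
  p <- chart_partials(geom, psi, t)
  ct <- cos(theta); st <- sin(theta)
  # tangent along increasing psi moves base -> apex; longitudinal = apex -> base
  dpsi <- cbind(p$rho_psi * ct, p$rho_psi * st, p$zeta_psi)
  norm_dpsi <- sqrt(rowSums(dpsi^2))
  # one-sided limit at the apex where the psi-tangent degenerates
  deg <- norm_dpsi < 1e-12
  if (any(deg)) {
    eps <- 1e-6
    pd <- chart_partials(geom, psi[deg] - eps, t[deg])
    dpsi[deg, ] <- cbind(pd$rho_psi * ct[deg], pd$rho_psi * st[deg], pd$zeta_psi)
    norm_dpsi[deg] <- sqrt(rowSums(dpsi[deg, , drop = FALSE]^2))
  }
  e_long <- -dpsi / norm_dpsi
  e_circ <- cbind(-st, ct, 0)
  alpha <- (90 - 150 * t) * pi / 180
  f <- cos(alpha) * e_circ + sin(alpha) * e_long
  # transmural (outward) direction, orthogonalized against f
  dt <- cbind(p$rho_t * ct, p$rho_t * st, p$zeta_t)
  s <- dt - rowSums(dt * f) * f
  s <- s / sqrt(rowSums(s^2))
  nvec <- cbind(f[, 2] * s[, 3] - f[, 3] * s[, 2],
                f[, 3] * s[, 1] - f[, 1] * s[, 3],
                f[, 1] * s[, 2] - f[, 2] * s[, 1])
  dimnames(f) <- dimnames(s) <- dimnames(nvec) <- NULL
  list(f = f, s = s, n = nvec)
}

#' Tensor-product quadrature grid over the LV wall
#'
#' Gauss-Legendre nodes in (psi, t) crossed with a uniform midpoint rule in
#' theta. Weights are reference-volume weights from the chart Jacobian and sum
#' to the wall volume.
#'
#' @param geom An `lv_geometry`.
#' @param n_psi,n_t,n_theta Node counts per direction (default 24 x 8 x 24).
#' @return An object of class `lv_quadrature`: list with `points` (data frame
#'   psi, t, theta, x, y, z, zeta_norm), `weights` (mm^3) and `frames`
#'   (list of f, s, n matrices), plus the generating geometry.
#' @export
lv_quadrature <- function(geom, n_psi = 24, n_t = 8, n_theta = 24) {
  gp <- gauss_rule(n_psi, geom$psi0, pi / 2)
  gt <- gauss_rule(n_t, 0, 1)
  th <- (seq_len(n_theta) - 0.5) * 2 * pi / n_theta
  wth <- rep(2 * pi / n_theta, n_theta)
  idx <- expand.grid(ip = seq_len(n_psi), it = seq_len(n_t), ith = seq_len(n_theta))
  psi <- gp$x[idx$ip]; t <- gt$x[idx$it]; theta <- th[idx$ith]
  w <- gp$w[idx$ip] * gt$w[idx$it] * wth[idx$ith]
  p <- chart_partials(geom, psi, t)
  det <- abs(p$rho * (p$rho_t * p$zeta_psi - p$rho_psi * p$zeta_t))
  weights <- w * det
  if (any(weights <= 0)) stop("lv_quadrature: non-positive weight (degenerate chart)")
  pos <- lv_point(geom, psi, t, theta)
  structure(list(
    geom = geom,
    points = data.frame(psi = psi, t = t, theta = theta,
                        x = pos[, 1], y = pos[, 2], z = pos[, 3],
                        zeta_norm = pos[, 3] / basal_height(geom)),
    weights = weights,
    frames = fiber_frame(geom, psi, t, theta)),
    class = "lv_quadrature")
}

#' Select quadrature points in a transmural/longitudinal band
#'
#' Used to define the "midwall" averaging region: by default points between
#' 40 and 60% of the wall thickness and between 45 and 55% of the apex-base
#' distance.
#'
#' @param grid An `lv_quadrature`.
#' @param thickness_range Transmural fraction range, subset of \[0, 1\].
#' @param longitudinal_range Normalized axial position range, subset of \[0, 1\].
#' @return Integer indices of the selected points.
#' @export
region_mask <- function(grid, thickness_range = c(0.4, 0.6),
                        longitudinal_range = c(0.45, 0.55)) {
  chk <- function(r, nm) {
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0 || r[2] > 1)
      stop(sprintf("region_mask: %s must be an increasing range within [0, 1]", nm))
  }
  chk(thickness_range, "thickness_range")
  chk(longitudinal_range, "longitudinal_range")
  pts <- grid$points
  sel <- which(pts$t >= thickness_range[1] & pts$t <= thickness_range[2] &
               pts$zeta_norm >= longitudinal_range[1] &
               pts$zeta_norm <= longitudinal_range[2])
  if (length(sel) == 0)
    stop("region_mask: empty selection; use a finer quadrature grid")
  sel
}
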