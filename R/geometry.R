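#' Six-parameter truncated prolate spheroid LV geometry
#'
#' Constructs the analytic axisymmetric left-ventricular shape used throughout
#' the package. The epicardial and endocardial boundaries are profiles of
#' revolution indexed by an angle \eqn{\psi \in [\psi_0, \pi/2]}:
#' \deqn{\rho_{epi} = R_b[e\cos\psi + (1-e)(1-\sin\psi)], \quad
#'       \zeta_{epi} = Z(1-\sin\psi),}
#' \deqn{\rho_{end} = (R_b-L)[e\cos\psi + (1-e)(1-\sin\psi)], \quad
#'       \zeta_{end} = (Z-H)(1-\sin\psi) + H.}
#' The canonical pose places the epicardial apex at the origin with the long
#' axis along +z; the base sits at height \eqn{\zeta_{base} = Z(1-\sin\psi_0)}.
#'
#' @param R_b Outer radius at the base, mm.
#' @param Z Longitudinal semi-axis of the outer spheroid, mm.
#' @param L Wall thickness at the base, mm.
#' @param H Wall thickness at the apex, mm.
#' @param e Sphericity/conicity parameter, dimensionless in \[0, 1\].
#' @param psi0 Truncation angle, radians in (-pi/2, pi/2). Negative for all
#'   ventricles considered here (the base lies above the equator).
#' @return An object of class `lv_geometry`.
#' @examples
#' g <- lv_geometry(R_b = 33, Z = 48, L = 8.4, H = 7.6, e = 0.76,
#'                  psi0 = -66 * pi / 180)
#' cavity_volume(g)
#' @export
lv_geometry <- function(R_b, Z, L, H, e, psi0) {
  vals <- c(R_b = R_b, Z = Z, L = L, H = H, e = e, psi0 = psi0)
  if (any(!is.finite(vals))) stop("lv_geometry: all parameters must be finite")
  if (!(R_b > L && L > 0)) stop("lv_geometry: requires R_b > L > 0")
  if (!(Z > H && H > 0)) stop("lv_geometry: requires Z > H > 0")
  if (e < 0 || e > 1) stop("lv_geometry: requires e in [0, 1]")
  if (psi0 <= -pi / 2 || psi0 >= pi / 2)
    stop("lv_geometry: requires psi0 in (-pi/2, pi/2)")
  structure(list(R_b = R_b, Z = Z, L = L, H = H, e = e, psi0 = psi0),
            class = "lv_geometry")
}

#' @export
print.lv_geometry <- function(x, ...) {
  cat(sprintf(
    "LV geometry: R_b=%.2f  Z=%.2f  L=%.2f  H=%.2f mm, e=%.3f, psi0=%.1f deg\n",
    x$R_b, x$Z, x$L, x$H, x$e, x$psi0 * 180 / pi))
  cat(sprintf("  cavity %.1f ml, wall %.1f ml, base height %.1f mm\n",
              cavity_volume(x), wall_volume(x), basal_height(x)))
  invisible(x)
}

#' @export
as.numeric.lv_geometry <- function(x, ...) {
  c(R_b = x$R_b, Z = x$Z, L = x$L, H = x$H, e = x$e, psi0 = x$psi0)
}

geometry_param_names <- function() c("R_b", "Z", "L", "H", "e", "psi0")

#' @rdname lv_geometry
#' @param v Named (or positional R_b, Z, L, H, e, psi0) numeric vector.
#' @export
lv_geometry_from_vector <- function(v) {
  nm <- geometry_param_names()
  if (!is.null(names(v)) && all(nm %in% names(v))) v <- v[nm]
  if (length(v) != 6L) stop("expected 6 geometry parameters")
  lv_geometry(v[[1]], v[[2]], v[[3]], v[[4]], v[[5]], v[[6]])
}

# profile shape factor g(psi) = e cos(psi) + (1 - e)(1 - sin(psi)); g(0) = 1
profile_shape <- function(e, psi) e * cos(psi) + (1 - e) * (1 - sin(psi))
profile_shape_d <- function(e, psi) -e * sin(psi) - (1 - e) * cos(psi)

#' Basal plane height of a geometry in canonical pose
#'
#' @param geom An `lv_geometry`.
#' @return Height of the basal plane above the apex, mm.
#' @export
basal_height <- function(geom) geom$Z * (1 - sin(geom$psi0))

# height at which the endocardial profile ends (psi = psi0)
endo_top_height <- function(geom)
  (geom$Z - geom$H) * (1 - sin(geom$psi0)) + geom$H

#' Evaluate the epicardial and endocardial profiles
#'
#' Returns the four profile coordinates at the requested angle(s).
#'
#' @param geom An `lv_geometry`.
#' @param psi Profile angle(s), radians in `[psi0, pi/2]`.
#' @return A data frame with columns `rho_epi`, `zeta_epi`, `rho_end`,
#'   `zeta_end` (mm), one row per angle.
#' @export
evaluate_profile <- function(geom, psi) {
  tol <- 1e-9
  if (any(psi < geom$psi0 - tol) || any(psi > pi / 2 + tol))
    stop("evaluate_profile: psi outside [psi0, pi/2]")
  g <- profile_shape(geom$e, psi)
  data.frame(
    rho_epi = geom$R_b * g,
    zeta_epi = geom$Z * (1 - sin(psi)),
    rho_end = (geom$R_b - geom$L) * g,
    zeta_end = (geom$Z - geom$H) * (1 - sin(psi)) + geom$H)
}

#' Material-coordinate chart of the LV wall
#'
#' Maps material coordinates (psi, t, theta) to 3-D positions in canonical
#' pose. The transmural chart is the linear blend of the endocardial (t = 0)
#' and epicardial (t = 1) profiles at equal psi.
#'
#' @param geom An `lv_geometry`.
#' @param psi,t,theta Material coordinates (vectors of common length or
#'   length 1): profile angle (radians), transmural fraction in \[0,1\],
#'   circumferential angle (radians).
#' @return An n x 3 matrix of positions, mm.
#' @export
lv_point <- function(geom, psi, t, theta) {
  tol <- 1e-9
  if (any(psi < geom$psi0 - tol) || any(psi > pi / 2 + tol))
    stop("lv_point: psi outside [psi0, pi/2]")
  if (any(t < -tol) || any(t > 1 + tol)) stop("lv_point: t outside [0, 1]")
  n <- max(length(psi), length(t), length(theta))
  psi <- rep_len(psi, n); t <- rep_len(t, n); theta <- rep_len(theta, n)
  g <- profile_shape(geom$e, psi)
  rho <- (geom$R_b - geom$L + t * geom$L) * g
  zeta <- (geom$Z - geom$H + t * geom$H) * (1 - sin(psi)) + (1 - t) * geom$H
  cbind(x = rho * cos(theta), y = rho * sin(theta), z = zeta)
}

# Chart partials at (psi, t, theta); returns list of length-n vectors.
# rho(psi,t) = (R_b - L + t L) g(psi); zeta = (Z - H + t H)(1 - sin psi) + (1-t) H
chart_partials <- function(geom, psi, t) {
  g <- profile_shape(geom$e, psi)
  gd <- profile_shape_d(geom$e, psi)
  r_t <- geom$R_b - geom$L + t * geom$L
  z_t <- geom$Z - geom$H + t * geom$H
  list(
    rho = r_t * g,
    zeta = z_t * (1 - sin(psi)) + (1 - t) * geom$H,
    rho_psi = r_t * gd,
    rho_t = geom$L * g,
    zeta_psi = -z_t * cos(psi),
    zeta_t = -geom$H * sin(psi))
}

# Full 3x3 chart Jacobian entries at (psi,t,theta), vectorized; returns a list
# of nine length-n vectors J[i][j] (columns d/dpsi, d/dt, d/dtheta) plus det.
chart_jacobian <- function(geom, psi, t, theta) {
  p <- chart_partials(geom, psi, t)
  ct <- cos(theta); st <- sin(theta)
  J <- list(
    j11 = p$rho_psi * ct, j12 = p$rho_t * ct, j13 = -p$rho * st,
    j21 = p$rho_psi * st, j22 = p$rho_t * st, j23 = p$rho * ct,
    j31 = p$zeta_psi,     j32 = p$zeta_t,     j33 = rep_len(0, length(p$rho)))
  J$det <- p$rho * (p$rho_t * p$zeta_psi - p$rho_psi * p$zeta_t)
  J
}

# 1-D Gauss-Legendre rule on [a, b]; reference nodes on [-1, 1] are cached
# per n because the rule is requested inside tight optimization loops
.gauss_cache <- new.env(parent = emptyenv())

gauss_rule <- function(n, a, b) {
  key <- as.character(n)
  ref <- .gauss_cache[[key]]
  if (is.null(ref)) {
    ref <- pracma::gaussLegendre(n, -1, 1)
    .gauss_cache[[key]] <- ref
  }
  list(x = (a + b) / 2 + (b - a) / 2 * ref$x, w = (b - a) / 2 * ref$w)
}

#' Cavity volume of the LV geometry
#'
#' Volume enclosed by the endocardial surface of revolution, closed at the
#' base by the straight truncation edge (the psi = psi0 coordinate line
#' between the endocardial and epicardial rims) and the flat basal plane.
#'
#' @param geom An `lv_geometry`.
#' @param n_psi Number of Gauss-Legendre nodes for the profile integral.
#' @return Cavity volume, ml.
#' @export
cavity_volume <- function(geom, n_psi = 64) {
  # body of revolution: V = pi * int rho_end^2 dzeta, zeta = (Z-H)(1-sin psi)+H
  gl <- gauss_rule(n_psi, geom$psi0, pi / 2)
  g <- profile_shape(geom$e, gl$x)
  integrand <- pi * ((geom$R_b - geom$L) * g)^2 * (geom$Z - geom$H) * cos(gl$x)
  v_rev <- sum(gl$w * integrand)
  # basal closure: frustum between the endocardial rim (radius r1 at the endo
  # top height) and the epicardial rim (radius r2 at the basal plane)
  r1 <- (geom$R_b - geom$L) * profile_shape(geom$e, geom$psi0)
  r2 <- geom$R_b * profile_shape(geom$e, geom$psi0)
  dz <- basal_height(geom) - endo_top_height(geom)  # = -H sin(psi0) >= 0
  v_cap <- pi / 3 * dz * (r1^2 + r1 * r2 + r2^2)
  v <- (v_rev + v_cap) / 1000
  if (!is.finite(v) || v <= 0) stop("cavity_volume: infeasible geometry")
  v
}

#' Wall volume of the LV geometry
#'
#' Volume of the myocardial wall (region between the endocardial and
#' epicardial surfaces, including the solid apical cap), computed by
#' integrating the chart Jacobian.
#'
#' @param geom An `lv_geometry`.
#' @param n_psi,n_t Gauss-Legendre node counts in the psi and t directions.
#' @return Wall volume, ml.
#' @export
wall_volume <- function(geom, n_psi = 64, n_t = 16) {
  gp <- gauss_rule(n_psi, geom$psi0, pi / 2)
  gt <- gauss_rule(n_t, 0, 1)
  psi <- rep(gp$x, times = n_t)
  t <- rep(gt$x, each = n_psi)
  w <- rep(gp$w, times = n_t) * rep(gt$w, each = n_psi)
  p <- chart_partials(geom, psi, t)
  det <- abs(p$rho * (p$rho_t * p$zeta_psi - p$rho_psi * p$zeta_t))
  v <- 2 * pi * sum(w * det) / 1000
  if (!is.finite(v) || v <= 0) stop("wall_volume: infeasible geometry")
  v
}

# axial center of gravity (height above apex, mm) of cavity + wall region,
# by thin-slab integration of the classification used for voxelization
lv_centroid_height <- function(geom, n = 200) {
  zb <- basal_height(geom)
  gl <- gauss_rule(n, 0, zb)
  area <- vapply(gl$x, function(z) {
    r <- epi_radius_at_height(geom, z)
    pi * r^2
  }, numeric(1))
  sum(gl$w * gl$x * area) / sum(gl$w * area)
}

# epicardial radius at height zeta in [0, zeta_base]
epi_radius_at_height <- function(geom, zeta) {
  s <- pmin(1, pmax(sin(geom$psi0), 1 - zeta / geom$Z))
  geom$R_b * (geom$e * sqrt(pmax(0, 1 - s^2)) + (1 - geom$e) * (1 - s))
}

# cavity radius at height zeta (NA outside [H, zeta_base])
cavity_radius_at_height <- function(geom, zeta) {
  z_top <- endo_top_height(geom)
  zb <- basal_height(geom)
  out <- rep(NA_real_, length(zeta))
  lower <- zeta >= geom$H & zeta <= z_top
  if (any(lower)) {
    s <- pmin(1, pmax(sin(geom$psi0), 1 - (zeta[lower] - geom$H) / (geom$Z - geom$H)))
    out[lower] <- (geom$R_b - geom$L) *
      (geom$e * sqrt(pmax(0, 1 - s^2)) + (1 - geom$e) * (1 - s))
  }
  upper <- zeta > z_top & zeta <= zb
  if (any(upper) && zb > z_top) {
    r1 <- (geom$R_b - geom$L) * profile_shape(geom$e, geom$psi0)
    r2 <- geom$R_b * profile_shape(geom$e, geom$psi0)
    f <- (zeta[upper] - z_top) / (zb - z_top)
    out[upper] <- r1 + f * (r2 - r1)
  }
  out
}
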