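# Infarct parameterization on the idealized LV and a reduced active-cycle
# model mapping lesion geometry to stroke volume, emulated by kriging.

#' Infarct lesion descriptor
#'
#' Four normalized parameters place a lesion on the idealized LV wall:
#' longitudinal position `long_pos` (0 base, 1 apex), circumferential
#' extension `d_circ` (radians, up to pi), longitudinal extension fraction
#' `d_long`, and transmural `depth` (1 = fully transmural). Lesions grow
#' from the endocardium and are centered at theta = 0.
#'
#' @param long_pos,d_long,depth Fractions in \[0, 1\].
#' @param d_circ Radians in \[0, pi\].
#' @return An object of class `infarct_spec`.
#' @export
infarct_spec <- function(long_pos, d_circ, d_long, depth) {
  if (long_pos < 0 || long_pos > 1 || d_long < 0 || d_long > 1 ||
      depth < 0 || depth > 1 || d_circ < 0 || d_circ > pi)
    stop("infarct_spec: parameter out of range")
  structure(list(long_pos = long_pos, d_circ = d_circ, d_long = d_long,
                 depth = depth), class = "infarct_spec")
}

#' Lesion membership of material points
#'
#' A point (psi, t, theta) lies inside the lesion iff its normalized
#' longitudinal coordinate u = (psi - psi0)/(pi/2 - psi0) falls within
#' `long_pos +/- d_long/2`, its circumferential angle within
#' `+/- d_circ/2` of the lesion center (theta = 0), and its transmural
#' fraction within `[0, depth]`.
#'
#' @param geom An `lv_geometry`.
#' @param spec An `infarct_spec`.
#' @param psi,t,theta Material coordinates (vectors).
#' @return Logical vector.
#' @export
lesion_membership <- function(geom, spec, psi, t, theta) {
  n <- max(length(psi), length(t), length(theta))
  psi <- rep_len(psi, n); t <- rep_len(t, n); theta <- rep_len(theta, n)
  u <- (psi - geom$psi0) / (pi / 2 - geom$psi0)
  th <- atan2(sin(theta), cos(theta))  # wrap to (-pi, pi]
  u >= spec$long_pos - spec$d_long / 2 & u <= spec$long_pos + spec$d_long / 2 &
    abs(th) <= spec$d_circ / 2 & t <= spec$depth
}

#' Infarct volume and wall-volume fraction
#'
#' The lesion membership is a box in material coordinates, so the integral
#' separates: the circumferential factor is exact (`d_circ`), and the
#' (psi, t) integral of the chart Jacobian runs over the exact lesion
#' sub-domain with Gauss-Legendre quadrature.
#'
#' @param geom An `lv_geometry`.
#' @param spec An `infarct_spec`.
#' @param n_psi,n_t Quadrature resolution over the lesion sub-domain.
#' @return List with `volume` (ml) and `fraction` (of wall volume).
#' @export
infarct_volume <- function(geom, spec, n_psi = 48, n_t = 16) {
  u_lo <- max(0, spec$long_pos - spec$d_long / 2)
  u_hi <- min(1, spec$long_pos + spec$d_long / 2)
  if (u_hi <= u_lo || spec$d_circ == 0 || spec$depth == 0)
    return(list(volume = 0, fraction = 0))
  span <- pi / 2 - geom$psi0
  gp <- gauss_rule(n_psi, geom$psi0 + u_lo * span, geom$psi0 + u_hi * span)
  gt <- gauss_rule(n_t, 0, spec$depth)
  psi <- rep(gp$x, times = n_t)
  t <- rep(gt$x, each = n_psi)
  w <- rep(gp$w, times = n_t) * rep(gt$w, each = n_psi)
  p <- chart_partials(geom, psi, t)
  det <- abs(p$rho * (p$rho_t * p$zeta_psi - p$rho_psi * p$zeta_t))
  vol <- spec$d_circ * sum(w * det) / 1000
  list(volume = vol, fraction = vol / wall_volume(geom))
}

#' Hemodynamic settings of the reduced cycle model
#'
#' @param EDP End-diastolic pressure, kPa.
#' @param P_ao Aortic (end-systolic ventricular) pressure, kPa.
#' @param E_min Residual end-systolic elastance of fully deactivated
#'   myocardium, kPa/ml; NA until calibrated.
#' @param E_max Maximal active elastance, kPa/ml; NA until calibrated.
#' @param V0 Elastance volume intercept, ml.
#' @return Named list.
#' @export
hemo_settings <- function(EDP = 1.5, P_ao = 12, E_min = NA, E_max = NA,
                          V0 = 10) {
  list(EDP = EDP, P_ao = P_ao, E_min = E_min, E_max = E_max, V0 = V0)
}

#' Calibrate the elastance bounds to stroke-volume anchors
#'
#' E_max is chosen so that the lesion-free ventricle ejects `SV_target` ml
#' from the end-diastolic volume produced by passive inflation to EDP.
#' E_min (the residual elastance when contraction is fully deactivated) is
#' then chosen so that the maximal lesion admitted by the design box (half
#' the wall: d_circ = pi, d_long = 1, depth = 1, infarct fraction 1/2)
#' ejects `SV_min_target` ml. The two anchors tie the reduced cycle model
#' to the healthy-baseline and worst-lesion stroke volumes.
#'
#' @param geom_unloaded Baseline unloaded `lv_geometry`.
#' @param mat A `material_model`.
#' @param hemo A [hemo_settings()] list.
#' @param SV_target Baseline (lesion-free) stroke volume, ml.
#' @param SV_min_target Stroke volume at the maximal in-box lesion, ml.
#' @param options Solver options.
#' @return The hemo list with `E_max`, `E_min` filled in and `EDV` attached.
#' @export
calibrate_elastance <- function(geom_unloaded, mat, hemo = hemo_settings(),
                                SV_target = 49, SV_min_target = 21,
                                options = list()) {
  edv <- inflate(geom_unloaded, mat, hemo$EDP, options)$cavity_vol
  esv_target <- edv - SV_target
  if (esv_target <= hemo$V0)
    stop("calibrate_elastance: target stroke volume exceeds available volume")
  hemo$E_max <- hemo$P_ao / (esv_target - hemo$V0)
  if (!is.finite(hemo$E_min)) {
    if (SV_min_target >= SV_target)
      stop("calibrate_elastance: SV_min_target must be below SV_target")
    e_half <- hemo$P_ao / (edv - SV_min_target - hemo$V0)
    hemo$E_min <- 2 * e_half - hemo$E_max
    if (hemo$E_min <= 0)
      stop("calibrate_elastance: stroke-volume anchors give negative E_min")
  }
  if (hemo$E_max <= hemo$E_min)
    stop("calibrate_elastance: calibrated E_max below E_min")
  hemo$EDV <- edv
  hemo
}

#' Simulate one cardiac cycle with a regional infarct
#'
#' Reduced time-varying-elastance cycle: EDV comes from passive inflation of
#' the unloaded geometry to EDP; contraction is scaled by the healthy
#' wall-volume fraction, so the effective maximal elastance is
#' `E_min + (E_max - E_min) * (1 - infarct_fraction)`; ESV follows from the
#' aortic pressure on the end-systolic elastance line, and SV = EDV - ESV.
#'
#' @param geom_unloaded Baseline unloaded `lv_geometry`.
#' @param mat A `material_model`.
#' @param spec An `infarct_spec` (or NULL for the lesion-free baseline).
#' @param hemo Calibrated [hemo_settings()] (with `E_max`; if `EDV` is
#'   attached the passive inflation is reused instead of recomputed).
#' @param n_pv Number of points sampled on the reported PV loop.
#' @param options Solver options.
#' @return An object of class `cycle_result`: EDV, ESV, SV (ml), lesion
#'   volume and fraction, effective elastance, and a PV-loop sample table.
#' @export
simulate_cycle <- function(geom_unloaded, mat, spec = NULL,
                           hemo = hemo_settings(), n_pv = 40,
                           options = list()) {
  if (!is.finite(hemo$E_max))
    stop("simulate_cycle: hemo$E_max not set; run calibrate_elastance()")
  edv <- if (!is.null(hemo$EDV)) hemo$EDV
         else inflate(geom_unloaded, mat, hemo$EDP, options)$cavity_vol
  les <- if (is.null(spec)) list(volume = 0, fraction = 0)
         else infarct_volume(geom_unloaded, spec)
  e_eff <- hemo$E_min + (hemo$E_max - hemo$E_min) * (1 - les$fraction)
  esv <- max(hemo$V0, hemo$V0 + hemo$P_ao / e_eff)
  sv <- edv - esv
  if (sv < 0) {
    warning("simulate_cycle: ESV exceeds EDV; stroke volume clamped at 0")
    sv <- 0
    esv <- edv
  }
  # PV loop for reporting: filling along the passive EDPVR (approximated by
  # an exponential through (V0, 0) and (EDV, EDP)), isovolumic legs, and
  # ejection at aortic pressure
  nq <- max(4, n_pv %/% 4)
  vfill <- seq(esv, edv, length.out = nq)
  k <- log(hemo$EDP / 0.01) / (edv - hemo$V0)
  pfill <- 0.01 * exp(k * (vfill - hemo$V0))
  pv <- rbind(
    data.frame(phase = "filling", volume = vfill, pressure = pfill),
    data.frame(phase = "isovolumic_contraction", volume = rep(edv, nq),
               pressure = seq(hemo$EDP, hemo$P_ao, length.out = nq)),
    data.frame(phase = "ejection", volume = seq(edv, esv, length.out = nq),
               pressure = rep(hemo$P_ao, nq)),
    data.frame(phase = "isovolumic_relaxation", volume = rep(esv, nq),
               pressure = seq(hemo$P_ao, pfill[1], length.out = nq)))
  structure(list(EDV = edv, ESV = esv, SV = sv,
                 infarct_volume = les$volume, infarct_fraction = les$fraction,
                 E_max_eff = e_eff, pv = pv, hemo = hemo),
            class = "cycle_result")
}

#' @export
print.cycle_result <- function(x, ...) {
  cat(sprintf("cycle_result: EDV %.1f, ESV %.1f, SV %.1f ml (lesion %.1f ml, %.1f%% of wall)\n",
              x$EDV, x$ESV, x$SV, x$infarct_volume, 100 * x$infarct_fraction))
  invisible(x)
}

#' The 4-D lesion parameter box
#'
#' @return List with named `lower` and `upper` bounds over
#'   (long_pos, d_circ, d_long, depth).
#' @export
infarct_box <- function() {
  list(lower = c(long_pos = 0, d_circ = 0, d_long = 0, depth = 0),
       upper = c(long_pos = 1, d_circ = pi, d_long = 1, depth = 1))
}

#' Run the infarct parametric study
#'
#' Uniform latin hypercube design over the 4-D lesion space (default
#' n = 40 = 10 x 4), one cycle simulation per lesion on a fixed baseline.
#'
#' @param baseline Unloaded baseline `lv_geometry` (default the packaged
#'   failing-LV fixture).
#' @param mat A `material_model` (default the Fung-type set).
#' @param n Number of lesions.
#' @param seed Integer seed for the design.
#' @param hemo Hemo settings; calibrated here when `E_max` is NA.
#' @param options Solver options.
#' @return Data frame: lesion parameters, infarct volume and fraction, EDV,
#'   ESV, SV; attributes `hemo`, `baseline`.
#' @export
run_infarct_study <- function(baseline = infarct_baseline(),
                              mat = material("usyk"), n = 40, seed = 1,
                              hemo = hemo_settings(), options = list()) {
  if (!is.finite(hemo$E_max))
    hemo <- calibrate_elastance(baseline, mat, hemo, options = options)
  X <- lhs_uniform(n, infarct_box(), seed = derive_seed(seed, "infarct-design"))
  rows <- lapply(seq_len(n), function(i) {
    spec <- infarct_spec(X[i, 1], X[i, 2], X[i, 3], X[i, 4])
    cy <- simulate_cycle(baseline, mat, spec, hemo, options = options)
    data.frame(long_pos = X[i, 1], d_circ = X[i, 2], d_long = X[i, 3],
               depth = X[i, 4], infarct_volume = cy$infarct_volume,
               infarct_fraction = cy$infarct_fraction,
               EDV = cy$EDV, ESV = cy$ESV, SV = cy$SV)
  })
  out <- do.call(rbind, rows)
  attr(out, "hemo") <- hemo
  attr(out, "baseline") <- baseline
  out
}

#' Train the stroke-volume emulator
#'
#' GP regression from the four lesion parameters to simulated SV.
#'
#' @param table Study table from [run_infarct_study()].
#' @param seed Integer seed.
#' @return A `gp_surrogate` with one output (SV, ml).
#' @export
train_sv_surrogate <- function(table, seed = 1) {
  if (nrow(table) < 5) stop("train_sv_surrogate: need at least 5 rows")
  X <- as.matrix(table[, c("long_pos", "d_circ", "d_long", "depth")])
  Y <- matrix(table$SV, ncol = 1, dimnames = list(NULL, "SV"))
  gp_surrogate(X, Y, seed = seed, metadata = list(response = "SV"))
}

#' 2-D slice map of emulated SV
#'
#' Evaluates the emulator on a grid over two lesion axes, the other two held
#' at mid-range.
#'
#' @param gp SV `gp_surrogate`.
#' @param axes Character pair among long_pos, d_circ, d_long, depth.
#' @param n_grid Grid resolution per axis.
#' @return Data frame with the two axis coordinates and `SV`.
#' @export
slice_map <- function(gp, axes, n_grid = 25) {
  box <- infarct_box()
  nm <- names(box$lower)
  axes <- match.arg(axes, nm, several.ok = TRUE)
  if (length(axes) != 2 || axes[1] == axes[2])
    stop("slice_map: give two distinct axes")
  mid <- (box$lower + box$upper) / 2
  g1 <- seq(box$lower[axes[1]], box$upper[axes[1]], length.out = n_grid)
  g2 <- seq(box$lower[axes[2]], box$upper[axes[2]], length.out = n_grid)
  gr <- expand.grid(a = g1, b = g2)
  X <- matrix(rep(mid, each = nrow(gr)), nrow = nrow(gr),
              dimnames = list(NULL, nm))
  X[, axes[1]] <- gr$a; X[, axes[2]] <- gr$b
  pr <- gp_surrogate_predict(gp, X)
  out <- data.frame(gr$a, gr$b, SV = drop(pr$mean))
  names(out)[1:2] <- axes
  out
}

#' Cross-validated accuracy of the SV emulator
#'
#' Seeded shuffled k-fold cross-validation; per-row relative error
#' |SV_pred - SV_sim| / SV_sim, reported as mean percent.
#'
#' @param table Study table from [run_infarct_study()].
#' @param k Number of folds.
#' @param seed Integer seed for the shuffle.
#' @return Mean relative SV error, percent, with per-fold errors as
#'   attribute `"folds"`.
#' @export
kfold_cv <- function(table, k = 5, seed = 1) {
  n <- nrow(table)
  if (n < k) stop("kfold_cv: fewer rows than folds")
  keep <- table$SV != 0
  if (any(!keep)) {
    warning(sprintf("kfold_cv: excluding %d rows with zero simulated SV",
                    sum(!keep)))
    table <- table[keep, ]
    n <- nrow(table)
  }
  idx <- with_seed(derive_seed(seed, "cv-folds"), sample.int(n))
  folds <- split(idx, rep(seq_len(k), length.out = n))
  errs <- numeric(0)
  fold_means <- numeric(k)
  for (f in seq_len(k)) {
    test <- folds[[f]]
    train <- setdiff(idx, test)
    gp <- train_sv_surrogate(table[train, ], seed = derive_seed(seed, paste0("cv", f)))
    pr <- gp_surrogate_predict(
      gp, as.matrix(table[test, c("long_pos", "d_circ", "d_long", "depth")]))
    rel <- abs(drop(pr$mean) - table$SV[test]) / table$SV[test]
    errs <- c(errs, rel)
    fold_means[f] <- mean(rel)
  }
  structure(100 * mean(errs), folds = 100 * fold_means)
}
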