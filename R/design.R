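#' Population statistics of the geometry parameters
#'
#' Per-parameter mean and standard deviation computed from the packaged
#' population table (or any compatible table).
#'
#' @param phase Cardiac phase to use, default `"BoD"` (the reference state
#'   for the unloading design).
#' @param group Optional patient group; default pools the whole population.
#' @param table Optional replacement table with the [patient_table()] layout.
#' @return An object of class `population_stats`: list with named numeric
#'   vectors `mean` and `sd` over (R_b, Z, L, H, e, psi0).
#' @export
population_stats <- function(phase = "BoD", group = NULL, table = NULL) {
  tab <- if (is.null(table)) patient_table(phase = phase, group = group) else table
  nm <- geometry_param_names()
  m <- vapply(nm, function(p) mean(tab[[p]]), numeric(1))
  s <- vapply(nm, function(p) stats::sd(tab[[p]]), numeric(1))
  if (any(s <= 0)) stop("population_stats: zero-variance parameter")
  structure(list(mean = m, sd = s, phase = phase,
                 group = if (is.null(group)) "all" else group),
            class = "population_stats")
}

# hard physical bounds on individual parameters (radians for psi0); wall
# thicknesses are floored at 1 mm (sub-voxel walls are not meaningful
# against the imaging resolutions considered)
hard_bounds <- function() {
  list(lower = c(R_b = 1, Z = 1, L = 1, H = 1, e = 0,
                 psi0 = -88 * pi / 180),
       upper = c(R_b = Inf, Z = Inf, L = Inf, H = Inf, e = 1,
                 psi0 = -10 * pi / 180))
}

#' Parameter box for the unloading design
#'
#' Mean +/- `k_sd` standard deviations per parameter, intersected with hard
#' physical bounds (positive lengths, e in \[0,1\], psi0 in \[-88, -10\]
#' degrees, and minimum cavity semi-axes R_b - L >= 5 mm, Z - H >= 5 mm
#' enforced jointly at sampling/feasibility time).
#'
#' @param stats A `population_stats`.
#' @param k_sd Half-width of the box in standard deviations (default 3.5).
#' @return An object of class `parameter_box`: list with named vectors
#'   `lower`, `upper`.
#' @export
build_box <- function(stats, k_sd = 3.5) {
  hb <- hard_bounds()
  lower <- pmax(stats$mean - k_sd * stats$sd, hb$lower)
  upper <- pmin(stats$mean + k_sd * stats$sd, hb$upper)
  if (any(upper <= lower))
    stop("build_box: empty box after intersection with hard bounds")
  structure(list(lower = lower, upper = upper), class = "parameter_box")
}

# clip a parameter matrix (columns R_b, Z, L, H, e, psi0) into box and joint
# constraints (closest admissible point: per-parameter clip, then shrink L/H)
project_into_box <- function(X, box) {
  for (j in seq_along(box$lower)) {
    X[, j] <- pmin(pmax(X[, j], box$lower[j]), box$upper[j])
  }
  X[, "L"] <- pmin(X[, "L"], X[, "R_b"] - 5)
  X[, "H"] <- pmin(X[, "H"], X[, "Z"] - 5)
  X
}

#' Latin hypercube sample from the population normal model
#'
#' Stratified uniforms (one stratum per sample and dimension) mapped through
#' per-parameter normal quantiles centered on the population mean with the
#' standard deviation inflated by `sd_scale` (default doubled). Samples
#' falling outside the admissible box are projected onto the closest
#' admissible point.
#'
#' @param n Number of samples (the reference design uses 100 x 6 = 600).
#' @param stats A `population_stats`.
#' @param sd_scale Standard-deviation inflation factor (default 2).
#' @param box A `parameter_box` (default `build_box(stats)`).
#' @param seed Integer seed; the sample is reproducible given the seed.
#' @return List of `lv_geometry` of length `n`. The raw parameter matrix is
#'   attached as attribute `"params"`.
#' @export
lhs_normal <- function(n, stats, sd_scale = 2, box = build_box(stats), seed = 1) {
  stopifnot(n >= 1)
  u <- with_seed(seed, lhs::randomLHS(n, 6))
  nm <- geometry_param_names()
  X <- sapply(seq_along(nm), function(j)
    stats::qnorm(u[, j], mean = stats$mean[j], sd = sd_scale * stats$sd[j]))
  colnames(X) <- nm
  X <- project_into_box(X, box)
  geoms <- lapply(seq_len(n), function(i) lv_geometry_from_vector(X[i, ]))
  attr(geoms, "params") <- X
  geoms
}

#' Uniform latin hypercube sample on a box
#'
#' @param n Number of samples.
#' @param box A `parameter_box`, or any list with named `lower`/`upper`
#'   vectors (of any dimension).
#' @param seed Integer seed.
#' @return An n x d matrix of parameter vectors.
#' @export
lhs_uniform <- function(n, box, seed = 1) {
  stopifnot(n >= 1)
  d <- length(box$lower)
  u <- with_seed(seed, lhs::randomLHS(n, d))
  X <- sapply(seq_len(d), function(j)
    box$lower[j] + u[, j] * (box$upper[j] - box$lower[j]))
  X <- matrix(X, nrow = n)
  colnames(X) <- names(box$lower)
  X
}

#' Feasibility screen for a geometry
#'
#' A geometry is feasible when the hard bounds hold (positive lengths,
#' R_b - L >= 5 mm, Z - H >= 5 mm, e in \[0,1\], psi0 in \[-88, -10\] deg),
#' the endocardial radius stays above 1 mm over the basal-to-near-apical
#' profile (psi up to `apex_frac * pi/2`), and the cavity holds at least
#' 5 ml. Screens out the degenerate shapes that a thick wall plus a strongly
#' negative truncation angle can produce in small ventricles.
#'
#' @param geom An `lv_geometry` (or a named 6-vector).
#' @param apex_frac Fraction of pi/2 up to which the 1 mm endocardial-radius
#'   rule is enforced (default 0.85).
#' @param min_thickness Wall-thickness floor, mm. The default (1 mm) applies
#'   to reference/unloaded geometries; loaded states may thin below it.
#' @return Logical flag with attribute `"reason"` (string, `""` if feasible).
#' @export
is_feasible <- function(geom, apex_frac = 0.85, min_thickness = 1) {
  fail <- function(reason) structure(FALSE, reason = reason)
  if (!inherits(geom, "lv_geometry")) {
    geom <- tryCatch(lv_geometry_from_vector(geom),
                     error = function(e) NULL)
    if (is.null(geom)) return(fail("parameter bound violation"))
  }
  hb <- hard_bounds()
  hb$lower[c("L", "H")] <- min_thickness
  v <- as.numeric(geom)
  if (any(v < hb$lower - 1e-12) || any(v > hb$upper + 1e-12))
    return(fail("parameter bound violation"))
  if (geom$R_b - geom$L < 5) return(fail("cavity too small: R_b - L < 5 mm"))
  if (geom$Z - geom$H < 5) return(fail("cavity too small: Z - H < 5 mm"))
  psi <- seq(geom$psi0, apex_frac * pi / 2, length.out = 101)
  rho_end <- (geom$R_b - geom$L) * profile_shape(geom$e, psi)
  if (min(rho_end) <= 1) return(fail("cavity too small: endocardial radius < 1 mm"))
  if (cavity_volume(geom) < 5) return(fail("cavity too small: volume < 5 ml"))
  structure(TRUE, reason = "")
}

# evaluate an expression with a local RNG seed, restoring the global state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# derive a bounded sub-seed from a master seed and a stream label
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483629)
}
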