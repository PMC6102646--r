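# Inverse estimation of the unloaded (stress-free) configuration.

# residual scaling: 0.1 mm for lengths, 0.005 for e, 0.5 degrees for psi0
unload_tolerance <- function() {
  c(R_b = 0.1, Z = 0.1, L = 0.1, H = 0.1, e = 0.005, psi0 = 0.5 * pi / 180)
}

# Broyden (inverse, "good") update of the residual-map Jacobian inverse in
# scaled coordinates. The plain fixed-point update corresponds to H = -I;
# the quasi-Newton correction handles both slowly contracting and coupled
# oscillating residual modes that the plain update resolves only after many
# iterations.
broyden_step <- function(H, F_new, F_old, s) {
  dF <- F_new - F_old
  denom <- sum(s * (H %*% dF))
  if (is.finite(denom) && abs(denom) > 1e-10) {
    H <- H + tcrossprod(s - H %*% dF, s) %*% H / denom
  }
  H
}

# project an iterate into the feasible parameter region (transient Aitken
# overshoots are clipped rather than aborted)
project_iterate <- function(cand) {
  hb <- hard_bounds()
  lower <- pmax(hb$lower, c(6, 6, 0.6, 0.6, 0.02, -87.5 * pi / 180))
  upper <- pmin(hb$upper, c(Inf, Inf, Inf, Inf, 1, -10.5 * pi / 180))
  cand <- pmin(pmax(cand, lower), upper)
  cand["L"] <- min(cand["L"], cand["R_b"] - 5)
  cand["H"] <- min(cand["H"], cand["Z"] - 5)
  cand
}

#' Fixed-point (backward displacement) unloading
#'
#' Iterates \eqn{\xi_u^{k+1} = \xi_u^k + (\xi_{target} - G(\xi_u^k))} in the
#' six-parameter space, where G inflates a candidate unloaded shape to
#' pressure P, starting from \eqn{\xi_u^0 = \xi_{target}}. Converged when the
#' scaled parameter residual drops below 1 (0.1 mm for lengths, 0.005 for e,
#' 0.5 degrees for psi0, scaled by `tol`). Two numerical refinements are
#' layered on the plain scheme: equilibrium solves are warm-started from the
#' previous iterate's solution (falling back to full pressure continuations
#' if progress stalls), and the update is safeguarded quasi-Newton (Broyden)
#' in scaled coordinates, initialized at the plain update, which resolves
#' the slowly contracting and jointly oscillating residual modes of the
#' basal-plane-constrained forward map within a few iterations.
#'
#' @param xi_loaded Target loaded `lv_geometry`.
#' @param P Loading pressure, kPa.
#' @param mat A `material_model`.
#' @param tol Tolerance multiplier on the standard residual scales.
#' @param max_iter Iteration cap (error when exceeded).
#' @param options Solver options, see [inflate()].
#' @return List with `xi_unloaded`, `n_iterations`, `residual_history`
#'   (max scaled residual per iteration), and `xi_reloaded` (the forward
#'   inflation of the result, for round-trip checks).
#' @export
fixed_point_unload <- function(xi_loaded, P, mat, tol = 1, max_iter = 25,
                               options = list()) {
  feas <- is_feasible(xi_loaded, min_thickness = 0.3)
  if (!feas) stop(sprintf("fixed_point_unload: infeasible target (%s)",
                          attr(feas, "reason")))
  target <- as.numeric(xi_loaded)
  scales <- unload_tolerance() * tol
  cand <- target
  hist <- numeric(0)
  warm <- NULL
  warm_mode <- TRUE
  h0 <- 0.7   # initial under-relaxation of the plain update
  H <- -h0 * diag(6)
  prev_F <- NULL
  prev_s <- NULL
  cand_hist <- list(cand, cand, cand)
  for (k in seq_len(max_iter)) {
    geom <- tryCatch(lv_geometry_from_vector(cand), error = function(e) NULL)
    if (is.null(geom) || !is_feasible(geom, min_thickness = 0.3))
      stop(sprintf(
        "fixed_point_unload: infeasible iterate at iteration %d (residuals: %s)",
        k, paste(sprintf("%.3f", hist), collapse = " ")))
    # near convergence the equilibrium solves are tightened so that solver
    # hysteresis does not put a noise floor above the residual tolerance
    opts_k <- if (k >= 6) utils::modifyList(options, list(factr = 2e7))
              else options
    setup <- inflation_setup(geom, mat, opts_k)
    if (P == 0) {
      state <- state_from_params(setup, 0, free_params(geom))
    } else if (is.null(warm) || !warm_mode) {
      x <- free_params(geom)
      for (p in pressure_steps(P, setup$opt$dP)) {
        res <- equilibrium_solve(setup, p, x)
        x <- res$par
      }
      state <- state_from_params(setup, P, x)
      warm <- x
    } else {
      res <- equilibrium_solve(setup, P, warm)
      warm <- res$par
      state <- state_from_params(setup, P, warm)
    }
    deformed <- as.numeric(state$xi_deformed)
    F_new <- (target - deformed) / scales
    hist <- c(hist, max(abs(F_new)))
    if (hist[k] < 1) {
      return(list(xi_unloaded = geom, n_iterations = k,
                  residual_history = hist, xi_reloaded = state$xi_deformed))
    }
    # a stall needs both a flat residual and a candidate that stopped
    # moving (a saturated forward map can flatten the residual while the
    # iterate is still making progress toward the preimage)
    stalled <- k >= 4 && all(abs(diff(utils::tail(hist, 3))) < 0.05) &&
      max(abs(cand / scales - utils::tail(cand_hist, 3)[[1]] / scales)) < 0.5
    if (stalled) {
      if (warm_mode && P > 0) {
        # warm-started solves can track a different equilibrium branch on
        # hard cases; restart the quasi-Newton model on full continuations
        warm_mode <- FALSE
        H <- -h0 * diag(6)
        prev_F <- NULL
      } else {
        stop(sprintf(
          "fixed_point_unload: stalled at scaled residual %.2f (no feasible preimage; residuals: %s)",
          hist[k], paste(sprintf("%.2f", hist), collapse = " ")))
      }
    } else if (k >= 2 && hist[k] > 1.5 * hist[k - 1]) {
      # monotone safeguard: a marked residual increase means the
      # quasi-Newton model went bad; forget the accumulated curvature
      H <- -h0 * diag(6)
      prev_F <- NULL
    }
    if (!is.null(prev_F)) H <- broyden_step(H, F_new, prev_F, prev_s)
    s <- as.numeric(-H %*% F_new)
    smax <- max(abs(s))
    cap <- min(25, max(3, 5 * hist[k]))  # step trust region, scaled units
    if (smax > cap) s <- s * cap / smax
    newcand <- project_iterate(stats::setNames(cand + s * scales,
                                               geometry_param_names()))
    prev_s <- (newcand - cand) / scales
    prev_F <- F_new
    cand <- newcand
    cand_hist <- c(cand_hist[-1], list(cand))
  }
  stop(sprintf("fixed_point_unload: no convergence in %d iterations (residuals: %s)",
               max_iter, paste(sprintf("%.2f", hist), collapse = " ")))
}

#' Training sets for the unloading surrogate
#'
#' For each sampled unloaded geometry, runs the forward solver and records
#' (loaded parameters -> unloaded parameters) pairs. In pressure mode one
#' record per conditioning pressure is produced per geometry (a single
#' continuation visits all requested pressures). In stretch mode the
#' pressure at which the midwall fiber stretch reaches each target is
#' located on a sweep, and the record carries that pressure as an extra
#' output. Geometries that fail the feasibility screen or the solve are
#' dropped and logged.
#'
#' @param samples List of unloaded `lv_geometry`s.
#' @param mat A `material_model`.
#' @param pressures Conditioning pressures, kPa (pressure mode).
#' @param stretch_targets Midwall stretch targets, e.g. 1.10 (stretch mode).
#' @param P_max,dP Sweep settings used in stretch mode.
#' @param options Solver options.
#' @return Named list of `training_set` objects (one per conditioning
#'   value): data frame with loaded parameters (prefix `l_`), unloaded
#'   parameters (prefix `u_`), pressure, and attributes `material`, `mode`,
#'   `conditioning`, `log` (dropped-geometry messages).
#' @export
build_training_set <- function(samples, mat, pressures = NULL,
                               stretch_targets = NULL, P_max = 5, dP = 0.25,
                               options = list()) {
  if (is.null(pressures) == is.null(stretch_targets))
    stop("build_training_set: give exactly one of pressures / stretch_targets")
  mode <- if (is.null(pressures)) "stretch" else "pressure"
  cond <- if (mode == "pressure") sort(pressures) else sort(stretch_targets)
  rows <- stats::setNames(vector("list", length(cond)), as.character(cond))
  log <- character(0)
  nm <- geometry_param_names()
  for (i in seq_along(samples)) {
    g <- samples[[i]]
    feas <- is_feasible(g)
    if (!feas) {
      log <- c(log, sprintf("sample %d dropped: %s", i, attr(feas, "reason")))
      next
    }
    res <- tryCatch({
      if (mode == "pressure") {
        setup <- inflation_setup(g, mat, options)
        x <- free_params(g)
        p_prev <- 0
        out <- list()
        for (j in seq_along(cond)) {
          for (p in p_prev + pressure_steps(cond[j] - p_prev, setup$opt$dP)) {
            sol <- equilibrium_solve(setup, p, x)
            x <- sol$par
          }
          p_prev <- cond[j]
          st <- state_from_params(setup, cond[j], x)
          out[[j]] <- list(loaded = as.numeric(st$xi_deformed), P = cond[j],
                           lambda = st$lambda_ff_midwall)
        }
        out
      } else {
        traj <- inflation_sweep(g, mat, P_max = P_max, dP = dP,
                                options = options)
        lapply(cond, function(l_star) {
          Pstar <- pressure_at_stretch(traj, l_star)
          setup <- inflation_setup(g, mat, options)
          x <- free_params(g)
          for (p in pressure_steps(Pstar, setup$opt$dP)) {
            sol <- equilibrium_solve(setup, p, x)
            x <- sol$par
          }
          st <- state_from_params(setup, Pstar, x)
          list(loaded = as.numeric(st$xi_deformed), P = Pstar,
               lambda = st$lambda_ff_midwall)
        })
      }
    }, error = function(e) {
      log <<- c(log, sprintf("sample %d dropped: %s", i, conditionMessage(e)))
      NULL
    })
    if (is.null(res)) next
    for (j in seq_along(cond)) {
      rec <- res[[j]]
      row <- as.data.frame(as.list(c(
        stats::setNames(rec$loaded, paste0("l_", nm)),
        stats::setNames(as.numeric(g), paste0("u_", nm)),
        P = rec$P, lambda = rec$lambda)))
      rows[[j]] <- c(rows[[j]], list(row))
    }
  }
  if (all(vapply(rows, length, 1L) == 0))
    stop("build_training_set: all samples failed")
  out <- lapply(seq_along(cond), function(j) {
    df <- do.call(rbind, rows[[j]])
    structure(df, material = mat$label, mode = mode,
              conditioning = cond[j], log = log, class = c("training_set",
                                                           class(df)))
  })
  stats::setNames(out, as.character(cond))
}

#' Train GP unloading surrogates
#'
#' One multi-output surrogate per training set: inputs are the six loaded
#' parameters; outputs are the six unloaded parameters, plus the located
#' pressure in stretch mode (so end-diastolic pressure is predicted jointly
#' with the unloaded shape).
#'
#' @param training_sets A list of `training_set`s (from
#'   [build_training_set()]) or a single one.
#' @param seed Integer seed for hyperparameter restarts.
#' @return An object of class `unloader`: list of `gp_surrogate`s keyed by
#'   conditioning value.
#' @export
train_unloader <- function(training_sets, seed = 1) {
  if (inherits(training_sets, "training_set"))
    training_sets <- list(training_sets)
  nm <- geometry_param_names()
  models <- lapply(training_sets, function(ts) {
    X <- as.matrix(ts[, paste0("l_", nm)])
    Y <- as.matrix(ts[, paste0("u_", nm)])
    colnames(X) <- nm; colnames(Y) <- nm
    mode <- attr(ts, "mode")
    if (mode == "stretch") Y <- cbind(Y, P = ts$P)
    gp_surrogate(X, Y, seed = derive_seed(seed, format(attr(ts, "conditioning"))),
                 metadata = list(material = attr(ts, "material"),
                                 mode = mode,
                                 conditioning = attr(ts, "conditioning")))
  })
  structure(models, class = "unloader")
}

find_model <- function(unloader, conditioning, tol = 0.025) {
  conds <- vapply(unloader, function(m) m$metadata$conditioning, numeric(1))
  i <- which.min(abs(conds - conditioning))
  if (abs(conds[i] - conditioning) > tol)
    stop(sprintf("predict_unloaded: no trained model within %.3f of conditioning %.3f",
                 tol, conditioning))
  unloader[[i]]
}

#' Predict an unloaded configuration with a trained surrogate
#'
#' @param unloader An `unloader` (or a single `gp_surrogate`).
#' @param xi_loaded Loaded `lv_geometry`.
#' @param conditioning Conditioning value (pressure in kPa, or stretch
#'   target); the nearest trained model within 0.025 is used.
#' @return List with `xi_unloaded` (`lv_geometry`), `sd` (per-output
#'   predictive sd), `pressure` (stretch mode only), `extrapolation` flag.
#' @export
predict_unloaded <- function(unloader, xi_loaded, conditioning) {
  model <- if (inherits(unloader, "gp_surrogate")) unloader
           else find_model(unloader, conditioning)
  pr <- gp_surrogate_predict(model, as.numeric(xi_loaded))
  mu <- drop(pr$mean)
  geom <- lv_geometry_from_vector(pmin(pmax(
    mu[geometry_param_names()],
    c(5, 5, 0.5, 0.5, 0.01, -87 * pi / 180)),
    c(Inf, Inf, Inf, Inf, 1, -6 * pi / 180)))
  out <- list(xi_unloaded = geom, sd = drop(pr$sd),
              extrapolation = pr$extrapolation[1])
  if (model$metadata$mode == "stretch") out$pressure <- unname(mu["P"])
  out
}

#' Compare surrogate and fixed-point unloading on a cohort
#'
#' For each loaded geometry in the cohort, computes the unloaded shape by
#' fixed-point iteration (the oracle) and by the GP surrogate, and reports
#' the wall Dice score between the two, together with the Dice between the
#' loaded configuration itself and the fixed-point result (the error made
#' when an imaged configuration is used in place of the unloaded state).
#'
#' @param cohort List of loaded `lv_geometry`s.
#' @param unloader An `unloader` or `gp_surrogate`.
#' @param P Unloading pressure, kPa.
#' @param mat A `material_model`.
#' @param spacing Dice voxel spacing, mm.
#' @param options Solver options.
#' @return List with `table` (per-case Dice scores and fixed-point iteration
#'   counts) and `summary` (mean, 10th percentile, min of the GP Dice).
#' @export
evaluate_against_fixed_point <- function(cohort, unloader, P, mat,
                                         spacing = 1, options = list()) {
  rows <- lapply(seq_along(cohort), function(i) {
    fp <- fixed_point_unload(cohort[[i]], P, mat, options = options)
    gp_res <- predict_unloaded(unloader, cohort[[i]], P)
    data.frame(
      case = i,
      dice_gp = dice_score(gp_res$xi_unloaded, fp$xi_unloaded, spacing),
      dice_loaded = dice_score(cohort[[i]], fp$xi_unloaded, spacing),
      n_iter_fpi = fp$n_iterations)
  })
  tab <- do.call(rbind, rows)
  list(table = tab,
       summary = c(mean = mean(tab$dice_gp),
                   p10 = unname(stats::quantile(tab$dice_gp, 0.1)),
                   min = min(tab$dice_gp)))
}

#' Surrogate-versus-oracle unloading study
#'
#' Runs the full desk-scale comparison: samples training and test unloaded
#' geometries from the population normal model by latin hypercube, builds
#' per-pressure training sets with the forward solver for each requested
#' material, trains GP surrogates, and then for every test case inflates the
#' test geometry to each conditioning pressure to produce a loaded target,
#' unloads that target by fixed-point iteration (the oracle) and by the GP
#' surrogate, and reports the wall Dice score between the two unloaded
#' shapes. Because the targets are forward inflations, every test case is an
#' attainable loaded state (arbitrary parameter vectors need not be: the
#' reduced forward map does not reach all of the six-parameter box, just as
#' a fraction of full-order simulations cannot be completed). Samples
#' failing the feasibility screen or the solve are dropped and logged.
#'
#' @param n_train Number of (feasible) training geometries; drawn from the
#'   conservative doubled-standard-deviation design.
#' @param n_test Number of completed test cases required. Test geometries
#'   are drawn at population scale (`test_sd_scale`): the surrogate is
#'   trained on the deliberately wide design but evaluated on
#'   population-like ventricles, mirroring the use of imaged patient
#'   configurations as test cases.
#' @param pressures Conditioning pressures, kPa.
#' @param materials List of `material_model`s (default all three packaged
#'   sets).
#' @param stats Population statistics (default pooled BoD).
#' @param test_sd_scale Standard-deviation scale of the test draw
#'   (default 1).
#' @param seed Integer master seed.
#' @param spacing Dice voxel spacing, mm.
#' @param options Solver options.
#' @return List with `table` (case, material, pressure, dice_gp =
#'   surrogate vs oracle, dice_truth = surrogate vs the true unloaded
#'   sample, dice_loaded = loaded target vs oracle, n_iter_fpi),
#'   `summary` (min/mean/p10 of dice_gp and max fixed-point iterations),
#'   `unloaders`, and `log`.
#' @export
unloading_study <- function(n_train = 75, n_test = 15, pressures = c(1, 2),
                            materials = material(), stats = population_stats("BoD"),
                            test_sd_scale = 1, seed = 1, spacing = 1,
                            options = list()) {
  train <- lhs_normal(ceiling(1.5 * n_train), stats,
                      seed = derive_seed(seed, "train"))
  train <- Filter(function(g) isTRUE(as.logical(is_feasible(g))), train)
  if (length(train) < n_train)
    warning(sprintf("unloading_study: only %d feasible training geometries",
                    length(train)))
  train <- train[seq_len(min(n_train, length(train)))]
  pool <- lhs_normal(2 * n_test, stats, sd_scale = test_sd_scale,
                     seed = derive_seed(seed, "test"))
  pool <- Filter(function(g) isTRUE(as.logical(is_feasible(g))), pool)
  unloaders <- list()
  log <- character(0)
  for (mi in seq_along(materials)) {
    mat <- materials[[mi]]
    ts <- build_training_set(train, mat, pressures = pressures,
                             options = options)
    log <- c(log, attr(ts[[1]], "log"))
    unloaders[[mat$label]] <- train_unloader(
      ts, seed = derive_seed(seed, paste0("gp-", mat$label)))
  }
  rows <- list()
  completed <- 0
  for (ci in seq_along(pool)) {
    if (completed >= n_test) break
    g <- pool[[ci]]
    case_rows <- list()
    ok <- TRUE
    for (mi in seq_along(materials)) {
      mat <- materials[[mi]]
      res <- tryCatch({
        targets <- build_training_set(list(g), mat, pressures = pressures,
                                      options = options)
        nm <- geometry_param_names()
        lapply(seq_along(pressures), function(pi) {
          P <- pressures[pi]
          tgt_row <- targets[[as.character(P)]]
          if (is.null(tgt_row) || nrow(tgt_row) == 0)
            stop("forward inflation failed")
          target <- lv_geometry_from_vector(
            stats::setNames(as.numeric(tgt_row[1, paste0("l_", nm)]), nm))
          fp <- fixed_point_unload(target, P, mat, options = options)
          pred <- predict_unloaded(unloaders[[mat$label]], target, P)
          data.frame(
            case = ci, material = mat$label, pressure = P,
            dice_gp = dice_score(pred$xi_unloaded, fp$xi_unloaded, spacing),
            dice_truth = dice_score(pred$xi_unloaded, g, spacing),
            dice_loaded = dice_score(target, fp$xi_unloaded, spacing),
            n_iter_fpi = fp$n_iterations)
        })
      }, error = function(e) e)
      if (inherits(res, "error")) {
        log <- c(log, sprintf("test candidate %d dropped (%s): %s",
                              ci, mat$label, conditionMessage(res)))
        ok <- FALSE
        break
      }
      case_rows <- c(case_rows, res)
    }
    if (ok) {
      completed <- completed + 1
      rows <- c(rows, case_rows)
    }
  }
  if (completed < n_test)
    warning(sprintf("unloading_study: only %d of %d test cases completed",
                    completed, n_test))
  tab <- do.call(rbind, rows)
  list(table = tab,
       summary = c(min = min(tab$dice_gp), mean = mean(tab$dice_gp),
                   p10 = unname(stats::quantile(tab$dice_gp, 0.1)),
                   max_iter_fpi = max(tab$n_iter_fpi)),
       unloaders = unloaders, log = log)
}

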