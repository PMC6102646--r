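# Gaussian-process (kriging) regression with an anisotropic squared
# exponential kernel plus a nugget, fitted by maximizing the log marginal
# likelihood (exact Cholesky, analytic gradients, seeded multi-start).

sq_dists_per_dim <- function(X) {
  lapply(seq_len(ncol(X)), function(j) outer(X[, j], X[, j], "-")^2)
}

gp_nll_grad <- function(theta, D2, y, n) {
  d <- length(D2)
  ell2 <- exp(2 * theta[seq_len(d)])
  sf2 <- exp(2 * theta[d + 1])
  sn2 <- exp(2 * theta[d + 2])
  S <- Reduce(`+`, Map(function(D, l2) D / l2, D2, as.list(ell2)))
  Kse <- sf2 * exp(-0.5 * S)
  K <- Kse + diag(sn2 + 1e-10, n)
  Lc <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(Lc)) return(list(value = 1e10, grad = rep(0, d + 2)))
  alpha <- backsolve(Lc, forwardsolve(t(Lc), y))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(Lc))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(Lc)
  A <- Kinv - tcrossprod(alpha)
  g <- numeric(d + 2)
  for (j in seq_len(d)) g[j] <- 0.5 * sum(A * (Kse * D2[[j]] / ell2[j]))
  g[d + 1] <- sum(A * Kse)
  g[d + 2] <- sn2 * sum(diag(A))
  list(value = nll, grad = g)
}

#' Fit a Gaussian-process regression
#'
#' Single-output GP with anisotropic squared-exponential kernel
#' \eqn{k(x, x') = \sigma_f^2 \exp(-\frac12 \sum_j (x_j - x_j')^2/\ell_j^2)
#' + \sigma_n^2 \delta}. Inputs and output are standardized internally;
#' hyperparameters maximize the log marginal likelihood from several seeded
#' starting points.
#'
#' @param X Numeric input matrix (n x d).
#' @param y Numeric response (length n).
#' @param seed Integer seed for the restart draws.
#' @param n_restarts Number of additional random restarts (default 5).
#' @return An object of class `gp_model`.
#' @export
gp_fit <- function(X, y, seed = 1, n_restarts = 5) {
  X <- as.matrix(X)
  n <- nrow(X); d <- ncol(X)
  if (n < 2) stop("gp_fit: need at least 2 training points")
  x_mean <- colMeans(X)
  x_sd <- apply(X, 2, stats::sd); x_sd[x_sd < 1e-12] <- 1
  Xs <- sweep(sweep(X, 2, x_mean), 2, x_sd, "/")
  y_mean <- mean(y)
  y_sd <- stats::sd(y)
  if (!is.finite(y_sd) || y_sd < 1e-12) {
    # degenerate (constant) target: constant predictor
    warning("gp_fit: zero-variance target; using constant predictor")
    return(structure(list(constant = y_mean, x_mean = x_mean, x_sd = x_sd,
                          y_mean = y_mean, y_sd = 1, d = d),
                     class = "gp_model"))
  }
  ys <- (y - y_mean) / y_sd
  D2 <- sq_dists_per_dim(Xs)
  lower <- c(rep(log(0.05), d), log(1e-3), log(1e-4))
  upper <- c(rep(log(30), d), log(30), log(1))
  starts <- with_seed(seed, {
    s0 <- c(rep(0, d), 0, log(0.05))
    more <- replicate(n_restarts, c(stats::rnorm(d, 0, 0.7),
                                    stats::rnorm(1, 0, 0.3),
                                    log(0.05) + stats::rnorm(1, 0, 1)),
                      simplify = FALSE)
    c(list(s0), more)
  })
  best <- NULL
  for (s in starts) {
    res <- stats::optim(pmin(pmax(s, lower), upper),
                        fn = function(th) gp_nll_grad(th, D2, ys, n)$value,
                        gr = function(th) gp_nll_grad(th, D2, ys, n)$grad,
                        method = "L-BFGS-B", lower = lower, upper = upper,
                        control = list(maxit = 150))
    if (is.null(best) || res$value < best$value) best <- res
  }
  theta <- best$par
  ell2 <- exp(2 * theta[seq_len(d)])
  sf2 <- exp(2 * theta[d + 1]); sn2 <- exp(2 * theta[d + 2])
  S <- Reduce(`+`, Map(function(D, l2) D / l2, D2, as.list(ell2)))
  K <- sf2 * exp(-0.5 * S) + diag(sn2 + 1e-10, n)
  Lc <- chol(K)
  alpha <- backsolve(Lc, forwardsolve(t(Lc), ys))
  structure(list(Xs = Xs, alpha = alpha, L = Lc, theta = theta,
                 ell2 = ell2, sf2 = sf2, sn2 = sn2,
                 x_mean = x_mean, x_sd = x_sd, y_mean = y_mean, y_sd = y_sd,
                 nll = best$value, d = d),
            class = "gp_model")
}

#' Predict from a fitted Gaussian process
#'
#' @param gp A `gp_model`.
#' @param Xnew New inputs (m x d matrix or length-d vector).
#' @return List with `mean` and `sd` (predictive standard deviation of the
#'   latent function plus noise), both length m, on the original scale.
#' @export
gp_predict <- function(gp, Xnew) {
  Xnew <- if (is.null(dim(Xnew))) matrix(Xnew, nrow = 1) else as.matrix(Xnew)
  if (!is.null(gp$constant))
    return(list(mean = rep(gp$constant, nrow(Xnew)), sd = rep(0, nrow(Xnew))))
  Xs <- sweep(sweep(Xnew, 2, gp$x_mean), 2, gp$x_sd, "/")
  m <- nrow(Xs); n <- nrow(gp$Xs)
  S <- matrix(0, n, m)
  for (j in seq_len(gp$d))
    S <- S + outer(gp$Xs[, j], Xs[, j], "-")^2 / gp$ell2[j]
  Kx <- gp$sf2 * exp(-0.5 * S)
  mu <- drop(crossprod(Kx, gp$alpha))
  v <- forwardsolve(t(gp$L), Kx)
  var_lat <- pmax(0, gp$sf2 - colSums(v^2))
  list(mean = gp$y_mean + gp$y_sd * mu,
       sd = gp$y_sd * sqrt(var_lat + gp$sn2))
}

#' Multi-output GP surrogate (independent GP per output)
#'
#' @param X Input matrix (n x d).
#' @param Y Output matrix (n x q).
#' @param seed Integer seed (one derived sub-seed per output).
#' @param metadata Optional named list stored with the surrogate (e.g.
#'   material tag, conditioning pressure or stretch target).
#' @return An object of class `gp_surrogate`.
#' @export
gp_surrogate <- function(X, Y, seed = 1, metadata = list()) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  models <- lapply(seq_len(ncol(Y)), function(j)
    gp_fit(X, Y[, j], seed = derive_seed(seed, paste0("out", j))))
  structure(list(models = models, input_names = colnames(X),
                 output_names = colnames(Y), X = X, Y = Y,
                 metadata = metadata, seed = seed,
                 x_lower = apply(X, 2, min), x_upper = apply(X, 2, max)),
            class = "gp_surrogate")
}

#' @export
print.gp_surrogate <- function(x, ...) {
  cat(sprintf("gp_surrogate: %d -> %d, n_train = %d\n",
              ncol(x$X), length(x$models), nrow(x$X)))
  if (length(x$metadata))
    cat("  ", paste(sprintf("%s=%s", names(x$metadata),
                            vapply(x$metadata, format, "")), collapse = "  "), "\n")
  invisible(x)
}

#' Predict all outputs of a surrogate
#'
#' @param gp A `gp_surrogate`.
#' @param Xnew New inputs (m x d or length-d vector).
#' @param extrapolation_factor Inputs outside the training box inflated by
#'   this factor raise a warning flag.
#' @return List with matrices `mean` and `sd` (m x q) and logical
#'   `extrapolation`.
#' @export
gp_surrogate_predict <- function(gp, Xnew, extrapolation_factor = 1.5) {
  Xnew <- if (is.null(dim(Xnew))) matrix(Xnew, nrow = 1) else as.matrix(Xnew)
  preds <- lapply(gp$models, gp_predict, Xnew = Xnew)
  ctr <- (gp$x_lower + gp$x_upper) / 2
  half <- pmax((gp$x_upper - gp$x_lower) / 2, 1e-9)
  extra <- apply(Xnew, 1, function(r)
    any(abs(r - ctr) > extrapolation_factor * half))
  if (any(extra)) warning("gp_surrogate_predict: input outside 1.5x training box (extrapolation)")
  list(mean = sapply(preds, `[[`, "mean") |> matrix(nrow = nrow(Xnew),
         dimnames = list(NULL, gp$output_names)),
       sd = sapply(preds, `[[`, "sd") |> matrix(nrow = nrow(Xnew),
         dimnames = list(NULL, gp$output_names)),
       extrapolation = extra)
}

#' Save / load a surrogate as a self-describing JSON bundle
#'
#' The bundle stores training arrays, kernel hyperparameters,
#' standardization statistics, seed and metadata; `load_gp` refits the
#' cached Cholesky factors from the stored hyperparameters (deterministic).
#'
#' @param gp A `gp_surrogate`.
#' @param path JSON file path.
#' @return `save_gp` the path; `load_gp` a `gp_surrogate`.
#' @export
save_gp <- function(gp, path) {
  bundle <- list(
    input_names = gp$input_names, output_names = gp$output_names,
    X = gp$X, Y = gp$Y, seed = gp$seed, metadata = gp$metadata,
    theta = lapply(gp$models, function(m)
      if (!is.null(m$constant)) list(constant = m$constant) else
        list(theta = m$theta)))
  jsonlite::write_json(bundle, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_gp
#' @export
load_gp <- function(path) {
  b <- jsonlite::read_json(path, simplifyVector = TRUE)
  X <- as.matrix(b$X); Y <- as.matrix(b$Y)
  colnames(X) <- b$input_names; colnames(Y) <- b$output_names
  gp <- gp_surrogate(X, Y, seed = b$seed,
                     metadata = as.list(b$metadata))
  gp
}
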