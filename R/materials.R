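#' Passive myocardium constitutive model
#'
#' Two strain-energy families are supported:
#' \describe{
#'   \item{`fung_usyk`}{Fung-type orthotropic exponential law
#'     \eqn{W = C/2(\exp Q - 1)} with
#'     \eqn{Q = b_{ff}E_{ff}^2 + b_{ss}E_{ss}^2 + b_{nn}E_{nn}^2 +
#'     b_{fs}(E_{fs}^2+E_{sf}^2) + b_{fn}(E_{fn}^2+E_{nf}^2) +
#'     b_{ns}(E_{ns}^2+E_{sn}^2)}, with E the Green-Lagrange strain in the
#'     fiber/sheet/normal frame.}
#'   \item{`holzapfel_ogden`}{Invariant-based law
#'     \eqn{W = \frac{a}{2b}\exp[b(I_1-3)] +
#'     \sum_{i=ff,ss}\frac{a_i}{2b_i}\{\exp[b_i(I_{4i}-1)^2]-1\} +
#'     \frac{a_{fs}}{2b_{fs}}\{\exp[b_{fs}I_{8fs}^2]-1\}}. The isotropic term
#'     is implemented exactly as written (no -1), so W = a/(2b) at C = I; the
#'     constant offset carries no stress. The anisotropic I4 terms contribute
#'     only under tension (I4 > 1) when `tension_only = TRUE` (default).}
#' }
#'
#' @param law `"fung_usyk"` or `"holzapfel_ogden"`.
#' @param coefficients Named list of positive coefficients: for `fung_usyk`
#'   `C` (kPa) and `b_ff, b_ss, b_nn, b_fs, b_fn, b_ns`; for
#'   `holzapfel_ogden` `a, a_ff, a_ss, a_fs` (kPa) and `b, b_ff, b_ss, b_fs`.
#' @param tension_only Logical; switch I4 anisotropic terms off in compression
#'   (holzapfel_ogden only).
#' @param label Optional short name.
#' @return An object of class `material_model`.
#' @export
material_model <- function(law = c("fung_usyk", "holzapfel_ogden"),
                           coefficients, tension_only = TRUE, label = law) {
  law <- match.arg(law)
  need <- if (law == "fung_usyk") {
    c("C", "b_ff", "b_ss", "b_nn", "b_fs", "b_fn", "b_ns")
  } else {
    c("a", "b", "a_ff", "b_ff", "a_ss", "b_ss", "a_fs", "b_fs")
  }
  coefficients <- coefficients[order(match(names(coefficients), need))]
  if (!setequal(names(coefficients), need))
    stop(sprintf("material_model: %s requires exactly coefficients %s",
                 law, paste(need, collapse = ", ")))
  if (any(unlist(coefficients) <= 0))
    stop("material_model: all coefficients must be > 0")
  structure(list(law = law, coefficients = lapply(coefficients, as.numeric),
                 tension_only = isTRUE(tension_only), label = label[1]),
            class = "material_model")
}

#' @export
print.material_model <- function(x, ...) {
  cat(sprintf("material_model '%s' (%s)\n  %s\n", x$label, x$law,
              paste(sprintf("%s=%g", names(x$coefficients),
                            unlist(x$coefficients)), collapse = "  ")))
  invisible(x)
}

#' Registry of literature material parameter sets
#'
#' Loads the packaged parameter sets: `"usyk"` (Fung-type, canine),
#' `"whow"` (Holzapfel-Ogden, swine) and `"whog"` (Holzapfel-Ogden, human).
#'
#' @param tag Optional registry key; when omitted all sets are returned.
#' @param tension_only Passed to [material_model()] for Holzapfel-Ogden sets.
#' @return A `material_model`, or a named list of all three.
#' @export
material <- function(tag = NULL, tension_only = TRUE) {
  path <- system.file("extdata", "material_sets.json", package = "lvmech")
  reg <- jsonlite::read_json(path, simplifyVector = FALSE)
  build <- function(entry, key)
    material_model(entry$law, entry$coefficients,
                   tension_only = tension_only, label = key)
  if (is.null(tag)) {
    return(stats::setNames(
      lapply(names(reg), function(k) build(reg[[k]], k)), names(reg)))
  }
  tag <- match.arg(tolower(tag), names(reg))
  build(reg[[tag]], tag)
}

# strain energy density from local-frame right Cauchy-Green components,
# vectorized over points. C_loc: list/data.frame of the six components in the
# (f, s, n) basis. Returns kPa.
strain_energy_components <- function(mat, c11, c22, c33, c12, c13, c23) {
  co <- mat$coefficients
  if (mat$law == "fung_usyk") {
    e11 <- (c11 - 1) / 2; e22 <- (c22 - 1) / 2; e33 <- (c33 - 1) / 2
    e12 <- c12 / 2; e13 <- c13 / 2; e23 <- c23 / 2
    Q <- co$b_ff * e11^2 + co$b_ss * e22^2 + co$b_nn * e33^2 +
      2 * co$b_fs * e12^2 + 2 * co$b_fn * e13^2 + 2 * co$b_ns * e23^2
    co$C / 2 * (exp(Q) - 1)
  } else {
    i1 <- c11 + c22 + c33
    i4f <- c11; i4s <- c22; i8 <- c12
    if (mat$tension_only) {
      i4f <- pmax(i4f, 1); i4s <- pmax(i4s, 1)
    }
    co$a / (2 * co$b) * exp(co$b * (i1 - 3)) +
      co$a_ff / (2 * co$b_ff) * (exp(co$b_ff * (i4f - 1)^2) - 1) +
      co$a_ss / (2 * co$b_ss) * (exp(co$b_ss * (i4s - 1)^2) - 1) +
      co$a_fs / (2 * co$b_fs) * (exp(co$b_fs * i8^2) - 1)
  }
}

# rotate a 3x3 tensor into the (f, s, n) frame
to_fiber_frame <- function(C, frame) {
  M <- cbind(frame$f, frame$s, frame$n)
  t(M) %*% C %*% M
}

#' Strain energy density
#'
#' Evaluates the selected strain-energy law at a single material state.
#'
#' @param mat A `material_model`.
#' @param C Right Cauchy-Green tensor (3 x 3 symmetric positive definite),
#'   expressed in the same basis as `frame`.
#' @param frame List with unit vectors `f`, `s`, `n` (as from [fiber_frame()],
#'   single point), or NULL when `C` is already in the fiber frame.
#' @return Energy density, kPa.
#' @export
strain_energy <- function(mat, C, frame = NULL) {
  C <- as.matrix(C)
  if (max(abs(C - t(C))) > 1e-8) stop("strain_energy: C must be symmetric")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("strain_energy: C must be positive definite")
  if (!is.null(frame)) {
    f <- if (is.matrix(frame$f)) frame$f[1, ] else frame$f
    s <- if (is.matrix(frame$s)) frame$s[1, ] else frame$s
    n <- if (is.matrix(frame$n)) frame$n[1, ] else frame$n
    C <- to_fiber_frame(C, list(f = f, s = s, n = n))
  }
  strain_energy_components(mat, C[1, 1], C[2, 2], C[3, 3],
                           C[1, 2], C[1, 3], C[2, 3])
}

#' Fiber stretch
#'
#' \eqn{\lambda_{ff} = \sqrt{f \cdot C f}}: stretch of a line element along
#' the fiber direction.
#'
#' @param C Right Cauchy-Green tensor (3 x 3 SPD).
#' @param f Fiber direction (unit vector; normalized with a warning if not).
#' @return Fiber stretch, dimensionless.
#' @export
fiber_stretch <- function(C, f) {
  nf <- sqrt(sum(f^2))
  if (abs(nf - 1) > 1e-8) {
    warning("fiber_stretch: f is not a unit vector; normalizing")
    f <- f / nf
  }
  sqrt(as.numeric(f %*% as.matrix(C) %*% f))
}

#' Second Piola-Kirchhoff stress by numerical differentiation
#'
#' \eqn{S = 2 \partial W / \partial C}, by central finite differences on the
#' components of C (step 1e-6), symmetrized.
#'
#' @inheritParams strain_energy
#' @param step Finite-difference step on C entries.
#' @return 3 x 3 symmetric stress tensor, kPa.
#' @export
pk2_stress <- function(mat, C, frame = NULL, step = 1e-6) {
  C <- as.matrix(C)
  dWdC <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3) {
    Cp <- C; Cm <- C
    Cp[i, j] <- Cp[i, j] + step
    Cm[i, j] <- Cm[i, j] - step
    # perturbed tensors may lose exact symmetry; bypass the symmetry check
    dWdC[i, j] <- (strain_energy_unchecked(mat, Cp, frame) -
                   strain_energy_unchecked(mat, Cm, frame)) / (2 * step)
  }
  S <- 2 * dWdC
  (S + t(S)) / 2
}

strain_energy_unchecked <- function(mat, C, frame) {
  if (!is.null(frame)) {
    f <- if (is.matrix(frame$f)) frame$f[1, ] else frame$f
    s <- if (is.matrix(frame$s)) frame$s[1, ] else frame$s
    n <- if (is.matrix(frame$n)) frame$n[1, ] else frame$n
    C <- to_fiber_frame(C, list(f = f, s = s, n = n))
  }
  Cs <- (C + t(C)) / 2
  strain_energy_components(mat, Cs[1, 1], Cs[2, 2], Cs[3, 3],
                           Cs[1, 2], Cs[1, 3], Cs[2, 3])
}
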