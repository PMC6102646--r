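#' Packaged population geometry table
#'
#' Best-fit six-parameter geometries for the 45 ventricles of the reference
#' cine-MRI population (9 normal, 12 hypertrophic, 12 failing without and 12
#' with infarct), at the beginning (BoD) and end (EoD) of diastole. Angles are
#' stored in degrees in the file and returned in both degrees (`psi0_deg`)
#' and radians (`psi0`).
#'
#' @param phase Optional filter, `"BoD"` or `"EoD"`.
#' @param group Optional filter among `"N"`, `"HYP"`, `"HF-NI"`, `"HF-I"`.
#' @return A data frame with columns id, group, phase, R_b, L, Z, H, e,
#'   psi0_deg, psi0.
#' @export
patient_table <- function(phase = NULL, group = NULL) {
  path <- system.file("extdata", "patient_geometry.csv", package = "lvmech")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) != 90L || length(unique(tab$id)) != 45L)
    stop("patient_table: packaged table corrupted (expected 45 patients x 2 phases)")
  tab$psi0 <- tab$psi0_deg * pi / 180
  if (!is.null(phase)) tab <- tab[tab$phase == match.arg(phase, c("BoD", "EoD")), ]
  if (!is.null(group)) tab <- tab[tab$group == match.arg(group, c("N", "HYP", "HF-NI", "HF-I")), ]
  tab
}

#' Packaged table of stretch-conditioned unloaded geometries
#'
#' Unloaded six-parameter geometries for the 45 population ventricles as
#' inferred by stretch-conditioned GP regression (Fung-type material set),
#' for midwall end-diastolic fiber stretches of 1.10 and 1.15.
#'
#' @param stretch_target Optional filter, 1.10 or 1.15.
#' @return Data frame with columns id, stretch_target, R_b, L, Z, H, e,
#'   psi0_deg, psi0.
#' @export
unloaded_table <- function(stretch_target = NULL) {
  path <- system.file("extdata", "unloaded_gp_wu.csv", package = "lvmech")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(tab) != 90L)
    stop("unloaded_table: packaged table corrupted (expected 45 patients x 2 targets)")
  tab$psi0 <- tab$psi0_deg * pi / 180
  if (!is.null(stretch_target))
    tab <- tab[abs(tab$stretch_target - stretch_target) < 1e-9, ]
  tab
}

#' Geometry from a table row
#'
#' @param row One-row data frame with columns R_b, Z, L, H, e and either
#'   psi0 (radians) or psi0_deg.
#' @return An `lv_geometry`.
#' @export
geometry_from_row <- function(row) {
  psi0 <- if (!is.null(row$psi0)) row$psi0 else row$psi0_deg * pi / 180
  lv_geometry(row$R_b, row$Z, row$L, row$H, row$e, psi0)
}

#' Baseline failing ventricle for the infarct study
#'
#' The unloaded geometry obtained by fixed-point unloading of the HF-I-02
#' end-diastolic configuration at 1 kPa with the Fung-type material set,
#' shipped as a precomputed fixture (synthetic: produced by this package's
#' own solver, not an imaged geometry).
#'
#' @return An `lv_geometry`.
#' @export
infarct_baseline <- function() {
  path <- system.file("extdata", "infarct_baseline_synthetic.json",
                      package = "lvmech")
  v <- jsonlite::read_json(path, simplifyVector = TRUE)
  lv_geometry(v$R_b, v$Z, v$L, v$H, v$e, v$psi0)
}
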