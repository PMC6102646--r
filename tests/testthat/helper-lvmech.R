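# Shared fixtures and a cache for expensive computations reused across files.

reference_geometry <- function() {
  # Table-layout values of the dilated failing ventricle used as the running
  # example (HF-I-02 at end of diastole)
  lv_geometry(R_b = 44, Z = 52, L = 9.5, H = 5.7, e = 0.65,
              psi0 = -75 * pi / 180)
}

ellipsoid_geometry <- function(R_b = 40, Z = 53, L = 10, H = 5) {
  # e = 1, psi0 -> -pi/2: exact ellipsoids of revolution
  lv_geometry(R_b = R_b, Z = Z, L = L, H = H, e = 1, psi0 = -pi / 2 + 1e-9)
}

.lvmech_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.lvmech_test_cache[[key]]))
    .lvmech_test_cache[[key]] <- force(expr)
  .lvmech_test_cache[[key]]
}

# the full surrogate-vs-oracle study (used by several acceptance checks)
full_unloading_study <- function() {
  cached("unloading_study", unloading_study(
    n_train = 75, n_test = 15, pressures = c(1, 2), seed = 1))
}

full_infarct_study <- function() {
  cached("infarct_study", run_infarct_study(n = 40, seed = 1))
}
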