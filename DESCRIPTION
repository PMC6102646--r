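Package: lvmech
Title: Surrogate Modelling of Left-Ventricular Passive Mechanics and Unloading
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for reduced-order modelling of left-ventricular (LV)
    mechanics on an analytic six-parameter truncated-prolate-spheroid shape
    family. Provides passive hyperelastic inflation with Fung-type and
    Holzapfel-Ogden myocardium laws via a Rayleigh-Ritz solver constrained to
    the shape family, fitting of the idealized model to labeled cardiac images,
    latin-hypercube experiment design from population shape statistics,
    inverse estimation of the unloaded (stress-free) configuration by
    fixed-point iteration and by Gaussian-process (kriging) regression
    surrogates conditioned on pressure or midwall fiber stretch, and a
    Gaussian-process emulator of infarct-geometry effects on stroke volume
    with cross-validated accuracy assessment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    lhs,
    pracma,
    RNifti,
    stats,
    utils
Suggests:
    kernlab,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
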