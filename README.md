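# lvmech

Reduced-order modelling of left-ventricular (LV) passive mechanics on an
analytic six-parameter shape family, with Gaussian-process (kriging)
surrogates for two problems that full 3-D finite-element studies solve at
great cost: estimating the *unloaded* (stress-free) configuration of a
ventricle from a loaded, imaged one, and emulating the effect of infarct
geometry on stroke volume.

The package is aimed at cardiac-mechanics researchers who want a
desk-scale, fully scripted version of the surrogate-modelling workflow:
shape statistics from a patient population, latin hypercube experiment
designs, a deterministic forward solver, fixed-point (backward
displacement) unloading as the oracle, and trained GP surrogates that
replace it at negligible cost.

## The models

**Shape family.** Every ventricle is a truncated prolate spheroid
$\xi = \{R_b, Z, L, H, e, \psi_0\}$ whose epicardial/endocardial profiles
over $\psi \in [\psi_0, \pi/2]$ are

$$\rho_{epi} = R_b[e\cos\psi + (1-e)(1-\sin\psi)], \quad
  \zeta_{epi} = Z(1-\sin\psi),$$
$$\rho_{end} = (R_b-L)[e\cos\psi + (1-e)(1-\sin\psi)], \quad
  \zeta_{end} = (Z-H)(1-\sin\psi) + H.$$

**Materials.** Fung-type orthotropic ($W = \tfrac{C}{2}(e^Q - 1)$) and
Holzapfel–Ogden invariant-based strain energies with three literature
parameter sets (canine, swine, human), rule-based myofiber helix
(+90° endo to −60° epi).

**Forward solver.** Quasi-static inflation by Rayleigh–Ritz minimization of
total potential energy over the shape family (isochoric split + volumetric
penalty; basal plane fixed; near-base epicardium tethered), with pressure
continuation. Deterministic, seconds per ventricle.

**Unloading.** Fixed-point iteration
$\xi_u^{k+1} = \xi_u^k + (\xi_{target} - G(\xi_u^k))$ with quasi-Newton
safeguards (the oracle), and per-pressure GP surrogates mapping the six
loaded parameters to the six unloaded ones — or, conditioned on midwall
fiber stretch $\lambda_{ff} = \sqrt{f\cdot C f}$, jointly predicting the
unloaded shape and the end-diastolic pressure.

**Infarct emulator.** Lesions parameterized by longitudinal position,
circumferential and longitudinal extension, and transmural depth; a
time-varying-elastance cycle model calibrated to two stroke-volume anchors
(49 ml lesion-free, 21 ml at the maximal half-wall lesion) maps lesions to
stroke volume; a GP emulator over the 4-D lesion space is assessed by
5-fold cross-validation.

## Worked example

```r
library(lvmech)

# a dilated failing ventricle from the packaged population table
tab <- patient_table(phase = "EoD")
geom <- geometry_from_row(tab[tab$id == "HF-I-02", ])
geom
#> LV geometry: R_b=44.00  Z=52.00  L=9.50  H=5.70 mm, e=0.650, psi0=-75.0 deg
#>   cavity 293.6 ml, wall 206.9 ml, base height 102.2 mm

# inflate it to 1 kPa with the human Holzapfel-Ogden set
st <- inflate(geom, material("whog"), P = 1)
st
#> Loaded state at P = 1.00 kPa: cavity 378.0 ml, wall 206.4 ml, midwall lambda_ff 1.0955

# estimate the unloaded configuration by fixed-point iteration
fp <- fixed_point_unload(geom, P = 1, mat = material("whog"))
fp$n_iterations
#> [1] 3
fp$xi_unloaded
#> LV geometry: R_b=41.27  Z=51.88  L=10.38  H=6.55 mm, e=0.650, psi0=-76.1 deg
#>   cavity 234.2 ml, wall 206.0 ml, base height 102.2 mm
```

The unloaded ventricle is smaller in cavity (234 vs 294 ml) with a thicker
wall (10.4 vs 9.5 mm at the base) — the state a simulation must start from,
and one that cannot be imaged because the ventricle is never unpressurized.
Training a GP surrogate replaces the iteration:

```r
samples <- lhs_normal(25, population_stats("BoD"), seed = 1)
samples <- Filter(is_feasible, samples)
ts <- build_training_set(samples, material("whog"), pressures = 1)
un <- train_unloader(ts, seed = 1)
pred <- predict_unloaded(un, geom, conditioning = 1)
dice_score(pred$xi_unloaded, fp$xi_unloaded)
#> [1] 0.9295495
```

A command-line wrapper over the same functions ships in
`inst/cli/lvmech.R` (`synth-image`, `fit-image`, `inflate`, `sweep`,
`unload-fpi`, `train-unloader`, `unload-gp`, `infarct-study`,
`infarct-cv`).

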