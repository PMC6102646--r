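---
title: "Reduced-order LV mechanics and kriging surrogates: models, assumptions, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reduced-order LV mechanics and kriging surrogates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lvmech)
```

## The shape family

Every ventricle in this package is a truncated prolate spheroid described by
six parameters $\xi = \{R_b, Z, L, H, e, \psi_0\}$. The epicardial and
endocardial boundaries are profiles of revolution over the angle
$\psi \in [\psi_0, \pi/2]$:

$$
\rho_{epi} = R_b\,[e\cos\psi + (1-e)(1-\sin\psi)], \qquad
\zeta_{epi} = Z(1-\sin\psi),
$$
$$
\rho_{end} = (R_b - L)\,[e\cos\psi + (1-e)(1-\sin\psi)], \qquad
\zeta_{end} = (Z-H)(1-\sin\psi) + H.
$$

$R_b$ (mm) is the outer radius at the base, $Z$ (mm) the outer longitudinal
semi-axis, $L$ and $H$ (mm) the basal and apical wall thicknesses, $e \in
[0,1]$ the sphericity ($e = 1$ with $\psi_0 = -\pi/2$ gives exact ellipsoids
of revolution, which is the closed-form limit the volume code is tested
against), and $\psi_0$ (radians, negative in every case here) the
truncation angle at the base. The canonical pose puts the epicardial apex at
the origin and the long axis along $+z$; rigid poses are applied only at
image interfaces. Units are fixed: mm, kPa, ml, radians internally and
degrees in files and at the command line.

The wall is charted by material coordinates $(\psi, t, \theta)$, where $t
\in [0,1]$ blends the endocardial ($t=0$) and epicardial ($t=1$) profiles
linearly at equal $\psi$ and $\theta$ is the circumferential angle. The
blend at equal $\psi$ is a convention: a full 3-D model interpolates
displacements through the mesh, which has no unique analogue in the family.
Cavity volume closes the endocardial surface of revolution with the straight
$\psi_0$ truncation edge and the flat basal plane; this frustum convention
is likewise ours, chosen so that cavity + wall tile the inside of the
epicardial surface exactly (voxel classification, Dice scores and volume
integrals all share it).

Myofiber directions follow the rule-based helix: the fiber angle from the
local circumferential direction varies linearly across the wall from
$+90^\circ$ at the endocardium (fully longitudinal, as printed in the
source rule) to $-60^\circ$ at the epicardium. Frames are orthonormalized
per point; quadrature grids are tensor-product Gauss-Legendre in $(\psi,
t)$ times a uniform midpoint rule in $\theta$, with volume weights from the
analytic chart Jacobian (default 24 x 8 x 24, matching the wall volume to
better than 0.5%).

## Passive material laws

Two strain-energy families cover the three parameter sets shipped in the
registry (`material()`): a Fung-type orthotropic exponential
(`usyk`, canine) and the Holzapfel-Ogden invariant form (`whow`, swine;
`whog`, human). The Holzapfel-Ogden isotropic term is implemented exactly
as printed in its source, i.e. $\frac{a}{2b}\exp[b(I_1-3)]$ without a $-1$:
the constant offset $a/(2b)$ at $C = I$ carries no stress and is documented
rather than removed. The anisotropic $I_4$ terms act only in tension
($I_4 > 1$), the standard convention; a `tension_only = FALSE` switch is
provided because the source is silent on the point. At equal fiber stretch
along an incompressible uniaxial path the three sets rank, softest to
stiffest, Fung-type < human HO < swine HO, and the forward solver
reproduces the same ranking in cavity compliance.

Incompressibility is not built into the laws: the solver evaluates the
energies on the isochoric part $\bar C = J^{-2/3} C$ and adds a volumetric
penalty $\kappa/2\,(J-1)^2$. The default $\kappa = 400$ kPa keeps the wall
volume change below 2% at 5 kPa inflation for the softest material on the
default quadrature; at $\kappa = 250$ the drift reaches 2.5%, which is why
the default sits higher. The penalty sweep test checks that $|J-1|$
decreases monotonically as $\kappa$ doubles.

## The reduced forward model

The full-order problem this package stands in for solves 3-D finite-element
equilibrium on meshes of several hundred thousand tetrahedra. Here the
deformed configuration is constrained to the same six-parameter family as
the reference, and equilibrium is the minimizer of the total potential
energy (Ritz method):

$$
\Pi(\xi_d) = \sum_q w_q\left[W(\bar C_q) + \tfrac{\kappa}{2}(J_q-1)^2\right]
  - P\,(V_c(\xi_d) - V_c(\xi_u)) + \text{basal tether},
$$

with the deformation gradient of the in-family map computed analytically
from the chart Jacobians at matched material coordinates. The
justification for the family-constrained state space is that the
surrogate-modelling strategy itself re-parameterizes every full-order
result back into the family before training, so the family is the method's
effective state space; the solver interface is pluggable so a genuine FEM
could substitute.

Boundary conditions mirror the full-order problem: the basal plane height
$\zeta_{base} = Z(1-\sin\psi_0)$ is held fixed (nodes at the base do not
move axially), and epicardial material points within 3 mm of the base are
tethered to their reference positions by a quadratic penalty (`clamp_k =
200` kPa mm, three sample points). The tether deserves a note, because it
was a genuinely open design point. Without it, the deformed truncation
angle is almost unobservable: the energy is nearly flat along combined
$(Z, \psi_0)$ changes at fixed basal height, the deformed $\psi_0$ responds
to the unloaded one with slope ~0.16, and six-parameter fixed-point
unloading stalls above its $0.5^\circ$ tolerance, with some targets having
no feasible preimage at all. The basal clamp pins the basal epicardial
geometry, restores identifiability of $\psi_0$, and is also what the
full-order study did - at the cost, there as here, of artifacts near the
base. One visible consequence of the reduced kinematics: upon inflation the
deformed $\psi_0$ becomes slightly *less* negative, so unloaded estimates
have more negative truncation angles than the loaded shapes.

Each pressure is reached by continuation in steps of at most 0.25 kPa, each
step minimized by bounded L-BFGS-B over the five free parameters ($Z$ is
implied by the fixed basal height) with finite-difference gradients,
warm-started from the previous step, with a Nelder-Mead fallback on
line-search failure. Candidates with $\det F \le 0$ or outside the
feasibility box are rejected with a large finite energy. The relative
convergence tolerance (`factr = 2e8`) was chosen by comparing converged
parameters across tolerances: tightening it 20-fold changes parameters by
less than 0.01 mm / 0.01 degrees while doubling cost. The solver is fully
deterministic.

Pressure sweeps solve the ladder $P = \delta, 2\delta, \dots$ sequentially
with warm starts; the default $\delta = 0.05$ kPa to 5 kPa yields exactly
100 loaded configurations. The midwall fiber stretch
$\lambda_{ff} = \sqrt{f \cdot C f}$ is averaged (unweighted) over a fixed
evaluation lattice spanning 40-60% of the wall thickness and 45-55% of the
apex-base distance; a dedicated lattice is used rather than whichever
quadrature points happen to fall in the band, so the summary does not
depend on the solver's quadrature resolution.

## Fitting the family to images and surfaces

`similarity_j()` implements the cavity-and-wall overlap functional
$J = 1 - \frac12(\text{Jaccard}_{cavity} + \text{Jaccard}_{wall})$ on voxel
sets; `fit_to_image()` minimizes it with Nelder-Mead over the six
parameters, preceding every evaluation by a rigid alignment that matches
the candidate's long axis and center of gravity to those estimated from
the target. The long-axis estimator starts from the total-least-squares
line through per-axial-slice centroids and then re-slices perpendicular to
the current estimate a few times: axial-slice centroids are biased for
tilted ventricles (oblique cuts through a tapering body have off-axis
centroids), and the re-slicing iteration removes that bias. Fine grids get
a coarse strided pass before refinement; three perturbed restarts guard
against local minima, stopping early once $J < 0.02$.

`fit_to_surfaces()` is the two-block alternating fit used to
re-parameterize deformed shapes: $\{R_b, Z, e, \psi_0\}$ against the
epicardial cloud, then $\{L, H\}$ against the endocardial cloud, iterated
to a $10^{-3}$ relative parameter tolerance with at most 20 alternations
(a monolithic six-parameter variant is provided for comparison).
Point-to-profile distances use dense sampling of the profile curve (512
points). Because the reduced solver's outputs are already in the family,
this fit recovers them exactly; its real work is on out-of-family clouds.

`generate_label_image()` emulates short-axis cine-MRI segmentations:
anisotropic voxels (default 1.36 x 1.36 x 8.8 mm) and label noise
restricted to boundary-adjacent voxels, each flipped voxel taking a random
6-neighbor's label. It does not emulate intensity artifacts, papillary
muscles, or slice misregistration - so passing recovery tests show the
fitting machinery works, not that real segmentations are this benign.

## Experiment design

Population statistics (mean and SD per parameter) come from the packaged
45-ventricle table at beginning of diastole. The design box is mean
$\pm$ 3.5 SD, clipped to hard physical bounds ($e \in [0,1]$, $\psi_0 \in
[-88^\circ, -10^\circ]$, positive lengths, $R_b - L \ge 5$ mm, $Z - H \ge
5$ mm); 3.5 was chosen once as "more than 3" SDs, and every population row
lies inside the pooled box. `lhs_normal()` draws latin hypercube samples
through normal quantiles with doubled SD (600 = 100 x 6 in the reference
design), projecting outliers onto the box. `is_feasible()` additionally
rejects shapes whose endocardial radius falls below 1 mm along the profile
up to $0.85 \cdot \pi/2$ or whose cavity is under 5 ml. The 0.85 cutoff is
deliberate: the radius vanishes at the apex for every geometry, so the
check must stop short of it, and 0.85 is the largest round fraction at
which all 90 population rows pass. Under the pooled design roughly 10-15%
of samples are infeasible, the same order as the full-order study's 67/600.

## Unloading: fixed point and kriging

The fixed-point (backward displacement) scheme iterates
$\xi_u^{k+1} = \xi_u^k + (\xi_{target} - G(\xi_u^k))$, where $G$ inflates a
candidate to the target pressure, starting from the target itself.
Convergence is declared when the scaled residual (0.1 mm lengths, 0.005
sphericity, $0.5^\circ$ truncation) drops below one. Two numerical
amendments matter. First, from the second iteration on, the equilibrium
solve is warm-started from the previous iterate's solution instead of
re-running the continuation (with an automatic fall-back to full
continuations if progress stalls - warm starts can track a different
branch of a flat energy valley on hard cases). Second, the update is
safeguarded quasi-Newton: Broyden's inverse update of the residual-map
Jacobian in scaled coordinates, initialized at 0.7 times the plain update,
with a trust region on the step and a model reset whenever the residual
increases. The plain update oscillates with ratio about $-0.76$ in a
coupled $(R_b, L, H)$ mode for compliant materials at 2 kPa and contracts
at ratio about $0.8$ in the $\psi_0$ mode, either way needing well over
ten iterations; the quasi-Newton scheme needs 3-8 on typical cases and
stays within about ten on the hardest, bracketing the 7-10 reported for
the standard scheme at full order. Iterates are projected into the
feasibility box; a residual that stops moving while pinned at the boundary
means the target has no feasible preimage, and the routine reports it as
an error. Such targets exist (arbitrary parameter vectors outside the
image of the forward map), which is why the study driver tests on
forward-inflated loaded states; they are the analogue of the full-order
geometries whose simulations could not be completed, and drivers drop and
log them.

The kriging surrogate maps the six loaded parameters to the six unloaded
ones with one GP per output (anisotropic squared-exponential kernel plus
nugget, inputs and outputs standardized, hyperparameters by exact maximum
marginal likelihood with analytic gradients and five seeded restarts).
Kernel family, standardization and independent-output structure are our
choices - the source leaves them unspecified - and are isolated behind the
surrogate interface. One surrogate is trained per conditioning pressure
(the per-pressure dictionary mirrors the reference's "one statistical
model per pressure"); prediction uses the nearest trained pressure within
0.025 kPa. In stretch mode the conditioning variable is the midwall fiber
stretch: the sweep locates the pressure at which each target stretch is
reached, and the surrogate predicts that pressure jointly with the
unloaded shape (the joint-output choice was open; a separate pressure
model would be equivalent in accuracy and less convenient). Because
scaling all stiffness coefficients by a constant rescales the
pressure-stretch curve without moving the shape trajectory,
stretch-conditioned unloading is invariant under homogeneous stiffness
scaling while the predicted pressure scales proportionally - a property
tested on a doubled Fung-type set.

`unloading_study()` runs the desk-scale comparison the package is sized
for: 75 training and 15 test geometries, pressures 1 and 2 kPa, all three
material sets, wall Dice between surrogate and fixed-point unloaded
shapes on a 1 mm grid. Training geometries come from the conservative
doubled-SD design; test geometries are drawn at population scale and
forward-inflated to produce the loaded targets - the analogue of testing
on imaged patient configurations, and the only way every test target is
guaranteed to be an attainable loaded state of the reduced forward map.
This is a deliberate scale-down of the full-order study (533 geometries,
100 pressures); problem sizes were chosen so the whole study runs in
minutes on one core while keeping the headline comparison (surrogate vs
oracle at $n_{train} = 75$) intact.

## The infarct emulator

Lesions are boxes in material coordinates: normalized longitudinal
position, circumferential extension (centered at $\theta = 0$; the
axisymmetric baseline makes the phase irrelevant), longitudinal extension,
and transmural depth growing from the endocardium. Growth from the
endocardium, and the identification of the longitudinal coordinate with
the normalized $\psi$ position, are stated conventions - the source does
not pin them down, so printed lesion volumes are not comparison targets.
Because membership is a box, the volume integral separates and the
circumferential factor is exact, making lesion volume exactly linear in
the angular extension.

The cycle model is a time-varying-elastance reduction: end-diastolic
volume from passive inflation to EDP = 1.5 kPa, end-systolic volume from
the aortic pressure (12 kPa) on the end-systolic elastance line with
intercept $V_0 = 10$ ml, and contraction scaled by the healthy
wall-volume fraction, $E_{eff} = E_{min} + (E_{max} - E_{min})(1 - f)$
with $f$ the infarct fraction. Both elastance bounds are calibrated to
stroke-volume anchors: $E_{max}$ so the lesion-free baseline (the
fixed-point-unloaded dilated ventricle shipped as a fixture) ejects 49 ml,
and $E_{min}$ so the maximal in-box lesion (half the wall) ejects 21 ml.
Calibrating $E_{min}$ rather than fixing it is forced: with the reduced
solver the baseline EDV is 262-345 ml depending on material, so any fixed
$E_{min}$ of the usual magnitude either exceeds the calibrated $E_{max}$
or collapses large-lesion stroke volumes to zero. The two-anchor
calibration keeps the emulated response inside the reported range by
construction; what the study then measures is the emulator's ability to
learn the response surface, not the anchors. By construction stroke volume
depends on the lesion only through its wall-volume fraction - a documented,
deliberate divergence from full-order models, where location retains a
small residual effect.

The study design is a uniform 40-point latin hypercube (10 per dimension)
over the 4-D lesion box on the fixed baseline; the emulator is the same GP
machinery as the unloading surrogate; accuracy is assessed by seeded
5-fold cross-validation of the mean relative stroke-volume error.

## Degenerate inputs, ties, tolerances

Profile evaluation outside $[\psi_0, \pi/2]$, non-SPD strain states,
mismatched image grids, empty region masks and single-slice images are
errors, not warnings. The apex ($\psi = \pi/2$) degenerates the chart;
fiber frames there use a one-sided limit, and quadrature nodes never sit
on it. Voxel membership is decided by the voxel center, so whole-pitch
translations on an aligned grid are exact symmetries. Dice between
geometries uses wall labels only, at 1 mm isotropic spacing in canonical
pose on a common grid - cavity-only or two-class variants would change
absolute values, which is why the metric sits behind one function.

## Known limitations

The forward model cannot represent deformations outside the shape family
(regional bulging, non-axisymmetric modes), so basal and apical details
diverge from full-order mechanics even where global volumes agree. The
unloading comparison is internally consistent - surrogate against
fixed-point on the same reduced solver - and says nothing about absolute
agreement with a 3-D FEM. The cycle model has no active constitutive law,
no border zone (the lesion boundary is sharp), and no circulation; it
preserves the input-output structure of the infarct study (4 lesion
parameters in, stroke volume out), which is exactly what the emulation
method needs and no more. Viscoelasticity is out of scope throughout.
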