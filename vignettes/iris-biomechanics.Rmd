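---
title: "Iris biomechanics from pupillary light reflex imaging: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Iris biomechanics from pupillary light reflex imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

During the pupillary light reflex (PLR) the circumferential sphincter muscle
at the pupil margin contracts, shrinking the pupil while the limbus — the
outer boundary of the iris, anchored at the corneo-scleral junction — stays
essentially fixed. The iris stroma in between undergoes very large
deformations (radial strains can exceed 100%). Because the loading event is
easy to induce and to film in the near infrared (NIR), the PLR offers a
non-invasive window on iris mechanics: from the measured pupil-margin strain
one can infer how strong the sphincter's active traction is relative to the
stiffness of the stroma it pulls against. That dimensionless ratio, written
Ts:E, is the package's headline quantity; its absolute constituents (the
traction Ts in kPa and Young's modulus E in kPa) are *not* identifiable from
kinematic data alone.

irisMech implements the full chain: synthetic (or user-supplied) NIR frame
sequences, pupil/limbus tracking, margin strains, digital image correlation
(DIC) strain fields, a finite-strain annulus model with an active sphincter
ring, and inverse identification of Ts:E as a function of the assumed
sphincter width.

# Measurement model

## Pupil and limbus tracking

Per analyzed frame (default: every 10th frame, i.e. 2.5 Hz at a 25 Hz
acquisition):

* the **pupil** is segmented by intensity: range-normalization to [0, 1], a
  3x3 median filter, binarization of pixels darker than 0.1, an
  erosion/dilation pass with a 2 px square element, hole filling (corneal
  glints inside the pupil), and the largest connected component. The radius
  is `sqrt(area / pi)`. A component covering most of the image border is
  rejected ("no pupil found"). An optional Otsu threshold is available but a
  supplied numeric threshold takes precedence.
* the **limbus** is localized with the Daugman integro-differential
  operator: the radius and centre maximizing the Gaussian-smoothed (sigma =
  2 px) radial derivative of the mean intensity along circular arcs. Only
  lateral arcs (±45° about the horizontal) are integrated, because the
  eyelids interrupt the limbus contour superiorly and inferiorly. The search
  is coarse-to-fine over centres with a parabolic sub-pixel refinement of
  the radius. A flat response landscape (max/median < 1.5) raises "limbus
  not found".

The per-frame ratio beta = r_p / r_l and the margin Lagrangian strains
`eps_i = ((r_i / rbar_i0)^2 - 1) / 2` follow, with `rbar_i0` the mean radius
over the 15 s dark-acclimation phase. The maximum-constriction summary
`eps_p,max` is the mean pupil strain over 17–20 s. Quality control excludes
scans whose `eps_p,max` lies more than three standard deviations from the
cohort mean (single pass); cohort statistics average test–retest scans per
eye before computing mean, SD and the normal-theory 95% CI (z = 1.96 — the
intended cohorts have n of order 40+, and the quantile is configurable).

## Digital image correlation

`correlateIncremental()` is a subset-based incremental DIC engine:

* subsets of 31 px (default) on a 4 px grid inside a user ROI;
* matching by normalized sum of squared differences with a per-subset
  optimal intensity gain and offset, affine (first-order) subset shape
  functions, an integer-pixel search around the motion predicted from the
  previous increment, and Gauss–Newton sub-pixel refinement with bicubic
  image interpolation. The first increment is additionally seeded by a
  coarse pyramid search so fast constrictions stay inside the basin.
* subsets carry a Gaussian weight (sigma = subset/6). On a circular
  geometry the displacement field is not affine over a 31 px subset; with
  uniform weighting the resulting curvature bias is about 1% of the local
  displacement and accumulates over increments. Interior weighting reduces
  the cumulative error on the generator's full constriction from ~0.39 to
  ~0.18 px RMS while leaving pure-translation precision at ~0.001 px.
* a point's match residual is the 1-sigma uncertainty of its translation
  estimate from the Gauss–Newton covariance; points above the matchability
  threshold (0.1 px) or failing convergence are invalidated and never
  revived, mirroring standard DIC practice and blink handling (frames
  flagged by a global-brightness heuristic are dropped, keeping time
  labels).
* displacements are accumulated incrementally, evaluating each increment's
  affine shape function at the true sub-pixel advected location.

Strains come from windowed least squares: all valid grid points within a
15 x 15 *image-pixel* window (the literal reading of a 15 px strain filter)
enter an affine fit of the displacement, giving the deformation gradient F
and the Lagrangian strain E = (F'F − I)/2, rotated to polar components about
the reference pupil centre. A 15-*grid-point* window (57 px at step 4) was
rejected: it spans most of the iris annulus and biases the median radial
strain by roughly −20% on closed-form test fields, whereas the pixel
reading recovers them to ~2%.

Profiles pool the nasal and temporal arms of a box through the pupil centre
(height half the reference pupil radius, width the limbus diameter) and
report median/IQR per bin of the normalized coordinate
`xbar = (|x − xc| − r_p0)/(r_l − r_p0)`. A Hausdorff-distance screen against
the pointwise-median curve excludes profiles beyond mean + 2 SD of the
distances (the threshold is configurable; no canonical value exists). A
"virtual tensometer" converts the chord between the two valid tracked
points nearest the margin on the N-T axis into a margin strain estimate.

The DIC ROI must stay at least subset/2 plus a few pixels inside both the
pupil margin and the limbus: the limbus edge is a strong *static* image
feature, and subsets overlapping it are biased toward zero motion. This is
the synthetic counterpart of the well-known unreliability of DIC near the
iris margins on real recordings.

# The mechanical model

The iris is modelled as a thin annulus (reference inner radius 3.4 mm,
outer radius 6 mm, thickness 0.17 mm) of compressible neo-Hookean material
under plane stress, with strain-energy density

Psi = E / (2(1+nu)) [ (I1 − 3)/2 − ln J ] + E nu / (2(1+nu)(1−2nu)) (ln J)^2,

whose principal Cauchy stresses are
`sigma_i = (mu/J)(lambda_i^2 − 1) + (lambda_L/J) ln J`. The sphincter is an
active circumferential stress of magnitude Ts confined to the material ring
`[Rin, Rin + a_s]` (the ring is pinned in the reference configuration; the
deformed-ring alternative is not distinguishable from the data and the
reference convention matches how muscle elements are embedded in a mesh).
The active Cauchy stress is the push-forward of a fiber stress Ts along the
hoop direction, `sigma_act = (Ts/J) lambda_theta^2`, the convention used by
standard finite-element implementations of prescribed uniaxial active
contraction; at the reference state it reduces to Ts exactly. With the
plain `Ts/J` form the model cannot reproduce the observed traction ratios —
it under-predicts them about four-fold at maximum constriction, where
`lambda_theta ≈ 0.48` at the margin.

Axisymmetry reduces the problem to one dimension: the equilibrium
deformation r(R) solves the weak form of radial equilibrium with nominal
stresses `P_i = dPsi/dlambda_i`, the through-thickness stretch condensed
out pointwise by the plane-stress condition `sigma_zz = 0` (a nested scalar
Newton solve), a traction-free inner edge and a fixed outer edge (the
measured limbus strain is negligible). Discretization: 1-d Galerkin finite
elements, linear shape functions, 2-point Gauss quadrature, 200 elements by
default with a node placed exactly at the sphincter outer edge — without
that alignment the Gauss-point activation of the ring makes the converged
solution jitter with mesh density at the 1e-3 level; with it,
`|eps_p(n=100) − eps_p(n=400)| ~ 2e-6`. Loading ramps Ts in 20 equal
increments (adaptive halving on divergence, floor 1/128 of the base step)
with a damped Newton iteration (feasibility line search keeping r positive
and monotone; relative residual tolerance 1e-9).

The pupil-margin strain is `eps_p = (lambda_theta(Rin)^2 − 1)/2`. Because
the stresses are homogeneous of degree one in (E, Ts), eps_p depends on the
material only through rho = Ts:E and nu — verified to 1e-8 under decade
rescalings, and the basis for the inverse stage.

Two independent checks validate the reduction: a closed-form solution of
the *linearized* plane-stress annulus with an active hoop ring (piecewise
Lamé solution; agreement within 1% at small load), and the reproduction of
the study-scale quantities below.

# Inverse identification

`ratioRoot()` exploits scale invariance: fixing E = 1 it brackets and
solves `eps_p(rho) = target` for the ratio — deterministic and
optimizer-free. `fitSingle()` reproduces the multi-start protocol: 25
deterministic Halton starting points in the box 0 < E < 1000 kPa,
0 < nu < 0.5, 0 < Ts < 1000 kPa; Nelder–Mead minimization of
`|eps_p(model) − target|` per start (the FE objective has noisy numerical
derivatives, so a simplex method is appropriate); fits with objective below
1e-3 strain are accepted; the ratio is the through-origin regression slope
of Ts on E over accepted fits (scale invariance forces a zero intercept;
the free-intercept slope and the median per-fit ratio are reported as
diagnostics).

Poisson's ratio is *not* identifiable: every nu admits a fit with objective
at numerical zero. The implied ratio does depend on nu — it falls smoothly
by roughly 20% from nu = 0.05 to nu = 0.49 in this reduction — so the
deterministic path fixes nu = 0.49, the conventional near-incompressibility
value for soft tissue. The multi-start cloud, which spans the whole nu box,
accordingly shows per-fit ratios spread over that range and a slope a few
percent above the nu = 0.49 value; both routes are exposed, and tests check
their agreement when nu is pinned.

`widthSweep()` repeats the identification at sphincter widths 0.4, 0.7,
1.0 and 1.3 mm — the physiological range — and `fitPowerLaw()` fits the
empirical relation `Ts:E = (A / a_s)^B` by nonlinear least squares
(initialized from the log-log regression), with confidence intervals from
the linearized covariance and t-quantiles at n − 2 degrees of freedom.
Against the target strain −0.386 the sweep is strictly decreasing from
about 11.6-fold at 0.4 mm to about 4.1-fold at 1.3 mm, and the power-law
coefficients land within the reported confidence intervals (A ≈ 6.13 mm,
B ≈ 0.90). A fit of four nearly-exact model evaluations yields much
narrower formal CIs than a fit of scattered multi-start clouds would; only
the point estimates are meaningful here.

# The synthetic-data generator

`renderSequence()` emulates the acquisition the pipeline targets: 30 s at
25 Hz, 768 x 576 px at 39 µm/px, a 15 s dark acclimation (pupil at
beta = 0.566 of the 6 mm limbus radius), 5 s of light with exponential
constriction to beta = 0.262, and 10 s of darkness with exponential
recovery toward baseline that the protocol truncates before completion
(the partial-recovery feature of real recordings). Time constants default
to 0.5 s (constriction) and 4 s (recovery); no measured values exist for
this protocol, and the defaults qualitatively match published beta
time courses. Sensor noise (SD 0.02), two saturated corneal glints fixed in
*image* coordinates (they do not advect with the tissue), and a 10% upper
eyelid occlusion band are on by default as realistic confounds; tests
switch them off where a clean oracle is needed.

The kinematic map is linear in the reference radius between the moving
pupil margin and the fixed limbus, so the radial stretch is spatially
uniform — matching the empirical observation that the measured radial
strain is nearly constant across the iris body — and every ground-truth
strain is closed-form. The iris texture is a seeded multiscale speckle on a
reference polar grid (band-passed Gaussian fields, mildly elongated
radially like iridial crypts and furrows, periodic in the angle), advected
exactly by the map with bicubic interpolation. The generator does *not*
emulate corneal refraction, iris curvature out of plane, hippus, gaze
motion, or the spatially varying reflectance of real irides; passing tests
therefore demonstrate correctness of the algorithms on known kinematics,
not performance on clinical data.

Test problem sizes: segmentation and kinematics suites run on a 220 x 190 px
sequence at 78 µm/px (limbus 77 px) at 1 Hz; DIC accuracy suites run at the
study pixel scale (39 µm/px, limbus 154 px) on a 330 x 330 px crop at
2.5 Hz with the constriction slowed to tau = 2 s, i.e. the motion per
analyzed frame matches the real 2.5 Hz analysis cadence. These are the
package's standard verification conditions.

# Numerical choices and degenerate inputs

* FE Newton tolerance 1e-9 (relative to max(E, Ts)); nested plane-stress
  solve to 1e-14; load-step halving floor 2^-7 of the base increment, after
  which the solver reports the last converged load fraction.
* `ratioRoot` brackets upward from rho = 8 by doubling (cap 200) and solves
  to 1e-7; a target of exactly 0 returns 0 without solving.
* Targets must lie in (−0.5, 0]: −0.5 is the kinematic limit of a closing
  pupil.
* Segmentation of a uniformly bright frame, a flat Daugman landscape, an
  empty acclimation window, an all-invalid DIC increment, an empty
  tensometer band, and a power-law fit with fewer than three points all
  raise typed errors with the messages used throughout the tests.
* Ties in the Daugman response are resolved by the first maximum; the
  parabolic radius refinement is skipped at the search boundary.
* The three-sigma outlier screen is applied once, not iteratively; with
  fewer than three values it warns and keeps everything.

# Known limitations

* The axisymmetric reduction cannot represent eyelid-induced asymmetry or
  gaze motion; it reproduces the sector model's plane-stress mechanics
  exactly, but the through-thickness stress state of a real, curved iris
  only approximately.
* Ts:E at a given width inherits the nu convention (near-incompressible by
  default); reporting alongside the width sweep makes the dependence
  explicit rather than hiding it.
* DIC displacement accuracy is ~1% of the local displacement under the
  generator's extreme (100% strain) deformations; real-world accuracy also
  depends on texture quality and illumination stability, which the
  generator idealizes.
* The stroma is modelled as isotropic, elastic and homogeneous;
  viscoelasticity, anisotropy, regional thickness variation and the dilator
  muscle are out of scope.
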