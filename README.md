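# irisMech

In vivo iris biomechanics from near-infrared pupillary light reflex (PLR)
imaging.

During the PLR the circumferential sphincter muscle constricts the pupil
while the limbus — the outer boundary of the iris — stays fixed, stretching
the stroma in between by up to 100% radial strain. From the measured
pupil-margin strain alone the *absolute* sphincter traction Ts (kPa) and
stromal stiffness E (kPa) cannot be separated, but their dimensionless ratio
can: modelling the iris as a compressible neo-Hookean annulus under plane
stress with an active hoop stress of magnitude Ts in a sphincter ring of
width a_s, the equilibrium pupil strain

    eps_p = (lambda_theta(R_in)^2 - 1) / 2

depends on the material only through Ts:E (and weakly on Poisson's ratio,
which is unidentifiable and fixed at 0.49 by convention). Inverting the
model against a measured eps_p yields Ts:E per assumed sphincter width, and
the width dependence follows the empirical power law

    Ts : E = (A / a_s)^B.

The package implements the full measurement-to-model chain:

- `renderSequence()` — seeded synthetic NIR frame sequences (dark pupil,
  speckle-textured iris advected by a closed-form kinematic map, fixed
  limbus, glints, eyelid, noise) so every stage is testable with known
  ground truth;
- `segmentPupil()`, `detectLimbus()`, `traceSequence()` — threshold
  segmentation of the pupil and Daugman integro-differential localization
  of the limbus, at 2.5 Hz effective sampling;
- `marginStrain()`, `qcOutliers()`, `summarizeStrains()` — Lagrangian
  margin strains, three-sigma quality control, test–retest cohort
  statistics;
- `correlateIncremental()`, `computeStrainField()`, `extractProfile()`,
  `hausdorffOutlier()`, `virtualTensometer()` — incremental subset DIC
  (NSSD, 31 px subsets, 4 px grid, 0.1 px matchability) with Lagrangian
  strain fields and median/IQR radial profiles;
- `solveIris()`, `cauchyStress()`, `strainProfiles()` — the finite-strain
  axisymmetric plane-stress finite-element model with the active sphincter
  ring;
- `ratioRoot()`, `fitSingle()`, `widthSweep()`, `fitPowerLaw()` — inverse
  identification: a deterministic root-solve on the ratio, the 25-start
  multi-start fit over 0 < E, Ts < 1000 kPa and 0 < nu < 0.5, the
  sphincter-width sweep, and the power-law regression;
- `runPipeline()` plus a thin CLI at `inst/cli/iris-mech.R`.

## Worked example

Identify the traction-to-stiffness ratio for a measured maximum pupil
margin strain of −0.386 (the cohort mean of the study conditions the
synthetic generator emulates), sweep the physiological sphincter widths,
and fit the power law:

```r
library(irisMech)

ratioRoot(-0.386, asMm = 1)          # deterministic route, nu = 0.49
#> [1] 5.057331

fit <- fitSingle(-0.386, asMm = 1)   # the multi-start protocol
fit
#> FitResult: target -0.3860 at a_s = 1 mm; 24/25 starts accepted
#>   Ts:E slope (through origin) = 5.6818; median ratio = 5.6593

sw <- widthSweep(-0.386)
sw
#>   asMm     ratio
#> 1  0.4 11.564334
#> 2  0.7  6.879899
#> 3  1.0  5.057331
#> 4  1.3  4.114115

pl <- fitPowerLaw(sw)
c(A = pl$A, B = pl$B)
#>         A         B
#> 6.1307698 0.8957028
```

Reading: a 1 mm sphincter must pull with about 5 times the stromal Young's
modulus to produce the observed constriction; a narrow (0.4 mm) sphincter
needs about 11.6-fold, a wide (1.3 mm) one about 4.1-fold. The multi-start
slope (5.68) sits a few percent above the nu = 0.49 root because the
accepted-fit cloud spans the whole 0–0.5 Poisson box; the two routes agree
when nu is pinned. A full synthetic end-to-end run:

```r
cfg <- protocolConfig(rngSeed = 1L)
res <- runPipeline(cfg, outDir = "out",
                   stages = c("simulate", "trace", "strain", "fit"))
pupilStrainMax(res$strain)   # measured from the rendered frames
```

See `vignettes/iris-biomechanics.Rmd` for the model, its assumptions, the
numerical choices, and what the synthetic generator does and does not
emulate.

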