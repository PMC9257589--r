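#' @import methods
NULL

#' Acquisition-protocol configuration for synthetic PLR sequences
#'
#' Describes the imaging protocol emulated by [renderSequence()]: a 15 s dark
#' acclimation phase, 5 s of visible-light stimulation driving pupil
#' constriction, and 10 s of darkness with partial recovery, imaged in the
#' near infrared at a fixed frame rate and pixel scale.
#'
#' @slot durationS total protocol duration (s).
#' @slot frameRateHz acquisition frame rate (Hz).
#' @slot acclimEndS end of the dark-acclimation phase (s).
#' @slot lightEndS end of the light-stimulation phase (s).
#' @slot pixelScaleUm physical pixel size (micrometres per pixel).
#' @slot imageSizePx image width and height (pixels).
#' @slot limbusRadiusMm limbus (outer iris boundary) radius (mm); fixed in time.
#' @slot betaAcclim pupil-to-limbus radius ratio during acclimation.
#' @slot betaMin pupil-to-limbus radius ratio at maximum constriction.
#' @slot constrictionTauS time constant of light-driven constriction (s).
#' @slot recoveryTauS time constant of post-stimulus recovery (s).
#' @slot noiseSd standard deviation of additive Gaussian sensor noise
#'   (normalized intensity units).
#' @slot glintCount number of corneal-reflection glints (saturated discs,
#'   fixed in image coordinates).
#' @slot eyelidCoverageFraction fraction of the limbus diameter covered from
#'   the top by the upper eyelid.
#' @slot rngSeed integer seed controlling texture, glint placement and noise.
#' @export
setClass("ProtocolConfig",
  representation(
    durationS = "numeric", frameRateHz = "numeric",
    acclimEndS = "numeric", lightEndS = "numeric",
    pixelScaleUm = "numeric", imageSizePx = "integer",
    limbusRadiusMm = "numeric", betaAcclim = "numeric", betaMin = "numeric",
    constrictionTauS = "numeric", recoveryTauS = "numeric",
    noiseSd = "numeric", glintCount = "integer",
    eyelidCoverageFraction = "numeric", rngSeed = "integer"
  ),
  prototype(
    durationS = 30, frameRateHz = 25, acclimEndS = 15, lightEndS = 20,
    pixelScaleUm = 39, imageSizePx = c(768L, 576L), limbusRadiusMm = 6,
    betaAcclim = 0.566, betaMin = 0.262,
    constrictionTauS = 0.5, recoveryTauS = 4,
    noiseSd = 0.02, glintCount = 2L, eyelidCoverageFraction = 0.10,
    rngSeed = 1L
  )
)

setValidity("ProtocolConfig", function(object) {
  msg <- character()
  if (!(object@betaMin > 0 && object@betaMin < object@betaAcclim &&
        object@betaAcclim < 1))
    msg <- c(msg, "need 0 < betaMin < betaAcclim < 1")
  if (!(object@acclimEndS > 0 && object@acclimEndS < object@lightEndS &&
        object@lightEndS < object@durationS))
    msg <- c(msg, "invalid phase ordering: need 0 < acclimEndS < lightEndS < durationS")
  if (object@frameRateHz <= 0) msg <- c(msg, "frameRateHz must be positive")
  if (object@pixelScaleUm <= 0) msg <- c(msg, "pixelScaleUm must be positive")
  if (length(object@imageSizePx) != 2L || any(object@imageSizePx < 16L))
    msg <- c(msg, "imageSizePx must be two integers >= 16")
  if (object@constrictionTauS < 0 || object@recoveryTauS < 0)
    msg <- c(msg, "time constants must be non-negative")
  if (object@noiseSd < 0) msg <- c(msg, "noiseSd must be non-negative")
  if (object@eyelidCoverageFraction < 0 || object@eyelidCoverageFraction > 0.5)
    msg <- c(msg, "eyelidCoverageFraction must be in [0, 0.5]")
  if (length(msg)) msg else TRUE
})

#' Time-stamped grayscale frame stack
#'
#' Frames are stored as a numeric array with dimensions (width, height, time)
#' and intensities in `[0, 1]`; `frames(x)[i, j, k]` is the pixel at image
#' column `i`, row `j` (row 1 at the top) of frame `k`. Synthetic sequences
#' carry their generating configuration and closed-form ground truth in
#' `groundTruth(x)`.
#'
#' @slot frames numeric array (nx, ny, nt) of intensities in `[0, 1]`.
#' @slot times frame time stamps (s).
#' @slot phase per-frame protocol phase label
#'   (`"acclimation"`, `"light"`, `"recovery"`).
#' @slot pixelScaleUm physical pixel size (micrometres per pixel).
#' @slot groundTruth list with generator ground truth (empty for loaded data):
#'   `cfg`, `centerPx`, `pupilRadiusMm` (per frame), `rp0Mm`.
#' @export
setClass("FrameSequence",
  representation(
    frames = "array", times = "numeric", phase = "character",
    pixelScaleUm = "numeric", groundTruth = "list"
  )
)

setValidity("FrameSequence", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3L) return("frames must be a 3-d array (nx, ny, nt)")
  if (d[3] != length(object@times)) return("length(times) must equal frame count")
  if (d[3] != length(object@phase)) return("length(phase) must equal frame count")
  if (is.unsorted(object@times, strictly = TRUE)) return("times must be increasing")
  TRUE
})

#' Per-frame pupil and limbus geometry
#'
#' One row per analyzed frame: pupil centre/radius from threshold
#' segmentation, limbus centre/radius from the Daugman integro-differential
#' operator, and the pupil-to-limbus radius ratio beta. Radii are kept in
#' pixels and converted to mm via the pixel scale.
#'
#' @slot data data.frame with columns `frame`, `tS`, `xp`, `yp`, `rpPx`,
#'   `xl`, `yl`, `rlPx`, `beta`, `rpMm`, `rlMm`.
#' @slot pixelScaleUm pixel size (micrometres per pixel).
#' @slot stride analysis stride (every stride-th frame).
#' @export
setClass("PupilLimbusTrace",
  representation(data = "data.frame", pixelScaleUm = "numeric",
                 stride = "integer")
)

#' Margin-strain time course
#'
#' Lagrangian strains of the pupil margin and limbus computed from a
#' [PupilLimbusTrace-class] relative to the mean radii over the acclimation
#' phase, plus the maximum-constriction summary strain (mean over a late
#' light-phase window).
#'
#' @slot data data.frame with columns `frame`, `tS`, `epsP`, `epsL`.
#' @slot rp0Px,rl0Px reference (acclimation-mean) radii in pixels.
#' @slot epsPmax mean pupil-margin strain over the maximum-constriction window.
#' @slot maxWindow the window (s) used for `epsPmax`.
#' @export
setClass("StrainTrace",
  representation(data = "data.frame", rp0Px = "numeric", rl0Px = "numeric",
                 epsPmax = "numeric", maxWindow = "numeric")
)

#' Cumulative DIC displacement field
#'
#' Reference-grid displacement vectors accumulated over incremental
#' subset correlations, with per-point validity and a displacement-equivalent
#' match residual. Points that fail convergence or exceed the matchability
#' threshold are invalidated and never revived.
#'
#' @slot points reference grid coordinates (n x 2, px).
#' @slot disp cumulative displacements (n x 2, px).
#' @slot valid logical validity mask.
#' @slot residual per-point match residual (px).
#' @slot step grid step (px).
#' @slot subsetSize subset edge length (px, odd).
#' @slot geometry list with `center`, `rp0Px`, `rlPx` of the reference frame.
#' @slot nIncrements number of accumulated increments.
#' @export
setClass("DisplacementField",
  representation(points = "matrix", disp = "matrix", valid = "logical",
                 residual = "numeric", step = "integer", subsetSize = "integer",
                 geometry = "list", nIncrements = "integer")
)

#' Lagrangian strain field on a DIC grid
#'
#' Strain tensors from windowed least-squares fits of the displacement field,
#' in Cartesian components and rotated to polar components about the
#' reference pupil centre.
#'
#' @slot points reference grid coordinates (n x 2, px).
#' @slot strains matrix with columns `Exx`, `Eyy`, `Exy`, `Err`, `Ett`, `Ert`.
#' @slot valid logical validity mask.
#' @slot center polar origin (reference pupil centre, px).
#' @export
setClass("StrainField",
  representation(points = "matrix", strains = "matrix", valid = "logical",
                 center = "numeric")
)

#' Radial strain profile
#'
#' Median and interquartile range of strain components versus the normalized
#' radial coordinate `xbar` (0 at the pupillary margin, 1 at the limbus),
#' pooled over the nasal and temporal arms of a rectangular box through the
#' pupil centre.
#'
#' @slot data data.frame with columns `xbar`, `component`, `median`, `q1`,
#'   `q3`, `n`.
#' @slot source `"dic"` or `"model"`.
#' @export
setClass("StrainProfile",
  representation(data = "data.frame", source = "character")
)

#' Iris annulus model configuration
#'
#' Geometry, material and loading of the axisymmetric plane-stress iris model:
#' a compressible neo-Hookean annulus (Young's modulus `EkPa`, Poisson ratio
#' `nu`) with an active circumferential sphincter traction of magnitude
#' `TskPa` in the material ring `[RinMm, RinMm + asMm]`.
#'
#' @slot RinMm reference pupil radius (mm).
#' @slot RoutMm limbus radius (mm).
#' @slot thicknessMm model thickness (mm); does not affect the solution.
#' @slot asMm sphincter ring width (mm).
#' @slot EkPa stroma Young's modulus (kPa).
#' @slot nu Poisson's ratio, in (0, 0.5).
#' @slot TskPa sphincter traction magnitude (kPa).
#' @slot nElements number of 1-d finite elements.
#' @slot loadSteps number of equal load increments in `TskPa`.
#' @slot newtonTol relative Newton residual tolerance.
#' @export
setClass("IrisModelConfig",
  representation(
    RinMm = "numeric", RoutMm = "numeric", thicknessMm = "numeric",
    asMm = "numeric", EkPa = "numeric", nu = "numeric", TskPa = "numeric",
    nElements = "integer", loadSteps = "integer", newtonTol = "numeric"
  ),
  prototype(
    RinMm = 3.4, RoutMm = 6, thicknessMm = 0.17, asMm = 1,
    EkPa = 10, nu = 0.49, TskPa = 0, nElements = 200L, loadSteps = 20L,
    newtonTol = 1e-9
  )
)

setValidity("IrisModelConfig", function(object) {
  msg <- character()
  if (!(object@RinMm > 0 && object@RinMm < object@RoutMm))
    msg <- c(msg, "need 0 < RinMm < RoutMm")
  if (!(object@asMm > 0 && object@asMm <= object@RoutMm - object@RinMm))
    msg <- c(msg, "need 0 < asMm <= RoutMm - RinMm")
  if (!(object@nu > 0 && object@nu < 0.5))
    msg <- c(msg, "need 0 < nu < 0.5")
  if (object@EkPa <= 0) msg <- c(msg, "EkPa must be positive")
  if (object@TskPa < 0) msg <- c(msg, "TskPa must be non-negative")
  if (object@nElements < 8L) msg <- c(msg, "nElements must be >= 8")
  if (object@loadSteps < 1L) msg <- c(msg, "loadSteps must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Converged finite-element solution of the iris model
#'
#' Equilibrium deformation of the annulus: nodal reference and deformed radii,
#' principal stretches at element midpoints (through-thickness stretch from
#' the pointwise plane-stress condition), and the pupil-margin Lagrangian
#' strain.
#'
#' @slot config the [IrisModelConfig-class] solved.
#' @slot nodesR nodal reference radii (mm).
#' @slot r nodal deformed radii (mm).
#' @slot midR element-midpoint reference radii (mm).
#' @slot lambdaR,lambdaTheta,lambdaZ principal stretches at element midpoints.
#' @slot J Jacobian `lambdaR * lambdaTheta * lambdaZ` at midpoints.
#' @slot epsP pupil-margin Lagrangian strain `(lambdaTheta(Rin)^2 - 1)/2`.
#' @slot converged logical; whether the full load was reached.
#' @slot loadFraction fraction of `TskPa` at the last converged state.
#' @export
setClass("FESolution",
  representation(
    config = "IrisModelConfig", nodesR = "numeric", r = "numeric",
    midR = "numeric", lambdaR = "numeric", lambdaTheta = "numeric",
    lambdaZ = "numeric", J = "numeric", epsP = "numeric",
    converged = "logical", loadFraction = "numeric"
  )
)

#' Multi-start inverse identification result
#'
#' Converged local fits of (E, nu, Ts) to a target pupil-margin strain from
#' deterministic low-discrepancy starting points, with the
#' traction-to-stiffness ratio estimated as the through-origin regression
#' slope of Ts on E over the accepted fits.
#'
#' @slot starts data.frame with one row per start: initial guess, converged
#'   parameters, objective, convergence flag, accepted flag.
#' @slot slope through-origin regression slope of Ts on E (the ratio estimate).
#' @slot slopeFree free-intercept regression slope (diagnostic).
#' @slot ratioMedian median of per-fit Ts/E ratios (diagnostic).
#' @slot target target pupil-margin strain.
#' @slot asMm sphincter width used (mm).
#' @slot tol acceptance tolerance on the strain-mismatch objective.
#' @export
setClass("FitResult",
  representation(
    starts = "data.frame", slope = "numeric", slopeFree = "numeric",
    ratioMedian = "numeric", target = "numeric", asMm = "numeric",
    tol = "numeric"
  )
)
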