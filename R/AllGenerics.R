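#' @title Accessors for irisMech containers
#' @name accessors
#' @rdname accessors
#' @param x an irisMech object.
NULL

#' @describeIn accessors frame array of a [FrameSequence-class].
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @describeIn accessors frame time stamps (s).
#' @export
setGeneric("frameTimes", function(x) standardGeneric("frameTimes"))
#' @describeIn accessors number of frames.
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @describeIn accessors pixel size (micrometres per pixel).
#' @export
setGeneric("pixelScale", function(x) standardGeneric("pixelScale"))
#' @describeIn accessors generator ground truth (list; empty if not synthetic).
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @describeIn accessors per-frame protocol phase labels.
#' @export
setGeneric("protocolPhase", function(x) standardGeneric("protocolPhase"))
#' @describeIn accessors tabular payload of a trace, strain or profile object.
#' @export
setGeneric("traceData", function(x) standardGeneric("traceData"))
#' @describeIn accessors pupil-to-limbus radius ratio series.
#' @export
setGeneric("betaSeries", function(x) standardGeneric("betaSeries"))
#' @describeIn accessors maximum-constriction pupil-margin strain.
#' @export
setGeneric("pupilStrainMax", function(x) standardGeneric("pupilStrainMax"))
#' @describeIn accessors per-point validity mask.
#' @export
setGeneric("validPoints", function(x) standardGeneric("validPoints"))
#' @describeIn accessors cumulative displacement matrix (n x 2, px).
#' @export
setGeneric("displacements", function(x) standardGeneric("displacements"))
#' @describeIn accessors strain-component matrix.
#' @export
setGeneric("strainComponents", function(x) standardGeneric("strainComponents"))
#' @describeIn accessors pupil-margin Lagrangian strain of an FE solution.
#' @export
setGeneric("pupilStrain", function(x) standardGeneric("pupilStrain"))
#' @describeIn accessors traction-to-stiffness ratio estimate of a fit.
#' @export
setGeneric("ratioEstimate", function(x) standardGeneric("ratioEstimate"))

setMethod("frames", "FrameSequence", function(x) x@frames)
setMethod("frameTimes", "FrameSequence", function(x) x@times)
setMethod("nFrames", "FrameSequence", function(x) dim(x@frames)[3])
setMethod("pixelScale", "FrameSequence", function(x) x@pixelScaleUm)
setMethod("groundTruth", "FrameSequence", function(x) x@groundTruth)
setMethod("protocolPhase", "FrameSequence", function(x) x@phase)
setMethod("pixelScale", "PupilLimbusTrace", function(x) x@pixelScaleUm)
setMethod("traceData", "PupilLimbusTrace", function(x) x@data)
setMethod("betaSeries", "PupilLimbusTrace", function(x) x@data$beta)
setMethod("traceData", "StrainTrace", function(x) x@data)
setMethod("pupilStrainMax", "StrainTrace", function(x) x@epsPmax)
setMethod("validPoints", "DisplacementField", function(x) x@valid)
setMethod("displacements", "DisplacementField", function(x) x@disp)
setMethod("validPoints", "StrainField", function(x) x@valid)
setMethod("strainComponents", "StrainField", function(x) x@strains)
setMethod("traceData", "StrainProfile", function(x) x@data)
setMethod("pupilStrain", "FESolution", function(x) x@epsP)
setMethod("ratioEstimate", "FitResult", function(x) x@slope)

setMethod("show", "ProtocolConfig", function(object) {
  cat("ProtocolConfig:", object@durationS, "s at", object@frameRateHz, "Hz,",
      paste(object@imageSizePx, collapse = "x"), "px,",
      object@pixelScaleUm, "um/px\n")
  cat("  phases: dark 0-", object@acclimEndS, " s, light -", object@lightEndS,
      " s, dark -", object@durationS, " s\n", sep = "")
  cat("  beta:", object@betaAcclim, "->", object@betaMin,
      "; limbus", object@limbusRadiusMm, "mm; seed", object@rngSeed, "\n")
})

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames)
  cat("FrameSequence:", d[3], "frames of", d[1], "x", d[2], "px,",
      object@pixelScaleUm, "um/px,",
      if (length(object@groundTruth)) "synthetic (ground truth attached)"
      else "no ground truth", "\n")
})

setMethod("show", "PupilLimbusTrace", function(object) {
  d <- object@data
  ok <- is.finite(d$beta)
  cat("PupilLimbusTrace:", nrow(d), "analyzed frames (stride",
      object@stride, ");", sum(!ok), "failed\n")
  if (any(ok))
    cat(sprintf("  beta range %.3f - %.3f\n",
                min(d$beta[ok]), max(d$beta[ok])))
})

setMethod("show", "StrainTrace", function(object) {
  cat(sprintf(
    "StrainTrace: %d frames; eps_p,max = %.4f (window %g-%g s)\n",
    nrow(object@data), object@epsPmax, object@maxWindow[1], object@maxWindow[2]))
})

setMethod("show", "DisplacementField", function(object) {
  cat("DisplacementField:", nrow(object@points), "grid points (step",
      object@step, "px, subset", object@subsetSize, "px),",
      sum(object@valid), "valid after", object@nIncrements, "increments\n")
})

setMethod("show", "StrainField", function(object) {
  cat("StrainField:", nrow(object@points), "points,", sum(object@valid),
      "valid\n")
})

setMethod("show", "StrainProfile", function(object) {
  cat("StrainProfile (", object@source, "): ",
      length(unique(object@data$xbar)), " bins x ",
      length(unique(object@data$component)), " components\n", sep = "")
})

setMethod("show", "IrisModelConfig", function(object) {
  cat(sprintf(
    "IrisModelConfig: annulus %g-%g mm, a_s = %g mm, E = %g kPa, nu = %g, Ts = %g kPa\n",
    object@RinMm, object@RoutMm, object@asMm, object@EkPa, object@nu,
    object@TskPa))
})

setMethod("show", "FESolution", function(object) {
  cat(sprintf(
    "FESolution: %s at load fraction %.3f; eps_p = %.5f\n",
    if (object@converged) "converged" else "NOT converged",
    object@loadFraction, object@epsP))
})

setMethod("show", "FitResult", function(object) {
  acc <- sum(object@starts$accepted)
  cat(sprintf(
    "FitResult: target %.4f at a_s = %g mm; %d/%d starts accepted\n",
    object@target, object@asMm, acc, nrow(object@starts)))
  cat(sprintf("  Ts:E slope (through origin) = %.4f; median ratio = %.4f\n",
              object@slope, object@ratioMedian))
})
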