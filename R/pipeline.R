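#' Compare model and DIC strain profiles
#'
#' Interpolates the model medians onto the DIC profile's `xbar` support and
#' reports, per component, the RMS discrepancy of the medians and the
#' fraction of bins in which the model median lies inside the DIC
#' interquartile band.
#'
#' @param model a [StrainProfile-class] (typically `source = "model"`).
#' @param dic a [StrainProfile-class] with IQR information.
#' @return data.frame with columns `component`, `rms`, `coverage`, `nBins`.
#' @export
compareProfiles <- function(model, dic) {
  stopifnot(is(model, "StrainProfile"), is(dic, "StrainProfile"))
  md <- traceData(model); dd <- traceData(dic)
  comps <- intersect(unique(md$component), unique(dd$component))
  if (!length(comps)) stopIris("profiles share no strain components")
  rows <- lapply(comps, function(cmp) {
    m <- md[md$component == cmp & is.finite(md$median), ]
    d <- dd[dd$component == cmp & is.finite(dd$median), ]
    lo <- max(min(m$xbar), min(d$xbar)); hi <- min(max(m$xbar), max(d$xbar))
    sel <- d$xbar >= lo & d$xbar <= hi
    if (!any(sel)) stopIris("disjoint xbar supports for component ", cmp)
    mv <- stats::approx(m$xbar, m$median, xout = d$xbar[sel], rule = 2)$y
    data.frame(component = cmp,
               rms = sqrt(mean((mv - d$median[sel])^2)),
               coverage = mean(mv >= d$q1[sel] & mv <= d$q3[sel]),
               nBins = sum(sel))
  })
  do.call(rbind, rows)
}

# ROI mask for DIC on a synthetic or traced sequence: the iris annulus in
# the reference frame, away from margins, pupil and the eyelid band.
irisRoiMask <- function(dims, center, rp0Px, rlPx, marginPx = 6,
                        eyelidY = NULL) {
  x <- rep(seq_len(dims[1]), times = dims[2])
  y <- rep(seq_len(dims[2]), each = dims[1])
  r <- sqrt((x - center[1])^2 + (y - center[2])^2)
  m <- r > rp0Px + marginPx & r < rlPx - marginPx
  if (!is.null(eyelidY)) m <- m & y > eyelidY + marginPx
  matrix(m, dims[1], dims[2])
}

writeTraceCsv <- function(trace, path) {
  utils::write.csv(traceData(trace), path, row.names = FALSE)
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in order on either a synthetic configuration
#' or a user-supplied frame directory: `simulate` (render frames), `trace`
#' (pupil/limbus segmentation), `strain` (margin strains), `dic`
#' (displacement, strain field and radial profile over the constriction
#' phase), `fit` (inverse identification against the measured or supplied
#' target strain) and `sweep` (sphincter-width sweep plus power-law fit).
#' Each stage writes its artifact (CSV/JSON) into `outDir`, along with a
#' manifest recording the configuration, seed, package version and output
#' checksums; identical configuration and seed reproduce identical outputs.
#' A stage failure aborts downstream stages but preserves artifacts already
#' written.
#'
#' @param input a [ProtocolConfig-class] (synthetic run) or a directory of
#'   frames readable by [readFrameSequence()].
#' @param outDir output directory, created if needed.
#' @param stages character subset of
#'   `c("simulate", "trace", "strain", "dic", "fit", "sweep")`.
#' @param stride analysis stride for tracing.
#' @param target pupil-margin strain target for `fit`/`sweep`; defaults to
#'   the `strain` stage's measurement when available, else -0.386.
#' @param asMm sphincter width for `fit` (mm).
#' @param widths widths for `sweep` (mm).
#' @param nStarts multi-start count for `fit`.
#' @param dicStride frame stride within the light phase used for DIC.
#' @return (invisibly) a list with the in-memory stage results.
#' @export
runPipeline <- function(input, outDir,
                        stages = c("simulate", "trace", "strain", "fit"),
                        stride = 10L, target = NULL, asMm = 1,
                        widths = c(0.4, 0.7, 1.0, 1.3), nStarts = 25L,
                        dicStride = 10L) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  res <- list()
  manifest <- list(
    package = "irisMech",
    version = as.character(utils::packageVersion("irisMech")),
    rVersion = R.version.string,
    stages = stages,
    outputs = list())
  finish <- function() {
    outs <- list.files(outDir, full.names = TRUE)
    outs <- outs[!grepl("manifest\\.json$", outs)]
    manifest$outputs <- as.list(tools::md5sum(outs))
    names(manifest$outputs) <- basename(outs)
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  on.exit(finish())

  seqObj <- NULL
  if (is(input, "ProtocolConfig")) {
    manifest$config <- sapply(slotNames(input), function(s) slot(input, s),
                              simplify = FALSE)
    manifest$seed <- input@rngSeed
    if ("simulate" %in% stages) {
      seqObj <- renderSequence(input)
      res$sequence <- seqObj
    }
  } else {
    manifest$frameDir <- as.character(input)
    seqObj <- readFrameSequence(input)
    res$sequence <- seqObj
  }

  if ("trace" %in% stages) {
    if (is.null(seqObj)) stopIris("trace stage needs frames")
    res$trace <- traceSequence(seqObj, stride = stride)
    writeTraceCsv(res$trace, file.path(outDir, "trace.csv"))
  }
  if ("strain" %in% stages) {
    if (is.null(res$trace)) stopIris("strain stage needs a trace")
    res$strain <- marginStrain(res$trace)
    utils::write.csv(traceData(res$strain),
                     file.path(outDir, "strain.csv"), row.names = FALSE)
    if (is.null(target)) target <- pupilStrainMax(res$strain)
  }
  if ("dic" %in% stages) {
    if (is.null(seqObj)) stopIris("dic stage needs frames")
    gt <- groundTruth(seqObj)
    tr <- res$trace
    if (length(gt)) {
      center <- gt$centerPx
      mmPerPx <- pixelScale(seqObj) / 1000
      rp0Px <- gt$rp0Mm / mmPerPx
      rlPx <- gt$limbusRadiusPx
    } else if (!is.null(tr)) {
      d <- traceData(tr)
      first <- which(is.finite(d$rpPx))[1]
      center <- c(d$xp[first], d$yp[first])
      rp0Px <- d$rpPx[first]; rlPx <- d$rlPx[first]
    } else stopIris("dic stage needs ground truth or a trace")
    lightIdx <- which(protocolPhase(seqObj) %in% c("light", "recovery"))
    if (!length(lightIdx)) lightIdx <- seq_len(nFrames(seqObj))
    anaIdx <- lightIdx[seq(1, length(lightIdx), by = dicStride)]
    blinks <- detectBlinks(seqObj)
    anaIdx <- setdiff(anaIdx, blinks)
    mask <- irisRoiMask(dim(frames(seqObj))[1:2], center, rp0Px, rlPx)
    fld <- correlateIncremental(
      frames(seqObj)[, , anaIdx, drop = FALSE], mask,
      geometry = list(center = center, rp0Px = rp0Px, rlPx = rlPx))
    sf <- computeStrainField(fld)
    prof <- extractProfile(sf, rp0Px, rlPx)
    res$dic <- list(field = fld, strainField = sf, profile = prof)
    utils::write.csv(traceData(prof), file.path(outDir, "profiles.csv"),
                     row.names = FALSE)
  }
  if ("fit" %in% stages) {
    tgt <- if (is.null(target)) -0.386 else target
    fit <- fitSingle(tgt, asMm = asMm, nStarts = nStarts)
    res$fit <- fit
    jsonlite::write_json(
      list(target = tgt, asMm = asMm, slope = fit@slope,
           slopeFree = fit@slopeFree, ratioMedian = fit@ratioMedian,
           nAccepted = sum(fit@starts$accepted), nStarts = nrow(fit@starts)),
      file.path(outDir, "fit.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  if ("sweep" %in% stages) {
    tgt <- if (is.null(target)) -0.386 else target
    sw <- widthSweep(tgt, widths = widths)
    pl <- fitPowerLaw(sw)
    res$sweep <- sw; res$powerLaw <- pl
    jsonlite::write_json(
      list(target = tgt, widths = sw$asMm, ratios = sw$ratio,
           A = pl$A, B = pl$B, ciA = pl$ciA, ciB = pl$ciB),
      file.path(outDir, "sweep.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  invisible(res)
}
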