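#' Create an acquisition-protocol configuration
#'
#' Defaults emulate the study conditions of the near-infrared pupillary light
#' reflex (PLR) recordings the package targets: 30 s at 25 Hz and 768 x 576 px
#' (~39 um/px), a 15 s dark-acclimation phase, 5 s of light driving pupil
#' constriction from beta = 0.566 to beta = 0.262 of the (fixed, 6 mm) limbus
#' radius, then 10 s of darkness with partial recovery.
#'
#' @param ... named values overriding any [ProtocolConfig-class] slot
#'   (e.g. `durationS`, `noiseSd`, `rngSeed`).
#' @return A validated [ProtocolConfig-class] object.
#' @examples
#' cfg <- protocolConfig(noiseSd = 0, glintCount = 0L)
#' generatePLRTimecourse(cfg, times = c(0, 10, 20))
#' @export
protocolConfig <- function(...) {
  args <- list(...)
  for (nm in c("imageSizePx", "glintCount", "rngSeed"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("ProtocolConfig"), args))
}

#' Ground-truth pupil-radius time course (mm)
#'
#' Piecewise series: constant at `betaAcclim * limbusRadiusMm` during
#' acclimation; exponential decay toward `betaMin * limbusRadiusMm` with time
#' constant `constrictionTauS` during light; exponential recovery toward the
#' acclimation radius with time constant `recoveryTauS` during the final dark
#' phase. Because the recovery phase is truncated at `durationS`, the pupil
#' never regains its acclimation radius (partial recovery).
#'
#' @param cfg a [ProtocolConfig-class].
#' @param times evaluation times in seconds; defaults to the frame times.
#' @return numeric vector of pupil radii (mm).
#' @export
generatePLRTimecourse <- function(cfg, times = NULL) {
  stopifnot(is(cfg, "ProtocolConfig"))
  validObject(cfg)
  if (is.null(times)) {
    nt <- round(cfg@durationS * cfg@frameRateHz)
    times <- (seq_len(nt) - 1) / cfg@frameRateHz
  }
  rl <- cfg@limbusRadiusMm
  rp0 <- cfg@betaAcclim * rl
  rmin <- cfg@betaMin * rl
  decay <- function(dt, tau) if (tau <= 0) rep(0, length(dt)) else exp(-dt / tau)
  r <- rep(rp0, length(times))
  inLight <- times >= cfg@acclimEndS & times < cfg@lightEndS
  r[inLight] <- rmin + (rp0 - rmin) *
    decay(times[inLight] - cfg@acclimEndS, cfg@constrictionTauS)
  inRec <- times >= cfg@lightEndS
  r20 <- rmin + (rp0 - rmin) *
    decay(cfg@lightEndS - cfg@acclimEndS, cfg@constrictionTauS)
  r[inRec] <- rp0 - (rp0 - r20) *
    decay(times[inRec] - cfg@lightEndS, cfg@recoveryTauS)
  r
}

#' Ground-truth kinematic map of the iris annulus
#'
#' Maps reference radius `R` (mm) at time `t` (s) to the deformed radius,
#' interpolating linearly in `R` between the moving pupil margin and the fixed
#' limbus:
#' `r(R, t) = r_p(t) + (R - r_p0) * (r_l - r_p(t)) / (r_l - r_p0)`.
#' The radial stretch `(r_l - r_p(t)) / (r_l - r_p0)` is therefore spatially
#' uniform and all Lagrangian strains have closed form (see
#' [groundTruthStrains()]).
#'
#' @param R reference radii (mm), inside `[r_p0, r_l]`.
#' @param t a single time (s).
#' @param cfg a [ProtocolConfig-class].
#' @return deformed radii (mm).
#' @export
kinematicMap <- function(R, t, cfg) {
  stopifnot(is(cfg, "ProtocolConfig"), length(t) == 1L)
  rl <- cfg@limbusRadiusMm
  rp0 <- cfg@betaAcclim * rl
  if (any(R < rp0 - 1e-9 | R > rl + 1e-9))
    stopIris("reference radius outside the iris annulus [", rp0, ", ", rl, "] mm")
  rp <- generatePLRTimecourse(cfg, times = t)
  rp + (R - rp0) * (rl - rp) / (rl - rp0)
}

#' Closed-form ground-truth Lagrangian strains
#'
#' For the linear-in-R kinematic map the radial stretch is uniform,
#' `lambda_r = (r_l - r_p(t)) / (r_l - r_p0)`, and the hoop stretch is
#' `lambda_theta = r(R, t) / R`, so `E_rr = (lambda_r^2 - 1)/2`,
#' `E_tt = (lambda_theta^2 - 1)/2` and `E_rt = 0`.
#'
#' @inheritParams kinematicMap
#' @return data.frame with columns `R`, `r`, `lambdaR`, `lambdaTheta`,
#'   `Err`, `Ett`, `Ert`.
#' @export
groundTruthStrains <- function(R, t, cfg) {
  rl <- cfg@limbusRadiusMm
  rp0 <- cfg@betaAcclim * rl
  r <- kinematicMap(R, t, cfg)
  rp <- generatePLRTimecourse(cfg, times = t)
  lr <- (rl - rp) / (rl - rp0)
  lt <- r / R
  data.frame(R = R, r = r, lambdaR = lr, lambdaTheta = lt,
             Err = 0.5 * (lr^2 - 1), Ett = 0.5 * (lt^2 - 1), Ert = 0)
}

# Multiscale speckle texture on a reference polar grid (rows = R, cols =
# theta), periodic in theta. Features are mildly elongated along R to mimic
# iridial crypts and furrows.
makeIrisTexture <- function(nR, nTheta) {
  scales <- list(c(5, 1.6), c(12, 4), c(26, 9))
  weights <- c(1, 0.65, 0.45)
  z <- matrix(0, nR, nTheta)
  for (k in seq_along(scales)) {
    field <- matrix(stats::rnorm(nR * nTheta), nR, nTheta)
    z <- z + weights[k] *
      periodicSmooth2d(field, scales[[k]][1], scales[[k]][2]) *
      (scales[[k]][1] * scales[[k]][2])   # undo kernel attenuation roughly
  }
  z <- z / stats::sd(z)
  pmin(pmax(0.45 + 0.15 * z, 0.17), 0.85)
}

#' Render a synthetic NIR PLR frame sequence
#'
#' Draws, per frame, a dark pupil disc (intensity ~0.05), a speckle-textured
#' iris annulus advected by the ground-truth kinematic map (with bicubic
#' intensity interpolation in reference polar coordinates), and a bright
#' sclera; optionally adds Gaussian sensor noise, saturated corneal glints
#' fixed in image coordinates (they do not advect with the tissue), and an
#' upper-eyelid occlusion band. Output is fully determined by `cfg`
#' (including `rngSeed`).
#'
#' @param cfg a [ProtocolConfig-class].
#' @param map optional kinematic override: a `function(R, t)` returning the
#'   deformed radius (mm) of reference radius `R` (mm) at time `t` (s).
#'   Defaults to the linear-in-R map of [kinematicMap()]. Used, e.g., to
#'   render a sequence following a finite-element solution's kinematics.
#' @return a [FrameSequence-class] with ground truth attached.
#' @export
renderSequence <- function(cfg, map = NULL) {
  stopifnot(is(cfg, "ProtocolConfig"))
  validObject(cfg)
  nx <- cfg@imageSizePx[1]; ny <- cfg@imageSizePx[2]
  rlPx <- cfg@limbusRadiusMm * 1000 / cfg@pixelScaleUm
  if (2 * rlPx + 8 > min(nx, ny))
    stopIris("image too small for the limbus radius at this pixel scale (",
             "need >= ", ceiling(2 * rlPx + 8), " px, have ", min(nx, ny), ")")
  nt <- round(cfg@durationS * cfg@frameRateHz)
  times <- (seq_len(nt) - 1) / cfg@frameRateHz
  phase <- ifelse(times < cfg@acclimEndS, "acclimation",
                  ifelse(times < cfg@lightEndS, "light", "recovery"))
  rl <- cfg@limbusRadiusMm
  rp0 <- cfg@betaAcclim * rl
  rpSeries <- generatePLRTimecourse(cfg, times)
  center <- c((nx + 1) / 2, (ny + 1) / 2)
  mmPerPx <- cfg@pixelScaleUm / 1000

  withSeed(cfg@rngSeed, {
    nRtex <- max(64L, ceiling(2 * (rlPx - rp0 / mmPerPx)))
    nTtex <- max(256L, ceiling(2 * pi * rlPx))
    tex <- makeIrisTexture(nRtex, nTtex)
    if (cfg@glintCount > 0L) {
      gAng <- stats::runif(cfg@glintCount, 0, 2 * pi)
      gRad <- stats::runif(cfg@glintCount, 0.35, 0.8) * rlPx
      glints <- cbind(x = center[1] + gRad * cos(gAng),
                      y = center[2] + gRad * sin(gAng),
                      r = stats::runif(cfg@glintCount, 2, 3.5))
    } else glints <- NULL

    px <- rep(seq_len(nx), times = ny)
    py <- rep(seq_len(ny), each = nx)
    dx <- px - center[1]; dy <- py - center[2]
    radPx <- sqrt(dx^2 + dy^2)
    theta <- atan2(dy, dx)
    radMm <- radPx * mmPerPx
    inIris <- radMm < rl + 1.5 * mmPerPx
    eyelidY <- center[2] - rlPx * (1 - 2 * cfg@eyelidCoverageFraction)
    nT <- ncol(tex)
    texWrap <- cbind(tex[, nT - 1], tex[, nT], tex, tex[, 1], tex[, 2])
    frames <- array(0, dim = c(nx, ny, nt))

    for (k in seq_len(nt)) {
      rp <- rpSeries[k]
      img <- rep(0.88, nx * ny)                       # sclera
      idx <- which(inIris)
      rI <- radMm[idx]
      # invert the kinematic map: reference radius of each deformed pixel
      if (is.null(map)) {
        Rref <- rp0 + (rI - rp) * (rl - rp0) / (rl - rp)
      } else {
        # generic monotone map: invert by interpolation on a fine R grid
        Rg <- seq(rp0, rl, length.out = 512)
        rg <- map(Rg, times[k])
        Rref <- stats::approx(rg, Rg, xout = rI, rule = 2)$y
      }
      texR <- 1 + (Rref - rp0) / (rl - rp0) * (nRtex - 1)
      texT <- 3 + ((theta[idx] + pi) / (2 * pi)) * nTtex
      val <- cubicAt(texWrap, texR, texT, fill = 0.45)
      # blend pupil (dark) and sclera at the margins over ~1.5 px
      wPup <- pmin(pmax((rI - rp) / (1.5 * mmPerPx), 0), 1)
      wScl <- pmin(pmax((rl - rI) / (1.5 * mmPerPx), 0), 1)
      img[idx] <- 0.05 + wPup * (val - 0.05)
      img[idx] <- img[idx] + (1 - wScl) * (0.88 - img[idx])
      if (!is.null(glints)) {
        for (g in seq_len(nrow(glints))) {
          gi <- which((px - glints[g, "x"])^2 + (py - glints[g, "y"])^2 <=
                        glints[g, "r"]^2)
          img[gi] <- 1
        }
      }
      if (cfg@eyelidCoverageFraction > 0)
        img[py <= eyelidY] <- 0.72
      if (cfg@noiseSd > 0)
        img <- img + stats::rnorm(nx * ny, sd = cfg@noiseSd)
      frames[, , k] <- pmin(pmax(img, 0), 1)
    }

    new("FrameSequence", frames = frames, times = times, phase = phase,
        pixelScaleUm = cfg@pixelScaleUm,
        groundTruth = list(cfg = cfg, centerPx = center,
                           pupilRadiusMm = rpSeries, rp0Mm = rp0,
                           limbusRadiusPx = rlPx))
  })
}

#' Write a frame sequence to disk
#'
#' Writes zero-padded numbered grayscale PNG (or multi-page-equivalent
#' numbered TIFF) frames plus a `sidecar.json` holding the configuration,
#' seed, frame times and the ground-truth pupil-radius series.
#'
#' @param seq a [FrameSequence-class].
#' @param dir output directory (created if needed).
#' @param format `"png"` or `"tiff"`.
#' @return `dir`, invisibly.
#' @export
writeFrameSequence <- function(seq, dir, format = c("png", "tiff")) {
  format <- match.arg(format)
  if (format == "tiff" && !requireNamespace("tiff", quietly = TRUE))
    stopIris("the 'tiff' package is required for format = \"tiff\"")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nt <- nFrames(seq)
  fmt <- paste0("frame_%0", max(4, nchar(nt)), "d.", format)
  for (k in seq_len(nt)) {
    img <- t(frames(seq)[, , k])      # writers expect rows = image rows
    path <- file.path(dir, sprintf(fmt, k))
    if (format == "png") png::writePNG(img, path)
    else tiff::writeTIFF(img, path)
  }
  gt <- groundTruth(seq)
  side <- list(times = frameTimes(seq), phase = protocolPhase(seq),
               pixelScaleUm = pixelScale(seq))
  if (length(gt)) {
    cfg <- gt$cfg
    side$config <- sapply(slotNames(cfg), function(s) slot(cfg, s),
                          simplify = FALSE)
    side$pupilRadiusMm <- gt$pupilRadiusMm
    side$centerPx <- gt$centerPx
  }
  jsonlite::write_json(side, file.path(dir, "sidecar.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a frame sequence from a directory of grayscale images
#'
#' Frames are read in lexicographic order. If a `sidecar.json` written by
#' [writeFrameSequence()] is present, times, phase labels, pixel scale and
#' ground truth are restored from it; otherwise they are derived from
#' `frameRateHz` and `pixelScaleUm`.
#'
#' @param dir directory containing `.png` or `.tif(f)` frames.
#' @param frameRateHz frame rate used when no sidecar is present.
#' @param pixelScaleUm pixel scale used when no sidecar is present.
#' @return a [FrameSequence-class].
#' @export
readFrameSequence <- function(dir, frameRateHz = 25, pixelScaleUm = 39) {
  files <- sort(list.files(dir, pattern = "\\.(png|tif|tiff)$",
                           full.names = TRUE, ignore.case = TRUE))
  if (!length(files)) stopIris("no PNG/TIFF frames found in ", dir)
  readOne <- function(f) {
    img <- if (grepl("\\.png$", f, ignore.case = TRUE)) png::readPNG(f)
    else {
      if (!requireNamespace("tiff", quietly = TRUE))
        stopIris("the 'tiff' package is required to read TIFF frames")
      tiff::readTIFF(f)
    }
    if (length(dim(img)) == 3L) img <- img[, , 1]
    t(img)                             # back to [x, y]
  }
  imgs <- lapply(files, readOne)
  arr <- array(unlist(imgs), dim = c(dim(imgs[[1]]), length(imgs)))
  sidePath <- file.path(dir, "sidecar.json")
  if (file.exists(sidePath)) {
    side <- jsonlite::read_json(sidePath, simplifyVector = TRUE)
    gt <- list()
    if (!is.null(side$config)) {
      cfg <- do.call(protocolConfig, side$config)
      gt <- list(cfg = cfg, centerPx = side$centerPx,
                 pupilRadiusMm = side$pupilRadiusMm,
                 rp0Mm = cfg@betaAcclim * cfg@limbusRadiusMm,
                 limbusRadiusPx = cfg@limbusRadiusMm * 1000 / cfg@pixelScaleUm)
    }
    new("FrameSequence", frames = arr, times = as.numeric(side$times),
        phase = as.character(side$phase),
        pixelScaleUm = as.numeric(side$pixelScaleUm), groundTruth = gt)
  } else {
    nt <- dim(arr)[3]
    times <- (seq_len(nt) - 1) / frameRateHz
    new("FrameSequence", frames = arr, times = times,
        phase = rep("unknown", nt), pixelScaleUm = pixelScaleUm,
        groundTruth = list())
  }
}
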