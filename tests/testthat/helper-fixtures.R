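# Shared fixtures, built once per test run and cached.
#
# Two synthetic scales are used:
#  - "small": 220x190 px at 78 um/px (limbus 77 px), 1 Hz — cheap, used for
#    segmentation/trace tests;
#  - "dic": 330x330 px at the study pixel scale 39 um/px (limbus 154 px),
#    2.5 Hz, slowed constriction (tau 2 s) so consecutive analyzed frames
#    stay within the correlation search range — used for DIC accuracy tests.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (!exists(name, envir = .fixtures)) assign(name, build(), envir = .fixtures)
  get(name, envir = .fixtures)
}

cleanSmallCfg <- function(...) {
  base <- list(noiseSd = 0, glintCount = 0L, eyelidCoverageFraction = 0,
               frameRateHz = 1, pixelScaleUm = 78,
               imageSizePx = c(220L, 190L), rngSeed = 11L)
  over <- list(...)
  do.call(protocolConfig, utils::modifyList(base, over))
}

smallSeq <- function() memo("smallSeq", function() renderSequence(cleanSmallCfg()))

smallTrace <- function() memo("smallTrace", function()
  traceSequence(smallSeq(), stride = 1L))

dicCfg <- function() {
  protocolConfig(noiseSd = 0.005, glintCount = 0L, eyelidCoverageFraction = 0,
                 frameRateHz = 2.5, constrictionTauS = 2.0, pixelScaleUm = 39,
                 imageSizePx = c(330L, 330L), rngSeed = 7L)
}

dicGeometry <- function(seq) {
  gt <- groundTruth(seq)
  mmPerPx <- pixelScale(seq) / 1000
  list(center = gt$centerPx, rp0Px = gt$rp0Mm / mmPerPx,
       rlPx = gt$limbusRadiusPx, mmPerPx = mmPerPx, gt = gt)
}

# Annular ROI restricted to lateral (nasal-temporal) sectors, kept
# subset/2 + margin inside both the pupil margin and the limbus.
lateralMask <- function(dims, geo, marginPx = 19, sectorDeg = 35) {
  x <- rep(seq_len(dims[1]), times = dims[2])
  y <- rep(seq_len(dims[2]), each = dims[1])
  r <- sqrt((x - geo$center[1])^2 + (y - geo$center[2])^2)
  ang <- abs(atan2(y - geo$center[2], x - geo$center[1]))
  lat <- ang < sectorDeg * pi / 180 | ang > pi - sectorDeg * pi / 180
  matrix(r > geo$rp0Px + marginPx & r < geo$rlPx - marginPx & lat,
         dims[1], dims[2])
}

# Rendered sequence + DIC over the constriction phase, with ground truth.
dicFixture <- function() memo("dicFixture", function() {
  cfg <- dicCfg()
  seq <- renderSequence(cfg)
  geo <- dicGeometry(seq)
  idx <- which(frameTimes(seq) >= 14.7 & frameTimes(seq) <= 19.01)
  mask <- lateralMask(dim(frames(seq))[1:2], geo)
  fld <- correlateIncremental(frames(seq)[, , idx], mask,
                              geometry = geo[c("center", "rp0Px", "rlPx")])
  tEnd <- frameTimes(seq)[idx[length(idx)]]
  pts <- fld@points
  Rpx <- sqrt((pts[, 1] - geo$center[1])^2 + (pts[, 2] - geo$center[2])^2)
  scale <- (kinematicMap(Rpx * geo$mmPerPx, tEnd, cfg) / geo$mmPerPx) / Rpx
  uTrue <- cbind((pts[, 1] - geo$center[1]) * (scale - 1),
                 (pts[, 2] - geo$center[2]) * (scale - 1))
  lrTrue <- (cfg@limbusRadiusMm - geo$gt$pupilRadiusMm[idx[length(idx)]]) /
    (cfg@limbusRadiusMm - geo$gt$rp0Mm)
  list(cfg = cfg, seq = seq, geo = geo, idx = idx, mask = mask, field = fld,
       tEnd = tEnd, uTrue = uTrue, ErrTrue = 0.5 * (lrTrue^2 - 1))
})

# Full-box multi-start inverse fit at the study target (reused by several
# tests; deterministic).
fullFit <- function() memo("fullFit", function()
  fitSingle(-0.386, asMm = 1, nStarts = 25L))

# Deterministic width sweep + power law at the study target.
studySweep <- function() memo("studySweep", function()
  widthSweep(-0.386))

# Closed-form solution of the linearized (small-strain) plane-stress annulus
# with a uniform active hoop stress Ts in [Rin, Rin + as]: independent oracle
# for the finite-strain solver. Returns u(Rin).
linearAnnulusOracle <- function(Rin, Rout, as_, E, nu, Ts) {
  C <- E / (1 - nu^2)
  k <- Ts / (2 * C)
  Rm <- Rin + as_
  # u1 = a1 r + b1 / r + k r log r  on [Rin, Rm];  u2 = a2 r + b2 / r
  # rows: sigma_rr(Rin) = 0; u1(Rm) = u2(Rm); sigma_rr cont.; u2(Rout) = 0
  srr1 <- function(r) c((1 + nu), -(1 - nu) / r^2, 0, 0)
  srr1rhs <- function(r) -k * ((log(r) + 1) + nu * log(r))
  A <- rbind(
    c(srr1(Rin)[1:2], 0, 0),
    c(Rm, 1 / Rm, -Rm, -1 / Rm),
    c((1 + nu), -(1 - nu) / Rm^2, -(1 + nu), (1 - nu) / Rm^2),
    c(0, 0, Rout, 1 / Rout))
  b <- c(srr1rhs(Rin), -k * Rm * log(Rm), srr1rhs(Rm), 0)
  coefs <- solve(A, b)
  coefs[1] * Rin + coefs[2] / Rin + k * Rin * log(Rin)
}

expect_rel <- function(value, expected, tol) {
  expect_lt(abs(value - expected), tol * abs(expected))
}
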