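test_that("pupil-radius time course follows the three protocol phases", {
  cfg <- cleanSmallCfg()
  r <- generatePLRTimecourse(cfg, times = c(0, 7.5, 14.9))
  expect_equal(r, rep(0.566 * 6, 3), tolerance = 1e-12)

  # instantaneous constriction limit: exactly beta_min * r_l at light end
  cfg0 <- cleanSmallCfg(constrictionTauS = 0)
  expect_equal(generatePLRTimecourse(cfg0, times = 20), 0.262 * 6)

  # bounded by the acclimation radius at all times; recovery is partial
  tt <- seq(0, 29.99, by = 0.01)
  rAll <- generatePLRTimecourse(cfg, times = tt)
  expect_true(all(rAll <= 0.566 * 6 + 1e-12))
  expect_lt(rAll[length(rAll)], 0.566 * 6)
  expect_gt(rAll[length(rAll)], 0.262 * 6)
})

test_that("invalid phase ordering is rejected at construction", {
  expect_error(protocolConfig(acclimEndS = 21, lightEndS = 20),
               "phase ordering")
  expect_error(protocolConfig(betaAcclim = 0.2, betaMin = 0.3),
               "betaMin")
})

test_that("kinematic map fixes the limbus and tracks the pupil margin", {
  cfg <- cleanSmallCfg()
  rp0 <- 0.566 * 6
  for (t in c(0, 16, 19, 25)) {
    expect_equal(kinematicMap(6, t, cfg), 6, tolerance = 1e-12)
    expect_equal(kinematicMap(rp0, t, cfg),
                 generatePLRTimecourse(cfg, times = t), tolerance = 1e-12)
  }
  expect_error(kinematicMap(1.0, 16, cfg), "annulus")
  expect_error(kinematicMap(6.5, 16, cfg), "annulus")
})

test_that("ground-truth strains are closed-form and self-consistent", {
  # pupil constricted to 0.4775 of its reference radius: hoop strain at the
  # margin is (0.4775^2 - 1) / 2 = -0.386
  cfg <- cleanSmallCfg(betaMin = 0.4775 * 0.566, constrictionTauS = 0)
  gtv <- groundTruthStrains(0.566 * 6, 19, cfg)
  expect_equal(gtv$Ett, 0.5 * (0.4775^2 - 1), tolerance = 1e-9)
  expect_equal(gtv$Ett, -0.386, tolerance = 1e-3)

  # E_rr = (lambda_r^2 - 1)/2 with lambda_r the numerical radial derivative
  cfg2 <- cleanSmallCfg()
  R <- seq(0.566 * 6 + 0.1, 5.9, length.out = 7)
  for (t in c(16, 18, 24)) {
    g <- groundTruthStrains(R, t, cfg2)
    h <- 1e-5
    lrNum <- (kinematicMap(R + h, t, cfg2) - kinematicMap(R - h, t, cfg2)) /
      (2 * h)
    expect_equal(g$lambdaR, lrNum, tolerance = 1e-8)
    expect_equal(g$Err, 0.5 * (lrNum^2 - 1), tolerance = 1e-8)
    expect_true(all(g$Ert == 0))
    # radial stretch is spatially uniform
    expect_lt(diff(range(g$lambdaR)), 1e-12)
  }
})

test_that("rendering is deterministic and respects the protocol", {
  cfg <- cleanSmallCfg(frameRateHz = 0.5)
  s1 <- renderSequence(cfg)
  s2 <- renderSequence(cfg)
  expect_identical(frames(s1), frames(s2))
  expect_equal(nFrames(s1), round(30 * 0.5))
  expect_equal(dim(frames(s1))[1:2], c(220L, 190L))
  expect_equal(protocolPhase(s1)[1], "acclimation")

  # noiseless acclimation frames are identical
  accl <- which(protocolPhase(s1) == "acclimation")
  expect_true(length(accl) >= 2)
  expect_identical(frames(s1)[, , accl[1]], frames(s1)[, , accl[2]])

  # pixels at and beyond the limbus are stationary in every frame
  gt <- groundTruth(s1)
  nx <- dim(frames(s1))[1]; ny <- dim(frames(s1))[2]
  x <- rep(seq_len(nx), times = ny); y <- rep(seq_len(ny), each = nx)
  ring <- sqrt((x - gt$centerPx[1])^2 + (y - gt$centerPx[2])^2) >=
    gt$limbusRadiusPx
  f1 <- as.vector(frames(s1)[, , 1])[ring]
  for (k in 2:nFrames(s1))
    expect_equal(as.vector(frames(s1)[, , k])[ring], f1, tolerance = 1e-12)
})

test_that("rendering rejects an image too small for the limbus", {
  expect_error(
    renderSequence(cleanSmallCfg(imageSizePx = c(100L, 100L))),
    "image too small")
})

test_that("frame sequences round-trip through PNG directories", {
  cfg <- cleanSmallCfg(frameRateHz = 0.1)
  s <- renderSequence(cfg)
  dir <- withr::local_tempdir()
  writeFrameSequence(s, dir)
  expect_true(file.exists(file.path(dir, "sidecar.json")))
  s2 <- readFrameSequence(dir)
  expect_equal(nFrames(s2), nFrames(s))
  expect_equal(frameTimes(s2), frameTimes(s))
  expect_equal(pixelScale(s2), pixelScale(s))
  # 8-bit quantization on disk
  expect_lt(max(abs(frames(s2) - frames(s))), 1 / 254)
  gt <- groundTruth(s2)
  expect_equal(gt$pupilRadiusMm, groundTruth(s)$pupilRadiusMm,
               tolerance = 1e-8)
})
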