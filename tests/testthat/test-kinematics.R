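mkTrace <- function(tS, rpPx, rlPx = rep(100, length(tS))) {
  d <- data.frame(frame = seq_along(tS), tS = tS, xp = 0, yp = 0,
                  rpPx = rpPx, xl = 0, yl = 0, rlPx = rlPx,
                  beta = rpPx / rlPx, rpMm = NA_real_, rlMm = NA_real_)
  new("PupilLimbusTrace", data = d, pixelScaleUm = 39, stride = 1L)
}

test_that("margin strain follows the Lagrangian radius-ratio formula", {
  tS <- seq(0, 29, by = 1)
  # constant radius: zero strain everywhere
  st <- marginStrain(mkTrace(tS, rep(50, 30)))
  expect_equal(traceData(st)$epsP, rep(0, 30), tolerance = 1e-12)
  expect_equal(pupilStrainMax(st), 0, tolerance = 1e-12)

  # known ratios: r/r0 = 0.4775 -> -0.386; r/r0 = sqrt(3) -> +1
  rp <- c(rep(50, 16), rep(50 * 0.4775, 14))
  st2 <- marginStrain(mkTrace(tS, rp))
  expect_equal(pupilStrainMax(st2), 0.5 * (0.4775^2 - 1), tolerance = 1e-12)
  expect_equal(pupilStrainMax(st2), -0.386, tolerance = 1e-3)
  st3 <- marginStrain(mkTrace(tS, c(rep(50, 16), rep(50 * sqrt(3), 14))))
  expect_equal(pupilStrainMax(st3), 1, tolerance = 1e-12)
})

test_that("the strain formula round-trips to machine precision", {
  eps <- c(-0.45, -0.386, -0.1, 0, 0.3, 1)
  r0 <- 57.3
  r <- r0 * sqrt(1 + 2 * eps)
  st <- marginStrain(mkTrace(seq(0, 29, length.out = 6 + 15),
                             c(rep(r0, 15), r)))
  got <- traceData(st)$epsP[16:21]
  expect_equal(got, eps, tolerance = 1e-12)
  expect_equal(r / r0, sqrt(1 + 2 * got), tolerance = 1e-12)
})

test_that("an empty acclimation window is an error", {
  expect_error(marginStrain(mkTrace(c(20, 21, 22), c(30, 30, 30))),
               "no reference state")
})

test_that("the three-sigma screen excludes only gross outliers", {
  expect_length(qcOutliers(rep(-0.38, 10))$excluded, 0)

  x <- c(rep(-0.38, 20) + seq(-0.01, 0.01, length.out = 20), 0.9)
  qc <- qcOutliers(x)
  expect_equal(qc$excluded, 21L)

  expect_length(qcOutliers(c(-0.40, -0.38, -0.39, -0.37))$excluded, 0)
  expect_warning(qcOutliers(c(1, 2)), "fewer than 3")
})

test_that("cohort summaries average test-retest scans per eye first", {
  s1 <- summarizeStrains(-0.4, eye = "A")
  expect_equal(s1$mean, -0.4)
  expect_equal(s1$sd, 0)

  s2 <- summarizeStrains(c(-0.3, -0.5, -0.2), eye = c("A", "A", "B"))
  expect_equal(sort(s2$perEye$value), c(-0.4, -0.2))
  expect_equal(s2$mean, mean(c(-0.4, -0.2)))
  expect_equal(s2$n, 2L)

  # sampling check: cohort mean of a simulated population recovers the
  # generating mean within its own confidence interval
  set.seed(402)
  x <- rnorm(40, mean = -0.386, sd = 0.031)
  s3 <- summarizeStrains(x, eye = seq_along(x))
  expect_true(s3$ciLower <= -0.386 && -0.386 <= s3$ciUpper)
})

test_that("limbus strain on clean synthetic data is negligible", {
  st <- marginStrain(smallTrace())
  expect_lt(max(abs(traceData(st)$epsL)), 0.02)
})

test_that("measured maximum pupil strain matches the generator", {
  st <- marginStrain(smallTrace())
  cfg <- groundTruth(smallSeq())$cfg
  rpTrue <- generatePLRTimecourse(cfg, times = traceData(st)$tS)
  win <- traceData(st)$tS >= 17 & traceData(st)$tS <= 20
  epsTrue <- mean(0.5 * ((rpTrue[win] / (0.566 * 6))^2 - 1))
  expect_rel(pupilStrainMax(st), epsTrue, 0.05)
})
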