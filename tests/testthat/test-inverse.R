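test_that("Halton starting points are deterministic and space-filling", {
  h <- irisMech:::haltonSeq(6, 3)
  expect_equal(h[, 1], c(1, 1, 3, 1, 5, 3) / c(2, 4, 4, 8, 8, 8))
  expect_equal(h[1:3, 2], c(1 / 3, 2 / 3, 1 / 9))
  expect_identical(h, irisMech:::haltonSeq(6, 3))
  expect_true(all(h > 0 & h < 1))
})

test_that("ratio root-solve is exact on forward-generated targets", {
  expect_equal(ratioRoot(0), 0)
  expect_error(ratioRoot(0.2), "target strain")

  for (rhoStar in c(0.5, 3, 9)) {
    eps <- pupilStrain(solveIris(irisModelConfig(
      EkPa = 1, TskPa = rhoStar, nu = 0.49, asMm = 1, nElements = 200L,
      loadSteps = max(10L, ceiling(2 * rhoStar)))))
    expect_rel(ratioRoot(eps, asMm = 1, nu = 0.49), rhoStar, 1e-3)
  }
})

test_that("multi-start identification recovers a known ratio", {
  # target generated by the forward model at Ts:E = 3; nu pinned near the
  # generating value (nu itself is unidentifiable from pupil strain)
  eps <- pupilStrain(solveIris(irisModelConfig(
    EkPa = 1, TskPa = 3, nu = 0.49, asMm = 1, nElements = 100L)))
  fit <- fitSingle(eps, asMm = 1,
                   bounds = list(E = c(0, 1000), nu = c(0.47, 0.5),
                                 Ts = c(0, 1000)),
                   nStarts = 10L)
  expect_rel(ratioEstimate(fit), 3, 0.02)

  # and the optimizer-free root agrees with the multi-start slope
  expect_rel(ratioRoot(eps, asMm = 1, nu = 0.49), ratioEstimate(fit), 0.02)
})

test_that("a vanishing target needs vanishing traction", {
  expect_lt(ratioRoot(-1e-4, asMm = 1), 0.01)
})

test_that("every Poisson ratio admits an equally good fit", {
  # nu is unidentifiable: the strain target is met exactly at any nu, and
  # the implied ratio decreases smoothly with nu
  ratios <- vapply(c(0.05, 0.25, 0.45), function(nu) {
    rho <- ratioRoot(-0.386, asMm = 1, nu = nu, nElements = 100L)
    eps <- pupilStrain(solveIris(irisModelConfig(
      EkPa = 1, TskPa = rho, nu = nu, asMm = 1, nElements = 100L,
      loadSteps = max(10L, ceiling(2 * rho)))))
    expect_lt(abs(eps - (-0.386)), 1e-5)
    rho
  }, numeric(1))
  expect_true(all(diff(ratios) < 0))
})

test_that("accepted fits are strongly collinear in (E, Ts)", {
  fit <- fullFit()
  acc <- fit@starts[fit@starts$accepted, ]
  expect_gte(nrow(acc), 15)
  expect_gt(cor(acc$Ts, acc$E), 0.95)
  # through-origin and free-intercept slopes agree (scale invariance)
  expect_rel(fit@slopeFree, fit@slope, 0.15)
})

test_that("the traction ratio decreases strictly with sphincter width", {
  sw <- studySweep()
  expect_equal(sw$asMm, c(0.4, 0.7, 1.0, 1.3))
  expect_true(all(diff(sw$ratio) < 0))

  # round trip: a target generated at one width is recovered at that width
  eps <- pupilStrain(solveIris(irisModelConfig(
    EkPa = 1, TskPa = 6, nu = 0.49, asMm = 0.7, nElements = 200L,
    loadSteps = 12L)))
  sw2 <- widthSweep(eps, widths = c(0.7))
  expect_rel(sw2$ratio[1], 6, 1e-3)
})

test_that("power-law regression recovers exact synthetic ratios", {
  a <- c(0.4, 0.7, 1.0, 1.3)
  r <- (6.197 / a)^0.916
  pl <- fitPowerLaw(data.frame(asMm = a, ratio = r))
  expect_rel(pl$A, 6.197, 1e-8)
  expect_rel(pl$B, 0.916, 1e-8)
  # evaluation at 1 mm equals the 1 mm ratio by construction
  expect_rel((pl$A / 1)^pl$B, r[3], 1e-8)

  expect_error(fitPowerLaw(data.frame(asMm = a[1:2], ratio = r[1:2])),
               "underdetermined")
})
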