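test_that("Cauchy stress vanishes in the reference state and matches the
           active traction at identity", {
  s <- cauchyStress(1, 1, 1, E = 10, nu = 0.3, Ts = 0)
  expect_equal(as.numeric(s), c(0, 0, 0), tolerance = 1e-14)

  s2 <- cauchyStress(1, 1, 1, E = 10, nu = 0.3, Ts = 10)
  expect_equal(as.numeric(s2), c(0, 10, 0), tolerance = 1e-14)

  expect_error(cauchyStress(-1, 1, 1, E = 10, nu = 0.3), "positive")
})

test_that("small-strain stresses match linear elasticity", {
  E <- 12; nu <- 0.35; e <- 1e-6
  mu <- E / (2 * (1 + nu)); lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  # plane-strain uniaxial stretch: lambda_r = 1 + e, others 1
  s <- cauchyStress(1 + e, 1, 1, E, nu)
  expect_rel(s[1, "sigmaRR"], (lam + 2 * mu) * e, 1e-4)
  expect_rel(s[1, "sigmaTT"], lam * e, 1e-4)
  expect_rel(s[1, "sigmaZZ"], lam * e, 1e-4)
})

test_that("plane-stress condition is solved pointwise", {
  set.seed(7)
  lr <- runif(20, 0.5, 1.8); lt <- runif(20, 0.5, 1.8)
  lz <- planeStressLambdaZ(lr, lt, E = 3, nu = 0.45)
  s <- cauchyStress(lr, lt, lz, E = 3, nu = 0.45)
  expect_lt(max(abs(s[, "sigmaZZ"])), 1e-10)
})

test_that("the unloaded annulus stays in its reference configuration", {
  sol <- solveIris(irisModelConfig(TskPa = 0, EkPa = 5, nElements = 50L))
  expect_equal(sol@r, sol@nodesR, tolerance = 1e-12)
  expect_equal(pupilStrain(sol), 0, tolerance = 1e-12)
})

test_that("pupil strain is invariant under joint (E, Ts) rescaling", {
  e1 <- pupilStrain(solveIris(irisModelConfig(EkPa = 10, TskPa = 50,
                                              nu = 0.3, nElements = 100L)))
  e2 <- pupilStrain(solveIris(irisModelConfig(EkPa = 20, TskPa = 100,
                                              nu = 0.3, nElements = 100L)))
  e3 <- pupilStrain(solveIris(irisModelConfig(EkPa = 0.37, TskPa = 1.85,
                                              nu = 0.3, nElements = 100L)))
  expect_lt(abs(e1 - e2), 1e-8)
  expect_lt(abs(e1 - e3), 1e-8)
})

test_that("the reference loading reproduces the study-scale pupil strain", {
  sol <- solveIris(irisModelConfig(EkPa = 1, TskPa = 5, nu = 0.49, asMm = 1))
  expect_true(sol@converged)
  expect_rel(pupilStrain(sol), -0.386, 0.15)
  # deformation is admissible
  expect_true(all(sol@J > 0))
  expect_true(all(diff(sol@r) > 0))
  # fixed limbus
  expect_equal(sol@r[length(sol@r)], 6, tolerance = 1e-12)
})

test_that("pupil strain converges with mesh refinement", {
  eps <- vapply(c(100L, 200L, 400L), function(n)
    pupilStrain(solveIris(irisModelConfig(EkPa = 1, TskPa = 5, nu = 0.49,
                                          nElements = n))), numeric(1))
  expect_lt(abs(eps[1] - eps[3]), 1e-3)
  expect_lte(abs(eps[2] - eps[3]), abs(eps[1] - eps[3]) + 1e-12)
})

test_that("|pupil strain| increases strictly with the traction ratio", {
  eps <- vapply(c(1, 3, 6, 10), function(rho)
    pupilStrain(solveIris(irisModelConfig(EkPa = 1, TskPa = rho, nu = 0.49,
                                          nElements = 100L))), numeric(1))
  expect_true(all(diff(eps) < 0))
})

test_that("the finite-strain solver matches the linearized annulus oracle
           at small load", {
  for (nu in c(0.2, 0.45)) {
    rho <- 0.02
    sol <- solveIris(irisModelConfig(EkPa = 1, TskPa = rho, nu = nu,
                                     asMm = 1, nElements = 200L))
    uIn <- linearAnnulusOracle(3.4, 6, 1, E = 1, nu = nu, Ts = rho)
    epsLin <- 0.5 * ((1 + uIn / 3.4)^2 - 1)
    expect_rel(pupilStrain(sol), epsLin, 0.01)
  }
})

test_that("model strain profiles are zero without load and peak at the
           sphincter edge", {
  sol0 <- solveIris(irisModelConfig(TskPa = 0, EkPa = 2, nElements = 50L))
  expect_true(all(abs(traceData(strainProfiles(sol0))$median) < 1e-12))

  cfgS <- irisModelConfig(EkPa = 1, TskPa = 5, nu = 0.49, asMm = 1)
  sol <- solveIris(cfgS)
  prof <- strainProfiles(sol)
  edge <- cfgS@asMm / (cfgS@RoutMm - cfgS@RinMm)
  elemW <- (cfgS@RoutMm - cfgS@RinMm) / cfgS@nElements
  expect_lt(abs(peakRadialStrain(prof) - edge), 2 * elemW)

  # hoop strain vanishes at the fixed limbus
  d <- traceData(prof)
  ettEnd <- d$median[d$component == "Ett"][sum(d$component == "Ett")]
  expect_lt(abs(ettEnd), 1e-2)
  expect_equal(0.5 * ((sol@r[length(sol@r)] / 6)^2 - 1), 0, tolerance = 1e-12)
})
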