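# Manual construction helpers for strain-operator tests.
gridField <- function(disp, nx = 12, ny = 12, step = 4L,
                      center = c(1, 1)) {
  pts <- as.matrix(expand.grid(x = seq(41, by = step, length.out = nx),
                               y = seq(41, by = step, length.out = ny)))
  d <- disp(pts[, 1], pts[, 2])
  new("DisplacementField", points = pts, disp = d,
      valid = rep(TRUE, nrow(pts)), residual = rep(0, nrow(pts)),
      step = step, subsetSize = 31L,
      geometry = list(center = center), nIncrements = 1L)
}

test_that("identical frames give zero displacement", {
  f <- frames(smallSeq())[, , 1]
  geo <- dicGeometry(smallSeq())
  mask <- lateralMask(dim(f), geo, marginPx = 6, sectorDeg = 60)
  fld <- correlateIncremental(array(c(f, f), dim = c(dim(f), 2)), mask,
                              geometry = geo[c("center", "rp0Px", "rlPx")])
  expect_true(all(fld@valid))
  expect_lt(max(abs(fld@disp)), 1e-3)
  expect_lt(max(fld@residual), 0.05)
})

test_that("a pure 3 px shift is recovered to 0.05 px", {
  f <- frames(dicFixture()$seq)[, , 1]
  nx <- nrow(f); ny <- ncol(f)
  g <- f
  g[4:nx, ] <- f[1:(nx - 3), ]          # content moves +3 px in x
  geo <- dicFixture()$geo
  mask <- lateralMask(c(nx, ny), geo)
  fld <- correlateIncremental(array(c(f, g), dim = c(nx, ny, 2)), mask,
                              geometry = geo[c("center", "rp0Px", "rlPx")])
  v <- fld@valid
  expect_gt(mean(v), 0.9)
  expect_lt(max(abs(fld@disp[v, 1] - 3)), 0.05)
  expect_lt(max(abs(fld@disp[v, 2])), 0.05)
})

test_that("cumulative displacement matches the closed-form map", {
  fx <- dicFixture()
  v <- fx$field@valid
  expect_gt(mean(v), 0.9)
  err <- sqrt(rowSums((fx$field@disp[v, ] - fx$uTrue[v, ])^2))
  expect_lt(sqrt(mean(err^2)), 0.2)
})

test_that("the strain operator is exact on affine displacement fields", {
  # uniform translation: all strains zero
  fld0 <- gridField(function(x, y) cbind(rep(2.3, length(x)),
                                         rep(-1.1, length(x))))
  sf0 <- computeStrainField(fld0)
  expect_lt(max(abs(sf0@strains[sf0@valid, c("Exx", "Eyy", "Exy")])), 1e-12)

  # u_x = 0.1 x: E_xx = ((1.1)^2 - 1) / 2 = 0.105 exactly
  fld1 <- gridField(function(x, y) cbind(0.1 * x, rep(0, length(x))))
  sf1 <- computeStrainField(fld1)
  v <- sf1@valid
  expect_equal(unname(sf1@strains[v, "Exx"]), rep(0.105, sum(v)),
               tolerance = 1e-10)
  expect_lt(max(abs(sf1@strains[v, c("Eyy", "Exy")])), 1e-12)
})

test_that("DIC strains recover the uniform radial strain of the generator", {
  fx <- dicFixture()
  sf <- computeStrainField(fx$field)
  med <- median(sf@strains[sf@valid, "Err"], na.rm = TRUE)
  expect_rel(med, fx$ErrTrue, 0.10)
})

test_that("strain profiles are flat for the uniform-stretch contraction and
           shear-free by symmetry", {
  fx <- dicFixture()
  sf <- computeStrainField(fx$field)
  prof <- extractProfile(sf, fx$geo$rp0Px, fx$geo$rlPx)
  d <- traceData(prof)
  err <- d[d$component == "Err", ]
  expect_true(all(abs(err$median - fx$ErrTrue) < 0.10 * abs(fx$ErrTrue)))
  ert <- d[d$component == "Ert", ]
  expect_lt(max(abs(ert$median)), 0.02)
})

test_that("a spatially uniform strain field gives a constant, zero-IQR
           profile", {
  pts <- as.matrix(expand.grid(x = seq(60, 300, by = 4),
                               y = seq(140, 190, by = 4)))
  n <- nrow(pts)
  E <- matrix(0.37, n, 6,
              dimnames = list(NULL, c("Exx", "Eyy", "Exy", "Err", "Ett", "Ert")))
  sf <- new("StrainField", points = pts, strains = E,
            valid = rep(TRUE, n), center = c(165.5, 165.5))
  prof <- extractProfile(sf, rp0Px = 87, rlPx = 154)
  d <- traceData(prof)
  expect_true(all(abs(d$median - 0.37) < 1e-12))
  expect_true(all(d$q3 - d$q1 < 1e-12))
})

test_that("strain objectivity: a global integer shift leaves strains
           unchanged", {
  fx <- dicFixture()
  sub <- fx$idx[1:3]
  arr <- frames(fx$seq)[, , sub]
  nx <- dim(arr)[1]; ny <- dim(arr)[2]
  sh <- 2L
  arrS <- array(0.5, dim = dim(arr))
  arrS[(1 + sh):nx, , ] <- arr[1:(nx - sh), , ]
  geo <- fx$geo
  mask <- lateralMask(c(nx, ny), geo)
  maskS <- matrix(FALSE, nx, ny)
  maskS[(1 + sh):nx, ] <- mask[1:(nx - sh), ]
  gS <- geo; gS$center <- geo$center + c(sh, 0)
  f1 <- correlateIncremental(arr, mask,
                             geometry = geo[c("center", "rp0Px", "rlPx")])
  f2 <- correlateIncremental(arrS, maskS,
                             geometry = gS[c("center", "rp0Px", "rlPx")])
  s1 <- computeStrainField(f1)
  s2 <- computeStrainField(f2, center = gS$center)
  m1 <- median(s1@strains[s1@valid, "Err"], na.rm = TRUE)
  m2 <- median(s2@strains[s2@valid, "Err"], na.rm = TRUE)
  expect_lt(abs(m1 - m2), 1e-3)
})

test_that("incremental accumulation matches direct correlation for small
           total deformation", {
  fx <- dicFixture()
  sub <- fx$idx[1:3]          # < 5 px total motion over two increments
  arr <- frames(fx$seq)[, , sub]
  geo <- fx$geo
  mask <- lateralMask(dim(arr)[1:2], geo)
  inc <- correlateIncremental(arr, mask,
                              geometry = geo[c("center", "rp0Px", "rlPx")])
  dir <- correlateIncremental(arr[, , c(1, 3)], mask,
                              geometry = geo[c("center", "rp0Px", "rlPx")])
  v <- inc@valid & dir@valid
  expect_gt(mean(v), 0.9)
  dd <- sqrt(rowSums((inc@disp[v, ] - dir@disp[v, ])^2))
  expect_lt(max(dd), 0.1)
})

test_that("the Hausdorff screen excludes only gross profile outliers", {
  mkProf <- function(offset = 0) {
    d <- data.frame(xbar = seq(0.05, 0.95, length.out = 10),
                    component = "Err",
                    median = 1.5 + offset, q1 = 1.3 + offset,
                    q3 = 1.7 + offset, n = 50L)
    new("StrainProfile", data = d, source = "dic")
  }
  same <- replicate(5, mkProf(), simplify = FALSE)
  h1 <- hausdorffOutlier(same)
  expect_length(h1$excluded, 0)

  shifted <- c(replicate(5, mkProf(), simplify = FALSE), list(mkProf(1.0)))
  h2 <- hausdorffOutlier(shifted)
  expect_equal(h2$excluded, 6L)

  expect_warning(h3 <- hausdorffOutlier(same[1:2]), "fewer than 3")
  expect_length(h3$excluded, 0)
})

test_that("the virtual tensometer measures chord strain at the margin", {
  # zero displacement: zero strain
  fld0 <- gridField(function(x, y) cbind(rep(0, length(x)),
                                         rep(0, length(x))),
                    nx = 20, ny = 6, center = c(81, 52))
  fld0@geometry <- list(center = c(81, 52), rp0Px = 10, rlPx = 45)
  expect_equal(as.numeric(virtualTensometer(fld0)), 0, tolerance = 1e-12)

  # synthetic contraction: agrees with the ground-truth chord strain of the
  # two tracked endpoints
  fx <- dicFixture()
  vt <- virtualTensometer(fx$field, bandPx = 40)
  ep <- attr(vt, "endpoints")
  geo <- fx$geo
  Rch <- sqrt((ep[, 1] - geo$center[1])^2 + (ep[, 2] - geo$center[2])^2)
  rDef <- kinematicMap(Rch * geo$mmPerPx, fx$tEnd, fx$cfg) / geo$mmPerPx
  gtChord <- 0.5 * ((sum(rDef) / sum(Rch))^2 - 1)
  expect_rel(as.numeric(vt), gtChord, 0.10)

  # fully invalidated band: error
  fldBad <- fx$field
  fldBad@valid[] <- FALSE
  expect_error(virtualTensometer(fldBad, bandPx = 40), "tensometer failed")
})

test_that("blink frames are flagged by the brightness heuristic", {
  arr <- frames(smallSeq())[, , 1:8]
  arr[, , 5] <- 0.85                    # closed lid: bright skin everywhere
  expect_equal(detectBlinks(arr), 5L)
  expect_length(detectBlinks(frames(smallSeq())[, , 1:8]), 0)
})
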