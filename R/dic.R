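# Subset-based incremental digital image correlation.
#
# Matching criterion: normalized sum of squared differences with optimal
# per-subset intensity gain/offset, minimized over a first-order (affine)
# subset shape function by integer-pixel coarse search followed by
# Gauss-Newton subpixel refinement with bilinear image-gradient
# interpolation.

# Match one subset between ref patch F (vector) and image G.
# cc: integer template centre in G's predecessor frame coordinates;
# xi: subset offsets. Returns list(du, residualPx, ok).
matchSubset <- function(Fpatch, G, Gx, Gy, cc, xiX, xiY, init,
                        searchRadius, maxIter, tol = 1e-3, weights = NULL) {
  nxG <- nrow(G); nyG <- ncol(G)
  Fm <- Fpatch - mean(Fpatch)
  nF <- sqrt(sum(Fm^2))
  if (nF < 1e-8) return(list(ok = FALSE))          # textureless subset
  if (is.null(weights)) weights <- rep(1, length(Fpatch))
  sw <- sqrt(weights)
  wsum <- sum(weights)

  # integer-pixel coarse search around the initial guess
  bestD <- c(round(init[1]), round(init[2])); bestC <- -Inf
  if (searchRadius > 0) {
    for (dx in (round(init[1]) - searchRadius):(round(init[1]) + searchRadius))
      for (dy in (round(init[2]) - searchRadius):(round(init[2]) + searchRadius)) {
        xs <- cc[1] + xiX + dx; ys <- cc[2] + xiY + dy
        if (min(xs) < 1 || min(ys) < 1 || max(xs) > nxG || max(ys) > nyG) next
        g <- G[cbind(xs, ys)]
        gm <- g - mean(g)
        ng <- sqrt(sum(gm^2))
        if (ng < 1e-8) next
        cc0 <- sum(Fm * gm) / (nF * ng)            # ZNCC, equivalent ranking
        if (cc0 > bestC) { bestC <- cc0; bestD <- c(dx, dy) }
      }
    if (!is.finite(bestC)) return(list(ok = FALSE))
  }

  # Gauss-Newton refinement of affine parameters p = (u, ux, uy, v, vx, vy)
  p <- c(bestD[1], 0, 0, bestD[2], 0, 0)
  okConv <- FALSE
  a <- 1
  for (it in seq_len(maxIter)) {
    xw <- cc[1] + xiX + p[1] + p[2] * xiX + p[3] * xiY
    yw <- cc[2] + xiY + p[4] + p[5] * xiX + p[6] * xiY
    g <- cubicAt(G, xw, yw)
    if (anyNA(g)) return(list(ok = FALSE))
    mF <- sum(weights * Fpatch) / wsum
    mG <- sum(weights * g) / wsum
    vg <- sum(weights * (g - mG)^2) / wsum
    if (vg < 1e-12) return(list(ok = FALSE))
    a <- sum(weights * (Fpatch - mF) * (g - mG)) / wsum / vg  # optimal gain
    b <- mF - a * mG
    rvec <- sw * (Fpatch - a * g - b)
    gx <- bilinearAt(Gx, xw, yw, fill = 0)
    gy <- bilinearAt(Gy, xw, yw, fill = 0)
    J <- cbind(gx, gx * xiX, gx * xiY, gy, gy * xiX, gy * xiY) * (a * sw)
    JtJ <- crossprod(J)
    dp <- tryCatch(solve(JtJ + diag(1e-8, 6), crossprod(J, rvec)),
                   error = function(e) NULL)
    if (is.null(dp)) return(list(ok = FALSE))
    p <- p + as.numeric(dp)
    if (sqrt(dp[1]^2 + dp[4]^2) < tol) { okConv <- TRUE; break }
  }
  if (!okConv) return(list(ok = FALSE))
  # displacement-equivalent residual: 1-sigma uncertainty of the translation
  # estimate from the Gauss-Newton covariance sigma^2 (J'J)^-1
  sig2 <- sum(rvec^2) / wsum
  JtJinv <- tryCatch(solve(JtJ + diag(1e-10, 6)), error = function(e) NULL)
  resPx <- if (is.null(JtJinv)) Inf
           else sqrt(sig2 * (JtJinv[1, 1] + JtJinv[4, 4]))
  list(ok = TRUE, du = c(p[1], p[4]), p = p, residualPx = resPx)
}

#' Incremental subset correlation of a frame stack
#'
#' For each consecutive pair of supplied frames, matches each grid subset by
#' normalized-sum-of-squared-differences with first-order (affine) subset
#' shape functions: an integer-pixel coarse search followed by iterative
#' Gauss-Newton subpixel refinement with bicubic image interpolation and
#' Gaussian subset weighting.
#' The reference subset is re-centred at the advected point location each
#' increment (incremental correlation) and displacements are accumulated.
#' Points that fail convergence or whose displacement-equivalent residual
#' exceeds `matchTol` are invalidated and never revived.
#'
#' @param framesArr numeric array (nx, ny, nt) of the frames to correlate,
#'   in analysis order (e.g. every 10th frame from light onset, blink frames
#'   already removed), or a [FrameSequence-class].
#' @param roiMask logical matrix (nx, ny); the grid covers `TRUE` pixels
#'   (typically the iris annulus excluding pupil and eyelids).
#' @param subset odd subset edge length (px), default 31.
#' @param step grid step (px), default 4.
#' @param matchTol matchability threshold on the residual (px), default 0.1.
#' @param maxIter Gauss-Newton iteration cap.
#' @param searchRadius integer-pixel search radius around the predicted
#'   position each increment; the first increment is additionally seeded by
#'   a coarse pyramid search.
#' @param geometry optional list (`center`, `rp0Px`, `rlPx`) describing the
#'   reference frame; attached for downstream profile extraction.
#' @return a [DisplacementField-class] with cumulative displacements.
#' @export
correlateIncremental <- function(framesArr, roiMask, subset = 31L, step = 4L,
                                 matchTol = 0.1, maxIter = 30L,
                                 searchRadius = 3L, geometry = list()) {
  if (is(framesArr, "FrameSequence")) framesArr <- frames(framesArr)
  stopifnot(length(dim(framesArr)) == 3L, dim(framesArr)[3] >= 2L,
            is.matrix(roiMask), subset %% 2 == 1)
  nx <- dim(framesArr)[1]; ny <- dim(framesArr)[2]
  nt <- dim(framesArr)[3]
  stopifnot(nrow(roiMask) == nx, ncol(roiMask) == ny)
  hw <- (subset - 1L) %/% 2L

  gx <- seq(hw + 2L, nx - hw - 1L, by = step)
  gy <- seq(hw + 2L, ny - hw - 1L, by = step)
  pts <- as.matrix(expand.grid(x = gx, y = gy))
  keep <- roiMask[pts]
  pts <- pts[keep, , drop = FALSE]
  if (!nrow(pts)) stopIris("ROI contains no grid points")

  xi <- as.matrix(expand.grid(x = -hw:hw, y = -hw:hw))
  xiX <- xi[, 1]; xiY <- xi[, 2]
  # Gaussian subset weighting reduces the curvature bias of affine subset
  # shape functions on circumferentially curved fields
  wSub <- exp(-(xiX^2 + xiY^2) / (2 * (hw / 3)^2))

  npts <- nrow(pts)
  ucum <- matrix(0, npts, 2)
  lastDu <- matrix(0, npts, 2)
  valid <- rep(TRUE, npts)
  residual <- rep(0, npts)

  # Coarse initial guesses for an increment via a downsampled ZNCC search;
  # needed when the inter-frame motion exceeds the Gauss-Newton basin
  # (e.g. the first increments of a fast constriction).
  coarseInit <- function(Fimg, Gimg, centers, factor = 4L, half = 8L,
                         subsetC = 9L) {
    Fc <- as.matrix(EBImage::resize(EBImage::Image(Fimg),
                                    w = nx %/% factor, h = ny %/% factor))
    Gc <- as.matrix(EBImage::resize(EBImage::Image(Gimg),
                                    w = nx %/% factor, h = ny %/% factor))
    hwc <- (subsetC - 1L) %/% 2L
    xic <- as.matrix(expand.grid(-hwc:hwc, -hwc:hwc))
    out <- matrix(0, nrow(centers), 2)
    for (i in seq_len(nrow(centers))) {
      cc <- round(centers[i, ] / factor)
      xs <- cc[1] + xic[, 1]; ys <- cc[2] + xic[, 2]
      if (min(xs) < 1 || min(ys) < 1 || max(xs) > nrow(Fc) ||
          max(ys) > ncol(Fc)) next
      f <- Fc[cbind(xs, ys)]
      fm <- f - mean(f); nf <- sqrt(sum(fm^2))
      if (nf < 1e-8) next
      bestC <- -Inf
      for (dx in -half:half) for (dy in -half:half) {
        xg <- xs + dx; yg <- ys + dy
        if (min(xg) < 1 || min(yg) < 1 || max(xg) > nrow(Gc) ||
            max(yg) > ncol(Gc)) next
        g <- Gc[cbind(xg, yg)]
        gm <- g - mean(g); ng <- sqrt(sum(gm^2))
        if (ng < 1e-8) next
        z <- sum(fm * gm) / (nf * ng)
        if (z > bestC) { bestC <- z; out[i, ] <- c(dx, dy) * factor }
      }
    }
    out
  }

  for (k in seq_len(nt - 1L)) {
    Fimg <- framesArr[, , k]
    Gimg <- framesArr[, , k + 1L]
    Gx <- Gimg * 0; Gy <- Gimg * 0
    Gx[2:(nx - 1), ] <- (Gimg[3:nx, ] - Gimg[1:(nx - 2), ]) / 2
    Gy[, 2:(ny - 1)] <- (Gimg[, 3:ny] - Gimg[, 1:(ny - 2)]) / 2
    if (k == 1L) {
      adv <- pts + ucum
      lastDu[valid, ] <- coarseInit(Fimg, Gimg,
                                    adv[valid, , drop = FALSE])[seq_len(sum(valid)), ]
    }
    for (i in which(valid)) {
      ccF <- round(pts[i, ] + ucum[i, ])
      if (ccF[1] - hw < 1 || ccF[2] - hw < 1 ||
          ccF[1] + hw > nx || ccF[2] + hw > ny) { valid[i] <- FALSE; next }
      Fpatch <- Fimg[cbind(ccF[1] + xiX, ccF[2] + xiY)]
      m <- matchSubset(Fpatch, Gimg, Gx, Gy, ccF, xiX, xiY,
                       init = lastDu[i, ], searchRadius = searchRadius,
                       maxIter = maxIter, weights = wSub)
      if (!isTRUE(m$ok) || m$residualPx > matchTol) { valid[i] <- FALSE; next }
      # evaluate the incremental displacement at the true (sub-pixel)
      # advected location, not the rounded subset centre, using the affine
      # shape function
      dlt <- pts[i, ] + ucum[i, ] - ccF
      du <- c(m$p[1] + m$p[2] * dlt[1] + m$p[3] * dlt[2],
              m$p[4] + m$p[5] * dlt[1] + m$p[6] * dlt[2])
      ucum[i, ] <- ucum[i, ] + du
      lastDu[i, ] <- du
      residual[i] <- m$residualPx
    }
    if (!any(valid))
      stopIris("tracking lost: all points invalid at increment ", k)
  }

  new("DisplacementField", points = pts, disp = ucum, valid = valid,
      residual = residual, step = as.integer(step),
      subsetSize = as.integer(subset), geometry = geometry,
      nIncrements = nt - 1L)
}

#' Lagrangian strain field from a displacement field
#'
#' At each valid grid point, fits the displacement over a square window of
#' `filterSize` x `filterSize` image pixels by local least squares
#' (`u = a0 + a1 X + a2 Y`, same for `v`), forms the deformation gradient
#' `F = I + grad(u)` and the Lagrangian strain `E = (F'F - I) / 2`, and
#' rotates it to polar components about the reference pupil centre.
#'
#' @param field a [DisplacementField-class].
#' @param filterSize strain window edge length in image pixels (default 15,
#'   i.e. grid points within ±7 px enter each fit).
#' @param minNeighbors minimum valid neighbors for a fit (default 6).
#' @param center polar origin; defaults to `field@geometry$center`.
#' @return a [StrainField-class].
#' @export
computeStrainField <- function(field, filterSize = 15L, minNeighbors = 6L,
                               center = NULL) {
  stopifnot(is(field, "DisplacementField"))
  if (is.null(center)) center <- field@geometry$center
  if (is.null(center)) stopIris("no polar origin: supply `center`")
  pts <- field@points
  half <- (filterSize - 1) / 2
  n <- nrow(pts)
  E <- matrix(NA_real_, n, 6,
              dimnames = list(NULL, c("Exx", "Eyy", "Exy", "Err", "Ett", "Ert")))
  ok <- rep(FALSE, n)
  vIdx <- which(field@valid)
  vp <- pts[vIdx, , drop = FALSE]
  vd <- field@disp[vIdx, , drop = FALSE]
  for (i in vIdx) {
    sel <- abs(vp[, 1] - pts[i, 1]) <= half & abs(vp[, 2] - pts[i, 2]) <= half
    if (sum(sel) < minNeighbors) next
    X <- vp[sel, 1] - pts[i, 1]
    Y <- vp[sel, 2] - pts[i, 2]
    if (length(unique(X)) < 2L || length(unique(Y)) < 2L) next
    Amat <- cbind(1, X, Y)
    cu <- stats::lm.fit(Amat, vd[sel, 1])$coefficients
    cv <- stats::lm.fit(Amat, vd[sel, 2])$coefficients
    Fm <- matrix(c(1 + cu[2], cv[2], cu[3], 1 + cv[3]), 2, 2)
    Em <- (crossprod(Fm) - diag(2)) / 2
    phi <- atan2(pts[i, 2] - center[2], pts[i, 1] - center[1])
    cphi <- cos(phi); sphi <- sin(phi)
    err <- cphi^2 * Em[1, 1] + 2 * cphi * sphi * Em[1, 2] + sphi^2 * Em[2, 2]
    ett <- sphi^2 * Em[1, 1] - 2 * cphi * sphi * Em[1, 2] + cphi^2 * Em[2, 2]
    ert <- (Em[2, 2] - Em[1, 1]) * cphi * sphi +
      (cphi^2 - sphi^2) * Em[1, 2]
    E[i, ] <- c(Em[1, 1], Em[2, 2], Em[1, 2], err, ett, ert)
    ok[i] <- TRUE
  }
  new("StrainField", points = pts, strains = E, valid = ok,
      center = as.numeric(center))
}

#' Strain profile along the nasal-temporal axis
#'
#' Collects valid strain values inside a rectangular box through the pupil
#' centre (total height half the reference pupil radius, width the limbus
#' diameter), pools the nasal and temporal arms, and reports median and
#' interquartile range per component in bins of the normalized coordinate
#' `xbar = (|x - xc| - rp0) / (rl - rp0)` (0 at the pupillary margin, 1 at
#' the limbus), computed in the reference configuration.
#'
#' @param strain a [StrainField-class].
#' @param rp0Px reference pupil radius (px).
#' @param rlPx limbus radius (px).
#' @param center pupil centre; defaults to the strain field's polar origin.
#' @param nBins number of `xbar` bins.
#' @return a [StrainProfile-class] with `source = "dic"`.
#' @export
extractProfile <- function(strain, rp0Px, rlPx, center = NULL, nBins = 24L) {
  stopifnot(is(strain, "StrainField"))
  if (is.null(center)) center <- strain@center
  pts <- strain@points
  inBox <- abs(pts[, 2] - center[2]) <= rp0Px / 4 &
    abs(pts[, 1] - center[1]) <= rlPx & strain@valid
  xbar <- (abs(pts[, 1] - center[1]) - rp0Px) / (rlPx - rp0Px)
  sel <- which(inBox & xbar >= 0 & xbar <= 1)
  if (!length(sel)) stopIris("profile box lies outside the strain field")
  breaks <- seq(0, 1, length.out = nBins + 1L)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  bin <- findInterval(xbar[sel], breaks, rightmost.closed = TRUE)
  rows <- list()
  for (compName in c("Err", "Ett", "Ert")) {
    v <- strain@strains[sel, compName]
    for (b in sort(unique(bin))) {
      vb <- v[bin == b & is.finite(v)]
      if (!length(vb)) next
      q <- stats::quantile(vb, c(0.25, 0.5, 0.75), names = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        xbar = mids[b], component = compName,
        median = q[2], q1 = q[1], q3 = q[3], n = length(vb))
    }
  }
  new("StrainProfile", data = do.call(rbind, rows), source = "dic")
}

#' Hausdorff-distance outlier screen for strain profiles
#'
#' Computes, for each profile, the Hausdorff distance between its
#' `(xbar, median)` curve (one component) and the pointwise-median curve of
#' the collection, and excludes profiles whose distance exceeds
#' `mean + k * sd` of the distances. With fewer than 3 profiles no exclusion
#' is performed.
#'
#' @param profiles list of [StrainProfile-class] objects.
#' @param component strain component screened (default `"Err"`).
#' @param k exclusion threshold in standard deviations (default 2).
#' @param nGrid common `xbar` grid size.
#' @return list with `keep`, `excluded` (indices) and `distances`.
#' @export
hausdorffOutlier <- function(profiles, component = "Err", k = 2,
                             nGrid = 32L) {
  n <- length(profiles)
  if (n < 3L) {
    warning("fewer than 3 profiles; no outlier exclusion performed")
    return(list(keep = seq_len(n), excluded = integer(),
                distances = rep(NA_real_, n)))
  }
  curves <- lapply(profiles, function(p) {
    d <- traceData(p)
    d <- d[d$component == component & is.finite(d$median), ]
    d[order(d$xbar), c("xbar", "median")]
  })
  lo <- max(vapply(curves, function(c) min(c$xbar), numeric(1)))
  hi <- min(vapply(curves, function(c) max(c$xbar), numeric(1)))
  if (hi <= lo) stopIris("profiles have disjoint xbar supports")
  grid <- seq(lo, hi, length.out = nGrid)
  vals <- vapply(curves, function(c)
    stats::approx(c$xbar, c$median, xout = grid)$y, numeric(nGrid))
  med <- apply(vals, 1, stats::median)
  dist <- vapply(seq_len(n), function(i)
    pracma::hausdorff_dist(cbind(grid, vals[, i]), cbind(grid, med)),
    numeric(1))
  thr <- mean(dist) + k * stats::sd(dist)
  excluded <- which(dist > thr)
  list(keep = setdiff(seq_len(n), excluded), excluded = excluded,
       distances = dist)
}

#' DIC-based pupil-margin strain (virtual tensometer)
#'
#' Takes the two valid tracked points nearest the reference pupil margin on
#' opposite sides of the nasal-temporal axis, and converts the stretch of
#' the chord between them into a Lagrangian strain
#' `((L / L0)^2 - 1) / 2`.
#'
#' @param field a [DisplacementField-class].
#' @param rp0Px reference pupil radius (px); defaults to the field geometry.
#' @param center pupil centre; defaults to the field geometry.
#' @param bandPx radial band outside the margin searched for points (px).
#' @param axisTolPx maximum distance from the horizontal axis (px).
#' @return the chord Lagrangian strain (dimensionless).
#' @export
virtualTensometer <- function(field, rp0Px = NULL, center = NULL,
                              bandPx = 25, axisTolPx = NULL) {
  stopifnot(is(field, "DisplacementField"))
  if (is.null(rp0Px)) rp0Px <- field@geometry$rp0Px
  if (is.null(center)) center <- field@geometry$center
  if (is.null(rp0Px) || is.null(center))
    stopIris("tensometer failed: no margin geometry")
  if (is.null(axisTolPx)) axisTolPx <- 2.5 * field@step
  pts <- field@points
  rad <- sqrt((pts[, 1] - center[1])^2 + (pts[, 2] - center[2])^2)
  nearAxis <- abs(pts[, 2] - center[2]) <= axisTolPx
  inBand <- rad >= rp0Px - 1 & rad <= rp0Px + bandPx
  pick <- function(side) {
    onSide <- if (side > 0) pts[, 1] > center[1] else pts[, 1] < center[1]
    cand <- which(field@valid & nearAxis & inBand & onSide)
    if (!length(cand)) stopIris("tensometer failed: no valid margin points")
    cand[which.min(rad[cand])]
  }
  iR <- pick(+1); iL <- pick(-1)
  p0 <- pts[iR, ] - pts[iL, ]
  p1 <- (pts[iR, ] + field@disp[iR, ]) - (pts[iL, ] + field@disp[iL, ])
  L0 <- sqrt(sum(p0^2)); L1 <- sqrt(sum(p1^2))
  structure(0.5 * ((L1 / L0)^2 - 1),
            endpoints = rbind(pts[iL, ], pts[iR, ]), L0 = L0, L1 = L1)
}

#' Flag likely blink frames by global brightness
#'
#' A closing eyelid replaces the dark pupil and iris with brighter skin, so
#' blink frames appear as transient spikes of the global mean intensity.
#' Each frame's mean is compared against a running median (window 5), which
#' tracks the slow brightness change of normal pupil constriction; frames
#' deviating by more than `z` robust standard deviations are flagged.
#'
#' @param seq a [FrameSequence-class] or (nx, ny, nt) array.
#' @param z flagging threshold (default 4).
#' @return integer vector of flagged frame indices (possibly empty).
#' @export
detectBlinks <- function(seq, z = 4) {
  arr <- if (is(seq, "FrameSequence")) frames(seq) else seq
  m <- apply(arr, 3, mean)
  n <- length(m)
  if (n < 3L) return(integer())
  ref <- stats::runmed(m, k = min(5L, n - (1 - n %% 2)))
  dev <- abs(m - ref)
  s <- max(stats::mad(dev), 1e-3)   # floor: identical frames have zero MAD
  which(dev / s > z)
}
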