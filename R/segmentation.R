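#' Threshold-based pupil segmentation
#'
#' Normalizes intensities to `[0, 1]` by range, applies a 3x3 median filter,
#' binarizes pixels below the (normalized) dark threshold, runs an erosion
#' then dilation with a 2-px square structuring element, fills holes (e.g.
#' glints inside the pupil), and keeps the largest connected component. The
#' pupil radius is `sqrt(area / pi)` and the centre is the component
#' centroid.
#'
#' @param frame numeric matrix `[x, y]` of intensities.
#' @param threshold dark threshold on normalized intensity (default 0.1).
#' @param useOtsu if `TRUE`, replace the fixed threshold by Otsu's method
#'   (fallback; the supplied numeric threshold is the documented behaviour).
#' @return list with `center` (x, y in px), `radiusPx`, `areaPx`.
#' @export
segmentPupil <- function(frame, threshold = 0.1, useOtsu = FALSE) {
  stopifnot(is.matrix(frame), all(is.finite(frame)))
  rng <- range(frame)
  img <- if (rng[2] > rng[1]) (frame - rng[1]) / (rng[2] - rng[1])
         else frame * 0
  med <- as.matrix(EBImage::medianFilter(img, 1L))
  if (useOtsu) threshold <- EBImage::otsu(EBImage::Image(med))
  bw <- EBImage::Image(med < threshold)
  kern <- matrix(1, 2, 2)
  bw <- EBImage::dilate(EBImage::erode(bw, kern), kern)
  bw <- EBImage::fillHull(bw)
  lab <- EBImage::bwlabel(bw)
  labm <- as.matrix(lab)
  if (max(labm) < 1) stopIris("no pupil found")
  areas <- tabulate(labm[labm > 0])
  comp <- which.max(areas)
  idx <- which(labm == comp, arr.ind = TRUE)
  nx <- nrow(frame); ny <- ncol(frame)
  onBorder <- idx[, 1] == 1L | idx[, 1] == nx | idx[, 2] == 1L | idx[, 2] == ny
  if (sum(onBorder) > 0.5 * (2 * nx + 2 * ny - 4)) stopIris("no pupil found")
  area <- nrow(idx)
  list(center = c(mean(idx[, 1]), mean(idx[, 2])),
       radiusPx = sqrt(area / pi), areaPx = area)
}

# Daugman integro-differential response for one candidate centre:
# smoothed |d/dr mean_theta I(x0 + r cos t, y0 + r sin t)| over lateral arcs.
daugmanResponse <- function(frame, x0, y0, radii, angles, sigma) {
  co <- cos(angles); si <- sin(angles)
  xs <- outer(radii, co, function(r, c) x0 + r * c)
  ys <- outer(radii, si, function(r, s) y0 + r * s)
  vals <- matrix(bilinearAt(frame, as.vector(xs), as.vector(ys)),
                 nrow = length(radii))
  m <- rowMeans(vals, na.rm = TRUE)
  d <- c(NA, diff(m) / diff(radii))
  resp <- abs(gaussSmooth1d(ifelse(is.finite(d), d, 0), sigma))
  resp[1] <- 0
  resp
}

#' Daugman integro-differential limbus localization
#'
#' Maximizes the smoothed radial derivative of the mean image intensity over
#' circles, i.e. the integro-differential operator
#' `|G_sigma(r) * d/dr (mean of I over the circle of radius r at (x0, y0))|`,
#' over a coarse-then-refined grid of centres and radii. The contour integral
#' is restricted to left/right angular sectors (±45° about the horizontal) to
#' avoid eyelid boundaries. The radius is refined to sub-pixel precision by a
#' parabolic fit around the response peak.
#'
#' @param frame numeric matrix `[x, y]`.
#' @param centerHint approximate centre `(x, y)` in px (e.g. the pupil centre).
#' @param rRange numeric length-2 bracket on the limbus radius (px).
#' @param sigma Gaussian smoothing width for the radial derivative (px).
#' @param sectorHalfAngleDeg half-width of each lateral arc sector (degrees).
#' @param flatRatio minimum max/median response ratio; below it the response
#'   landscape is considered flat and no limbus is reported.
#' @return list with `center` (x, y), `radiusPx`, `response`.
#' @export
detectLimbus <- function(frame, centerHint, rRange, sigma = 2,
                         sectorHalfAngleDeg = 45, flatRatio = 1.5) {
  stopifnot(is.matrix(frame), length(centerHint) == 2L, length(rRange) == 2L,
            rRange[1] < rRange[2])
  a <- sectorHalfAngleDeg * pi / 180
  nA <- 32L
  angles <- c(seq(-a, a, length.out = nA), seq(pi - a, pi + a, length.out = nA))
  radii <- seq(rRange[1], rRange[2], by = 1)
  if (length(radii) < 5L) radii <- seq(rRange[1], rRange[2], length.out = 5L)

  best <- list(resp = -Inf)
  evalCenter <- function(x0, y0) {
    resp <- daugmanResponse(frame, x0, y0, radii, angles, sigma)
    i <- which.max(resp)
    list(x = x0, y = y0, i = i, resp = resp[i], all = resp)
  }
  coarse <- expand.grid(x = centerHint[1] + seq(-8, 8, by = 4),
                        y = centerHint[2] + seq(-8, 8, by = 4))
  for (k in seq_len(nrow(coarse))) {
    cand <- evalCenter(coarse$x[k], coarse$y[k])
    if (cand$resp > best$resp) best <- cand
  }
  fine <- expand.grid(x = best$x + seq(-3, 3, by = 1),
                      y = best$y + seq(-3, 3, by = 1))
  for (k in seq_len(nrow(fine))) {
    cand <- evalCenter(fine$x[k], fine$y[k])
    if (cand$resp > best$resp) best <- cand
  }
  medResp <- stats::median(best$all[best$all > 0], na.rm = TRUE)
  if (!is.finite(best$resp) || !is.finite(medResp) || medResp <= 0 ||
      best$resp / medResp < flatRatio)
    stopIris("limbus not found")
  # parabolic sub-pixel refinement of the radius
  i <- best$i
  rPk <- radii[i]
  if (i > 1L && i < length(radii)) {
    y1 <- best$all[i - 1]; y2 <- best$all[i]; y3 <- best$all[i + 1]
    den <- y1 - 2 * y2 + y3
    if (is.finite(den) && abs(den) > .Machine$double.eps)
      rPk <- rPk + 0.5 * (y1 - y3) / den * diff(radii[1:2])
  }
  list(center = c(best$x, best$y), radiusPx = rPk, response = best$resp)
}

#' Trace pupil and limbus through a frame sequence
#'
#' Applies [segmentPupil()] and [detectLimbus()] to every `stride`-th frame
#' (default every 10th, i.e. an effective 2.5 Hz at 25 Hz acquisition). The
#' limbus search is seeded by the previous analyzed frame; per-frame failures
#' are recorded as missing values and reported in a warning.
#'
#' @param seq a [FrameSequence-class].
#' @param stride analyze every stride-th frame.
#' @param threshold pupil dark threshold (normalized intensity).
#' @param rRange optional limbus-radius bracket (px) for the first frame;
#'   defaults to `[1.15 * rp, min(image)/2 - 2]`.
#' @return a [PupilLimbusTrace-class].
#' @export
traceSequence <- function(seq, stride = 10L, threshold = 0.1, rRange = NULL) {
  stopifnot(is(seq, "FrameSequence"))
  nt <- nFrames(seq)
  if (nt < 1L) stopIris("empty frame sequence")
  idx <- seq.int(1L, nt, by = as.integer(stride))
  n <- length(idx)
  out <- data.frame(frame = idx, tS = frameTimes(seq)[idx],
                    xp = NA_real_, yp = NA_real_, rpPx = NA_real_,
                    xl = NA_real_, yl = NA_real_, rlPx = NA_real_,
                    beta = NA_real_)
  prevLimbus <- NULL
  failed <- integer()
  for (k in seq_len(n)) {
    fr <- frames(seq)[, , idx[k]]
    res <- tryCatch({
      pup <- segmentPupil(fr, threshold = threshold)
      if (is.null(prevLimbus)) {
        hint <- pup$center
        rr <- if (is.null(rRange))
          c(1.15 * pup$radiusPx, min(dim(fr)) / 2 - 2) else rRange
      } else {
        hint <- prevLimbus$center
        rr <- prevLimbus$radiusPx + c(-6, 6)
      }
      lim <- detectLimbus(fr, hint, rr)
      list(pup = pup, lim = lim)
    }, error = function(e) e)
    if (inherits(res, "error")) { failed <- c(failed, idx[k]); next }
    prevLimbus <- res$lim
    out$xp[k] <- res$pup$center[1]; out$yp[k] <- res$pup$center[2]
    out$rpPx[k] <- res$pup$radiusPx
    out$xl[k] <- res$lim$center[1]; out$yl[k] <- res$lim$center[2]
    out$rlPx[k] <- res$lim$radiusPx
    out$beta[k] <- res$pup$radiusPx / res$lim$radiusPx
  }
  if (length(failed))
    warning("segmentation failed on frame(s): ",
            paste(failed, collapse = ", "))
  mmPerPx <- pixelScale(seq) / 1000
  out$rpMm <- out$rpPx * mmPerPx
  out$rlMm <- out$rlPx * mmPerPx
  new("PupilLimbusTrace", data = out, pixelScaleUm = pixelScale(seq),
      stride = as.integer(stride))
}
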