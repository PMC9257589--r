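# Internal helpers shared across modules.

# Evaluate expr with a temporary RNG state seeded by `seed`, restoring the
# caller's state afterwards so package functions have no hidden global effect.
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Vectorized bilinear interpolation of img[x, y] at fractional coordinates.
# Out-of-range queries return `fill`.
bilinearAt <- function(img, x, y, fill = NA_real_) {
  nx <- nrow(img); ny <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  ok <- x0 >= 1 & y0 >= 1 & x0 <= nx - 1 & y0 <= ny - 1
  out <- rep(fill, length(x))
  if (!any(ok)) return(out)
  x0 <- x0[ok]; y0 <- y0[ok]; fxo <- fx[ok]; fyo <- fy[ok]
  i00 <- cbind(x0, y0); i10 <- cbind(x0 + 1, y0)
  i01 <- cbind(x0, y0 + 1); i11 <- cbind(x0 + 1, y0 + 1)
  out[ok] <- img[i00] * (1 - fxo) * (1 - fyo) + img[i10] * fxo * (1 - fyo) +
    img[i01] * (1 - fxo) * fyo + img[i11] * fxo * fyo
  out
}

# Vectorized Catmull-Rom bicubic interpolation of img[x, y]; indices are
# clamped one pixel inside the support so queries near the border degrade
# gracefully. Out-of-range queries (beyond 1 px) return `fill`.
cubicAt <- function(img, x, y, fill = NA_real_) {
  nx <- nrow(img); ny <- ncol(img)
  ok <- x >= 1 & y >= 1 & x <= nx & y <= ny
  out <- rep(fill, length(x))
  if (!any(ok)) return(out)
  xq <- pmin(pmax(x[ok], 2), nx - 2)
  yq <- pmin(pmax(y[ok], 2), ny - 2)
  x0 <- floor(xq); y0 <- floor(yq)
  tx <- xq - x0; ty <- yq - y0
  w <- function(t) cbind(
    -0.5 * t + t^2 - 0.5 * t^3,
    1 - 2.5 * t^2 + 1.5 * t^3,
    0.5 * t + 2 * t^2 - 1.5 * t^3,
    -0.5 * t^2 + 0.5 * t^3)
  wx <- w(tx); wy <- w(ty)
  acc <- numeric(length(xq))
  for (j in 1:4) {
    rowAcc <- numeric(length(xq))
    yj <- y0 + j - 2L
    for (i in 1:4)
      rowAcc <- rowAcc + wx[, i] * img[cbind(x0 + i - 2L, yj)]
    acc <- acc + wy[, j] * rowAcc
  }
  out[ok] <- acc
  out
}

# First deterministic Halton points (radical-inverse sequences) in [0,1)^d.
haltonSeq <- function(n, dim = 3L) {
  bases <- c(2L, 3L, 5L, 7L, 11L, 13L)[seq_len(dim)]
  radical <- function(i, b) {
    f <- 1; r <- 0
    while (i > 0) { f <- f / b; r <- r + f * (i %% b); i <- i %/% b }
    r
  }
  vapply(bases, function(b) vapply(seq_len(n), radical, numeric(1), b = b),
         numeric(n))
}

# Gaussian smoothing of a vector ('same' length, edge-renormalized).
gaussSmooth1d <- function(v, sigma) {
  if (sigma <= 0) return(v)
  half <- max(1L, ceiling(3 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  n <- length(v)
  padded <- c(rep(v[1], half), v, rep(v[n], half))
  as.numeric(stats::filter(padded, k / sum(k), sides = 2))[half + seq_len(n)]
}

# Periodic 2-d Gaussian smoothing via FFT (used for polar texture fields,
# which must be continuous across the theta seam).
periodicSmooth2d <- function(m, sigmaRow, sigmaCol) {
  nr <- nrow(m); nc <- ncol(m)
  gr <- exp(-0.5 * (pmin(0:(nr - 1), nr - 0:(nr - 1)) / sigmaRow)^2)
  gc <- exp(-0.5 * (pmin(0:(nc - 1), nc - 0:(nc - 1)) / sigmaCol)^2)
  kern <- outer(gr / sum(gr), gc / sum(gc))
  Re(stats::fft(stats::fft(m) * stats::fft(kern), inverse = TRUE)) / (nr * nc)
}

stopIris <- function(...) stop(..., call. = FALSE)
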