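#' Margin Lagrangian strains from a pupil/limbus trace
#'
#' Computes, per analyzed frame, the Lagrangian strain of the pupil margin
#' and of the limbus, `eps_i = ((r_i / rbar_i0)^2 - 1) / 2`, where `rbar_i0`
#' is the mean radius over the dark-acclimation window. The
#' maximum-constriction summary `eps_p,max` is the mean pupil-margin strain
#' over `maxWindow` (default 17-20 s, late in the light phase).
#'
#' @param trace a [PupilLimbusTrace-class].
#' @param acclimWindow reference window (s), default `c(0, 15)`.
#' @param maxWindow maximum-constriction window (s), default `c(17, 20)`.
#' @return a [StrainTrace-class].
#' @export
marginStrain <- function(trace, acclimWindow = c(0, 15),
                         maxWindow = c(17, 20)) {
  stopifnot(is(trace, "PupilLimbusTrace"))
  d <- traceData(trace)
  inAcc <- d$tS >= acclimWindow[1] & d$tS < acclimWindow[2] &
    is.finite(d$rpPx) & is.finite(d$rlPx)
  if (!any(inAcc)) stopIris("no reference state: acclimation window is empty")
  if (sum(inAcc) < 2L)
    warning("fewer than 2 valid frames in the acclimation window")
  rp0 <- mean(d$rpPx[inAcc])
  rl0 <- mean(d$rlPx[inAcc])
  lag <- function(r, r0) 0.5 * ((r / r0)^2 - 1)
  res <- data.frame(frame = d$frame, tS = d$tS,
                    epsP = lag(d$rpPx, rp0), epsL = lag(d$rlPx, rl0))
  inMax <- res$tS >= maxWindow[1] & res$tS <= maxWindow[2] &
    is.finite(res$epsP)
  epsPmax <- if (any(inMax)) mean(res$epsP[inMax]) else NA_real_
  new("StrainTrace", data = res, rp0Px = rp0, rl0Px = rl0,
      epsPmax = epsPmax, maxWindow = maxWindow)
}

#' Three-sigma outlier screen
#'
#' Single-pass rule: values more than `nSd` standard deviations from the mean
#' (mean and sd computed once over the full collection) are excluded. With
#' fewer than 3 values no exclusion is performed.
#'
#' @param x numeric vector (e.g. per-scan maximum pupil-margin strains).
#' @param nSd exclusion threshold in standard deviations (default 3).
#' @return list with `keep` and `excluded` integer indices, plus the `mean`
#'   and `sd` used.
#' @export
qcOutliers <- function(x, nSd = 3) {
  stopifnot(is.numeric(x))
  if (length(x) < 3L) {
    warning("fewer than 3 values; no outlier exclusion performed")
    return(list(keep = seq_along(x), excluded = integer(),
                mean = mean(x), sd = stats::sd(x)))
  }
  m <- mean(x); s <- stats::sd(x)
  out <- which(abs(x - m) > nSd * s)
  list(keep = setdiff(seq_along(x), out), excluded = out, mean = m, sd = s)
}

#' Cohort summary of maximum pupil-margin strains
#'
#' Averages test-retest scans within each eye, then reports the cohort mean,
#' standard deviation and normal-theory confidence interval
#' (`mean ± z * sd / sqrt(n)`) over eyes.
#'
#' @param values numeric strain values, one per scan.
#' @param eye eye labels (test-retest scans share a label).
#' @param z CI quantile (default 1.96 for 95%).
#' @return list with `perEye` (data.frame `eye`, `value`, `nScans`), `mean`,
#'   `sd`, `ciLower`, `ciUpper`, `n`.
#' @export
summarizeStrains <- function(values, eye, z = 1.96) {
  stopifnot(length(values) == length(eye))
  ok <- is.finite(values)
  if (any(!ok)) {
    warning(sum(!ok), " non-finite value(s) omitted")
    values <- values[ok]; eye <- eye[ok]
  }
  if (!length(values)) stopIris("no values to summarize")
  perEye <- stats::aggregate(values, by = list(eye = eye), FUN = mean)
  names(perEye)[2] <- "value"
  perEye$nScans <- as.integer(table(eye)[as.character(perEye$eye)])
  v <- perEye$value
  n <- length(v)
  m <- mean(v)
  s <- if (n > 1) stats::sd(v) else 0
  half <- z * s / sqrt(n)
  list(perEye = perEye, mean = m, sd = s,
       ciLower = m - half, ciUpper = m + half, n = n)
}
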