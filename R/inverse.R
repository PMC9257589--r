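#' Traction-to-stiffness ratio by scalar root finding
#'
#' The pupil-margin strain of the iris model depends on the material and
#' loading only through `rho = Ts / E` (and `nu`): stresses are homogeneous
#' of degree one in `(E, Ts)`. This solves `eps_p(rho) = target` by bracketed
#' root finding with `E = 1`, providing a deterministic, optimizer-free route
#' to the ratio (and an independent cross-check for [fitSingle()]).
#'
#' @param target target pupil-margin Lagrangian strain, in `(-0.5, 0]`.
#' @param asMm sphincter ring width (mm).
#' @param nu Poisson's ratio. The default 0.49 is the conventional
#'   near-incompressibility value for soft tissue; `nu` is not identifiable
#'   from pupil strain alone.
#' @param nElements finite elements in the solver.
#' @param rhoMax upper limit for bracket expansion.
#' @param tol root tolerance on `rho`.
#' @return the ratio `Ts : E` (dimensionless).
#' @export
ratioRoot <- function(target, asMm = 1, nu = 0.49, nElements = 200L,
                      rhoMax = 200, tol = 1e-7) {
  if (!is.finite(target) || target > 0 || target <= -0.5)
    stopIris("target strain must be in (-0.5, 0]")
  if (target == 0) return(0)
  epsAt <- function(rho) {
    cfg <- irisModelConfig(EkPa = 1, TskPa = rho, nu = nu, asMm = asMm,
                           nElements = nElements,
                           loadSteps = max(10L, ceiling(2 * rho)))
    sol <- solveIris(cfg)
    if (!sol@converged) stopIris("solver failed at rho = ", signif(rho, 4))
    sol@epsP
  }
  f <- function(rho) epsAt(rho) - target
  hi <- 8
  fhi <- f(hi)
  while (fhi > 0 && hi < rhoMax) {    # strain not yet negative enough
    hi <- hi * 2
    fhi <- f(hi)
  }
  if (fhi > 0)
    stopIris("no bracket for target ", target, " within rho <= ", rhoMax)
  stats::uniroot(f, c(0, hi), f.upper = fhi, tol = tol)$root
}

#' Multi-start inverse identification of (E, nu, Ts)
#'
#' Minimizes the absolute difference between the model and target
#' pupil-margin strain over `(E, nu, Ts)` from `nStarts` deterministic
#' low-discrepancy (Halton) starting points inside the search box, using
#' gradient-free Nelder-Mead local minimization (the FE objective has noisy
#' numerical derivatives). Fits with objective below `tol` are accepted; the
#' traction-to-stiffness ratio is reported as the through-origin regression
#' slope of `Ts` on `E` over accepted fits (scale invariance forces a zero
#' intercept), with the free-intercept slope and the median per-fit ratio as
#' diagnostics.
#'
#' @inheritParams ratioRoot
#' @param bounds list with elements `E`, `nu`, `Ts`, each `c(lo, hi)`.
#'   Default: `0 < E < 1000` kPa, `0 < nu < 0.5`, `0 < Ts < 1000` kPa.
#' @param nStarts number of starting points (default 25).
#' @param tol acceptance tolerance on the strain-mismatch objective.
#' @param nElements finite elements used in the forward model.
#' @param maxit Nelder-Mead iteration cap per start.
#' @return a [FitResult-class].
#' @export
fitSingle <- function(target, asMm = 1,
                      bounds = list(E = c(0, 1000), nu = c(0, 0.5),
                                    Ts = c(0, 1000)),
                      nStarts = 25L, tol = 1e-3, nElements = 100L,
                      maxit = 200L) {
  if (!is.finite(target) || target > 0 || target <= -0.5)
    stopIris("target strain must be in (-0.5, 0]")
  lo <- vapply(bounds, `[`, numeric(1), 1L)
  hiB <- vapply(bounds, `[`, numeric(1), 2L)
  stopifnot(all(hiB > lo))

  objective <- function(p) {
    if (any(p < lo) || any(p > hiB))
      return(1 + sum(pmax(lo - p, 0) + pmax(p - hiB, 0)))
    E <- max(p[1], 1e-6); nuv <- min(max(p[2], 1e-4), 0.4999)
    Ts <- max(p[3], 0)
    rho <- Ts / E
    cfg <- irisModelConfig(EkPa = E, TskPa = Ts, nu = nuv, asMm = asMm,
                           nElements = nElements,
                           loadSteps = max(5L, ceiling(2 * rho)))
    sol <- tryCatch(suppressWarnings(solveIris(cfg)), error = function(e) NULL)
    if (is.null(sol) || !sol@converged) return(10)
    abs(sol@epsP - target)
  }

  u <- haltonSeq(nStarts, 3L)
  starts <- sweep(sweep(u, 2, (hiB - lo) * 0.96, `*`), 2,
                  lo + 0.02 * (hiB - lo), `+`)
  colnames(starts) <- c("E0", "nu0", "Ts0")
  rows <- vector("list", nStarts)
  for (i in seq_len(nStarts)) {
    fit <- stats::optim(starts[i, ], objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = 1e-10))
    rows[[i]] <- data.frame(
      E0 = starts[i, 1], nu0 = starts[i, 2], Ts0 = starts[i, 3],
      E = fit$par[1], nu = fit$par[2], Ts = fit$par[3],
      objective = fit$value, converged = fit$convergence == 0L,
      accepted = fit$value < tol)
  }
  res <- do.call(rbind, rows)
  acc <- res[res$accepted, ]
  if (!nrow(acc)) stopIris("identification failed: no accepted fits")
  slope <- sum(acc$Ts * acc$E) / sum(acc$E^2)
  slopeFree <- if (nrow(acc) > 1)
    unname(stats::coef(stats::lm(Ts ~ E, data = acc))[2]) else NA_real_
  new("FitResult", starts = res, slope = slope, slopeFree = slopeFree,
      ratioMedian = stats::median(acc$Ts / acc$E), target = target,
      asMm = asMm, tol = tol)
}

#' Traction-to-stiffness ratio across sphincter widths
#'
#' Repeats the inverse identification for each sphincter ring width via
#' [ratioRoot()] (optionally cross-checked against the multi-start route).
#' The ratio needed to reach the same pupil strain decreases strictly with
#' muscle width.
#'
#' @inheritParams ratioRoot
#' @param widths sphincter widths to sweep (mm);
#'   default `c(0.4, 0.7, 1.0, 1.3)`.
#' @param crossCheck if `TRUE`, also run [fitSingle()] per width and include
#'   its slope.
#' @param ... passed to [fitSingle()] when `crossCheck = TRUE`.
#' @return data.frame with columns `asMm`, `ratio` (and `slopeMultistart` if
#'   cross-checked).
#' @export
widthSweep <- function(target, widths = c(0.4, 0.7, 1.0, 1.3), nu = 0.49,
                       nElements = 200L, crossCheck = FALSE, ...) {
  stopifnot(all(widths > 0))
  out <- data.frame(asMm = widths, ratio = NA_real_)
  for (i in seq_along(widths)) {
    out$ratio[i] <- tryCatch(
      ratioRoot(target, asMm = widths[i], nu = nu, nElements = nElements),
      error = function(e)
        stopIris("width ", widths[i], " mm: ", conditionMessage(e)))
  }
  if (crossCheck)
    out$slopeMultistart <- vapply(widths, function(w)
      ratioEstimate(fitSingle(target, asMm = w, ...)), numeric(1))
  out
}

#' Power-law regression of ratio versus sphincter width
#'
#' Fits `ratio = (A / asMm)^B` by nonlinear least squares (initialized from
#' the log-log linear regression), with 95% confidence intervals from the
#' linearized covariance and t-quantiles at `n - 2` degrees of freedom.
#'
#' @param sweep data.frame with columns `asMm` and `ratio`
#'   (as returned by [widthSweep()]), or a numeric vector of widths when
#'   `ratio` is given separately.
#' @param ratio optional numeric ratios matching `sweep` as a width vector.
#' @param level confidence level (default 0.95).
#' @return list with `A` (mm), `B`, `ciA`, `ciB`, `fitted`, `residuals` and
#'   the underlying `nls` fit.
#' @export
fitPowerLaw <- function(sweep, ratio = NULL, level = 0.95) {
  if (is.data.frame(sweep)) {
    a <- sweep$asMm; r <- sweep$ratio
  } else {
    a <- sweep; r <- ratio
  }
  ok <- is.finite(a) & is.finite(r) & a > 0 & r > 0
  a <- a[ok]; r <- r[ok]
  if (length(a) < 3L) stopIris("underdetermined: need >= 3 width/ratio pairs")
  ll <- stats::lm(log(r) ~ log(a))
  B0 <- max(unname(-stats::coef(ll)[2]), 1e-3)
  A0 <- exp(unname(stats::coef(ll)[1]) / B0)
  fit <- minpack.lm::nlsLM(r ~ (A / a)^B, start = list(A = A0, B = B0),
                           lower = c(1e-6, 1e-6))
  est <- stats::coef(fit)
  se <- summary(fit)$coefficients[, "Std. Error"]
  tq <- stats::qt(1 - (1 - level) / 2, df = length(a) - 2)
  list(A = unname(est["A"]), B = unname(est["B"]),
       ciA = unname(est["A"] + c(-1, 1) * tq * se["A"]),
       ciB = unname(est["B"] + c(-1, 1) * tq * se["B"]),
       fitted = unname(stats::fitted(fit)),
       residuals = unname(stats::residuals(fit)),
       fit = fit)
}
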