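#' Create an iris annulus model configuration
#'
#' Defaults follow the reference geometry: inner (pupil) radius 3.4 mm, outer
#' (limbus) radius 6 mm, thickness 0.17 mm, sphincter ring width 1 mm. The
#' stroma is compressible neo-Hookean with Young's modulus `EkPa` and Poisson
#' ratio `nu`; the sphincter contributes an active circumferential Cauchy
#' stress of magnitude `TskPa` in the material ring `[RinMm, RinMm + asMm]`.
#'
#' @param ... named values overriding any [IrisModelConfig-class] slot.
#' @return a validated [IrisModelConfig-class].
#' @export
irisModelConfig <- function(...) {
  args <- list(...)
  for (nm in c("nElements", "loadSteps"))
    if (!is.null(args[[nm]])) args[[nm]] <- as.integer(args[[nm]])
  do.call(new, c(list("IrisModelConfig"), args))
}

lameParams <- function(E, nu) {
  list(mu = E / (2 * (1 + nu)), lambda = E * nu / ((1 + nu) * (1 - 2 * nu)))
}

#' Through-thickness stretch from the plane-stress condition
#'
#' Solves `sigma_zz = 0` for `lambda_z` given the in-plane stretches, i.e.
#' `mu (lambda_z^2 - 1) + lambda_L log(lambda_r lambda_t lambda_z) = 0`,
#' by a vectorized Newton iteration.
#'
#' @param lambdaR,lambdaTheta in-plane principal stretches (> 0).
#' @param E Young's modulus, any stress unit.
#' @param nu Poisson's ratio in (0, 0.5).
#' @param init initial guess (recycled).
#' @return lambda_z values satisfying plane stress to ~1e-14.
#' @export
planeStressLambdaZ <- function(lambdaR, lambdaTheta, E, nu, init = 1) {
  if (any(lambdaR <= 0) || any(lambdaTheta <= 0))
    stopIris("stretches must be positive")
  lp <- lameParams(E, nu)
  lz <- rep_len(init, length(lambdaR))
  for (k in 1:100) {
    g <- lp$mu * (lz^2 - 1) + lp$lambda * log(lambdaR * lambdaTheta * lz)
    dg <- 2 * lp$mu * lz + lp$lambda / lz
    d <- g / dg
    lz <- pmax(lz - d, 1e-8)
    if (max(abs(d)) < 1e-14) break
  }
  lz
}

#' Principal Cauchy stresses of the iris material model
#'
#' Passive compressible neo-Hookean part
#' `sigma_i = (mu / J)(lambda_i^2 - 1) + (lambda_L / J) log J` with
#' `mu = E / (2(1 + nu))`, `lambda_L = E nu / ((1 + nu)(1 - 2 nu))`, plus an
#' active circumferential part `Ts * lambda_theta^2 / J` added to
#' `sigma_thetatheta` only. The active part is the push-forward of a fiber
#' stress of magnitude `Ts` per unit reference area along the hoop direction
#' (the convention of standard FE implementations of prescribed uniaxial
#' active contraction); at the reference state it reduces to `Ts` exactly.
#'
#' @param lambdaR,lambdaTheta,lambdaZ principal stretches (> 0), recycled.
#' @param E Young's modulus (kPa).
#' @param nu Poisson's ratio.
#' @param Ts active traction magnitude (kPa); applies at the evaluated point
#'   (pass 0 outside the sphincter ring).
#' @return matrix with columns `sigmaRR`, `sigmaTT`, `sigmaZZ` (kPa).
#' @export
cauchyStress <- function(lambdaR, lambdaTheta, lambdaZ, E, nu, Ts = 0) {
  if (any(lambdaR <= 0) || any(lambdaTheta <= 0) || any(lambdaZ <= 0))
    stopIris("stretches must be positive")
  lp <- lameParams(E, nu)
  J <- lambdaR * lambdaTheta * lambdaZ
  lnJ <- log(J)
  pass <- function(l) (lp$mu * (l^2 - 1) + lp$lambda * lnJ) / J
  cbind(sigmaRR = pass(lambdaR),
        sigmaTT = pass(lambdaTheta) + Ts * lambdaTheta^2 / J,
        sigmaZZ = pass(lambdaZ))
}

# Mesh with a node snapped to the sphincter outer edge so the active ring is
# resolved exactly; without it the converged solution jitters with mesh
# density at the 1e-3 level.
irisMesh <- function(Rin, Rout, as_, nel) {
  n1 <- max(4L, round(nel * as_ / (Rout - Rin)))
  n2 <- max(4L, nel - n1)
  c(seq(Rin, Rin + as_, length.out = n1 + 1),
    seq(Rin + as_, Rout, length.out = n2 + 1)[-1])
}

#' Solve the axisymmetric plane-stress iris boundary-value problem
#'
#' Finds the equilibrium deformation `r(R)` of the annulus under active
#' sphincter traction: 1-d Galerkin finite elements (linear shape functions,
#' 2-point Gauss quadrature) on the weak form of radial equilibrium in the
#' reference configuration, with the through-thickness stretch condensed out
#' pointwise by the plane-stress condition. Boundary conditions: traction-free
#' inner edge (natural) and fixed outer edge `r(Rout) = Rout` (the limbus does
#' not move). The load is ramped in `loadSteps` equal increments of `TskPa`
#' with Newton iteration, a feasibility line search, and adaptive step
#' halving on divergence.
#'
#' @param cfg an [IrisModelConfig-class].
#' @return an [FESolution-class]; `pupilStrain(sol)` is the pupil-margin
#'   Lagrangian strain `(lambda_theta(Rin)^2 - 1) / 2`.
#' @export
solveIris <- function(cfg) {
  stopifnot(is(cfg, "IrisModelConfig"))
  validObject(cfg)
  E <- cfg@EkPa; nu <- cfg@nu; Ts <- cfg@TskPa
  lp <- lameParams(E, nu)
  mu <- lp$mu; lam <- lp$lambda
  nodes <- irisMesh(cfg@RinMm, cfg@RoutMm, cfg@asMm, cfg@nElements)
  nel <- length(nodes) - 1L
  n <- nel + 1L
  h <- diff(nodes)
  gp <- c(-1, 1) / sqrt(3)
  Rq <- as.vector(vapply(seq_len(nel), function(e)
    (nodes[e] + nodes[e + 1]) / 2 + gp * h[e] / 2, numeric(2)))
  eidx <- rep(seq_len(nel), each = 2L)
  active <- Rq <= cfg@RinMm + cfg@asMm + 1e-12
  wq <- rep(h / 2, each = 2L) * Rq          # Gauss weight x Jacobian x R
  B1 <- -1 / h[eidx]; B2 <- 1 / h[eidx]
  N2g <- (Rq - nodes[eidx]) / h[eidx]; N1g <- 1 - N2g

  lzState <- rep(1, length(Rq))
  resScale <- max(E, Ts, 1)

  assemble <- function(r, Tcur) {
    lr <- (r[eidx + 1] - r[eidx]) / h[eidx]
    lt <- (N1g * r[eidx] + N2g * r[eidx + 1]) / Rq
    lz <- planeStressLambdaZ(lr, lt, E, nu, init = lzState)
    lzState <<- lz
    lnJ <- log(lr * lt * lz)
    Tq <- ifelse(active, Tcur, 0)
    Pr <- (mu * (lr^2 - 1) + lam * lnJ) / lr        # nominal radial stress
    Pt <- (mu * (lt^2 - 1) + lam * lnJ) / lt + Tq * lt
    # condensed tangent moduli d P_i / d lambda_j with lambda_z eliminated
    psi2 <- function(l) mu + (mu + lam * (1 - lnJ)) / l^2
    pzz <- psi2(lz)
    Crr <- psi2(lr) - (lam / (lr * lz))^2 / pzz
    Ctt <- psi2(lt) - (lam / (lt * lz))^2 / pzz + Tq
    Crt <- lam / (lr * lt) - (lam / (lr * lz)) * (lam / (lt * lz)) / pzz

    f1 <- wq * (Pr * B1 + Pt * N1g / Rq)
    f2 <- wq * (Pr * B2 + Pt * N2g / Rq)
    res <- numeric(n)
    for (q in seq_along(Rq)) {
      e <- eidx[q]
      res[e] <- res[e] + f1[q]
      res[e + 1] <- res[e + 1] + f2[q]
    }
    k11 <- wq * (B1 * Crr * B1 + (B1 * N1g + N1g * B1) * Crt / Rq +
                   N1g * Ctt * N1g / Rq^2)
    k12 <- wq * (B1 * Crr * B2 + (B1 * N2g + N1g * B2) * Crt / Rq +
                   N1g * Ctt * N2g / Rq^2)
    k21 <- wq * (B2 * Crr * B1 + (B2 * N1g + N2g * B1) * Crt / Rq +
                   N2g * Ctt * N1g / Rq^2)
    k22 <- wq * (B2 * Crr * B2 + (B2 * N2g + N2g * B2) * Crt / Rq +
                   N2g * Ctt * N2g / Rq^2)
    dSub <- dSup <- dDiag <- numeric(n)
    for (q in seq_along(Rq)) {
      e <- eidx[q]
      dDiag[e] <- dDiag[e] + k11[q]
      dDiag[e + 1] <- dDiag[e + 1] + k22[q]
      dSup[e] <- dSup[e] + k12[q]      # entry (e, e+1)
      dSub[e] <- dSub[e] + k21[q]      # entry (e+1, e)
    }
    list(res = res, dDiag = dDiag, dSup = dSup, dSub = dSub)
  }

  # Thomas algorithm for the tridiagonal Newton system with the Dirichlet
  # row at the outer node.
  triSolve <- function(dDiag, dSup, dSub, rhs) {
    dDiag[n] <- 1; rhs[n] <- 0
    dSub[n - 1] <- 0
    cp <- numeric(n); dp <- numeric(n)
    cp[1] <- dSup[1] / dDiag[1]; dp[1] <- rhs[1] / dDiag[1]
    for (i in 2:n) {
      m <- dDiag[i] - dSub[i - 1] * cp[i - 1]
      cp[i] <- if (i < n) dSup[i] / m else 0
      dp[i] <- (rhs[i] - dSub[i - 1] * dp[i - 1]) / m
    }
    x <- numeric(n)
    x[n] <- dp[n]
    for (i in (n - 1):1) x[i] <- dp[i] - cp[i] * x[i + 1]
    x
  }

  r <- nodes
  fLoad <- 0
  df <- 1 / cfg@loadSteps
  dfMin <- df / 2^7
  converged <- TRUE
  while (fLoad < 1 - 1e-12) {
    step <- min(df, 1 - fLoad)
    rTrial <- r
    ok <- FALSE
    for (it in 1:60) {
      sys <- assemble(rTrial, Ts * (fLoad + step))
      if (sqrt(sum(sys$res[-n]^2)) < cfg@newtonTol * resScale) { ok <- TRUE; break }
      dr <- triSolve(sys$dDiag, sys$dSup, sys$dSub, -sys$res)
      alpha <- 1
      feasible <- function(a) {
        rn <- rTrial + a * dr
        all(rn > 0) && all(diff(rn) > 0)
      }
      while (alpha > 1e-8 && !feasible(alpha)) alpha <- alpha / 2
      if (alpha <= 1e-8) break
      rTrial <- rTrial + alpha * dr
    }
    if (ok) {
      r <- rTrial
      fLoad <- fLoad + step
    } else {
      df <- df / 2
      if (df < dfMin) { converged <- FALSE; break }
    }
  }

  midR <- (nodes[-n] + nodes[-1]) / 2
  lrMid <- diff(r) / h
  ltMid <- (r[-n] + r[-1]) / 2 / midR
  lzMid <- planeStressLambdaZ(lrMid, ltMid, E, nu)
  if (!converged)
    warning(sprintf("solver failed: last converged load fraction %.4f", fLoad))
  new("FESolution", config = cfg, nodesR = nodes, r = r, midR = midR,
      lambdaR = lrMid, lambdaTheta = ltMid, lambdaZ = lzMid,
      J = lrMid * ltMid * lzMid,
      epsP = 0.5 * ((r[1] / cfg@RinMm)^2 - 1),
      converged = converged, loadFraction = fLoad)
}

#' Model strain profiles versus normalized radial position
#'
#' Lagrangian strains `E_rr = (lambda_r^2 - 1)/2` and
#' `E_tt = (lambda_theta^2 - 1)/2` (and `E_rt = 0` by axisymmetry) sampled at
#' element midpoints against `xbar = (R - Rin) / (Rout - Rin)`. The location
#' of the radial-strain peak (expected at the sphincter outer edge) is
#' available via [peakRadialStrain()].
#'
#' @param sol a converged [FESolution-class].
#' @return a [StrainProfile-class] with `source = "model"`.
#' @export
strainProfiles <- function(sol) {
  stopifnot(is(sol, "FESolution"))
  cfg <- sol@config
  xbar <- (sol@midR - cfg@RinMm) / (cfg@RoutMm - cfg@RinMm)
  comp <- function(name, v)
    data.frame(xbar = xbar, component = name, median = v, q1 = v, q3 = v,
               n = 1L)
  d <- rbind(comp("Err", 0.5 * (sol@lambdaR^2 - 1)),
             comp("Ett", 0.5 * (sol@lambdaTheta^2 - 1)),
             comp("Ert", rep(0, length(xbar))))
  new("StrainProfile", data = d, source = "model")
}

#' Location of the peak radial strain in a profile
#'
#' @param profile a [StrainProfile-class].
#' @param component component to scan (default `"Err"`).
#' @return `xbar` at the maximum median value of the component.
#' @export
peakRadialStrain <- function(profile, component = "Err") {
  d <- traceData(profile)
  d <- d[d$component == component & is.finite(d$median), ]
  d$xbar[which.max(d$median)]
}
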