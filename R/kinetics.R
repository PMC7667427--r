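# Compartment models: one-compartment (Kety) control agent and
# two-compartment (free + bound) targeted agent, driven by a biexponential
# plasma input. Both a numerical (adaptive Runge-Kutta) route and an exact
# closed-form route (eigendecomposition of the linear system) are provided;
# they are cross-checked in the test suite.

#' @describeIn rateK3 `kon * Bavail`
#' @export
setMethod("rateK3", "AgentKinetics", function(object) object@kon * object@Bavail)

#' @describeIn rateK4 `koff`
#' @export
setMethod("rateK4", "AgentKinetics", function(object) object@koff)

#' @describeIn dissociationConstant `koff / kon`
#' @export
setMethod("dissociationConstant", "AgentKinetics", function(object) {
  if (object@kon > 0) object@koff / object@kon else NA_real_
})

#' @describeIn bindingPotential `kon * Bavail / koff`
#' @export
setMethod("bindingPotential", "AgentKinetics", function(object) {
  if (object@koff > 0) object@kon * object@Bavail / object@koff else NA_real_
})

# Kety closed form, vectorized over (K1, k2) pairs: returns an
# length(K1) x length(t) matrix. Near-degenerate rates (|k2 - gamma| below
# tol) use the analytic limit K1 c t exp(-k2 t).
.ketyMulti <- function(K1, k2, p, t, tol = 1e-9) {
  n <- max(length(K1), length(k2))
  K1 <- rep_len(K1, n); k2 <- rep_len(k2, n)
  out <- matrix(0, n, length(t))
  ek2 <- exp(-outer(k2, t))
  for (m in 1:2) {
    cc <- p@scale * c(p@A, p@B)[m]
    g <- c(p@alpha, p@beta)[m]
    if (cc == 0) next
    deg <- abs(k2 - g) < tol
    if (any(!deg)) {
      coef <- ifelse(deg, 0, K1 * cc / (k2 - g))
      out <- out + coef * (matrix(exp(-g * t), n, length(t), byrow = TRUE) - ek2)
    }
    if (any(deg)) {
      tm <- matrix(t, n, length(t), byrow = TRUE)
      out[deg, ] <- out[deg, , drop = FALSE] +
        (K1[deg] * cc) * (tm * ek2)[deg, , drop = FALSE]
    }
  }
  out[out < 0] <- 0   # cancellation round-off near-degenerate rates
  out
}

#' Closed-form Kety (one-compartment) tissue curve
#'
#' Analytic solution of `dC/dt = K1 Cp(t) - k2 C(t)`, `C(0) = 0`, for a
#' biexponential plasma input:
#' \deqn{C(t) = K_1 s \left[\frac{A}{k_2-\alpha}(e^{-\alpha t}-e^{-k_2 t})
#'   + \frac{B}{k_2-\beta}(e^{-\beta t}-e^{-k_2 t})\right].}
#' When `k2` coincides with a plasma rate constant (within `1e-9`), the
#' degenerate limit \eqn{K_1 c\, t e^{-k_2 t}} is used for that term.
#'
#' @param K1 extravasation rate (1/min), `>= 0`.
#' @param k2 efflux rate (1/min), `>= 0`.
#' @param p a [PlasmaInput-class].
#' @param t time grid (min), nonnegative.
#' @return Free-concentration curve (nM), same length as `t`.
#' @examples
#' p <- plasmaInput(0.6, 0.2, 0.4, 5e-3)
#' ketyClosedForm(0.1, 0.02, p, seq(0, 60, 1))
#' @export
ketyClosedForm <- function(K1, k2, p, t) {
  stopifnot(is(p, "PlasmaInput"))
  .assertScalarNonneg(K1, "K1"); .assertScalarNonneg(k2, "k2")
  if (any(t < 0)) stop("negative times are outside the model domain", call. = FALSE)
  drop(.ketyMulti(K1, k2, p, t))
}

# Exact solution of the two-compartment targeted system for exponential
# inputs, vectorized over parameter vectors. Returns list(cf, cb) of
# n x length(t) matrices. Plasma rates resonant with a system eigenvalue
# are nudged by a relative 1e-7 (error of the same order, far below solver
# tolerances used elsewhere).
.targetedMulti <- function(K1, k2, k3, k4, p, t) {
  n <- max(length(K1), length(k2), length(k3), length(k4))
  K1 <- rep_len(K1, n); k2 <- rep_len(k2, n)
  k3 <- rep_len(k3, n); k4 <- rep_len(k4, n)
  nt <- length(t)
  cf <- matrix(0, n, nt); cb <- matrix(0, n, nt)

  zero4 <- k4 <= 0
  if (any(!zero4)) {
    i <- which(!zero4)
    a <- k2[i] + k3[i]
    disc <- sqrt((a - k4[i])^2 + 4 * k3[i] * k4[i])
    l1 <- (a + k4[i] - disc) / 2
    l2 <- (a + k4[i] + disc) / 2
    g1 <- a - l1; g2 <- a - l2
    Sf <- numeric(length(i)); Sb <- numeric(length(i))
    for (m in 1:2) {
      cc <- p@scale * c(p@A, p@B)[m]
      g <- c(p@alpha, p@beta)[m]
      if (cc == 0) next
      res <- pmin(abs(g - l1), abs(g - l2)) < 1e-7 * pmax(g, 1e-3)
      gv <- rep_len(g, length(i))
      gv[res] <- gv[res] * (1 + 1e-7) + 1e-12
      D <- (gv - l1) * (gv - l2)
      pf <- -K1[i] * cc * (gv - k4[i]) / D
      pb <- K1[i] * cc * k3[i] / D
      eg <- exp(-outer(gv, t))
      cf[i, ] <- cf[i, , drop = FALSE] + pf * eg
      cb[i, ] <- cb[i, , drop = FALSE] + pb * eg
      Sf <- Sf + pf; Sb <- Sb + pb
    }
    detV <- k4[i] * (l1 - l2)
    h1 <- (-g2 * Sf + k4[i] * Sb) / detV
    h2 <- (g1 * Sf - k4[i] * Sb) / detV
    e1 <- exp(-outer(l1, t)); e2 <- exp(-outer(l2, t))
    cf[i, ] <- cf[i, , drop = FALSE] + k4[i] * (h1 * e1 + h2 * e2)
    cb[i, ] <- cb[i, , drop = FALSE] + g1 * h1 * e1 + g2 * h2 * e2
  }

  if (any(zero4)) {
    # irreversible binding: Cf is Kety with efflux k2 + k3, Cb = k3 int Cf
    i <- which(zero4)
    a <- k2[i] + k3[i]
    cf[i, ] <- .ketyMulti(K1[i], a, p, t)
    for (m in 1:2) {
      cc <- p@scale * c(p@A, p@B)[m]
      g <- c(p@alpha, p@beta)[m]
      if (cc == 0) next
      deg <- abs(a - g) < 1e-9
      tm <- matrix(t, length(i), nt, byrow = TRUE)
      ea <- exp(-outer(a, t)); egm <- matrix(exp(-g * t), length(i), nt, byrow = TRUE)
      intCf <- matrix(0, length(i), nt)
      if (any(!deg)) {
        j <- !deg
        intCf[j, ] <- (K1[i][j] * cc / (a[j] - g)) *
          ((1 - egm[j, , drop = FALSE]) / g - (1 - ea[j, , drop = FALSE]) / a[j])
      }
      if (any(deg)) {
        j <- deg
        intCf[j, ] <- (K1[i][j] * cc / a[j]^2) *
          (1 - (1 + a[j] * tm[j, , drop = FALSE]) * ea[j, , drop = FALSE])
      }
      cb[i, ] <- cb[i, , drop = FALSE] + k3[i] * intCf
    }
  }

  # negative values can only be cancellation round-off (the solution of a
  # positive linear system with nonnegative input is nonnegative)
  cf[cf < 0] <- 0
  cb[cb < 0] <- 0
  list(cf = cf, cb = cb)
}

#' Closed-form targeted-agent uptake curves
#'
#' Exact solution of the linear two-compartment system
#' \deqn{dC_f/dt = K_1 C_p(t) - (k_2 + k_3) C_f + k_4 C_b, \quad
#'       dC_b/dt = k_3 C_f - k_4 C_b,}
#' with zero initial conditions and a biexponential plasma input, obtained
#' by eigendecomposition of the 2x2 system matrix. Agrees with
#' [solveTargeted()] to the solver tolerance and is considerably faster; it
#' is the engine behind the scene renderer and the Monte-Carlo study.
#'
#' @param k an [AgentKinetics-class].
#' @param p a [PlasmaInput-class].
#' @param t time grid (min) starting at 0.
#' @return An [UptakeCurves-class] with `cfT` and `cbT` populated.
#' @export
targetedClosedForm <- function(k, p, t) {
  stopifnot(is(k, "AgentKinetics"), is(p, "PlasmaInput"))
  .assertTimeGrid(t)
  sol <- .targetedMulti(k@K1, k@k2, rateK3(k), rateK4(k), p, t)
  .newTargetedCurves(t, drop(sol$cf), drop(sol$cb), k)
}

.newTargetedCurves <- function(t, cf, cb, k) {
  trace <- FALSE
  if (k@Bavail > 0 && rateK3(k) > 0) {
    trace <- max(cb) >= 0.05 * k@Bavail
    if (trace)
      warning("trace condition violated: max bound concentration ",
              sprintf("%.3g", max(cb)), " nM >= 5% of Bavail (",
              sprintf("%.3g", 0.05 * k@Bavail), " nM)", call. = FALSE)
  }
  new("UptakeCurves", time = t, cfT = pmax(cf, 0), cbT = pmax(cb, 0),
      bavail = k@Bavail, traceExceeded = trace)
}

#' Numerically solve the targeted-agent two-compartment model
#'
#' Integrates the free/bound system with an adaptive Runge-Kutta method
#' (Dormand-Prince 4(5), `rtol = 1e-8`, `atol = 1e-12`) with dense output on
#' the requested grid. Zero initial conditions. If the bound concentration
#' exceeds 5% of `Bavail` anywhere (trace-condition violation, outside the
#' regime in which the linear model is a faithful reduction of saturable
#' binding), a warning is emitted and the `traceExceeded` flag is set.
#'
#' @param k an [AgentKinetics-class].
#' @param p a [PlasmaInput-class].
#' @param t time grid (min) starting at 0.
#' @param rtol,atol solver tolerances.
#' @return An [UptakeCurves-class] with `cfT` and `cbT` populated.
#' @examples
#' k <- agentKinetics(K1 = 0.4, k2 = 0.2, kon = 0.1, koff = 0.1, Bavail = 10)
#' p <- plasmaInput(0.02, 0.3, 2e-3, 6e-4)
#' curves <- solveTargeted(k, p, seq(0, 60, 0.5))
#' @export
solveTargeted <- function(k, p, t, rtol = 1e-8, atol = 1e-12) {
  stopifnot(is(k, "AgentKinetics"), is(p, "PlasmaInput"))
  .assertTimeGrid(t)
  k3 <- rateK3(k); k4 <- rateK4(k)
  rhs <- function(time, y, parms) {
    cp <- p@scale * (p@A * exp(-p@alpha * time) + p@B * exp(-p@beta * time))
    list(c(k@K1 * cp - (k@k2 + k3) * y[1] + k4 * y[2],
           k3 * y[1] - k4 * y[2]))
  }
  sol <- deSolve::ode(y = c(cf = 0, cb = 0), times = t, func = rhs,
                      parms = NULL, method = "ode45", rtol = rtol, atol = atol)
  diagn <- attr(sol, "istate")
  if (!is.null(diagn) && diagn[1] < 0)
    stop("ODE integration failed (istate = ", diagn[1], ")", call. = FALSE)
  if (nrow(sol) != length(t) || any(!is.finite(sol[, 2:3])))
    stop("ODE integration failed: non-finite solution or truncated output",
         call. = FALSE)
  .newTargetedCurves(t, pmax(sol[, "cf"], 0), pmax(sol[, "cb"], 0), k)
}

#' Numerically solve the control-agent one-compartment (Kety) model
#'
#' Integrates `dC/dt = K1 Cp(t) - k2 C` with the same adaptive Runge-Kutta
#' settings as [solveTargeted()]. Agrees with [ketyClosedForm()] to the
#' solver tolerance.
#'
#' @param k an [AgentKinetics-class] (binding parameters ignored).
#' @param p a [PlasmaInput-class].
#' @param t time grid (min) starting at 0.
#' @param rtol,atol solver tolerances.
#' @return An [UptakeCurves-class] with `cfC` populated.
#' @export
solveControl <- function(k, p, t, rtol = 1e-8, atol = 1e-12) {
  stopifnot(is(k, "AgentKinetics"), is(p, "PlasmaInput"))
  .assertTimeGrid(t)
  rhs <- function(time, y, parms) {
    cp <- p@scale * (p@A * exp(-p@alpha * time) + p@B * exp(-p@beta * time))
    list(k@K1 * cp - k@k2 * y)
  }
  sol <- deSolve::ode(y = c(cf = 0), times = t, func = rhs, parms = NULL,
                      method = "ode45", rtol = rtol, atol = atol)
  if (nrow(sol) != length(t) || any(!is.finite(sol[, 2])))
    stop("ODE integration failed: non-finite solution or truncated output",
         call. = FALSE)
  new("UptakeCurves", time = t, cfC = pmax(sol[, "cf"], 0))
}

#' Combine targeted and control uptake curves
#'
#' @param targeted an [UptakeCurves-class] with `cfT`/`cbT` populated.
#' @param control an [UptakeCurves-class] with `cfC` populated, on the same
#'   time grid.
#' @return An [UptakeCurves-class] with all three channels.
#' @export
combineCurves <- function(targeted, control) {
  stopifnot(is(targeted, "UptakeCurves"), is(control, "UptakeCurves"))
  if (!isTRUE(all.equal(targeted@time, control@time)))
    stop("curves must share the same time grid", call. = FALSE)
  targeted@cfC <- control@cfC
  targeted
}

#' Assemble measurable ROI signals from tissue curves
#'
#' The targeted and control region-of-interest signals are weighted sums of
#' the vascular and tissue compartments:
#' \deqn{ROI_T = \eta_T [v_p C_p + (1 - v_p)(C_{f,T} + C_{b,T})], \quad
#'       ROI_C = \eta_C [v_p C_p + (1 - v_p) C_{f,C}].}
#'
#' @param curves an [UptakeCurves-class] with tissue channels populated.
#' @param p a [PlasmaInput-class] (for the vascular term).
#' @param vp fractional blood volume in `[0, 1)` (default 0).
#' @param etaT,etaC channel scale factors (default 1, the post-normalization
#'   convention).
#' @return The input curves with `roiT` and/or `roiC` populated.
#' @export
roiSignal <- function(curves, p, vp = 0, etaT = 1, etaC = 1) {
  stopifnot(is(curves, "UptakeCurves"), is(p, "PlasmaInput"))
  if (length(vp) != 1L || !is.finite(vp) || vp < 0 || vp >= 1)
    stop("'vp' must lie in [0, 1)", call. = FALSE)
  cp <- plasmaConcentration(p, curves@time)
  if (length(curves@cfT)) {
    cb <- if (length(curves@cbT)) curves@cbT else 0
    curves@roiT <- etaT * (vp * cp + (1 - vp) * (curves@cfT + cb))
  }
  if (length(curves@cfC))
    curves@roiC <- etaC * (vp * cp + (1 - vp) * curves@cfC)
  curves@etaT <- etaT
  curves@etaC <- etaC
  curves
}

#' @describeIn bpRatio elementwise `(roiT - roiC) / roiC` on two signal
#'   vectors.
#' @param roiC control-channel signal (numeric method).
#' @export
setMethod("bpRatio", "numeric", function(x, roiC, ...) {
  if (length(x) != length(roiC))
    stop("signal vectors must have equal length", call. = FALSE)
  out <- rep(NA_real_, length(x))
  ok <- is.finite(roiC) & roiC > 0 & is.finite(x)
  out[ok] <- (x[ok] - roiC[ok]) / roiC[ok]
  out
})

#' @describeIn bpRatio applied to the populated `roiT`/`roiC` slots.
#' @export
setMethod("bpRatio", "UptakeCurves", function(x, ...) {
  if (!length(x@roiT) || !length(x@roiC))
    stop("ROI signals not populated; call roiSignal() first", call. = FALSE)
  bpRatio(x@roiT, roiC = x@roiC)
})
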