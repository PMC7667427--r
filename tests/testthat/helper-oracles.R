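# Independent numerical oracles used to pin the model solutions: fixed-step
# classical Runge-Kutta (RK4) integrators, written against the differential
# equations directly and sharing no code with the package solvers.

rk4March <- function(deriv, y0, tOut, dt = 1e-3) {
  stopifnot(tOut[1] == 0)
  out <- matrix(NA_real_, length(tOut), length(y0))
  out[1, ] <- y0
  y <- y0
  t <- 0
  for (i in seq_along(tOut)[-1]) {
    target <- tOut[i]
    while (t < target - 1e-12) {
      h <- min(dt, target - t)
      k1 <- deriv(t, y)
      k2 <- deriv(t + h / 2, y + h / 2 * k1)
      k3 <- deriv(t + h / 2, y + h / 2 * k2)
      k4 <- deriv(t + h, y + h * k3)
      y <- y + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      t <- t + h
    }
    out[i, ] <- y
  }
  out
}

cpFun <- function(p) function(t)
  p@scale * (p@A * exp(-p@alpha * t) + p@B * exp(-p@beta * t))

# one-compartment (Kety) oracle
rk4Kety <- function(K1, k2, p, tOut, dt = 1e-3) {
  cp <- cpFun(p)
  drop(rk4March(function(t, y) K1 * cp(t) - k2 * y, 0, tOut, dt))
}

# two-compartment targeted oracle
rk4Targeted <- function(K1, k2, k3, k4, p, tOut, dt = 1e-3) {
  cp <- cpFun(p)
  out <- rk4March(function(t, y)
    c(K1 * cp(t) - (k2 + k3) * y[1] + k4 * y[2],
      k3 * y[1] - k4 * y[2]),
    c(0, 0), tOut, dt)
  list(cf = out[, 1], cb = out[, 2])
}

relErr <- function(x, ref) {
  scale <- pmax(abs(ref), 1e-3 * max(abs(ref)))
  max(abs(x - ref) / scale)
}

# small rendered scene shared by several tests
testScene <- function(class = "peptide", cellLine = "A431", BPtumor = 10,
                      dim = 40L, seed = 11L, noise = "poisson", ...) {
  spec <- sceneFromPreset(class, cellLine, BPtumor = BPtumor,
                          dim = rep(dim, 2L), seed = seed,
                          detector = detectorSpec(noise = noise), ...)
  renderImageStack(spec)
}
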