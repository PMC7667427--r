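# Compartment-model solutions: closed forms, numerical integration, ROI
# assembly and the ratiometric binding potential.

pepPlasma <- plasmaInput(A = 0.02, alpha = 0.3, B = 2e-3, beta = 6e-4)
affPlasma <- plasmaInput(A = 0.6, alpha = 0.2, B = 0.4, beta = 5e-3)

test_that("Kety closed form matches a fine-step RK4 oracle", {
  t <- seq(0, 60, 2)
  ref <- rk4Kety(0.1, 0.02, pepPlasma, t, dt = 1e-3)
  expect_lt(relErr(ketyClosedForm(0.1, 0.02, pepPlasma, t), ref), 1e-6)
  # degenerate case k2 == alpha uses the t exp(-k2 t) limit
  refDeg <- rk4Kety(0.2, 0.3, pepPlasma, t, dt = 1e-3)
  expect_lt(relErr(ketyClosedForm(0.2, 0.3, pepPlasma, t), refDeg), 1e-6)
})

test_that("Kety trivial identities hold", {
  t <- seq(0, 30, 1)
  expect_equal(ketyClosedForm(0, 0.5, pepPlasma, t), rep(0, length(t)))
  expect_equal(ketyClosedForm(0.3, 0.1, pepPlasma, 0), 0)
  expect_true(all(ketyClosedForm(0.3, 0.1, affPlasma, t) >= 0))
  expect_error(ketyClosedForm(-0.1, 0.2, pepPlasma, t), "K1")
})

test_that("control solver agrees with the closed form and accumulates when k2 -> 0", {
  t <- seq(0, 40, 0.5)
  k <- agentKinetics(K1 = 0.01, k2 = 0.3)
  sol <- solveControl(k, affPlasma, t)
  expect_lt(relErr(sol@cfC, ketyClosedForm(0.01, 0.3, affPlasma, t)), 1e-6)
  expect_equal(solveControl(agentKinetics(K1 = 0, k2 = 0.3), affPlasma, t)@cfC,
               rep(0, length(t)))
  # pure accumulation limit: k2 -> 0 gives K1 * integral of Cp
  p <- affPlasma
  acc <- solveControl(agentKinetics(K1 = 0.05, k2 = 1e-9), p, t)@cfC
  intCp <- p@scale * (p@A / p@alpha * (1 - exp(-p@alpha * t)) +
                      p@B / p@beta * (1 - exp(-p@beta * t)))
  expect_lt(relErr(acc[-1], 0.05 * intCp[-1]), 1e-5)
})

test_that("targeted solver matches the RK4 oracle and its closed form", {
  t <- seq(0, 60, 2)
  # peptide-like tumor kinetics with BP = 10 at trace receptor occupancy
  k <- agentKinetics(K1 = 0.4, k2 = 0.2, kon = 1e-3, koff = 0.1, Bavail = 1000)
  expect_equal(bindingPotential(k), 10)
  ref <- rk4Targeted(0.4, 0.2, rateK3(k), rateK4(k), pepPlasma, t, dt = 1e-3)
  sol <- solveTargeted(k, pepPlasma, t)
  expect_lt(relErr(sol@cfT, ref$cf), 1e-5)
  expect_lt(relErr(sol@cbT, ref$cb), 1e-5)
  cf <- targetedClosedForm(k, pepPlasma, t)
  expect_lt(relErr(cf@cfT, ref$cf), 1e-5)
  expect_lt(relErr(cf@cbT, ref$cb), 1e-5)
})

test_that("targeted solver trivial structure: decoupling and irreversibility", {
  t <- seq(0, 60, 1)
  # k3 = 0: bound pool empty, free pool is exactly Kety
  k0 <- agentKinetics(K1 = 0.3, k2 = 0.15, kon = 0, koff = 0.2, Bavail = 50)
  s0 <- solveTargeted(k0, pepPlasma, t)
  expect_equal(max(s0@cbT), 0)
  expect_lt(relErr(s0@cfT, ketyClosedForm(0.3, 0.15, pepPlasma, t)), 1e-6)
  # k4 = 0, k3 > 0: bound concentration is monotone nondecreasing
  k1 <- agentKinetics(K1 = 0.3, k2 = 0.15, kon = 1e-3, koff = 0, Bavail = 500)
  s1 <- solveTargeted(k1, pepPlasma, t)
  expect_true(all(diff(s1@cbT) >= -1e-12))
  cf1 <- targetedClosedForm(k1, pepPlasma, t)
  expect_lt(relErr(cf1@cbT[-1], s1@cbT[-1]), 1e-5)
})

test_that("closed form tracks the ODE route across a parameter sweep", {
  t <- seq(0, 120, 4)
  set.seed(42)
  for (i in 1:8) {
    k <- agentKinetics(K1 = runif(1, 0.01, 0.5), k2 = runif(1, 0.02, 0.8),
                       kon = 1e-3, koff = runif(1, 0.01, 0.5),
                       Bavail = runif(1, 100, 2000))
    sol <- suppressWarnings(solveTargeted(k, affPlasma, t))
    cf <- suppressWarnings(targetedClosedForm(k, affPlasma, t))
    expect_lt(relErr(cf@cfT, sol@cfT), 1e-4)
    expect_lt(relErr(cf@cbT, sol@cbT), 1e-4)
  }
})

test_that("trace-condition violation warns and flags instead of erroring", {
  t <- seq(0, 60, 1)
  # tiny receptor pool: bound pool easily exceeds 5% of Bavail
  k <- agentKinetics(K1 = 0.4, k2 = 0.2, kon = 10, koff = 0.01, Bavail = 0.05)
  expect_warning(sol <- solveTargeted(k, pepPlasma, t), "trace")
  expect_true(sol@traceExceeded)
  k2 <- agentKinetics(K1 = 0.4, k2 = 0.2, kon = 1e-3, koff = 0.1, Bavail = 1000)
  expect_silent(sol2 <- solveTargeted(k2, pepPlasma, t))
  expect_false(sol2@traceExceeded)
})

test_that("ROI assembly weights compartments by vp and eta", {
  t <- seq(0, 30, 1)
  k <- agentKinetics(K1 = 0.2, k2 = 0.1, kon = 1e-3, koff = 0.1, Bavail = 500)
  cur <- combineCurves(targetedClosedForm(k, pepPlasma, t),
                       solveControl(k, pepPlasma, t))
  r0 <- roiSignal(cur, pepPlasma, vp = 0)
  expect_equal(r0@roiT, r0@cfT + r0@cbT)
  expect_equal(r0@roiC, r0@cfC)
  r2 <- roiSignal(cur, pepPlasma, vp = 0, etaT = 2)
  expect_equal(r2@roiT, 2 * r0@roiT)
  # vascular-only: zero tissue signal leaves roiT/roiC = etaT/etaC
  empty <- new("UptakeCurves", time = t, cfT = rep(0, length(t)),
               cbT = rep(0, length(t)), cfC = rep(0, length(t)))
  rv <- roiSignal(empty, pepPlasma, vp = 0.05, etaT = 3, etaC = 1.5)
  expect_equal(rv@roiT / rv@roiC, rep(2, length(t)))
  expect_error(roiSignal(cur, pepPlasma, vp = 1), "vp")
})

test_that("BPratio: zero for matched signals, NA where control is zero", {
  x <- c(1, 2, 3)
  expect_equal(bpRatio(x, roiC = x), c(0, 0, 0))
  expect_true(is.na(bpRatio(c(1, 1), roiC = c(1, 0))[2]))
  # non-binding matched-agent simulation: numerator of the ratio vanishes
  t <- seq(0, 60, 1)
  k <- agentKinetics(K1 = 0.3, k2 = 0.2, kon = 0, koff = 0.1, Bavail = 100)
  cur <- roiSignal(combineCurves(targetedClosedForm(k, pepPlasma, t),
                                 solveControl(k, pepPlasma, t)), pepPlasma)
  expect_lt(max(abs(bpRatio(cur)[-1])), 1e-6)
})

test_that("BPratio approaches k3/k4 = BP under a constant plasma input", {
  # quasi-constant input: elimination far slower than any tissue rate
  pConst <- plasmaInput(A = 0, alpha = 1, B = 1, beta = 1e-9)
  k <- agentKinetics(K1 = 0.1, k2 = 0.2, kon = 1e-3, koff = 0.1, Bavail = 5000)
  BP <- bindingPotential(k)   # 5
  k2a <- k2Apparent(k@k2, BP)
  tEnd <- 20 / k2a
  t <- seq(0, tEnd, length.out = 601)
  cur <- roiSignal(combineCurves(targetedClosedForm(k, pConst, t),
                                 solveControl(k, pConst, t)), pConst)
  ratioEnd <- bpRatio(cur)[length(t)]
  expect_lt(abs(ratioEnd - BP) / BP, 0.02)
  # bound-to-free ratio itself converges to k3/k4 within 1%
  tLate <- 20 * max(1 / k@k2, 1 / rateK4(k))
  i <- which.min(abs(t - tLate))
  expect_lt(abs(cur@cbT[length(t)] / cur@cfT[length(t)] - rateK3(k) / rateK4(k)) /
              (rateK3(k) / rateK4(k)), 0.01)
})

test_that("dose linearity: plasma scale propagates, BPratio unchanged", {
  t <- seq(0, 40, 1)
  k <- agentKinetics(K1 = 0.2, k2 = 0.3, kon = 1e-3, koff = 0.1, Bavail = 800)
  p1 <- pepPlasma
  p3 <- plasmaInput(p1@A, p1@alpha, p1@B, p1@beta, scale = 3)
  c1 <- roiSignal(combineCurves(targetedClosedForm(k, p1, t),
                                solveControl(k, p1, t)), p1)
  c3 <- roiSignal(combineCurves(targetedClosedForm(k, p3, t),
                                solveControl(k, p3, t)), p3)
  expect_equal(c3@roiT, 3 * c1@roiT, tolerance = 1e-9)
  # the control channel is solved numerically; ratios match to solver noise
  expect_equal(bpRatio(c3)[-1], bpRatio(c1)[-1], tolerance = 1e-5)
})

test_that("eta scaling moves the BPratio scale but not its peak time", {
  t <- seq(0, 120, 0.5)
  k <- agentKinetics(K1 = 0.3, k2 = 0.4, kon = 1e-3, koff = 0.1, Bavail = 3000)
  cur <- combineCurves(targetedClosedForm(k, pepPlasma, t),
                       solveControl(k, pepPlasma, t))
  r1 <- bpRatio(roiSignal(cur, pepPlasma, etaT = 1, etaC = 1))
  r5 <- bpRatio(roiSignal(cur, pepPlasma, etaT = 5, etaC = 5))
  expect_equal(which.max(r5), which.max(r1))
})
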