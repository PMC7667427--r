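# Closed-form time-of-maximum-contrast predictions.

test_that("apparent efflux rate arithmetic", {
  expect_equal(k2Apparent(0.5, 0), 0.5)
  expect_equal(k2Apparent(0.2, 19), 0.01)
  expect_equal(k2Apparent(0.66, 40), 0.66 / 41, tolerance = 1e-12)
  expect_error(k2Apparent(-1, 2), "nonnegative")
})

test_that("single-agent prediction evaluates, clamps and errors as specified", {
  expect_equal(as.numeric(tmaxSA(0.3, 0.3, 0.5, 0.4, 10)), 0)  # ln(1) = 0
  v <- tmaxSA(0.2, 0.4, 0.66, 0.5, 40)
  expect_equal(as.numeric(v), log(2) / (0.5 - 0.66 / 41), tolerance = 1e-10)
  expect_equal(as.numeric(v), 1.4324, tolerance = 1e-4)
  expect_false(attr(v, "contrastImmediate"))
  # tumor delivery exceeds normal: contrast maximal immediately, clamp at 0
  v0 <- tmaxSA(0.4, 0.2, 0.66, 0.5, 40)
  expect_equal(as.numeric(v0), 0)
  expect_true(attr(v0, "contrastImmediate"))
  expect_error(tmaxSA(0, 0.4, 0.66, 0.5, 40), "> 0")
  bp <- 0.5 / 0.66 # makes k2a equal k2_normal
  expect_error(tmaxSA(0.2, 0.4, 0.66, 0.66 / (1 + bp), bp), "singular")
})

test_that("paired-agent prediction matches the frozen scalar value", {
  # k2a = 0.0160976, ratio = (-3856.7)/(-183.65) = 21.0, prefactor 15.53
  expect_equal(tmaxPA(0.66, 40), 47.2824, tolerance = 1e-5)
  expect_error(tmaxPA(0.66, 0), "singular")
  expect_error(tmaxPA(0, 10), "> 0")
})

test_that("paired-agent prediction scales as 1/k2 and grows with BP", {
  base <- tmaxPA(0.66, 40)
  expect_equal(tmaxPA(0.66 * 3, 40), base / 3, tolerance = 1e-12)
  expect_equal(tmaxPA(0.66 / 5, 40), base * 5, tolerance = 1e-12)
  bps <- c(1, 5, 20, 100, 1000)
  vals <- vapply(bps, function(b) tmaxPA(0.5, b), numeric(1))
  expect_true(all(diff(vals) > 0))
  # unbounded (logarithmic) growth as BP -> infinity at fixed k2
  expect_gt(tmaxPA(0.5, 1e12), 2 * tmaxPA(0.5, 1e3))
})

test_that("paired-agent prediction ignores delivery and normal tissue", {
  # only tumor k2 and BP enter; nothing else to hold fixed -- assert the
  # closed form against its reduced algebraic form 10 (1+BP)/(k2 BP) ln(1+BP/2)
  for (k2 in c(0.05, 0.3, 0.9)) for (bp in c(0.5, 5, 50)) {
    expect_equal(tmaxPA(k2, bp),
                 10 * (1 + bp) / (k2 * bp) * log(1 + bp / 2),
                 tolerance = 1e-10)
  }
})

test_that("lookup grids reproduce pointwise calls and flag singular cells", {
  g1 <- tmaxLookupGrid(axis1 = 40, axis2 = 0.66, protocol = "PA")
  expect_equal(dim(g1), c(1L, 1L))
  expect_equal(g1[1, 1], tmaxPA(0.66, 40))
  g <- tmaxLookupGrid(axis1 = c(20, 40), axis2 = c(0.2, 0.4, 0.8),
                      protocol = "PA")
  expect_equal(g[2, 2], tmaxPA(0.4, 40))
  # strictly decreasing along the k2 axis at fixed BP
  expect_true(all(diff(g[1, ]) < 0) && all(diff(g[2, ]) < 0))
  gs <- tmaxLookupGrid(axis1 = c(0.5, 2), axis2 = c(0.1, 0.3),
                       protocol = "SA", k2_normal = 0.3)
  expect_true(is.na(gs[1, 2]))  # k2a == k2_normal is singular
  expect_equal(gs[2, 1], max(log(2) / (0.3 - 0.1), 0))
  expect_error(tmaxLookupGrid(1, 1, protocol = "SA"), "k2_normal")
})
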