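# Plasma input function and its invariants.

test_that("plasma concentration evaluates the biexponential exactly", {
  p <- plasmaInput(A = 0.6, alpha = 0.2, B = 0.4, beta = 5e-3)
  expect_equal(plasmaConcentration(p, 0), 1.0)
  expect_lt(plasmaConcentration(p, 1e6), 1e-12)
  # frozen scalar value, computed with arbitrary-precision arithmetic:
  # 0.02 e^-3 + 0.002 e^-0.006 = 2.98377726...e-3
  pep <- plasmaInput(A = 0.02, alpha = 0.3, B = 2e-3, beta = 6e-4)
  expect_equal(plasmaConcentration(pep, 10), 2.9837773e-3, tolerance = 1e-7)
  # scale maps the unitless form to nM
  expect_equal(plasmaConcentration(plasmaInput(0.6, 0.2, 0.4, 5e-3, scale = 5), 7),
               5 * plasmaConcentration(p, 7))
})

test_that("plasma curves are nonnegative and monotone nonincreasing", {
  p <- plasmaInput(0.4, 0.03, 0.5, 3e-4)
  cp <- plasmaConcentration(p, seq(0, 5000, length.out = 2001))
  expect_true(all(cp >= 0))
  expect_true(all(diff(cp) <= 0))
})

test_that("negative times and invalid parameters are rejected", {
  p <- plasmaInput(0.6, 0.2, 0.4, 5e-3)
  expect_error(plasmaConcentration(p, -1), "negative")
  expect_error(plasmaInput(-0.1, 0.2, 0.4, 5e-3), "'A'")
  expect_error(plasmaInput(0, 0.2, 0, 5e-3), "'A' \\+ 'B'")
  expect_error(plasmaInput(0.6, 0, 0.4, 5e-3), "'alpha'")
})
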