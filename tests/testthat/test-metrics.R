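# CVR, AUROC and the time-of-maximum-contrast window.

test_that("CVR reproduces direct substitutions", {
  expect_equal(cvr(c(2, 4), c(0, 2)), 1)          # means 3/1, SDs sqrt(2)
  # means 5 and 2 with sample SDs exactly 4 and 3
  tum <- 5 + c(-1, 1) * 4 / sqrt(2)
  bgd <- 2 + c(-1, 1) * 3 / sqrt(2)
  expect_equal(cvr(tum, bgd), 3 / 5)
  expect_equal(cvr(regionSamples(tum, bgd)), 3 / 5)
  expect_equal(cvr(c(1, 2, 3), c(2, 1, 3)), 0)    # equal means
})

test_that("CVR rejects degenerate inputs", {
  expect_error(cvr(c(1), c(1, 2)), "2 samples")
  expect_error(cvr(c(1, 1), c(2, 2)), "zero pooled variance")
  expect_error(cvr(c(1, NA), c(1, 2)), "finite")
})

test_that("AUROC counts pairs with ties at one half", {
  expect_equal(auroc(c(5, 5, 5), c(5, 5)), 0.5)
  expect_equal(auroc(c(10, 11), c(1, 2, 3)), 1.0)
  expect_equal(auroc(c(2, 3, 4), c(1, 2, 3)), 7 / 9)  # 6 wins + 2 ties of 9
  expect_equal(auroc(regionSamples(c(2, 3, 4), c(1, 2, 3))), 7 / 9)
  expect_error(auroc(numeric(), c(1)), "nonempty")
})

test_that("AUROC is invariant under strictly monotone transforms; CVR under affine maps", {
  set.seed(7)
  for (i in 1:5) {
    tum <- rnorm(40, 1.2, 0.5)
    bgd <- rnorm(50, 0.8, 0.4)
    a0 <- auroc(tum, bgd)
    expect_equal(auroc(exp(tum), exp(bgd)), a0)
    expect_equal(auroc(atan(tum), atan(bgd)), a0)
    expect_equal(cvr(3.7 * tum + 2, 3.7 * bgd + 2), cvr(tum, bgd))
  }
})

test_that("empirical AUROC increases with CVR on matched Gaussian populations", {
  set.seed(123)
  n <- 1000
  cvrs <- aucs <- numeric(12)
  for (i in seq_along(cvrs)) {
    delta <- 0.25 * (i - 1)
    tum <- rnorm(n, delta, 1)
    bgd <- rnorm(n, 0, 1)
    cvrs[i] <- cvr(tum, bgd)
    aucs[i] <- auroc(tum, bgd)
  }
  expect_gt(cor(cvrs, aucs, method = "spearman"), 0.95)
})

test_that("metric series: zero-contrast stacks give CVR ~ 0 and AUROC ~ 0.5", {
  set.seed(5)
  d <- c(16L, 16L, 4L)
  stack <- array(rnorm(prod(d), 100, 5), d)
  tumor <- matrix(FALSE, 16, 16); tumor[4:8, 4:8] <- TRUE
  bg <- matrix(FALSE, 16, 16); bg[10:15, 10:15] <- TRUE
  m <- metricTimeSeries(stack, NULL, tumor, bg, 0:3, "SA")
  expect_true(all(m@cvr < 0.5))
  expect_true(all(abs(m@auroc - 0.5) < 0.15))
  # SA ignores the control stack entirely
  ctl <- array(rnorm(prod(d), 500, 5), d)
  m2 <- metricTimeSeries(stack, ctl, tumor, bg, 0:3, "SA")
  expect_identical(as.data.frame(m), as.data.frame(m2))
  # config errors
  expect_error(metricTimeSeries(stack, NULL, tumor, tumor, 0:3, "SA"), "overlap")
  expect_error(metricTimeSeries(stack, NULL, tumor, bg, 0:3, "PA"), "control")
})

test_that("PA metrics on a receptor-positive scene discriminate at late frames", {
  scene <- testScene(BPtumor = 10, dim = 40L, seed = 21L)
  m <- metricTimeSeries(scene@targeted, scene@control, scene@tumorMask,
                        scene@bgMask, scene@frameTimes, "PA")
  late <- length(m@time) - 2:0
  expect_gt(min(m@auroc[late]), 0.9)
  expect_gt(max(m@cvr, na.rm = TRUE), 0.5)
})

test_that("Tmax window: constant and triangular geometries", {
  t <- 0:60
  wConst <- findTmax(rep(2, 61), time = t)
  expect_equal(wConst@tMax, 0)      # first index on exact ties
  expect_equal(wConst@tStart98, 0)
  expect_equal(wConst@tEnd98, 60)
  v <- pmax(0, 30 - abs(t - 30))    # unit-slope triangular peak at t = 30
  w <- findTmax(v, time = t)
  expect_equal(w@tMax, 30)
  expect_equal(w@tStart98, 30 - 0.02 * 30)   # 0.98 crossing by interpolation
  expect_equal(w@tEnd98, 30 + 0.02 * 30)
  expect_true(w@tStart98 <= w@tMax && w@tMax <= w@tEnd98)
  expect_error(findTmax(rep(NA_real_, 3), time = 0:2), "undefined")
})

test_that("Tmax on a coarse grid agrees with a dense-grid re-evaluation", {
  shape <- function(t) (exp(-0.02 * t) - exp(-0.2 * t)) * sqrt(1 + 0.05 * t)
  coarse <- seq(0, 120, 2)
  dense <- seq(0, 120, 0.01)
  wc <- findTmax(shape(coarse), time = coarse)
  wd <- findTmax(shape(dense), time = dense)
  expect_lt(abs(wc@tMax - wd@tMax), 2)   # within one coarse-grid step
})

test_that("the 98% window survives noise at no less than one frame", {
  set.seed(99)
  t <- seq(0, 60, 1)
  v <- (exp(-0.05 * t) - exp(-0.5 * t)) + rnorm(length(t), 0, 0.02)
  w <- findTmax(pmax(v, 0), time = t, smooth = 5L)
  expect_gte(w@tEnd98 - w@tStart98, 0)
  expect_true(w@tStart98 <= w@tMax && w@tMax <= w@tEnd98)
})
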