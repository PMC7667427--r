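# Synthetic-scene generation: presets, parameter maps, detector rendering.

test_that("packaged presets carry the published parameter values", {
  pep <- agentPreset("peptide")
  expect_equal(c(pep$plasma@A, pep$plasma@alpha, pep$plasma@B, pep$plasma@beta),
               c(0.02, 0.3, 2e-3, 6e-4))
  ab <- agentPreset("antibody")
  expect_equal(ab$tumor$K1[1], 2e-4)
  expect_equal(ab$tumor$k2[1], 8e-3)
  expect_equal(c(ab$kon, ab$koff, ab$KD), c(0.16, 0.07, 0.4))
  # affibody: printed KD (3) and derived koff/kon (2.5) differ by rounding
  aff <- agentPreset("affibody")
  expect_equal(aff$KDderived, 0.1 / 0.04)
  expect_equal(aff$KD, 3)
  expect_error(agentPreset("affibody", "A431"), "not characterized")
})

test_that("parameter maps: determinism, SD = 0, and target moments", {
  spec0 <- sceneFromPreset("peptide", "A431", dim = c(32L, 32L), seed = 5L)
  m1 <- generateParameterMaps(spec0)
  m2 <- generateParameterMaps(spec0)
  expect_identical(m1, m2)
  # SD = 0 collapses to the means
  specC <- sceneSpec(dim = c(16L, 16L),
                     tumorParams = list(K1 = c(0.3, 0), k2 = c(0.2, 0), BP = 10),
                     backgroundParams = list(K1 = c(0.1, 0), k2 = c(0.03, 0), BP = 0),
                     kon = 0.1, koff = 0.1,
                     plasma = plasmaInput(0.02, 0.3, 2e-3, 6e-4),
                     frameTimes = seq(0, 10, 2), seed = 2L)
  mc <- generateParameterMaps(specC)
  expect_true(all(mc$K1[mc$tumorMask] == 0.3))
  expect_true(all(mc$k2[!mc$tumorMask] == 0.03))
  # moment check at ~1e4 tumor pixels: sample mean/SD of tumor K1 within
  # 3 SE of the A431 values 0.3 / 0.2
  big <- sceneFromPreset("peptide", "A431", dim = c(130L, 130L),
                         tumorRadius = 57, bgInner = 58, bgOuter = 64,
                         seed = 9L)
  mb <- generateParameterMaps(big)
  k1t <- mb$K1[mb$tumorMask]
  n <- length(k1t)
  expect_gt(n, 9000)
  expect_lt(abs(mean(k1t) - 0.3), 3 * 0.2 / sqrt(n))
  expect_lt(abs(sd(k1t) - 0.2), 3 * 0.2 / sqrt(n))   # SE(sd) ~ sd/sqrt(2n)
  expect_true(all(mb$K1 > 0) && all(mb$k2 > 0))
})

test_that("rendering hits the detector peak and respects the noise switch", {
  sceneN <- testScene(dim = 32L, noise = "none", seed = 4L)
  expect_equal(max(sceneN@targetedExpected, sceneN@controlExpected),
               0.2 * 65535)  # = 13107
  expect_identical(sceneN@targeted, round(sceneN@targetedExpected))
  sceneP <- testScene(dim = 32L, noise = "poisson", seed = 4L)
  expect_identical(sceneP@targetedExpected, sceneN@targetedExpected)
  expect_false(identical(sceneP@targeted, sceneN@targeted))
})

test_that("Poisson counts have variance close to their mean", {
  # flat maps -> constant expected count within a frame
  spec <- sceneSpec(dim = c(110L, 110L),
                    tumorParams = list(K1 = c(0.3, 0), k2 = c(0.2, 0), BP = 0),
                    backgroundParams = list(K1 = c(0.3, 0), k2 = c(0.2, 0), BP = 0),
                    kon = 0, koff = 0.1,
                    plasma = plasmaInput(0.02, 0.3, 2e-3, 6e-4),
                    frameTimes = seq(0, 20, 5), seed = 31L)
  scene <- renderImageStack(spec)
  lam <- scene@targetedExpected[1, 1, ]
  f <- which(lam > 8000)[1]
  px <- as.vector(scene@targeted[, , f])
  expect_gt(length(px), 1e4)
  expect_lt(abs(var(px) / mean(px) - 1), 0.05)
})

test_that("joint channel scaling preserves the targeted/control ratio", {
  s1 <- testScene(dim = 24L, noise = "none", seed = 8L)
  spec2 <- s1@spec
  spec2@detector <- detectorSpec(fraction = 0.5, noise = "none")
  s2 <- renderImageStack(spec2)
  ok <- s1@controlExpected > 1e-6
  r1 <- s1@targetedExpected[ok] / s1@controlExpected[ok]
  r2 <- s2@targetedExpected[ok] / s2@controlExpected[ok]
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("changing only the seed changes the noise but not the physics", {
  sA <- testScene(dim = 24L, seed = 13L)
  sB <- testScene(dim = 24L, seed = 14L)
  expect_false(identical(sA@targeted, sB@targeted))
  # different map draws too (seed feeds maps); compare against fixed maps
  specA <- sA@spec
  mapsA <- generateParameterMaps(specA)
  specB <- specA; specB@seed <- 99L
  sA2 <- renderImageStack(specA, maps = mapsA)
  sB2 <- renderImageStack(specB, maps = mapsA)
  expect_identical(sA2@targetedExpected, sB2@targetedExpected)
  expect_false(identical(sA2@targeted, sB2@targeted))
})

test_that("metric standard errors shrink roughly as 1/sqrt(n)", {
  set.seed(55)
  sizes <- c(100, 400, 1600)
  sdByN <- vapply(sizes, function(n) {
    reps <- vapply(1:40, function(r) {
      tum <- rpois(n, 110)
      bgd <- rpois(n, 100)
      cvr(tum, bgd)
    }, numeric(1))
    sd(reps)
  }, numeric(1))
  expect_true(all(diff(sdByN) < 0))
  ratio <- sdByN[1] / sdByN[3]     # expect ~ sqrt(16) = 4
  expect_gt(ratio, 2)
  expect_lt(ratio, 8)
})
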