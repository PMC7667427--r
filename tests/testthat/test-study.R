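# Monte-Carlo contrast-timing study: sampling, iteration evaluation,
# summaries. (The comparison against the published correlation and error
# statistics lives in the acceptance suite.)

test_that("parameter sampling is uniform within ranges and reproducible", {
  cl <- classRanges("peptide")
  d1 <- sampleParameters(cl, 500, seed = 3L)
  d2 <- sampleParameters(cl, 500, seed = 3L)
  expect_identical(d1, d2)
  r <- cl@ranges
  for (v in rownames(r)) {
    expect_gte(min(d1[[v]]), r[v, 1])
    expect_lte(max(d1[[v]]), r[v, 2])
  }
  big <- sampleParameters(cl, 1e4, seed = 5L)
  mid <- (r["k2_tumor", 1] + r["k2_tumor", 2]) / 2
  se <- (r["k2_tumor", 2] - r["k2_tumor", 1]) / sqrt(12) / sqrt(1e4)
  expect_lt(abs(mean(big$k2_tumor) - mid), 3 * se)
  # degenerate range: all draws equal the single value
  deg <- new("ClassRanges", name = "deg",
             ranges = matrix(c(0.2, 0.2, 0.3, 0.3, 0.1, 0.1, 0.2, 0.2, 5, 5),
                             5, 2, byrow = TRUE,
                             dimnames = list(c("K1_tumor", "k2_tumor",
                                               "K1_normal", "k2_normal", "BP"),
                                             NULL)),
             plasma = cl@plasma, timeGrid = cl@timeGrid)
  dd <- sampleParameters(deg, 10, seed = 1L)
  expect_true(all(dd$BP == 5))
})

test_that("iteration records agree with the closed-form module", {
  cl <- classRanges("peptide")
  draw <- data.frame(K1_tumor = 0.4, k2_tumor = 0.66, K1_normal = 0.3,
                     k2_normal = 0.48, BP = 40)
  rec <- evaluateIteration(draw, cl@plasma, cl@timeGrid)
  expect_equal(rec$tmax_ana_pa, tmaxPA(0.66, 40))
  expect_equal(rec$tmax_ana_sa,
               as.numeric(tmaxSA(0.4, 0.3, 0.66, 0.48, 40)))
  expect_true(rec$sa_start98 <= rec$tmax_num_sa)
  expect_true(rec$tmax_num_pa >= rec$pa_start98 &&
                rec$tmax_num_pa <= rec$pa_end98)
})

test_that("the numeric paired-agent peak is invariant to joint delivery scaling", {
  cl <- classRanges("peptide")
  draw <- data.frame(K1_tumor = 0.3, k2_tumor = 0.5, K1_normal = 0.25,
                     k2_normal = 0.4, BP = 30)
  double <- transform(draw, K1_tumor = 2 * K1_tumor, K1_normal = 2 * K1_normal)
  r1 <- evaluateIteration(draw, cl@plasma, cl@timeGrid)
  r2 <- evaluateIteration(double, cl@plasma, cl@timeGrid)
  expect_equal(r2$tmax_num_pa, r1$tmax_num_pa)
})

test_that("near-degenerate draws survive with flags instead of failing", {
  cl <- classRanges("highmw")
  draw <- data.frame(K1_tumor = 0.005, k2_tumor = 0.01, K1_normal = 0.005,
                     k2_normal = 0.01 / (1 + 1), BP = 1)  # k2_normal == k2a
  rec <- evaluateIteration(draw, cl@plasma, cl@timeGrid)
  expect_true(rec$sa_singular)
  expect_true(is.finite(rec$tmax_num_sa))
  expect_true(is.finite(rec$tmax_ana_pa))
})

test_that("study runs are deterministic and summaries match records", {
  s1 <- runStudy(classes = c("peptide", "antibody"), n = 5L, seed = 7L)
  s2 <- runStudy(classes = c("peptide", "antibody"), n = 5L, seed = 7L)
  expect_identical(studyRecords(s1), studyRecords(s2))
  # class results are independent of evaluation order
  s3 <- runStudy(classes = c("antibody", "peptide"), n = 5L, seed = 7L)
  r1 <- studyRecords(s1); r3 <- studyRecords(s3)
  expect_equal(r1[r1$class == "peptide", ], r3[r3$class == "peptide", ],
               ignore_attr = TRUE)
  one <- runStudy(classes = "peptide", n = 1L, seed = 2L)
  rec <- studyRecords(one)
  expect_equal(studySummary(one)$per_class$peptide$tmax_num_pa[["mean"]],
               rec$tmax_num_pa)
})

test_that("the class table routes units: minutes for fast, hours for slow classes", {
  st <- runStudy(classes = c("peptide", "antibody"), n = 3L, seed = 1L)
  tab <- summarizeTmaxByClass(st)
  expect_equal(tab$unit[tab$class == "peptide"], "min")
  expect_equal(tab$unit[tab$class == "antibody"], "h")
  tabA <- summarizeTmaxByClass(st, pathway = "analytical")
  expect_equal(dim(tabA), dim(tab))
  empty <- new("StudyResult", records = data.frame(), summary = list(),
               seed = 1L, nIterations = 0L, plasmaMode = "mono")
  expect_equal(nrow(summarizeTmaxByClass(empty)), 0)
})

test_that("packaged ranges match the published sampling table verbatim", {
  expect_equal(unname(classRanges("peptide")@ranges["BP", ]), c(13.5, 67.5))
  expect_equal(unname(classRanges("lowmw")@ranges["K1_tumor", ]),
               c(0.0198, 0.0952))
  expect_equal(unname(classRanges("highmw")@ranges["k2_tumor", ]),
               c(3.28e-3, 0.0164))
  expect_equal(unname(classRanges("antibody")@ranges["BP", ]),
               c(0.0185, 0.037))
  # class-adaptive grids
  expect_equal(max(classRanges("peptide")@timeGrid), 600)
  expect_equal(max(classRanges("antibody")@timeGrid), 7200)
})
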