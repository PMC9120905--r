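refCanon <- canonicalReferenceIntervals()

test_that("reference intervals recover the configured control quantiles", {
  ctrl <- simulateControlSamples(refCanon, nSamples = 5, nEvents = 20000,
                                 seed = 1)
  ref <- buildReferenceIntervals(ctrl)
  iv <- referenceIntervals(ref)
  expect_setequal(iv$marker, referenceIntervals(refCanon)$marker)
  expect_true(all(abs(iv$negPD - 1) < 0.05))
  expect_true(all(abs(iv$pdPN - 2) < 0.05))
  expect_true(all(abs(iv$pnPB - 3) < 0.05))
  expect_equal(iv$scoreUnit, (iv$pnPB - iv$negPD) / 3)
  # deterministic given fixed controls
  expect_identical(referenceIntervals(buildReferenceIntervals(ctrl)), iv)
})

test_that("degenerate controls raise an error", {
  flat <- list(data.frame(marker = "CD34",
                          population = rep(c("negative", "positive"),
                                           each = 10),
                          value = rep(1.5, 20)))
  expect_error(buildReferenceIntervals(flat), "degenerate")
  expect_error(buildReferenceIntervals(list()), "control")
})

test_that("bimodal mixtures are recovered with accurate fractions", {
  set.seed(2)
  x <- c(rnorm(60000, 0.5, 0.12), rnorm(40000, 2.5, 0.12))
  det <- detectSubpopulations(x, "CD34", refCanon)
  expect_equal(det$modality, "bimodal")
  expect_equal(nrow(det$subpopulations), 2)
  expect_equal(det$subpopulations$fraction[1], 0.6, tolerance = 0.02 / 0.6)
  expect_equal(det$subpopulations$score, c("neg", "PN"))
})

test_that("the >1% rule merges minor populations", {
  set.seed(3)
  x <- c(rnorm(99500, 0.5, 0.12), rnorm(500, 2.5, 0.12))
  det <- detectSubpopulations(x, "CD34", refCanon)
  expect_equal(det$modality, "unimodal")
  expect_equal(sum(det$subpopulations$fraction), 1)
  expect_false(any(det$subpopulations$fraction <= 0.01))
})

test_that("broad vs narrow single peaks follow the 10%-width rule", {
  set.seed(4)
  narrow <- rnorm(50000, 2.5, 0.12)
  expect_equal(detectSubpopulations(narrow, "CD34", refCanon)$modality,
               "unimodal")
  wide <- rnorm(50000, 2.5, 0.28)   # 10% width ~1.2 > 1.5 * 2/3 score units
  expect_equal(detectSubpopulations(wide, "CD34", refCanon)$modality,
               "broad")
  # cross-lineage markers need 1.5 decades, not 1.5 score units
  expect_equal(detectSubpopulations(wide, "CD33", refCanon)$modality,
               "unimodal")
  wider <- rnorm(50000, 2.5, 0.45)
  expect_equal(detectSubpopulations(wider, "CD33", refCanon)$modality,
               "broad")
  expect_error(detectSubpopulations(rnorm(50), "CD34", refCanon),
               "insufficient")
})

test_that("marker scoring follows partition membership and dominance", {
  set.seed(5)
  ms <- scoreMarker(rnorm(5000, 0.4, 0.1), "CD34", refCanon)
  expect_equal(overallScore(ms), "neg")
  # bimodal 60% PN / 40% neg: dominant subpopulation wins
  x <- c(rnorm(24000, 0.5, 0.1), rnorm(36000, 2.5, 0.1))
  ms2 <- scoreMarker(x, "CD34", refCanon)
  expect_equal(ms2@modality, "bimodal")
  expect_equal(overallScore(ms2), "PN")
  expect_equal(ms2@mfiOverall, median(x))
  # boundary ties go to the higher category
  r <- referenceIntervals(refCanon)[1, ]
  expect_equal(blastnet:::scoreOfValue(c(r$negPD, r$pdPN, r$pnPB, 0),
                                       r$negPD, r$pdPN, r$pnPB),
               c("PD", "PN", "PB", "neg"))
})

test_that("shifting all events up by one score unit never lowers the score", {
  unit <- referenceIntervals(refCanon)$scoreUnit[1]
  rank <- setNames(1:4, c("neg", "PD", "PN", "PB"))
  set.seed(6)
  for (mu in c(0.4, 1.2, 1.9, 2.5)) {
    x <- rnorm(3000, mu, 0.15)
    s0 <- overallScore(scoreMarker(x, "CD34", refCanon))
    s1 <- overallScore(scoreMarker(x + unit, "CD34", refCanon))
    expect_gte(rank[s1], rank[s0])
  }
})

test_that("binary collapse applies the CD15/CD133 exception", {
  expect_equal(binarizeScore("PD", "CD34"), 0L)
  expect_equal(binarizeScore("PD", "CD133"), 1L)
  expect_equal(binarizeScore("PD", "CD15"), 1L)
  expect_equal(binarizeScore("PB", "CD34"), 1L)
  expect_equal(binarizeScore("neg", "CD133"), 0L)
  expect_warning(b <- binarizeScore("PD", "CD99"), "default")
  expect_equal(b, 0L)
})

test_that("patient-level scoring produces a coherent LAIP profile", {
  ref <- refCanon
  fc <- simulateFlowCohort(1, ref, nEvents = 20000,
                           markers = c("CD34", "CD19", "CD33"), seed = 7)
  prof <- scorePatient(fc$events[[1]], "P001", ref)
  expect_s4_class(prof, "LAIPProfile")
  expect_setequal(names(prof@markerScores), c("CD34", "CD19", "CD33"))
  tab <- laipTable(list(prof))
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$symbol %in% c("-", "+", "++", "+++")))
})
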