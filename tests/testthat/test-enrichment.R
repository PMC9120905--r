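test_that("preranked GSEA flags a set planted at the top of the ranking", {
  set.seed(1)
  stats <- setNames(sort(rnorm(1000), decreasing = TRUE),
                    sprintf("g%04d", 1:1000))
  top <- names(stats)[1:10]
  res <- prerankedGsea(stats, top, nPerm = 1000, seed = 2)
  expect_gt(res$ES, 0.9)
  expect_lte(res$p, 0.01)
  expect_setequal(res$leadingEdge, top)
  expect_error(prerankedGsea(stats, c("none1", "none2"), nPerm = 1000),
               "intersect")
})

test_that("weight 0 reduces GSEA to the unweighted KS statistic", {
  set.seed(3)
  stats <- setNames(rnorm(200), sprintf("g%03d", 1:200))
  set <- sample(names(stats), 20)
  res <- prerankedGsea(stats, set, nPerm = 100, weight = 0, seed = 4)
  # unweighted running sum: hits step 1/n_set, misses 1/(N - n_set)
  ord <- names(sort(stats, decreasing = TRUE))
  hit <- ord %in% set
  run <- cumsum(ifelse(hit, 1 / sum(hit), -1 / sum(!hit)))
  expect_equal(res$ES, run[which.max(abs(run))], tolerance = 1e-12)
})

test_that("GSEA p-values are calibrated under a null ranking", {
  set.seed(5)
  stats <- setNames(rnorm(400), sprintf("g%03d", 1:400))
  ps <- replicate(60, {
    prerankedGsea(stats, sample(names(stats), 30), nPerm = 200,
                  seed = sample.int(1e6, 1))$p
  })
  expect_gt(ks.test(ps, "punif")$p.value, 0.01)
})

test_that("ES flips sign for the complement signal on a symmetric ranking", {
  stats <- setNames(seq(5, -5, length.out = 100), sprintf("g%03d", 1:100))
  topSet <- names(stats)[1:10]
  botSet <- names(stats)[91:100]
  esTop <- prerankedGsea(stats, topSet, nPerm = 100, seed = 6)$ES
  esBot <- prerankedGsea(stats, botSet, nPerm = 100, seed = 6)$ES
  expect_gt(esTop, 0)
  expect_lt(esBot, 0)
  expect_equal(esTop, -esBot, tolerance = 1e-9)
})

test_that("hypergeometric overrepresentation matches closed form", {
  universe <- sprintf("u%03d", 1:50)
  set <- universe[1:10]
  # full overlap of a 5-gene selection with a 10-gene set in 50
  p <- hypergeomOverrepresentation(universe[1:5], set, universe)
  expect_equal(p, phyper(4, 10, 40, 5, lower.tail = FALSE))
  expect_lt(p, 0.05)
  expect_equal(hypergeomOverrepresentation(character(0), set, universe), 1)
  expect_warning(
    pTrim <- hypergeomOverrepresentation(universe[1:5],
                                         c(set, "outside"), universe),
    "trimmed")
  expect_equal(pTrim, p)
  # sampling oracle on a small universe
  set.seed(7)
  sel <- sample(universe, 8)
  k <- length(intersect(sel, set))
  draws <- replicate(2e4, length(intersect(sample(universe, 8), set)) >= k)
  pMc <- mean(draws)
  se <- sqrt(pMc * (1 - pMc) / 2e4)
  expect_lt(abs(hypergeomOverrepresentation(sel, set, universe) - pMc),
            3 * se + 1e-6)
})

test_that("Fisher exact reproduces the stemness table p-value", {
  res <- fisherExact2x2(matrix(c(18, 8, 8, 16), 2, byrow = TRUE))
  expect_equal(res$p, 0.0225, tolerance = 5e-4 / 0.0225)
  sym <- fisherExact2x2(matrix(c(5, 5, 5, 5), 2))
  expect_equal(sym$oddsRatio, 1)
  expect_equal(sym$p, 1)
  expect_error(fisherExact2x2(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("Fisher p matches brute-force enumeration and fisher.test", {
  set.seed(8)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 5), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- fisherExact2x2(tab)
    expect_equal(res$p, bruteForceFisher(tab), tolerance = 1e-10)
    expect_equal(res$p, fisher.test(tab)$p.value, tolerance = 1e-7)
  }
  # invariance under transposition and simultaneous row/column swap
  tab <- matrix(c(9, 2, 4, 11), 2)
  expect_equal(fisherExact2x2(tab)$p, fisherExact2x2(t(tab))$p)
  expect_equal(fisherExact2x2(tab)$p,
               fisherExact2x2(tab[2:1, 2:1])$p)
})

test_that("Yates chi-square follows the corrected formula", {
  flat <- yatesChi2(matrix(10, 2, 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)
  # hand evaluation: all |O - E| = 10, E = 20 -> 4 * 9.5^2 / 20 = 18.05
  res <- yatesChi2(matrix(c(30, 10, 10, 30), 2))
  expect_equal(res$statistic, 18.05, tolerance = 1e-12)
  expect_equal(res$p, chisq.test(matrix(c(30, 10, 10, 30), 2))$p.value,
               tolerance = 1e-10)
  # large counts: corrected statistic sits just below the uncorrected one
  big <- matrix(c(900, 800, 850, 950), 2)
  expect_lt(yatesChi2(big)$statistic,
            chisq.test(big, correct = FALSE)$statistic)
  expect_equal(yatesChi2(big)$statistic,
               unname(chisq.test(big, correct = TRUE)$statistic),
               tolerance = 1e-10)
  expect_error(yatesChi2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)),
               "zero margin")
})

test_that("GMT round-trip preserves set membership", {
  path <- tempfile(fileext = ".gmt")
  writeLines(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg2\tg4"), path)
  sets <- readGmt(path)
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_equal(sets$setB, c("g2", "g4"))
})
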