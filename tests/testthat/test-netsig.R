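test_that("Irwin-Hall closed-form anchors hold exactly", {
  expect_equal(edgingtonIntegrate(0.3)$pInt, 0.3, tolerance = 1e-12)
  expect_equal(edgingtonIntegrate(c(0.5, 0.5))$pInt, 0.5, tolerance = 1e-12)
  expect_equal(edgingtonIntegrate(c(0.1, 0.1, 0.1))$pInt, 0.3^3 / 6,
               tolerance = 1e-12)
  expect_equal(edgingtonIntegrate(c(0.1, 0.1, 0.1))$S, 0.3)
  expect_error(edgingtonIntegrate(numeric(0)), "empty")
  expect_error(edgingtonIntegrate(c(0.5, 1.2)), "\\[0, 1\\]")
  # symmetry of the distribution around n/2
  expect_equal(irwinHallCdf(4.7, 10), 1 - irwinHallCdf(10 - 4.7, 10),
               tolerance = 1e-9)
})

test_that("exact Irwin-Hall agrees with a Monte-Carlo oracle", {
  set.seed(1)
  for (n in c(2, 7, 20, 45)) {
    s <- sum(runif(n))
    mc <- mcIrwinHall(s, n, nDraw = 2e4)
    expect_lt(abs(irwinHallCdf(s, n) - mc$p), 3 * mc$se)
  }
  # the n > 50 Gaussian branch stays continuous with the exact branch
  expect_equal(irwinHallCdf(26, 51),
               irwinHallCdf(26, 51, exactLimit = 60), tolerance = 2e-3)
})

test_that("graph filtering applies the confidence threshold strictly", {
  g <- tinyPathGraph()  # confidences 0.5 and 0.9
  expect_equal(igraph::ecount(filterGraph(g, 0.119)), 2)
  expect_equal(igraph::ecount(filterGraph(g, 0.6)), 1)
  # an edge just under the threshold is dropped
  g118 <- igraph::set_edge_attr(g, "confidence", value = c(0.118, 0.119))
  expect_equal(igraph::ecount(filterGraph(g118, 0.119)), 1)
  expect_equal(igraph::ecount(filterGraph(g, 0)), 2)
  expect_error(filterGraph(g, 1.01), "invalid threshold")
  # isolated nodes survive filtering
  expect_equal(igraph::vcount(filterGraph(g, 0.95)), 3)
})

test_that("first-order neighborhoods are enumerated as defined", {
  star <- tinyStarGraph(4)
  nets <- enumerateNeighborhoods(star, minSize = 1, maxSize = 500)
  expect_setequal(nets$hub, c("hub", paste0("leaf", 1:4)))
  expect_setequal(nets$leaf1, c("leaf1", "hub"))
  path <- tinyPathGraph()
  netsP <- enumerateNeighborhoods(path, minSize = 1)
  expect_setequal(netsP$b, c("a", "b", "c"))
  # isolated node forms a size-1 network, dropped under default bounds
  iso <- igraph::add_vertices(path, 1, name = "z")
  netsI <- enumerateNeighborhoods(iso, minSize = 1)
  expect_equal(netsI$z, "z")
  expect_false("z" %in% names(enumerateNeighborhoods(iso)))  # minSize 3
})

test_that("permutation test boundaries behave as the estimator dictates", {
  set.seed(2)
  geneP <- setNames(runif(2000), sprintf("g%04d", 1:2000))
  strong <- sprintf("g%04d", 1:5)
  geneP[strong] <- 1e-6
  res <- networkPermutationTest(list(net1 = strong), geneP, nPerm = 1e4,
                                seed = 3)
  sc <- networkScores(res)
  # no shuffle can beat five p-values of 1e-6 at this scale
  expect_equal(sc$permCount, 0)
  expect_equal(sc$pEmp, 1 / 10001)
  expect_true(sc$selected)
  # a network holding the five largest p-values loses to every permutation
  worst <- names(sort(geneP, decreasing = TRUE))[1:5]
  resW <- networkPermutationTest(list(netW = worst), geneP, nPerm = 1e3,
                                 seed = 4)
  expect_equal(networkScores(resW)$pEmp, 1.0)
  expect_error(networkPermutationTest(list(net1 = strong), geneP,
                                      nPerm = 500), "unstable")
})

test_that("selection uses the strict permutation-count rule", {
  mk <- function(count, nPerm) {
    sc <- data.frame(seed = "s", n = 5, nExcluded = 0, S = 1, pInt = 0.01,
                     permCount = count, pEmp = (count + 1) / (nPerm + 1),
                     selected = FALSE)
    new("NetworkScoreSet", scores = sc, members = list(s = letters[1:5]),
        nPerm = nPerm, selectionRate = 1e-4, confidenceThreshold = 0.119,
        seed = 1)
  }
  # the study rule: < 1000 of 1e7 selects, exactly 1000 does not
  expect_true(networkScores(applySelectionRule(mk(999, 1e7)))$selected)
  expect_false(networkScores(applySelectionRule(mk(1000, 1e7)))$selected)
  # scaled desk rule: threshold 10 at 1e5 permutations
  expect_true(networkScores(applySelectionRule(mk(0, 1e5)))$selected)
  expect_false(networkScores(applySelectionRule(mk(10, 1e5)))$selected)
})

test_that("lowering a member p never worsens the network's standing", {
  set.seed(5)
  geneP <- setNames(runif(300), sprintf("g%03d", 1:300))
  net <- list(n1 = sprintf("g%03d", 1:8))
  base <- networkScores(networkPermutationTest(net, geneP, nPerm = 1e3,
                                               seed = 6))
  geneP2 <- geneP
  geneP2["g001"] <- geneP["g001"] / 10
  better <- networkScores(networkPermutationTest(net, geneP2, nPerm = 1e3,
                                                 seed = 6))
  expect_lt(better$S, base$S)
  expect_lte(better$pInt, base$pInt)
  expect_lte(better$permCount, base$permCount)
})

test_that("scores are invariant to network enumeration order", {
  set.seed(7)
  geneP <- setNames(runif(200), sprintf("g%03d", 1:200))
  nets <- list(a = sprintf("g%03d", 1:6), b = sprintf("g%03d", 50:57),
               c = sprintf("g%03d", 100:104))
  r1 <- networkScores(networkPermutationTest(nets, geneP, nPerm = 1e3,
                                             seed = 8))
  r2 <- networkScores(networkPermutationTest(rev(nets), geneP, nPerm = 1e3,
                                             seed = 8))
  r2 <- r2[match(r1$seed, r2$seed), ]
  expect_equal(r1$permCount, r2$permCount)
  expect_equal(r1$S, r2$S)
})

test_that("members without measured p-values are excluded and counted", {
  set.seed(9)
  geneP <- setNames(runif(100), sprintf("g%03d", 1:100))
  nets <- list(n1 = c(sprintf("g%03d", 1:4), "unmeasured1", "unmeasured2"))
  sc <- networkScores(networkPermutationTest(nets, geneP, nPerm = 1e3,
                                             seed = 10))
  expect_equal(sc$n, 4)
  expect_equal(sc$nExcluded, 2)
  expect_equal(sc$S, sum(geneP[sprintf("g%03d", 1:4)]))
})

test_that("label-permutation FDR behaves at the null and under signal", {
  g <- simulatePPIGraph(60, seed = 11)
  simNull <- simulateExpression(g, nGenes = 200, nA = 8, nB = 8, seed = 12)
  fdrNull <- estimateNetsigFdr(simNull$se, graph = g, nLabelPerms = 3,
                               nPerm = 1e3, seed = 13)
  expect_true(is.na(fdrNull$fdr) || fdrNull$fdr >= 0.5)
  # determinism
  fdrNull2 <- estimateNetsigFdr(simNull$se, graph = g, nLabelPerms = 3,
                                nPerm = 1e3, seed = 13)
  expect_identical(fdrNull$permSelected, fdrNull2$permSelected)
})
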