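#' Irwin-Hall cumulative distribution function
#'
#' Probability that the sum of `n` independent Uniform(0, 1) variables is at
#' most `s`. Evaluated by the exact alternating sum
#' \deqn{F_n(s) = \frac{1}{n!}\sum_{k=0}^{\lfloor s\rfloor} (-1)^k
#'   \binom{n}{k}(s-k)^n}
#' for `n <= 50` (the factorial normalisation keeps the cancellation mild:
#' the largest term stays within ~1e6 of the result over the whole support,
#' so double precision retains ~9 significant digits) and by the Gaussian
#' approximation with mean n/2 and variance n/12 beyond.
#'
#' @param s sum value(s).
#' @param n number of uniform summands.
#' @param exactLimit largest `n` evaluated exactly (default 50).
#' @return CDF value(s) in \[0, 1\].
#' @export
irwinHallCdf <- function(s, n, exactLimit = 50) {
  if (n < 1) stop("n must be >= 1")
  if (n > exactLimit) return(pnorm(s, mean = n / 2, sd = sqrt(n / 12)))
  vapply(s, function(si) {
    if (si <= 0) return(0)
    if (si >= n) return(1)
    k <- 0:floor(si)
    min(1, max(0, sum((-1)^k * choose(n, k) * (si - k)^n) / factorial(n)))
  }, numeric(1))
}

#' Edgington p-value integration
#'
#' Combines member p-values by their sum S; the integrated p-value is the
#' probability of a sum at most S under the null that all members are
#' independent Uniform(0, 1), i.e. the Irwin-Hall CDF at S.
#'
#' @param p vector of p-values in \[0, 1\] (length >= 1).
#' @return list with `S` (the sum), `n` and `pInt`.
#' @export
edgingtonIntegrate <- function(p) {
  if (!length(p)) stop("empty p-value vector")
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  S <- sum(p)
  list(S = S, n = length(p), pInt = irwinHallCdf(S, length(p)))
}

#' Filter an interactome to high-confidence edges
#'
#' @param graph igraph with edge attribute `confidence`.
#' @param threshold minimum confidence retained (default 0.119); edges with
#'   confidence below it are dropped, isolated nodes are kept.
#' @return filtered igraph.
#' @export
filterGraph <- function(graph, threshold = 0.119) {
  if (threshold < 0 || threshold > 1)
    stop("invalid threshold: must lie in [0, 1]")
  conf <- edge_attr(graph, "confidence")
  if (is.null(conf)) stop("graph has no 'confidence' edge attribute")
  delete_edges(graph, which(conf < threshold))
}

#' Enumerate first-order neighborhoods
#'
#' One candidate network per node: the node plus its direct neighbors,
#' retained when the member count lies within the size bounds.
#'
#' @param graph filtered igraph.
#' @param minSize,maxSize member-count bounds (defaults 3 and 500, excluding
#'   degenerate and hub-dominated networks).
#' @return named list of member character vectors (seed first).
#' @export
enumerateNeighborhoods <- function(graph, minSize = 3, maxSize = 500) {
  nodes <- V(graph)$name
  nets <- lapply(nodes, function(v) union(v, names(neighbors(graph, v))))
  names(nets) <- nodes
  nets[lengths(nets) >= minSize & lengths(nets) <= maxSize]
}

#' Permutation calibration of neighborhood Edgington scores
#'
#' For each network the observed Edgington sum of its members' p-values is
#' compared with sums obtained by uniformly shuffling the gene-to-p-value
#' assignment over all measured genes; because the Irwin-Hall CDF is
#' monotone in S for fixed network size, counting permutations with
#' `S_perm <= S_obs` equals counting permutations with an integrated p-value
#' at least as extreme. One shared shuffle per permutation index serves all
#' networks, so network scores are comparable under a common null draw.
#' Members without a measured p-value are excluded from S and n (the
#' exclusion count is reported).
#'
#' @param networks named list of member vectors (e.g. from
#'   [enumerateNeighborhoods()]).
#' @param geneP named p-value vector over measured genes.
#' @param nPerm number of permutations (>= 1000; tail estimates are unstable
#'   below).
#' @param seed RNG seed for the permutation stream.
#' @param selectionRate networks are selected when
#'   `permCount < selectionRate * nPerm` (default 1e-4, the "<1000 of 1e7"
#'   rule at study scale).
#' @param chunkSize permutations evaluated per block (memory control).
#' @return a [NetworkScoreSet-class], ordered by empirical p-value (ties by
#'   |S/n - 0.5| descending, then seed symbol).
#' @export
networkPermutationTest <- function(networks, geneP, nPerm = 1e5, seed = 1,
                                   selectionRate = 1e-4, chunkSize = 2000) {
  if (nPerm < 1e3) stop("nPerm < 1000 gives unstable tail estimates")
  if (!length(networks)) stop("no networks to score")
  if (is.null(names(geneP))) stop("geneP must be a named vector")
  measured <- names(geneP)
  idx <- lapply(networks, function(m) which(measured %in% m))
  nExcluded <- lengths(networks) - lengths(idx)
  keep <- lengths(idx) >= 1L
  if (!all(keep)) stop("every network must retain >= 1 measured p-value")
  n <- lengths(idx)
  Sobs <- vapply(idx, function(i) sum(geneP[i]), numeric(1))
  pInt <- vapply(seq_along(idx),
                 function(i) irwinHallCdf(Sobs[i], n[i]), numeric(1))
  # sparse incidence matrix: networks x measured genes
  M <- Matrix::sparseMatrix(
    i = rep(seq_along(idx), lengths(idx)), j = unlist(idx),
    x = 1, dims = c(length(idx), length(measured)))
  set.seed(seed)
  permCount <- numeric(length(idx))
  done <- 0
  nGenes <- length(geneP)
  tol <- 1e-12
  while (done < nPerm) {
    b <- min(chunkSize, nPerm - done)
    P <- vapply(seq_len(b), function(j) geneP[sample.int(nGenes)],
                numeric(nGenes))
    Sperm <- as.matrix(M %*% P)
    permCount <- permCount + rowSums(Sperm <= Sobs + tol)
    done <- done + b
  }
  scores <- data.frame(
    seed = names(networks), n = n, nExcluded = nExcluded, S = Sobs,
    pInt = pInt, permCount = permCount,
    pEmp = (permCount + 1) / (nPerm + 1),
    selected = permCount < selectionRate * nPerm,
    row.names = NULL, stringsAsFactors = FALSE)
  ord <- order(scores$pEmp, -abs(scores$S / scores$n - 0.5), scores$seed)
  new("NetworkScoreSet", scores = scores[ord, , drop = FALSE],
      members = networks[ord], nPerm = nPerm, selectionRate = selectionRate,
      confidenceThreshold = NA_real_, seed = seed)
}

#' Re-apply the selection rule to scored networks
#'
#' Selected iff `permCount < selectionRate * nPerm` (strict inequality,
#' mirroring the "< 1000 of the 1e7 permutations" rule).
#'
#' @param scoreSet a [NetworkScoreSet-class].
#' @param selectionRate permutation-rate threshold.
#' @return a [NetworkScoreSet-class] with updated selection flags.
#' @export
applySelectionRule <- function(scoreSet, selectionRate = 1e-4) {
  sc <- scoreSet@scores
  sc$selected <- sc$permCount < selectionRate * scoreSet@nPerm
  methods::initialize(scoreSet, scores = sc, selectionRate = selectionRate)
}

#' Run the full network significance pipeline
#'
#' Filters the interactome to high-confidence edges, enumerates first-order
#' neighborhoods, maps in the per-gene differential expression p-values,
#' integrates them by Edgington's method, and calibrates each network by
#' permutation.
#'
#' @param de a [moderatedTTest()] result (or any data.frame with `gene` and
#'   `p` columns).
#' @param graph igraph interactome with `confidence` edge attribute.
#' @param confidenceThreshold edge filter (default 0.119).
#' @param nPerm permutations (study scale 1e7; desk default 1e5).
#' @param selectionRate selection threshold as a permutation rate (default
#'   1e-4).
#' @param minSize,maxSize network size bounds.
#' @param seed RNG seed.
#' @return a [NetworkScoreSet-class].
#' @export
runNetworkSignificance <- function(de, graph, confidenceThreshold = 0.119,
                                   nPerm = 1e5, selectionRate = 1e-4,
                                   minSize = 3, maxSize = 500, seed = 1) {
  g <- filterGraph(graph, confidenceThreshold)
  nets <- enumerateNeighborhoods(g, minSize, maxSize)
  geneP <- setNames(de$p, de$gene)
  res <- networkPermutationTest(nets, geneP, nPerm = nPerm, seed = seed,
                                selectionRate = selectionRate)
  res@confidenceThreshold <- confidenceThreshold
  res
}

#' Estimate the selection false discovery rate by label permutation
#'
#' Permutes the group labels of the expression cohort, reruns differential
#' expression and the network significance test per permutation, and reports
#' FDR = mean(selected under permuted labels) / max(1, selected observed).
#'
#' @param x SummarizedExperiment or matrix of log2 expression.
#' @param labels two-level group factor (see [moderatedTTest()]).
#' @param graph igraph interactome.
#' @param nLabelPerms label permutations (default 20).
#' @param observed optionally, an already-computed observed
#'   [NetworkScoreSet-class] (saves one pipeline run).
#' @param seed RNG seed.
#' @param ... passed to [runNetworkSignificance()] (nPerm, thresholds, ...).
#' @return list: `fdr` (NA with a note when nothing is selected), `nObserved`,
#'   `permSelected` (per-permutation counts), `note`.
#' @export
estimateNetsigFdr <- function(x, labels = NULL, graph, nLabelPerms = 20,
                              observed = NULL, seed = 1, ...) {
  inp <- exprInput(x, labels)
  if (is.null(observed)) {
    de <- moderatedTTest(inp$mat, inp$labels)
    observed <- runNetworkSignificance(de, graph, seed = seed, ...)
  }
  nObs <- sum(observed@scores$selected)
  set.seed(seed)
  permSelected <- vapply(seq_len(nLabelPerms), function(i) {
    lab <- sample(inp$labels)
    deP <- moderatedTTest(inp$mat, lab)
    res <- runNetworkSignificance(deP, graph, seed = seed + i, ...)
    sum(res@scores$selected)
  }, numeric(1))
  note <- if (nObs == 0)
    "no networks selected on observed labels; FDR undefined" else NA_character_
  list(fdr = if (nObs == 0) NA_real_ else mean(permSelected) / nObs,
       nObserved = nObs, permSelected = permSelected, note = note)
}
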