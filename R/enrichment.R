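#' Preranked gene-set enrichment analysis
#'
#' Classic weighted Kolmogorov-Smirnov running sum on a ranked statistic
#' (e.g. the moderated t): walking down the ranking, set members increment
#' the sum by |stat|^weight (normalised over the set) and non-members
#' decrement it by 1/(N - n_set). The enrichment score is the signed
#' extremum; significance comes from gene-label permutation, and NES divides
#' ES by the mean |permuted ES| of the same sign (fgsea convention).
#'
#' @param stats named vector of ranking statistics (larger = more
#'   upregulated in the group of interest).
#' @param geneSet member gene symbols.
#' @param nPerm gene-label permutations (>= 100).
#' @param weight hit-weight exponent (default 1; 0 gives the unweighted KS
#'   statistic).
#' @param seed RNG seed.
#' @return list: `ES`, `NES`, `p`, `leadingEdge` (member genes up to the
#'   extremum, on the side of the signal), `n` set size used.
#' @export
prerankedGsea <- function(stats, geneSet, nPerm = 1000, weight = 1,
                          seed = 1) {
  if (nPerm < 100) stop("nPerm must be >= 100")
  if (is.null(names(stats))) stop("stats must be a named vector")
  inSet <- names(stats) %in% geneSet
  if (!any(inSet)) stop("gene set does not intersect the ranking")
  ord <- order(stats, decreasing = TRUE)
  s <- stats[ord]; hit <- inSet[ord]
  es <- gseaRunningES(s, hit, weight)
  set.seed(seed)
  nHit <- sum(hit)
  permES <- vapply(seq_len(nPerm), function(i) {
    h <- logical(length(s))
    h[sample.int(length(s), nHit)] <- TRUE
    gseaRunningES(s, h, weight)$ES
  }, numeric(1))
  same <- if (es$ES >= 0) permES[permES >= 0] else permES[permES < 0]
  p <- if (es$ES >= 0)
    (sum(same >= es$ES) + 1) / (length(same) + 1) else
    (sum(same <= es$ES) + 1) / (length(same) + 1)
  nes <- if (length(same)) es$ES / mean(abs(same)) else NA_real_
  leading <- if (es$ES >= 0) names(s)[seq_len(es$at)][hit[seq_len(es$at)]]
             else names(s)[es$at:length(s)][hit[es$at:length(s)]]
  list(ES = es$ES, NES = nes, p = p, leadingEdge = leading, n = nHit)
}

gseaRunningES <- function(orderedStats, hit, weight) {
  w <- abs(orderedStats)^weight
  inc <- numeric(length(hit))
  tot <- sum(w[hit])
  inc[hit] <- if (tot > 0) w[hit] / tot else 1 / sum(hit)
  inc[!hit] <- -1 / sum(!hit)
  run <- cumsum(inc)
  at <- which.max(abs(run))
  list(ES = run[at], at = at)
}

#' Hypergeometric overrepresentation test
#'
#' Upper-tail probability of observing at least the given overlap between a
#' selected gene list and a gene set inside a finite universe.
#'
#' @param selected selected gene symbols (subset of `universe`).
#' @param geneSet set member symbols (members outside the universe are
#'   trimmed with a warning).
#' @param universe all measured gene symbols.
#' @return upper-tail p-value.
#' @export
hypergeomOverrepresentation <- function(selected, geneSet, universe) {
  if (!all(selected %in% universe))
    stop("selected genes must lie inside the universe")
  out <- setdiff(geneSet, universe)
  if (length(out)) {
    warning(length(out), " set member(s) outside the universe; trimmed")
    geneSet <- intersect(geneSet, universe)
  }
  if (!length(selected)) return(1)
  k <- length(intersect(selected, geneSet))
  phyper(k - 1, length(geneSet), length(universe) - length(geneSet),
         length(selected), lower.tail = FALSE)
}

#' Fisher's exact test for a 2x2 table (two-sided, point probability)
#'
#' Conditional on the margins, sums the hypergeometric probabilities of all
#' tables whose point probability does not exceed that of the observed table
#' (the convention of `fisher.test`). The odds ratio reported is the sample
#' (cross-product) odds ratio.
#'
#' @param tab 2x2 matrix of non-negative integer counts.
#' @return list with `oddsRatio` and `p`.
#' @export
fisherExact2x2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  a <- tab[1, 1]
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  pObs <- dhyper(a, m, n, k)
  p <- min(1, sum(dens[dens <= pObs * (1 + 1e-7)]))
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(oddsRatio = or, p = p)
}

#' Chi-square test with Yates' continuity correction (2x2)
#'
#' Statistic \eqn{\sum (|O - E| - 0.5)^2 / E} with the correction clamped so
#' |O - E| - 0.5 never goes negative; p is the upper tail of the chi-square
#' distribution with one degree of freedom.
#'
#' @param tab 2x2 matrix of non-negative counts.
#' @return list with `statistic` and `p`.
#' @export
yatesChi2 <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2, 2))) stop("need a 2x2 table")
  if (any(tab < 0)) stop("counts must be non-negative")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero margin")
  E <- outer(rs, cs) / sum(tab)
  stat <- sum(pmax(abs(tab - E) - 0.5, 0)^2 / E)
  list(statistic = stat, p = pchisq(stat, df = 1, lower.tail = FALSE))
}

#' Read gene sets in GMT format
#'
#' @param path GMT file: one set per line, tab-separated
#'   (name, description, members...).
#' @return named list of unique member vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, character(1), 1)
  sets
}
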