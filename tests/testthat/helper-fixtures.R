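# Shared fixtures: tiny graphs and cohorts built in code at test time.

tinyPathGraph <- function() {
  g <- igraph::make_graph(c("a", "b", "b", "c"), directed = FALSE)
  igraph::set_edge_attr(g, "confidence", value = c(0.5, 0.9))
}

tinyStarGraph <- function(nLeaves = 4) {
  edges <- as.vector(rbind("hub", paste0("leaf", seq_len(nLeaves))))
  g <- igraph::make_graph(edges, directed = FALSE)
  igraph::set_edge_attr(g, "confidence", value = rep(0.9, nLeaves))
}

# brute-force BH by the defining formula q_i = min_{j: p_(j) >= p_i} p_(j)*m/j
bruteForceBH <- function(p) {
  m <- length(p)
  ps <- sort(p)
  vapply(p, function(pi) {
    js <- which(ps >= pi - 1e-15)
    min(1, min(ps[js] * m / js))
  }, numeric(1))
}

# brute-force AUC: all-pairs concordance with ties at 1/2
bruteForceAuc <- function(scores, outcomes) {
  pos <- scores[as.logical(outcomes)]
  neg <- scores[!as.logical(outcomes)]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# brute-force two-sided Fisher p: enumerate all tables with fixed margins
bruteForceFisher <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  dens <- dhyper(support, m, n, k)
  pObs <- dhyper(tab[1, 1], m, n, k)
  sum(dens[dens <= pObs * (1 + 1e-7)])
}

# Monte-Carlo oracle for the Irwin-Hall CDF
mcIrwinHall <- function(s, n, nDraw = 2e4) {
  sums <- colSums(matrix(runif(n * nDraw), n))
  p <- mean(sums <= s)
  list(p = p, se = sqrt(max(p * (1 - p), 1 / nDraw) / nDraw))
}
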