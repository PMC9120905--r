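#' Extract the expression matrix and group labels
#'
#' Accepts either a SummarizedExperiment with a `group` column in its colData
#' or a plain matrix plus an explicit label vector.
#' @noRd
exprInput <- function(x, labels = NULL) {
  if (is(x, "SummarizedExperiment")) {
    mat <- SummarizedExperiment::assay(x)
    if (is.null(labels)) labels <- SummarizedExperiment::colData(x)$group
  } else mat <- as.matrix(x)
  if (is.null(labels)) stop("group labels required")
  labels <- factor(labels)
  if (nlevels(labels) != 2) stop("exactly two groups required")
  if (ncol(mat) != length(labels)) stop("labels must match columns")
  list(mat = mat, labels = labels)
}

#' Moderated two-sample t-test with a fixed variance prior
#'
#' Per-gene two-group comparison on log2 expression in which the pooled
#' per-gene variance is shrunk toward a prior variance with `priorDf`
#' pseudo-observations (empirical-Bayes style):
#' \deqn{\tilde s^2_g = (d_0 s_0^2 + d s_g^2)/(d_0 + d)}
#' with \eqn{d} the residual degrees of freedom. The moderated t uses the
#' shrunken standard error with \eqn{d + d_0} degrees of freedom; the prior
#' variance \eqn{s_0^2} defaults to the mean of the per-gene pooled
#' variances. With `priorDf = 0` the statistic is the ordinary pooled
#' two-sample t. P-values are two-sided.
#'
#' @param x SummarizedExperiment (assay = log2 expression, colData `group`)
#'   or genes-by-samples matrix.
#' @param labels two-level group factor (first level is "group A"); taken
#'   from `colData(x)$group` when omitted.
#' @param priorDf prior degrees of freedom (default 4).
#' @param priorVar prior variance; default mean of per-gene variances.
#' @param fcNeutral absolute log2FC at or below which a gene is labelled
#'   `neutral` (default 0.1).
#' @return data.frame, one row per gene: `gene`, `meanA`, `meanB`, `log2FC`
#'   (A - B), `t`, `p`, `q` (Benjamini-Hochberg), `direction`.
#' @export
moderatedTTest <- function(x, labels = NULL, priorDf = 4, priorVar = NULL,
                           fcNeutral = 0.1) {
  inp <- exprInput(x, labels)
  mat <- inp$mat; labels <- inp$labels
  if (!all(is.finite(mat))) stop("expression matrix must be finite")
  if (is.null(rownames(mat)))
    rownames(mat) <- sprintf("gene%04d", seq_len(nrow(mat)))
  a <- labels == levels(labels)[1]
  nA <- sum(a); nB <- sum(!a)
  if (nA < 2 || nB < 2) stop("need >= 2 samples per group")
  meanA <- rowMeans(mat[, a, drop = FALSE])
  meanB <- rowMeans(mat[, !a, drop = FALSE])
  df <- nA + nB - 2
  ssA <- rowSums((mat[, a, drop = FALSE] - meanA)^2)
  ssB <- rowSums((mat[, !a, drop = FALSE] - meanB)^2)
  s2 <- (ssA + ssB) / df
  if (is.null(priorVar)) priorVar <- mean(s2)
  s2mod <- if (priorDf > 0) (priorDf * priorVar + df * s2) / (priorDf + df)
           else s2
  se <- sqrt(s2mod * (1 / nA + 1 / nB))
  log2FC <- meanA - meanB
  degenerate <- se == 0 & log2FC == 0
  if (any(degenerate))
    warning(sum(degenerate), " gene(s) with zero variance and zero ",
            "difference; p set to 1")
  t <- ifelse(se == 0, ifelse(log2FC == 0, 0, sign(log2FC) * Inf),
              log2FC / se)
  p <- 2 * pt(-abs(t), df + priorDf)
  data.frame(
    gene = rownames(mat), meanA = meanA, meanB = meanB, log2FC = log2FC,
    t = t, p = p, q = bhAdjust(p),
    direction = ifelse(abs(log2FC) <= fcNeutral, "neutral",
                       ifelse(log2FC > 0, "up-in-A", "up-in-B")),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' Step-up adjustment with monotonicity enforcement, returned in the input
#' order: \eqn{q_i = \min_{j: p_{(j)} \ge p_{(i)}} \min(1, p_{(j)} m / j)}.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return q-values, same order as `p`.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p, decreasing = TRUE)
  q <- pmin(1, cummin(p[o] * m / seq(m, 1)))
  q[order(o)]
}

#' Select seed genes for the network analysis
#'
#' Genes below the FDR cutoff, ordered by q then |log2FC| descending; these
#' differentially expressed genes seed the first-order PPI neighborhoods.
#'
#' @param de a [moderatedTTest()] result.
#' @param qCutoff FDR cutoff (default 0.05).
#' @return character vector of gene symbols.
#' @export
selectSeedGenes <- function(de, qCutoff = 0.05) {
  hit <- de[de$q < qCutoff, , drop = FALSE]
  hit$gene[order(hit$q, -abs(hit$log2FC))]
}

#' Direction-of-regulation counts within a gene set
#'
#' Counts the set members upregulated more than `fcNeutral` log2FC in group A
#' and in group B respectively; neutral genes count in neither.
#'
#' @param de a [moderatedTTest()] result.
#' @param geneSet gene symbols (unknown genes dropped with a warning).
#' @param fcNeutral threshold (default 0.1).
#' @return named integer vector `c(upA =, upB =)`.
#' @export
directionCounts <- function(de, geneSet = de$gene, fcNeutral = 0.1) {
  unknown <- setdiff(geneSet, de$gene)
  if (length(unknown))
    warning(length(unknown), " gene(s) not measured; dropped")
  fc <- de$log2FC[match(intersect(geneSet, de$gene), de$gene)]
  c(upA = sum(fc > fcNeutral), upB = sum(fc < -fcNeutral))
}
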