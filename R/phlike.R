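#' Resolve a probe-level PAM signature to per-gene factors
#'
#' Genes detected by multiple probes receive the mean of their probe-level
#' PAM factors.
#'
#' @param signature data.frame with columns `gene` and `factor` (a `probe`
#'   column may be present and is ignored after averaging).
#' @return data.frame `gene`/`factor`, one row per gene.
#' @export
resolveSignature <- function(signature) {
  if (!all(c("gene", "factor") %in% names(signature)))
    stop("signature needs 'gene' and 'factor' columns")
  f <- tapply(signature$factor, signature$gene, mean)
  data.frame(gene = names(f), factor = as.numeric(f),
             stringsAsFactors = FALSE)
}

#' Mock PAM score and top-5\% flag
#'
#' Per-sample score: the sum over measured signature genes of expression
#' times the resolved (per-gene mean) PAM factor. The flag marks membership
#' in the top `ceiling(topFraction * n)` scores; samples tied with the
#' boundary score are all included, so the flagged count can exceed the
#' ceiling only under ties.
#'
#' @param x SummarizedExperiment or log2 expression matrix (genes x samples).
#' @param signature probe/gene/factor data.frame.
#' @param topFraction fraction flagged (default 0.05).
#' @return list: `score` (named numeric), `flag` (named logical),
#'   `nMissing` signature genes not measured.
#' @export
mockPamScore <- function(x, signature, topFraction = 0.05) {
  mat <- if (is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x)
         else as.matrix(x)
  sig <- resolveSignature(signature)
  found <- sig$gene %in% rownames(mat)
  if (!any(found)) stop("no signature genes measured")
  if (!all(found))
    warning(sum(!found), " signature gene(s) not measured; dropped")
  sig <- sig[found, , drop = FALSE]
  score <- as.numeric(crossprod(mat[sig$gene, , drop = FALSE], sig$factor))
  names(score) <- colnames(mat)
  k <- ceiling(topFraction * length(score))
  boundary <- sort(score, decreasing = TRUE)[k]
  flag <- score >= boundary
  list(score = score, flag = flag, nMissing = sum(!found))
}

#' Flag the cluster most compatible with the PAM signature
#'
#' Agglomerative clustering (average linkage on correlation distance,
#' 1 - Pearson, by default) of the samples on the feature submatrix; the
#' "most compatible" cluster is the one with the highest mean mock-PAM score
#' and all its members are flagged. Degenerate inputs in which all samples
#' coincide yield a single effective cluster: no sample is flagged and a
#' warning is raised.
#'
#' @param x SummarizedExperiment or log2 expression matrix.
#' @param features feature gene symbols (must be measured).
#' @param signature probe/gene/factor data.frame (scores the clusters).
#' @param k number of clusters (default 2).
#' @param method linkage (default "average").
#' @return named logical flag vector.
#' @export
clusterCall <- function(x, features, signature, k = 2, method = "average") {
  mat <- if (is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x)
         else as.matrix(x)
  if (k < 2) stop("k must be >= 2")
  if (k > ncol(mat)) stop("k exceeds the number of samples")
  features <- intersect(features, rownames(mat))
  if (length(features) < 2) stop("need >= 2 measured feature genes")
  sub <- mat[features, , drop = FALSE]
  if (sd(as.vector(sub)) == 0) {
    warning("all samples identical on the feature set; no cluster flagged")
    return(setNames(rep(FALSE, ncol(mat)), colnames(mat)))
  }
  dis <- stats::as.dist(1 - cor(sub))
  dis[!is.finite(dis)] <- 1
  cl <- cutree(hclust(dis, method = method), k = k)
  pam <- mockPamScore(mat, signature)$score
  meanByCluster <- tapply(pam, cl, mean)
  best <- as.integer(names(meanByCluster)[which.max(meanByCluster)])
  setNames(cl == best, colnames(mat))
}

#' Derive the 25 most significant signature genes on a reference cohort
#'
#' Moderated-t p-values comparing Ph-like and other cases on an independent
#' reference dataset; the 25 smallest-p genes of the candidate pool are
#' returned (ties broken by |log2FC| then symbol). Pools smaller than 25 are
#' returned whole with a warning.
#'
#' @param reference SummarizedExperiment or log2 matrix of the reference
#'   cohort.
#' @param labels logical/two-level labels (Ph-like = first level or TRUE).
#' @param pool candidate gene symbols (signature genes measured in both
#'   datasets).
#' @param nTop number of genes to keep (default 25).
#' @return character vector of gene symbols.
#' @export
deriveTop25 <- function(reference, labels = NULL, pool, nTop = 25) {
  mat <- if (is(reference, "SummarizedExperiment")) {
    if (is.null(labels))
      labels <- SummarizedExperiment::colData(reference)$phlike
    SummarizedExperiment::assay(reference)
  } else as.matrix(reference)
  if (is.logical(labels))
    labels <- factor(ifelse(labels, "phlike", "other"),
                     levels = c("phlike", "other"))
  pool <- intersect(pool, rownames(mat))
  if (!length(pool)) stop("no candidate genes measured in the reference")
  de <- moderatedTTest(mat[pool, , drop = FALSE], labels)
  if (length(pool) < nTop) {
    warning("candidate pool smaller than ", nTop, "; returning all")
    nTop <- length(pool)
  }
  de$gene[order(de$p, -abs(de$log2FC), de$gene)][seq_len(nTop)]
}

#' Consensus of the three Ph-like strategies
#'
#' A sample is called Ph-like when at least two of the three strategy flags
#' are positive.
#'
#' @param flagPam,flagFull,flagTop25 equal-length logical vectors (named by
#'   sample).
#' @return a [PhLikeCallSet-class].
#' @export
consensusCall <- function(flagPam, flagFull, flagTop25) {
  n <- length(flagPam)
  if (length(flagFull) != n || length(flagTop25) != n)
    stop("flag vectors must have equal length")
  cnt <- as.integer(flagPam) + as.integer(flagFull) + as.integer(flagTop25)
  new("PhLikeCallSet", calls = data.frame(
    sample = if (is.null(names(flagPam))) sprintf("S%03d", seq_len(n)) else
      names(flagPam),
    flagPam = unname(flagPam), flagClusterFull = unname(flagFull),
    flagClusterTop25 = unname(flagTop25), strategyCount = cnt,
    consensus = cnt >= 2L, row.names = NULL, stringsAsFactors = FALSE),
    params = list())
}

#' Three-strategy Ph-like classification
#'
#' Runs (1) the mock-PAM top-5\% flag, (2) hierarchical clustering on the
#' full signature feature set, and (3) clustering on the 25 genes filtered on
#' an independent reference cohort, then forms the >= 2-of-3 consensus.
#' Without a reference the third strategy falls back to the full signature's
#' top genes ranked by |factor| (documented in the returned params).
#'
#' @param x SummarizedExperiment or log2 matrix of the study cohort.
#' @param signature probe/gene/factor data.frame.
#' @param reference optional reference SummarizedExperiment/matrix.
#' @param referenceLabels labels for the reference (see [deriveTop25()]).
#' @param k clusters (default 2).
#' @param topFraction mock-PAM flag fraction (default 0.05).
#' @return a [PhLikeCallSet-class].
#' @export
callPhLike <- function(x, signature, reference = NULL,
                       referenceLabels = NULL, k = 2, topFraction = 0.05) {
  mat <- if (is(x, "SummarizedExperiment")) SummarizedExperiment::assay(x)
         else as.matrix(x)
  sig <- resolveSignature(signature)
  measured <- intersect(sig$gene, rownames(mat))
  pam <- mockPamScore(mat, signature, topFraction)
  flagFull <- clusterCall(mat, measured, signature, k = k)
  top25 <- if (!is.null(reference))
    deriveTop25(reference, referenceLabels, pool = measured) else
    head(sig$gene[order(-abs(sig$factor))], 25)
  flagTop25 <- clusterCall(mat, top25, signature, k = k)
  calls <- consensusCall(pam$flag, flagFull, flagTop25)
  calls@params <- list(k = k, topFraction = topFraction, top25 = top25,
                       referenceUsed = !is.null(reference),
                       pamScore = pam$score)
  calls
}
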