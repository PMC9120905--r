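#' @import methods
#' @importFrom stats median quantile density rnorm runif rbeta sd var pt pchisq
#'   phyper dhyper pnorm qnorm qt setNames lm as.formula coef confint step
#'   drop1 ks.test p.adjust cor rlnorm hclust cutree dist complete.cases
#'   update terms
#' @importFrom utils head read.delim write.table read.csv write.csv
NULL

MARKER_PANEL <- c("CD19", "CD20", "CD22", "nTdT", "cyCD79a", "cyCD22",
                  "CD45", "CD34", "CD38", "CD10",
                  "CD123", "CD66c", "CD133", "CD13", "CD33", "CD15")

MARKER_CLASSES <- c(
  CD19 = "B-lineage", CD20 = "B-lineage", CD22 = "B-lineage",
  nTdT = "B-lineage", cyCD79a = "B-lineage", cyCD22 = "B-lineage",
  CD45 = "nonlineage", CD34 = "nonlineage", CD38 = "nonlineage",
  CD10 = "nonlineage",
  CD123 = "cross-lineage", CD66c = "cross-lineage", CD133 = "cross-lineage",
  CD13 = "cross-lineage", CD33 = "cross-lineage", CD15 = "cross-lineage")

SCORE_LEVELS <- c("neg", "PD", "PN", "PB")
SCORE_SYMBOLS <- c(neg = "-", PD = "+", PN = "++", PB = "+++")

#' Reference intervals for four-level marker scoring
#'
#' Holds, per marker, the three ascending log10-fluorescence cutpoints that
#' partition the intensity axis into neg | PD | PN | PB, together with the
#' marker class (B-lineage, nonlineage or cross-lineage) and the width of one
#' "score" in log10 units (used by the broad-expression rule).
#'
#' @slot intervals data.frame with columns `marker`, `markerClass`,
#'   `negPD`, `pdPN`, `pnPB`, `scoreUnit`.
#' @export
setClass("ReferenceIntervalSet",
  representation(intervals = "data.frame"))

setValidity("ReferenceIntervalSet", function(object) {
  iv <- object@intervals
  need <- c("marker", "markerClass", "negPD", "pdPN", "pnPB", "scoreUnit")
  if (!all(need %in% names(iv)))
    return(paste("intervals must have columns:", paste(need, collapse = ", ")))
  if (anyDuplicated(iv$marker)) return("duplicate marker rows")
  bad <- !(iv$negPD < iv$pdPN & iv$pdPN < iv$pnPB)
  if (any(bad))
    return(paste("boundaries not strictly ascending for:",
                 paste(iv$marker[bad], collapse = ", ")))
  if (any(iv$scoreUnit <= 0)) return("scoreUnit must be positive")
  TRUE
})

#' Four-level score of one marker on one sample
#'
#' @slot marker marker name.
#' @slot modality one of "unimodal", "bimodal", "broad".
#' @slot subpopulations data.frame with columns `fraction`, `mfi`, `score`;
#'   one row per subpopulation surviving the >1\% reporting rule.
#' @slot overallScore score of the dominant (largest-fraction) subpopulation.
#' @slot mfiOverall median log10 fluorescence over all events.
#' @export
setClass("MarkerScore",
  representation(marker = "character", modality = "character",
                 subpopulations = "data.frame",
                 overallScore = "character", mfiOverall = "numeric"))

setValidity("MarkerScore", function(object) {
  if (!object@modality %in% c("unimodal", "bimodal", "broad"))
    return("modality must be unimodal, bimodal or broad")
  sp <- object@subpopulations
  if (!all(c("fraction", "mfi", "score") %in% names(sp)))
    return("subpopulations needs fraction, mfi, score")
  if (abs(sum(sp$fraction) - 1) > 1e-9)
    return("subpopulation fractions must sum to 1")
  if (object@modality == "bimodal" && nrow(sp) < 2)
    return("bimodal marker must carry >= 2 subpopulations")
  if (any(sp$fraction <= 0.01))
    return("reported subpopulations must exceed the 1% rule")
  if (!object@overallScore %in% SCORE_LEVELS)
    return("overallScore must be one of neg/PD/PN/PB")
  dom <- sp$score[which.max(sp$fraction)]
  if (dom != object@overallScore)
    return("overallScore must equal the dominant subpopulation's score")
  TRUE
})

#' Leukemia-associated immunophenotype of one patient
#'
#' @slot patient patient identifier.
#' @slot markerScores named list of [MarkerScore-class] objects, one per
#'   measured marker.
#' @export
setClass("LAIPProfile",
  representation(patient = "character", markerScores = "list"))

setValidity("LAIPProfile", function(object) {
  ok <- vapply(object@markerScores, is, logical(1), class2 = "MarkerScore")
  if (!all(ok)) return("markerScores must all be MarkerScore objects")
  nm <- vapply(object@markerScores, function(m) m@marker, character(1))
  if (!identical(unname(nm), names(object@markerScores)))
    return("markerScores list names must match marker slots")
  if (anyDuplicated(nm)) return("one MarkerScore per marker")
  TRUE
})

#' Permutation-calibrated scores of first-order PPI neighborhoods
#'
#' Result container of the network significance test: one row per scored
#' neighborhood with its Edgington sum, Irwin-Hall integrated p-value,
#' permutation count and empirical p-value, plus the selection flag under the
#' configured permutation-rate rule.
#'
#' @slot scores data.frame with columns `seed`, `n`, `nExcluded`, `S`,
#'   `pInt`, `permCount`, `pEmp`, `selected`.
#' @slot members named list: member gene symbols per scored network.
#' @slot nPerm number of permutations used.
#' @slot selectionRate networks are selected when
#'   `permCount < selectionRate * nPerm`.
#' @slot confidenceThreshold edge confidence threshold applied upstream.
#' @slot seed RNG seed of the permutation stream.
#' @export
setClass("NetworkScoreSet",
  representation(scores = "data.frame", members = "list",
                 nPerm = "numeric", selectionRate = "numeric",
                 confidenceThreshold = "numeric", seed = "numeric"))

setValidity("NetworkScoreSet", function(object) {
  sc <- object@scores
  need <- c("seed", "n", "nExcluded", "S", "pInt", "permCount", "pEmp",
            "selected")
  if (!all(need %in% names(sc)))
    return(paste("scores must have columns:", paste(need, collapse = ", ")))
  if (nrow(sc) != length(object@members))
    return("one member list per scored network")
  if (any(sc$S < 0 | sc$S > sc$n + 1e-9))
    return("Edgington sum must lie in [0, n]")
  if (any(sc$pInt < 0 | sc$pInt > 1)) return("pInt must lie in [0, 1]")
  if (any(sc$permCount > object@nPerm))
    return("permCount cannot exceed nPerm")
  TRUE
})

#' Ph-like consensus calls
#'
#' Per-sample flags of the three Ph-like identification strategies (mock-PAM
#' top 5\%, hierarchical clustering on the full signature, clustering on the
#' 25 reference-filtered genes) and their >= 2-of-3 consensus.
#'
#' @slot calls data.frame with columns `sample`, `flagPam`,
#'   `flagClusterFull`, `flagClusterTop25`, `strategyCount`, `consensus`.
#' @slot params list of classifier settings used.
#' @export
setClass("PhLikeCallSet",
  representation(calls = "data.frame", params = "list"))

setValidity("PhLikeCallSet", function(object) {
  cl <- object@calls
  need <- c("sample", "flagPam", "flagClusterFull", "flagClusterTop25",
            "strategyCount", "consensus")
  if (!all(need %in% names(cl)))
    return(paste("calls must have columns:", paste(need, collapse = ", ")))
  sc <- cl$flagPam + cl$flagClusterFull + cl$flagClusterTop25
  if (!identical(as.integer(sc), as.integer(cl$strategyCount)))
    return("strategyCount must equal the number of positive flags")
  if (!identical(cl$consensus, cl$strategyCount >= 2L))
    return("consensus must be strategyCount >= 2")
  TRUE
})

#' Log-linear MRD model fit
#'
#' Ordinary least squares on log10(MRD) with effects reported as decade-fold
#' ratios (10^beta) and Wald confidence intervals.
#'
#' @slot fit the underlying `lm` fit.
#' @slot effects data.frame with columns `term`, `foldEffect`, `ciLow`,
#'   `ciHigh`, `p` (and `pBonferroni` when requested).
#' @slot aic AIC of the fit.
#' @export
setClass("MrdModelFit",
  representation(fit = "ANY", effects = "data.frame", aic = "numeric"))

setValidity("MrdModelFit", function(object) {
  if (!all(c("term", "foldEffect", "ciLow", "ciHigh", "p") %in%
           names(object@effects)))
    return("effects needs term, foldEffect, ciLow, ciHigh, p")
  if (any(object@effects$foldEffect <= 0))
    return("fold effects must be positive")
  TRUE
})
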