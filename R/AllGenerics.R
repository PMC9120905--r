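#' @rdname NetworkScoreSet-class
#' @param object a result object.
#' @export
setGeneric("networkScores", function(object) standardGeneric("networkScores"))

#' @rdname NetworkScoreSet-class
#' @export
setGeneric("selectedNetworks",
           function(object) standardGeneric("selectedNetworks"))

#' @rdname NetworkScoreSet-class
#' @export
setGeneric("networkMembers",
           function(object) standardGeneric("networkMembers"))

#' @rdname PhLikeCallSet-class
#' @export
setGeneric("phLikeCalls", function(object) standardGeneric("phLikeCalls"))

#' @rdname PhLikeCallSet-class
#' @export
setGeneric("consensusSamples",
           function(object) standardGeneric("consensusSamples"))

#' @rdname MrdModelFit-class
#' @export
setGeneric("foldEffects", function(object) standardGeneric("foldEffects"))

#' @rdname LAIPProfile-class
#' @export
setGeneric("markerScore",
           function(object, marker) standardGeneric("markerScore"))

#' @rdname MarkerScore-class
#' @export
setGeneric("overallScore", function(object) standardGeneric("overallScore"))

#' @rdname ReferenceIntervalSet-class
#' @export
setGeneric("referenceIntervals",
           function(object) standardGeneric("referenceIntervals"))

setMethod("networkScores", "NetworkScoreSet", function(object) object@scores)

setMethod("selectedNetworks", "NetworkScoreSet", function(object) {
  sc <- object@scores
  sc[sc$selected, , drop = FALSE]
})

setMethod("networkMembers", "NetworkScoreSet", function(object) object@members)

setMethod("phLikeCalls", "PhLikeCallSet", function(object) object@calls)

setMethod("consensusSamples", "PhLikeCallSet", function(object)
  object@calls$sample[object@calls$consensus])

setMethod("foldEffects", "MrdModelFit", function(object) object@effects)

setMethod("markerScore", "LAIPProfile",
          function(object, marker) object@markerScores[[marker]])

setMethod("overallScore", "MarkerScore", function(object) object@overallScore)

setMethod("referenceIntervals", "ReferenceIntervalSet",
          function(object) object@intervals)

setMethod("show", "ReferenceIntervalSet", function(object) {
  cat("ReferenceIntervalSet with", nrow(object@intervals), "markers\n")
  print(head(object@intervals, 6), row.names = FALSE)
  if (nrow(object@intervals) > 6) cat("...\n")
})

setMethod("show", "MarkerScore", function(object) {
  cat(sprintf("MarkerScore %s: %s (%s), MFI %.2f\n", object@marker,
              SCORE_SYMBOLS[object@overallScore], object@modality,
              object@mfiOverall))
  if (nrow(object@subpopulations) > 1)
    print(object@subpopulations, row.names = FALSE)
})

setMethod("show", "LAIPProfile", function(object) {
  sym <- vapply(object@markerScores,
                function(m) SCORE_SYMBOLS[[m@overallScore]], character(1))
  cat("LAIPProfile for patient", object@patient, "\n")
  print(noquote(sym))
})

setMethod("show", "NetworkScoreSet", function(object) {
  cat(sprintf(
    "NetworkScoreSet: %d neighborhoods, %g permutations (seed %g)\n",
    nrow(object@scores), object@nPerm, object@seed))
  cat(sprintf("selection rule: permCount < %g (rate %g); %d selected\n",
              object@selectionRate * object@nPerm, object@selectionRate,
              sum(object@scores$selected)))
  top <- object@scores[order(object@scores$pEmp), , drop = FALSE]
  print(head(top, 5), row.names = FALSE)
})

setMethod("show", "PhLikeCallSet", function(object) {
  cat(sprintf("PhLikeCallSet: %d samples, %d consensus Ph-like\n",
              nrow(object@calls), sum(object@calls$consensus)))
  hit <- object@calls[object@calls$consensus, , drop = FALSE]
  if (nrow(hit)) print(head(hit, 10), row.names = FALSE)
})

setMethod("show", "MrdModelFit", function(object) {
  cat("Log-linear MRD model (outcome log10 MRD), AIC",
      round(object@aic, 2), "\n")
  print(object@effects, row.names = FALSE)
})
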