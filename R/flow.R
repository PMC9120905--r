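#' @importFrom stats dnorm
NULL

#' Derive reference intervals from control bone-marrow samples
#'
#' Pools the control events per marker and derives the three score cutpoints
#' by a quantile rule: the neg/PD boundary at a high quantile of the negative
#' lymphocyte population (events labelled `"negative"`), and the PD/PN and
#' PN/PB boundaries at the lower/upper quartiles of the positive population.
#' One score unit is a third of the neg-to-PB span.
#'
#' @param controls list of control-sample data.frames with columns `marker`,
#'   `population` ("negative"/"positive") and `value` (log10 fluorescence).
#' @param negQuantile quantile of the negative population for the neg/PD
#'   boundary (default 0.995).
#' @param posQuantiles quantiles of the positive population for the PD/PN and
#'   PN/PB boundaries (default quartiles).
#' @param markerClasses named character giving each marker's class; defaults
#'   to the panel classification (unknown markers fall back to nonlineage).
#' @return a [ReferenceIntervalSet-class].
#' @export
buildReferenceIntervals <- function(controls, negQuantile = 0.995,
                                    posQuantiles = c(0.25, 0.75),
                                    markerClasses = MARKER_CLASSES) {
  if (!length(controls)) stop("need at least one control sample")
  pooled <- do.call(rbind, controls)
  if (!nrow(pooled)) stop("empty control table")
  rows <- lapply(split(pooled, pooled$marker), function(d) {
    neg <- d$value[d$population == "negative"]
    pos <- d$value[d$population == "positive"]
    if (!length(neg) || !length(pos))
      stop("marker ", d$marker[1], ": need negative and positive controls")
    b1 <- quantile(neg, negQuantile, names = FALSE)
    b23 <- quantile(pos, posQuantiles, names = FALSE)
    if (diff(range(d$value)) < 1e-8 || !(b1 < b23[1] && b23[1] < b23[2]))
      stop("degenerate reference interval for marker ", d$marker[1])
    cls <- markerClasses[d$marker[1]]
    data.frame(marker = d$marker[1],
               markerClass = ifelse(is.na(cls), "nonlineage", unname(cls)),
               negPD = b1, pdPN = b23[1], pnPB = b23[2],
               scoreUnit = (b23[2] - b1) / 3, stringsAsFactors = FALSE)
  })
  new("ReferenceIntervalSet",
      intervals = do.call(rbind, c(rows, make.row.names = FALSE)))
}

markerInterval <- function(ref, marker) {
  iv <- referenceIntervals(ref)
  r <- iv[iv$marker == marker, , drop = FALSE]
  if (nrow(r) != 1) stop("no reference interval for marker ", marker)
  as.list(r)
}

#' Detect subpopulations in one marker's event distribution
#'
#' Kernel-density estimate (Silverman bandwidth) on the log10-fluorescence
#' values; local maxima above a prominence floor define peaks, events are
#' assigned to peak basins split at the density minima between adjacent
#' peaks, and populations comprising <= 1\% of events are merged into the
#' nearest larger population. The marker is bimodal when >= 2 populations
#' survive; with a single population it is broad when the density's extent at
#' 10\% of the peak maximum spans at least 1.5 score units (B-/nonlineage
#' markers) or 1.5 log10 decades (cross-lineage markers); otherwise unimodal.
#'
#' @param x numeric vector of log10 fluorescence values (>= 200 events).
#' @param marker marker name (looked up in `ref`).
#' @param ref a [ReferenceIntervalSet-class].
#' @param prominence minimum peak height as a fraction of the global density
#'   maximum (default 0.05).
#' @param minFraction reporting limit for subpopulations (default 0.01, the
#'   >1\% rule).
#' @param dipRatio two maxima count as distinct peaks only when the density
#'   minimum between them falls below this fraction of the smaller peak
#'   (default 0.75).
#' @return list: `modality`, and `subpopulations` data.frame with columns
#'   `fraction`, `mfi`, `score` (largest fraction first).
#' @export
detectSubpopulations <- function(x, marker, ref, prominence = 0.05,
                                 minFraction = 0.01, dipRatio = 0.75) {
  if (length(x) < 200)
    stop("insufficient data: need >= 200 events, got ", length(x))
  r <- markerInterval(ref, marker)
  d <- density(x, bw = "nrd0", n = 1024)
  peaks <- localMaxima(d$y)
  peaks <- peaks[d$y[peaks] >= prominence * max(d$y)]
  if (!length(peaks)) peaks <- which.max(d$y)
  # "distinct peaks": adjacent maxima separated by an insufficient dip are
  # one population; merge until every valley drops below dipRatio of the
  # smaller flanking peak
  repeat {
    if (length(peaks) < 2L) break
    valley <- vapply(seq_len(length(peaks) - 1L), function(i)
      min(d$y[peaks[i]:peaks[i + 1L]]), numeric(1))
    flank <- pmin(d$y[peaks[-length(peaks)]], d$y[peaks[-1L]])
    shallow <- valley > dipRatio * flank
    if (!any(shallow)) break
    i <- which.max(valley / flank)  # least distinct pair first
    drop <- if (d$y[peaks[i]] < d$y[peaks[i + 1L]]) i else i + 1L
    peaks <- peaks[-drop]
  }
  # basin boundaries at the density minima between adjacent retained peaks
  cuts <- vapply(seq_len(length(peaks) - 1L), function(i) {
    span <- peaks[i]:peaks[i + 1L]
    d$x[span[which.min(d$y[span])]]
  }, numeric(1))
  assign <- findInterval(x, cuts) + 1L
  frac <- tabulate(assign, nbins = length(peaks)) / length(x)
  # merge sub-1% populations into the nearest larger neighbor
  while (length(frac) > 1L && any(frac <= minFraction)) {
    i <- which.min(frac)
    j <- if (i == 1L) 2L else if (i == length(frac)) i - 1L else
      if (frac[i - 1L] >= frac[i + 1L]) i - 1L else i + 1L
    assign[assign == i] <- j
    assign[assign > i] <- assign[assign > i] - 1L
    frac <- tabulate(assign, nbins = length(frac) - 1L) / length(x)
  }
  nPop <- length(frac)
  modality <- if (nPop >= 2L) "bimodal" else {
    above <- d$x[d$y >= 0.10 * max(d$y)]
    width <- max(above) - min(above)
    lim <- if (identical(r$markerClass, "cross-lineage")) 1.5 else
      1.5 * r$scoreUnit
    if (width >= lim) "broad" else "unimodal"
  }
  sp <- data.frame(
    fraction = frac,
    mfi = vapply(seq_len(nPop), function(i) median(x[assign == i]),
                 numeric(1)))
  sp$score <- scoreOfValue(sp$mfi, r$negPD, r$pdPN, r$pnPB)
  sp <- sp[order(-sp$fraction), , drop = FALSE]
  rownames(sp) <- NULL
  list(modality = modality, subpopulations = sp)
}

localMaxima <- function(y) {
  n <- length(y)
  which(y > c(-Inf, y[-n]) & y >= c(y[-1], -Inf))
}

#' Score one marker from its detected subpopulations
#'
#' Each subpopulation is scored by the reference partition its MFI falls in
#' (values exactly on a cutpoint go to the higher category); the overall
#' score is that of the dominant (largest-fraction) subpopulation and the
#' overall MFI is the median over all events.
#'
#' @param x the marker's events (log10 fluorescence).
#' @param marker marker name.
#' @param ref a [ReferenceIntervalSet-class].
#' @param ... passed to [detectSubpopulations()].
#' @return a [MarkerScore-class].
#' @export
scoreMarker <- function(x, marker, ref, ...) {
  det <- detectSubpopulations(x, marker, ref, ...)
  sp <- det$subpopulations
  new("MarkerScore", marker = marker, modality = det$modality,
      subpopulations = sp, overallScore = sp$score[which.max(sp$fraction)],
      mfiOverall = median(x))
}

#' Score a whole patient's marker panel
#'
#' @param events data.frame of one patient's events, one column per marker.
#' @param patient patient identifier.
#' @param ref a [ReferenceIntervalSet-class].
#' @param ... passed to [detectSubpopulations()].
#' @return a [LAIPProfile-class].
#' @export
scorePatient <- function(events, patient, ref, ...) {
  ms <- lapply(names(events), function(m) scoreMarker(events[[m]], m, ref,
                                                      ...))
  names(ms) <- names(events)
  new("LAIPProfile", patient = patient, markerScores = ms)
}

#' Collapse a four-level marker score to binary
#'
#' All markers: 1 iff the overall score is PN or PB (neg/dim vs pos/bright);
#' CD15 and CD133 are the exception, scored 1 for any positivity (neg vs
#' dim/pos/bright).
#'
#' @param score a [MarkerScore-class], or a score level string.
#' @param marker marker name (taken from the object when omitted).
#' @return integer 0/1.
#' @export
binarizeScore <- function(score, marker = NULL) {
  if (is(score, "MarkerScore")) {
    marker <- score@marker
    score <- score@overallScore
  }
  if (!score %in% SCORE_LEVELS) stop("unknown score level: ", score)
  if (is.null(marker) || !marker %in% MARKER_PANEL) {
    if (!is.null(marker))
      warning("unknown marker '", marker, "': default neg/PD vs PN/PB rule")
    positive <- c("PN", "PB")
  } else {
    positive <- if (marker %in% c("CD15", "CD133")) c("PD", "PN", "PB") else
      c("PN", "PB")
  }
  as.integer(score %in% positive)
}

#' LAIP profiles as a patient-by-marker table
#'
#' @param profiles list of [LAIPProfile-class] objects.
#' @return data.frame with one row per patient/marker: symbol (-/+/++/+++),
#'   modality, dominant fraction and overall MFI.
#' @export
laipTable <- function(profiles) {
  do.call(rbind, lapply(profiles, function(p) {
    do.call(rbind, lapply(p@markerScores, function(m) {
      data.frame(patient = p@patient, marker = m@marker,
                 score = m@overallScore,
                 symbol = unname(SCORE_SYMBOLS[m@overallScore]),
                 modality = m@modality,
                 dominantFraction = max(m@subpopulations$fraction),
                 mfi = m@mfiOverall, binary = binarizeScore(m),
                 stringsAsFactors = FALSE)
    }))
  }))
}
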