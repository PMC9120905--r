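#' Censor MRD values at the limit of detection
#'
#' Below-LOD sentinels (the `"<LOD"` token) and numeric values below the
#' limit of detection are set to `lod` (study rule: 1e-5). Idempotent.
#'
#' @param values numeric proportions, or character mixing numbers with the
#'   sentinel.
#' @param lod limit of detection (default 1e-5).
#' @param sentinel the below-LOD token (default `"<LOD"`).
#' @return numeric vector in \[lod, 1\].
#' @export
censorMrd <- function(values, lod = 1e-5, sentinel = BELOW_LOD) {
  if (is.character(values)) {
    isSent <- values == sentinel
    out <- suppressWarnings(as.numeric(values))
    if (any(is.na(out) & !isSent)) stop("unparseable MRD value")
    out[isSent] <- lod
  } else out <- values
  if (any(out > 1, na.rm = TRUE)) stop("MRD is a proportion; value > 1")
  pmax(out, lod)
}

#' Log-linear regression of end-of-induction MRD
#'
#' Ordinary least squares on log10(MRD) with marker scores and clinical
#' covariates as explanatory variables. Effects are reported as decade-fold
#' MRD ratios 10^beta with Wald confidence intervals; categorical marker
#' scores are coded against their reference level (negative for CD34 by
#' default), and `age` is rescaled so its effect corresponds to a 10-year
#' increase.
#'
#' @param data data.frame with an `mrd` column (numeric or sentinel-bearing
#'   character) and the covariates.
#' @param covariates covariate names (columns of `data`).
#' @param lod limit of detection used by [censorMrd()].
#' @param level confidence level (default 0.95).
#' @param bonferroniN optional family size; when given, a Bonferroni-adjusted
#'   p-value column is added.
#' @return a [MrdModelFit-class].
#' @export
fitLogMrdModel <- function(data, covariates, lod = 1e-5, level = 0.95,
                           bonferroniN = NULL) {
  if (nrow(data) < 10) stop("need >= 10 records")
  if (!all(covariates %in% names(data)))
    stop("missing covariates: ",
         paste(setdiff(covariates, names(data)), collapse = ", "))
  df <- data[, covariates, drop = FALSE]
  if ("age" %in% covariates) df$age <- df$age / 10
  dup <- duplicated(as.list(df))
  if (any(dup))
    stop("singular design: duplicated covariates ",
         paste(covariates[dup], collapse = ", "))
  df$.y <- log10(censorMrd(data$mrd, lod))
  fit <- lm(as.formula(paste(".y ~", paste(covariates, collapse = " + "))),
            data = df)
  if (any(is.na(coef(fit)))) {
    aliased <- names(coef(fit))[is.na(coef(fit))]
    stop("singular design: aliased terms ", paste(aliased, collapse = ", "))
  }
  mrdModelFit(fit, level = level, bonferroniN = bonferroniN)
}

mrdModelFit <- function(fit, level = 0.95, bonferroniN = NULL) {
  sm <- summary(fit)$coefficients
  ci <- confint(fit, level = level)
  keep <- rownames(sm) != "(Intercept)"
  eff <- data.frame(
    term = rownames(sm)[keep], foldEffect = 10^sm[keep, "Estimate"],
    ciLow = 10^ci[keep, 1], ciHigh = 10^ci[keep, 2],
    p = sm[keep, "Pr(>|t|)"], row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(bonferroniN))
    eff$pBonferroni <- pmin(1, eff$p * bonferroniN)
  new("MrdModelFit", fit = fit, effects = eff, aic = stats::AIC(fit))
}

#' Stepwise AIC covariate selection for the MRD model
#'
#' Runs forward selection (from the intercept-only model toward the full
#' candidate scope) and backward elimination (from the full model), both
#' minimising AIC; the final model contains the union of the covariates
#' either direction selected, filtered to those with p < `pKeep` in the
#' union fit.
#'
#' @param data data.frame with `mrd` and the candidate covariates.
#' @param candidates candidate covariate names.
#' @param pKeep p-value filter for the final model (default 0.05).
#' @param lod limit of detection.
#' @return list: `finalFit` (a [MrdModelFit-class], or NULL when nothing
#'   survives), `selectedForward`, `selectedBackward`, `union`, `final`.
#' @export
selectModelAic <- function(data, candidates, pKeep = 0.05, lod = 1e-5) {
  if (!length(candidates)) stop("no candidate covariates")
  df <- data[, candidates, drop = FALSE]
  if ("age" %in% candidates) df$age <- df$age / 10
  df$.y <- log10(censorMrd(data$mrd, lod))
  full <- as.formula(paste(".y ~", paste(candidates, collapse = " + ")))
  fitNull <- lm(.y ~ 1, data = df)
  fitFull <- lm(full, data = df)
  fwd <- step(fitNull, scope = list(lower = ~1, upper = full),
              direction = "forward", trace = 0)
  bwd <- step(fitFull, direction = "backward", trace = 0)
  termsOf <- function(f) attr(terms(f), "term.labels")
  sel <- union(termsOf(fwd), termsOf(bwd))
  if (!length(sel))
    return(list(finalFit = NULL, selectedForward = termsOf(fwd),
                selectedBackward = termsOf(bwd), union = character(0),
                final = character(0)))
  unionFit <- lm(as.formula(paste(".y ~", paste(sel, collapse = " + "))),
                 data = df)
  termP <- drop1(unionFit, test = "F")
  termP <- setNames(termP[["Pr(>F)"]], rownames(termP))[sel]
  final <- sel[!is.na(termP) & termP < pKeep]
  finalFit <- if (length(final))
    mrdModelFit(lm(as.formula(paste(".y ~", paste(final, collapse = " + "))),
                   data = df)) else NULL
  list(finalFit = finalFit, selectedForward = termsOf(fwd),
       selectedBackward = termsOf(bwd), union = sel, final = final)
}

#' ROC area under the curve with bootstrap confidence interval
#'
#' AUC by pairwise concordance (tied scores count 1/2), computed through the
#' rank (Mann-Whitney) identity; the confidence interval is a stratified
#' bootstrap percentile interval, resampling cases and controls separately.
#'
#' @param scores numeric predictor.
#' @param outcomes logical (or 0/1) outcome, e.g. MRD >= 0.001.
#' @param nBoot bootstrap resamples (default 2000).
#' @param level confidence level.
#' @param seed RNG seed.
#' @return list: `auc`, `ciLow`, `ciHigh`.
#' @export
rocAuc <- function(scores, outcomes, nBoot = 2000, level = 0.95, seed = 1) {
  outcomes <- as.logical(outcomes)
  if (length(scores) != length(outcomes)) stop("length mismatch")
  if (!any(outcomes) || all(outcomes))
    stop("both outcome classes must be present")
  aucOf <- function(s, y) {
    r <- rank(s)
    n1 <- sum(y)
    (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * sum(!y))
  }
  auc <- aucOf(scores, outcomes)
  set.seed(seed)
  pos <- which(outcomes); neg <- which(!outcomes)
  boot <- vapply(seq_len(nBoot), function(i) {
    idx <- c(sample(pos, replace = TRUE), sample(neg, replace = TRUE))
    aucOf(scores[idx], outcomes[idx])
  }, numeric(1))
  qs <- quantile(boot, c((1 - level) / 2, 1 - (1 - level) / 2),
                 names = FALSE)
  list(auc = auc, ciLow = qs[1], ciHigh = qs[2])
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of average ranks; the p-value uses the t
#' approximation \eqn{t = \rho\sqrt{(n-2)/(1-\rho^2)}} on n - 2 degrees of
#' freedom (two-sided).
#'
#' @param x,y numeric vectors (n >= 5).
#' @return list: `rho`, `p`, `n`.
#' @export
spearmanCor <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5) stop("need n >= 5")
  if (sd(x) == 0 || sd(y) == 0) stop("constant vector")
  rho <- cor(rank(x), rank(y))
  p <- if (abs(rho) >= 1) 0 else
    2 * pt(-abs(rho * sqrt((n - 2) / (1 - rho^2))), n - 2)
  list(rho = rho, p = p, n = n)
}
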