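#' @importFrom igraph sample_pa sample_gnp ecount vcount V E set_vertex_attr
#'   edge_attr set_edge_attr as_edgelist simplify delete_edges neighbors
#'   make_graph graph_from_data_frame degree
NULL

BELOW_LOD <- "<LOD"

#' Simulate a weighted protein-protein interactome
#'
#' Generates an undirected simple graph whose edges carry confidence values in
#' \[0, 1\], emulating a scored interactome resource. The default is a
#' preferential-attachment (scale-free) topology, matching the heavy-tailed
#' degree distributions of real interactomes; an Erdos-Renyi model is offered
#' for null studies.
#'
#' @param nProteins number of proteins (>= 2). Node names are gene symbols
#'   shared with the expression simulator.
#' @param model "scale-free" (preferential attachment) or "erdos-renyi".
#' @param edgesPerNode edges attached per new node (scale-free model).
#' @param edgeProb edge probability (Erdos-Renyi model).
#' @param confidence either a single numeric recycled to all edges, or a
#'   function of the edge count returning confidences in \[0, 1\]. Default
#'   Beta(2, 2): confidences centred at 0.5 so that the usual
#'   high-confidence threshold removes a substantial fraction of edges.
#' @param seed RNG seed; identical seeds give identical graphs.
#' @return an `igraph` object with edge attribute `confidence`.
#' @export
simulatePPIGraph <- function(nProteins,
                             model = c("scale-free", "erdos-renyi"),
                             edgesPerNode = 3, edgeProb = 0.05,
                             confidence = function(m) rbeta(m, 2, 2),
                             seed = NULL) {
  if (!is.numeric(nProteins) || length(nProteins) != 1 || nProteins < 2)
    stop("invalid config: nProteins must be a single integer >= 2")
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  g <- switch(model,
    "scale-free" = igraph::simplify(
      sample_pa(nProteins, power = 1, m = edgesPerNode, directed = FALSE)),
    "erdos-renyi" = sample_gnp(nProteins, edgeProb))
  g <- set_vertex_attr(g, "name", value = proteinSymbols(nProteins))
  m <- ecount(g)
  conf <- if (is.function(confidence)) confidence(m) else rep_len(confidence, m)
  if (m > 0 && (any(conf < 0) || any(conf > 1)))
    stop("invalid config: edge confidences must lie in [0, 1]")
  set_edge_attr(g, "confidence", value = conf)
}

proteinSymbols <- function(n) sprintf("G%05d", seq_len(n))

#' First-order neighborhood of a seed protein
#'
#' @param graph an igraph interactome.
#' @param seedProtein node name.
#' @return character vector: the seed and its direct neighbors.
#' @export
firstOrderNeighborhood <- function(graph, seedProtein) {
  if (!seedProtein %in% V(graph)$name)
    stop("seed protein not in graph: ", seedProtein)
  union(seedProtein, names(neighbors(graph, seedProtein)))
}

#' Simulate a two-group expression cohort with planted subnetworks
#'
#' Baseline per-gene means plus i.i.d. Gaussian noise on the log2 scale; the
#' members of each planted first-order neighborhood are shifted by the stated
#' log2 effect in group A. The first `vcount(graph)` genes share the graph's
#' protein symbols, so differential expression maps directly onto the
#' interactome.
#'
#' @param graph igraph interactome whose node names seed the gene namespace.
#' @param nGenes total genes (>= number of graph nodes).
#' @param nA,nB samples per group.
#' @param planted data.frame with columns `seed` (protein symbol), `log2fc`
#'   and `fraction` (of neighborhood members affected, in (0, 1\]); NULL for a
#'   null cohort.
#' @param noiseSd per-gene residual SD in log2 units.
#' @param baselineMean,baselineSd distribution of per-gene baseline means.
#' @param seed RNG seed.
#' @return list with elements `se` (a [SummarizedExperiment] with assay
#'   `log2expr` and `colData(se)$group` in \{"A","B"\}) and `truth`
#'   (`deFlags`, named logical; `planted`, per-network member/affected lists).
#' @export
simulateExpression <- function(graph, nGenes = vcount(graph), nA = 20,
                               nB = 20, planted = NULL, noiseSd = 0.5,
                               baselineMean = 7, baselineSd = 1.5,
                               seed = NULL) {
  if (nGenes < vcount(graph))
    stop("invalid config: nGenes must cover all graph nodes")
  if (nA < 2 || nB < 2) stop("invalid config: need >= 2 samples per group")
  if (!is.null(seed)) set.seed(seed)
  genes <- c(V(graph)$name,
             if (nGenes > vcount(graph))
               sprintf("X%05d", seq_len(nGenes - vcount(graph))))
  samples <- sprintf("S%03d", seq_len(nA + nB))
  group <- factor(rep(c("A", "B"), c(nA, nB)), levels = c("A", "B"))
  base <- rnorm(nGenes, baselineMean, baselineSd)
  mat <- matrix(rnorm(nGenes * (nA + nB), sd = noiseSd), nGenes,
                dimnames = list(genes, samples)) + base
  deFlags <- setNames(logical(nGenes), genes)
  plantedTruth <- list()
  if (!is.null(planted) && nrow(planted) > 0) {
    for (i in seq_len(nrow(planted))) {
      sd. <- as.character(planted$seed[i])
      if (!sd. %in% V(graph)$name)
        stop("planted seed absent from graph: ", sd.)
      members <- firstOrderNeighborhood(graph, sd.)
      frac <- planted$fraction[i]
      if (frac <= 0 || frac > 1)
        stop("invalid config: planted fraction must lie in (0, 1]")
      nAff <- ceiling(frac * length(members))
      affected <- if (nAff >= length(members)) members else
        sample(members, nAff)
      mat[affected, group == "A"] <-
        mat[affected, group == "A"] + planted$log2fc[i]
      deFlags[affected] <- TRUE
      plantedTruth[[sd.]] <- list(seed = sd., members = members,
                                  affected = affected,
                                  log2fc = planted$log2fc[i])
    }
  }
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = mat),
    colData = S4Vectors::DataFrame(group = group, row.names = samples))
  list(se = se, truth = list(deFlags = deFlags, planted = plantedTruth))
}

#' Probe-to-gene map with duplicated probes
#'
#' Emits a two-column probe/gene table in which `nDuplicated` genes are
#' detected by two probes, exercising the mean-factor resolution rule of the
#' Ph-like classifier.
#'
#' @param genes gene symbols.
#' @param nDuplicated number of genes carrying two probes.
#' @return data.frame with columns `probe`, `gene`.
#' @export
makeProbeMap <- function(genes, nDuplicated = 1) {
  nDuplicated <- min(nDuplicated, length(genes))
  gene <- c(genes, genes[seq_len(nDuplicated)])
  data.frame(probe = sprintf("P%05d", seq_along(gene)), gene = gene,
             stringsAsFactors = FALSE)
}

## ---- flow cytometry -------------------------------------------------------

#' Canonical reference intervals of the synthetic world
#'
#' All markers share the log10-fluorescence cutpoints (1, 2, 3) partitioning
#' neg | PD | PN | PB, so one score unit is (3 - 1)/3 log10 decades.
#'
#' @param markers marker names; defaults to the 16-marker BCP-ALL panel.
#' @return a [ReferenceIntervalSet-class].
#' @export
canonicalReferenceIntervals <- function(markers = MARKER_PANEL) {
  cls <- MARKER_CLASSES[markers]
  cls[is.na(cls)] <- "nonlineage"
  new("ReferenceIntervalSet", intervals = data.frame(
    marker = markers, markerClass = unname(cls),
    negPD = 1, pdPN = 2, pnPB = 3, scoreUnit = (3 - 1) / 3,
    stringsAsFactors = FALSE))
}

#' Gaussian mixture description of one marker's log10 fluorescence
#'
#' @param means,sds,weights component parameters; weights must sum to 1.
#' @return a `flowMixture` list.
#' @export
flowMixture <- function(means, sds, weights) {
  stopifnot(length(means) == length(sds), length(means) == length(weights))
  if (abs(sum(weights) - 1) > 1e-9)
    stop("invalid config: mixture weights must sum to 1")
  if (any(weights < 0)) stop("invalid config: negative mixture weight")
  structure(list(means = means, sds = sds, weights = weights),
            class = "flowMixture")
}

mixtureDensity <- function(mix, x) {
  rowSums(mapply(function(m, s, w) w * dnorm(x, m, s),
                 mix$means, mix$sds, mix$weights))
}

#' True modality of a mixture under the scoring rules
#'
#' Applies the >1\% subpopulation rule and the broad-expression rule (10\%-of-
#' peak width >= 1.5 score units for B-/nonlineage markers, >= 1.5 decades for
#' cross-lineage markers) to the analytic mixture density, yielding the
#' modality the scorer is expected to recover.
#'
#' @param mix a [flowMixture].
#' @param markerClass marker class string.
#' @param scoreUnit width of one score in log10 units.
#' @return "unimodal", "bimodal" or "broad".
#' @export
trueModality <- function(mix, markerClass, scoreUnit) {
  keep <- mix$weights > 0.01
  if (sum(keep) >= 2) return("bimodal")
  x <- seq(min(mix$means) - 4 * max(mix$sds),
           max(mix$means) + 4 * max(mix$sds), length.out = 2048)
  d <- mixtureDensity(flowMixture(mix$means[keep], mix$sds[keep],
                                  mix$weights[keep] / sum(mix$weights[keep])),
                      x)
  above <- x[d >= 0.10 * max(d)]
  width <- max(above) - min(above)
  lim <- if (identical(markerClass, "cross-lineage")) 1.5 else 1.5 * scoreUnit
  if (width >= lim) "broad" else "unimodal"
}

scoreOfValue <- function(x, negPD, pdPN, pnPB) {
  SCORE_LEVELS[findInterval(x, c(negPD, pdPN, pnPB)) + 1L]
}

#' Scenario catalogue for one marker
#'
#' Builds the stock of expression patterns the flow simulator draws from:
#' narrow unimodal peaks at each of the four score levels, well-separated
#' bimodal pairs, and a single broad peak wide enough to satisfy the class-
#' specific broad rule.
#'
#' @param markerClass marker class.
#' @param ref a [ReferenceIntervalSet-class] row as a list (negPD, pdPN,
#'   pnPB, scoreUnit).
#' @return named list of `flowMixture` objects.
#' @export
flowScenarios <- function(markerClass, ref) {
  centers <- c(neg = ref$negPD - 0.5, PD = (ref$negPD + ref$pdPN) / 2,
               PN = (ref$pdPN + ref$pnPB) / 2, PB = ref$pnPB + 0.4)
  narrow <- 0.12
  broadSd <- if (identical(markerClass, "cross-lineage")) 0.45 else
    0.35 * ref$scoreUnit / (2 / 3) # 0.35 at the canonical unit of 2/3
  list(
    uni_neg = flowMixture(centers["neg"], narrow, 1),
    uni_PD = flowMixture(centers["PD"], narrow, 1),
    uni_PN = flowMixture(centers["PN"], narrow, 1),
    uni_PB = flowMixture(centers["PB"], narrow, 1),
    bi_neg_PN = flowMixture(centers[c("neg", "PN")], c(narrow, narrow),
                            c(0.6, 0.4)),
    bi_neg_PN_minor = flowMixture(centers[c("neg", "PN")], c(narrow, narrow),
                                  c(0.85, 0.15)),
    bi_PD_PB = flowMixture(centers[c("PD", "PB")], c(narrow, narrow),
                           c(0.45, 0.55)),
    broad_PN = flowMixture(centers["PN"], broadSd, 1))
}

#' Simulate a per-patient flow-cytometry cohort with known truth
#'
#' For every patient and marker a scenario is drawn from the catalogue and
#' `nEvents` log10-fluorescence values are sampled from its mixture. The
#' ground truth records, per instance, the analytic modality, the component
#' fractions surviving the >1\% rule, the per-subpopulation scores and the
#' dominant-subpopulation overall score.
#'
#' @param nPatients number of patients.
#' @param ref a [ReferenceIntervalSet-class].
#' @param nEvents events per marker (default 100000).
#' @param markers subset of the panel to simulate.
#' @param seed RNG seed.
#' @return list: `events` (named list of per-patient data.frames, one column
#'   per marker) and `truth` (data.frame patient/marker/scenario/modality/
#'   overallScore plus list-columns `fractions` and `scores`).
#' @export
simulateFlowCohort <- function(nPatients, ref = canonicalReferenceIntervals(),
                               nEvents = 1e5,
                               markers = referenceIntervals(ref)$marker,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  iv <- referenceIntervals(ref)
  iv <- iv[match(markers, iv$marker), , drop = FALSE]
  patients <- sprintf("P%03d", seq_len(nPatients))
  events <- vector("list", nPatients)
  names(events) <- patients
  truth <- list()
  for (p in patients) {
    cols <- vector("list", length(markers))
    names(cols) <- markers
    for (j in seq_along(markers)) {
      r <- as.list(iv[j, ])
      scen <- flowScenarios(r$markerClass, r)
      pick <- sample(names(scen), 1)
      mix <- scen[[pick]]
      comp <- sample.int(length(mix$weights), nEvents, replace = TRUE,
                         prob = mix$weights)
      cols[[j]] <- rnorm(nEvents, mix$means[comp], mix$sds[comp])
      keep <- mix$weights > 0.01
      fr <- mix$weights[keep] / sum(mix$weights[keep])
      sc <- scoreOfValue(mix$means[keep], r$negPD, r$pdPN, r$pnPB)
      truth[[length(truth) + 1L]] <- data.frame(
        patient = p, marker = markers[j], scenario = pick,
        modality = trueModality(mix, r$markerClass, r$scoreUnit),
        overallScore = sc[which.max(fr)], stringsAsFactors = FALSE)
      truth[[length(truth)]]$fractions <- list(fr)
      truth[[length(truth)]]$scores <- list(sc)
    }
    events[[p]] <- as.data.frame(cols)
  }
  list(events = events, truth = do.call(rbind, truth))
}

#' Simulate non-ALL control bone-marrow samples for reference derivation
#'
#' Emits, per control sample and marker, lymphocyte events from a negative and
#' a positive population whose quantiles encode the canonical boundaries: the
#' 99.5th percentile of the negative population sits at the neg/PD cutpoint
#' and the quartiles of the positive population at the PD/PN and PN/PB
#' cutpoints.
#'
#' @param ref a [ReferenceIntervalSet-class] giving the target boundaries.
#' @param nSamples number of control samples (the study used five).
#' @param nEvents events per population per sample.
#' @param seed RNG seed.
#' @return list of data.frames with columns `marker`, `population`, `value`.
#' @export
simulateControlSamples <- function(ref, nSamples = 5, nEvents = 20000,
                                   seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  iv <- referenceIntervals(ref)
  sdNeg <- 0.15
  lapply(seq_len(nSamples), function(s) {
    do.call(rbind, lapply(seq_len(nrow(iv)), function(j) {
      r <- iv[j, ]
      negMean <- r$negPD - qnorm(0.995) * sdNeg
      posMean <- (r$pdPN + r$pnPB) / 2
      posSd <- (r$pnPB - r$pdPN) / (2 * qnorm(0.75))
      data.frame(
        marker = r$marker,
        population = rep(c("negative", "positive"), each = nEvents),
        value = c(rnorm(nEvents, negMean, sdNeg),
                  rnorm(nEvents, posMean, posSd)),
        stringsAsFactors = FALSE)
    }))
  })
}

## ---- Ph-like --------------------------------------------------------------

#' Random signed Ph-like signature
#'
#' @param nGenes signature size.
#' @param seed RNG seed.
#' @return data.frame with columns `probe`, `gene`, `factor` (signed weight).
#' @export
simulatePhlikeSignature <- function(nGenes = 60, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- sprintf("PH%04d", seq_len(nGenes))
  data.frame(probe = sprintf("PP%04d", seq_len(nGenes)), gene = genes,
             factor = sample(c(-1, 1), nGenes, replace = TRUE) *
                 runif(nGenes, 0.5, 1.5),
             stringsAsFactors = FALSE)
}

#' Simulate an expression cohort with planted Ph-like samples
#'
#' Positive samples are shifted on each signature gene by
#' `effect * sign(factor)` log2 units, so their mock-PAM scores exceed the
#' background. Used both for the main cohort and for the independent
#' reference dataset from which the 25-gene filter is derived.
#'
#' @param signature data.frame `gene`/`factor` (probe column optional).
#' @param nSamples cohort size.
#' @param nPhlike number of planted positives (must not exceed `nSamples`).
#' @param effect log2 shift applied along the signature.
#' @param nBackground additional unrelated genes.
#' @param noiseSd residual SD, log2 units.
#' @param seed RNG seed.
#' @return list: `se` (SummarizedExperiment, `colData(se)$phlike` logical)
#'   and `labels` (named logical).
#' @export
simulatePhlikeCohort <- function(signature, nSamples = 160, nPhlike = 10,
                                 effect = 1.5, nBackground = 400,
                                 noiseSd = 0.5, seed = NULL) {
  if (nPhlike > nSamples) stop("invalid config: nPhlike > nSamples")
  if (!is.null(seed)) set.seed(seed)
  sig <- resolveSignature(signature)
  genes <- c(sig$gene, sprintf("B%05d", seq_len(nBackground)))
  samples <- sprintf("S%03d", seq_len(nSamples))
  labels <- setNames(seq_len(nSamples) <= nPhlike, samples)
  base <- rnorm(length(genes), 7, 1.5)
  mat <- matrix(rnorm(length(genes) * nSamples, sd = noiseSd), length(genes),
                dimnames = list(genes, samples)) + base
  shift <- effect * sign(sig$factor)
  mat[sig$gene, labels] <- mat[sig$gene, labels] + shift
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(log2expr = mat),
    colData = S4Vectors::DataFrame(phlike = unname(labels),
                                   row.names = samples))
  list(se = se, labels = labels)
}

## ---- outcome --------------------------------------------------------------

#' Simulate an end-of-induction MRD cohort
#'
#' Log10 MRD is drawn as `intercept + log10(foldEffects[score]) + noise`,
#' so the configured fold effects are the true MRD ratios between each CD34
#' score level and the negative reference. Values below the limit of
#' detection are emitted as an explicit `"<LOD"` sentinel, never a number, so
#' censoring stays a deliberate pipeline step.
#'
#' @param nPatients cohort size.
#' @param foldEffects named numeric: true MRD fold vs the `neg` reference for
#'   `PD`, `PN`, `PB`. Default plants the study-scale 6.47-fold PN effect.
#' @param scoreProbs sampling distribution of the four CD34 levels.
#' @param intercept mean log10 MRD of the reference group.
#' @param noiseSd residual SD on log10 MRD.
#' @param ageFoldPer10y multiplicative MRD effect of 10 years of age.
#' @param lod limit of detection (proportion).
#' @param seed RNG seed.
#' @return list: `patients` (data.frame id, cd34Score, age, wbc, mrd as
#'   character with sentinel) and `truth` (the generating parameters).
#' @export
simulateOutcomeCohort <- function(nPatients = 200,
                                  foldEffects = c(PD = 2.0, PN = 6.47,
                                                  PB = 8.0),
                                  scoreProbs = c(neg = 0.2, PD = 0.15,
                                                 PN = 0.5, PB = 0.15),
                                  intercept = -3.5, noiseSd = 1.0,
                                  ageFoldPer10y = 1.0, lod = 1e-5,
                                  seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(all(names(foldEffects) %in% SCORE_LEVELS))
  score <- factor(sample(names(scoreProbs), nPatients, replace = TRUE,
                         prob = scoreProbs), levels = SCORE_LEVELS)
  age <- runif(nPatients, 1, 17)
  wbc <- rlnorm(nPatients, log(10), 1)
  fold <- c(neg = 1, foldEffects)[as.character(score)]
  logMrd <- intercept + log10(fold) + (age / 10) * log10(ageFoldPer10y) +
    rnorm(nPatients, sd = noiseSd)
  mrd <- pmin(10^logMrd, 1)
  mrdOut <- ifelse(mrd < lod, BELOW_LOD, format(mrd, digits = 8))
  list(
    patients = data.frame(id = sprintf("P%03d", seq_len(nPatients)),
                          cd34Score = score, age = age, wbc = wbc,
                          mrd = mrdOut, stringsAsFactors = FALSE),
    truth = list(foldEffects = foldEffects, intercept = intercept,
                 noiseSd = noiseSd, lod = lod))
}
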