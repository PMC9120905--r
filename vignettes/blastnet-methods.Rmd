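---
title: "blastnet: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{blastnet: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blastnet)
```

# The problem

In B-cell precursor acute lymphoblastic leukemia (BCP-ALL) the surface
immunophenotype of the blasts at diagnosis — in particular CD34 — carries
information about how well a patient will respond to induction chemotherapy,
measured as the minimal residual disease (MRD) fraction at end of induction
(EOI, day 29). blastnet implements the computational chain that links these
layers:

1. **Flow-cytometry scoring** of each marker of a 16-marker panel into a
   four-level score (negative, dim, normal, bright), with explicit handling
   of bimodal and broad expression — the leukemia-associated
   immunophenotype (LAIP).
2. **Differential expression** between immunophenotype groups with a
   moderated t-statistic and Benjamini–Hochberg FDR.
3. **Network significance**: scoring every protein's first-order
   protein–protein-interaction (PPI) neighborhood by Edgington integration
   of its members' p-values with permutation calibration.
4. **Ph-like classification** by a three-strategy consensus over a signed
   gene signature.
5. **Enrichment statistics**: preranked GSEA, hypergeometric
   overrepresentation, exact 2×2 tests.
6. **Outcome modelling**: log-linear regression of EOI MRD on marker scores
   with AIC model selection, ROC/AUC and rank correlation.

Patient-level data of the motivating study are not publicly available, so
the package ships a first-class synthetic-data module that emulates every
input with known ground truth; all tests run against that stated world.

# Flow-cytometry scoring

Each marker's log10 fluorescence axis is partitioned by three ascending
cutpoints into neg | PD | PN | PB. A *score unit* is a third of the
neg-to-PB span. Reference intervals come from non-ALL control bone-marrow
samples: the neg/PD boundary at the 99.5th percentile of the negative
lymphocyte population, the PD/PN and PN/PB boundaries at the quartiles of
the positive population. These quantile rules are configurable because the
original reference table is not published; the defaults are the package's
own choice.

Subpopulation detection operationalises contour-plot reading as a 1-D
kernel-density estimate (Silverman bandwidth, 1024 grid points):

* candidate peaks are local maxima at or above 5 % of the global density
  maximum (`prominence`);
* two maxima only count as *distinct* peaks when the density minimum
  between them drops below 75 % of the smaller flanking peak (`dipRatio`).
  Without this rule, plateau wiggles of the KDE on 10^4–10^5 events
  occasionally split a single population in two;
* events are assigned to peak basins split at inter-peak density minima;
* populations comprising ≤ 1 % of events are merged into their nearest
  larger neighbor (the >1 % reporting rule);
* a marker is **bimodal** with ≥ 2 surviving populations; with a single
  peak it is **broad** when the density's extent at 10 % of the peak
  maximum spans ≥ 1.5 score units (B-lineage and nonlineage markers) or
  ≥ 1.5 log10 decades (cross-lineage markers); otherwise unimodal.

The distinction between "1.5 score" and "1.5 decades" is deliberately kept
per marker class; under the canonical boundaries (1, 2, 3) one score unit is
2/3 of a decade, so the cross-lineage rule is the stricter one. Subpopulation
MFIs exactly on a cutpoint go to the higher category (half-open intervals).
The overall score is the dominant (largest-fraction) subpopulation's score —
invariant to the order in which subpopulations are listed. The binary
collapse is neg/PD vs PN/PB for all markers except CD15 and CD133, which are
neg vs PD/PN/PB.

```{r flow-example}
ref <- canonicalReferenceIntervals()
set.seed(1)
x <- c(rnorm(30000, 0.5, 0.12), rnorm(20000, 2.5, 0.12))
scoreMarker(x, "CD34", ref)
```

# Moderated differential expression

For gene $g$ with pooled two-group variance $s_g^2$ on $d$ residual degrees
of freedom, the shrunken variance is

$$\tilde s_g^2 = \frac{d_0 s_0^2 + d\, s_g^2}{d_0 + d},$$

with prior variance $s_0^2$ (default: the mean of the per-gene variances)
and prior degrees of freedom $d_0$ (default 4). The moderated t uses
$\tilde s_g$ with $d + d_0$ degrees of freedom, two-sided p-values
throughout. With $d_0 = 0$ this is the ordinary pooled t-test — the tests
verify both that limit and agreement with an independent linear-model fit.
A fixed prior (rather than estimating $d_0, s_0^2$ from the data) keeps the
implementation self-contained; under the generator's equal-variance world
the statistic is exactly calibrated, which the null-calibration tests check.
Direction labels use a 0.1 log2FC neutrality band.

# Network significance

The algorithm scores the first-order neighborhood (seed plus direct
neighbors) of every protein in the interactome after discarding edges with
confidence below 0.119:

* **Integration.** With member p-values $p_1,\dots,p_n$, the Edgington sum
  is $S = \sum p_i$ and the integrated p-value is the Irwin–Hall CDF
  $\Pr(\sum_n U_i \le S)$. The exact alternating sum
  $\frac{1}{n!}\sum_{k\le\lfloor S\rfloor}(-1)^k\binom{n}{k}(S-k)^n$
  is used for $n \le 50$; empirically its cancellation stays within ~6
  orders of magnitude of the result over the whole support, so double
  precision retains ~9 digits. For $n > 50$ a Gaussian with mean $n/2$ and
  variance $n/12$ takes over, validated against a Monte-Carlo oracle at the
  crossover.
* **Permutation calibration.** The gene→p-value assignment is shuffled
  uniformly over all measured genes; each network's sum is recomputed per
  shuffle. Because the Irwin–Hall CDF is monotone in $S$ at fixed $n$,
  counting permutations with $S_{perm} \le S_{obs}$ equals counting
  permutations with an equal-or-better integrated p-value. One shared
  shuffle per permutation index serves all networks, so their null draws
  are comparable. The original description ("shuffling and resampling the
  data values") is ambiguous between permuting p-values, expression values
  or sample labels; p-value permutation preserves the network topology and
  the p-value pool, matching the question "how likely is this score in a
  network of this size by coincidence". Sample-label permutation is
  reserved for the FDR estimate, mirroring "permutation of the input data".
* **Selection.** A network is selected when its raw permutation count is
  strictly below `selectionRate × nPerm` (the "< 1000 of 10^7" rule; 10 of
  10^5 at desk scale). The reported empirical p-value uses the add-one
  estimator $(c+1)/(N+1)$ to avoid zeros, but selection deliberately uses
  the raw count to stay faithful to the original rule.
* Members without a measured p-value are excluded from $S$ and $n$ (not
  imputed at 0.5); the exclusion count is reported. Network size bounds
  default to 3–500 members. The FDR of the selection is estimated by
  permuting group labels, rerunning the whole chain, and dividing the mean
  permuted selection count by the observed one.

Permutations run in blocks through a sparse incidence-matrix product
(networks × genes), which keeps 10^5 permutations over a few hundred
networks in the tens of seconds on one CPU. Study-scale runs (10^7) are the
same code with a larger `nPerm`.

# Ph-like consensus classification

The classifier takes any signed signature table (probe, gene, factor);
genes measured by several probes get the mean factor. Three strategies:

1. **Mock-PAM score**: $\text{score}_s=\sum_g x_{gs} f_g$ over measured
   signature genes; the top $\lceil 0.05\, n\rceil$ samples are flagged
   (ceiling, so 160 samples flag 8; boundary ties are all included).
2. **Clustering on the full signature**: agglomerative clustering, average
   linkage on correlation distance ($1-r$), cut at $k=2$; the cluster with
   the highest mean mock-PAM score is flagged. Metric, linkage and $k$ are
   configurable — the original publication names none of them, and these
   defaults are the common expression-clustering idiom.
3. **Clustering on 25 reference-filtered genes**: the 25 smallest
   moderated-t p-values comparing Ph-like vs other cases in an independent
   reference cohort (ties by |log2FC|, then symbol); clustering as in 2.
   Without a reference cohort the package falls back to the 25 largest
   |factor| genes and records that in the call parameters.

A sample is Ph-like when at least two strategies agree. "Most compatible
cluster" is operationalised as highest mean mock-PAM score.

# Enrichment statistics

Preranked GSEA uses the classic weighted Kolmogorov–Smirnov running sum
(hit increment $|t|^w$ normalised over the set, miss decrement
$1/(N-n_{set})$, default $w=1$), gene-label permutation p-values and the
signed-mean NES normalisation. The Fisher exact test is two-sided by the
point-probability convention — summing all tables with fixed margins whose
probability does not exceed the observed one — which reproduces the
published worked example (p = 0.0225). The Yates chi-square is
$\sum(\max(|O-E|-0.5,\,0))^2/E$ on one degree of freedom.

# MRD outcome modelling

EOI MRD values below the limit of detection arrive as an explicit `"<LOD"`
sentinel (never a numeric zero) and are set to $10^{-5}$ by `censorMrd()`.
The regression is ordinary least squares on $\log_{10}$ MRD; effects are
reported as decade-fold ratios $10^\beta$ with Wald intervals. Marker
scores enter as categorical covariates against their reference level
(negative for CD34), and age is rescaled so its coefficient is the effect
of a 10-year increase. Base 10 matches the decade-fold reporting
convention; any base is equivalent up to scaling. Stepwise selection runs
forward and backward AIC searches and keeps the union of selected terms
filtered to p < 0.05 (the LASSO third selector of the motivating study is
out of scope). AUC is computed by the rank (Mann–Whitney) identity with
ties at 1/2 and a stratified bootstrap percentile CI — the original CI
method is not stated. A Bonferroni-adjusted column is available with a
configurable family size, since the original correction's family is not
specified.

# The synthetic world

The generator's defaults are fixed once and are not tuned to test outcomes:

* **Interactome**: preferential attachment (heavy-tailed degrees, like real
  interactomes), 3 edges per new node; Erdős–Rényi available for null
  studies. Edge confidences Beta(2, 2) — a unimodal spread over (0, 1) so
  the 0.119 threshold removes a realistic minority of edges.
* **Expression**: per-gene baselines N(7, 1.5²) log2 units, i.i.d. Gaussian
  noise with SD 0.5 — typical residual spread for expression arrays; no
  array-specific or batch noise (preprocessing is out of scope). Planted
  networks shift a configurable fraction of a seed's first-order
  neighborhood by a stated log2 effect in group A.
* **Flow events**: per patient and marker, 10^5 events (matching routine
  acquisition counts) from a scenario catalogue — narrow unimodal peaks at
  each score level (σ = 0.12), well-separated bimodal pairs, a sub-1 %
  minor-component variant, and a broad peak wide enough for the
  class-specific broad rule. Ground-truth modality is computed analytically
  from the mixture, so scorer recovery is a genuine estimation check.
* **Outcome**: reference-group log10 MRD intercept −3.5 with residual SD
  1.0 (MRD spans several decades in practice), CD34 score distribution
  (0.20, 0.15, 0.50, 0.15), true fold effects PD 2.0, PN 6.47, PB 8.0 — the
  PN value mirrors the published study-scale effect; PD/PB interpolate a
  monotone dose–response. LOD 10^-5.

What a green test establishes: the estimators recover the truth of this
world at the stated scales. What it does not: robustness to array batch
effects, compensation/spillover artefacts, non-Gaussian flow populations,
or informative censoring — none of which the generator emulates.

# Numerical choices and degenerate inputs

* Irwin–Hall: exact for $n\le50$, Gaussian beyond; both branches are tested
  against Monte-Carlo oracles.
* Zero-variance genes with zero prior variance get p = 1 with a warning,
  never NaN.
* `nPerm < 1000` and GSEA `nPerm < 100` are refused outright.
* Degenerate (single-valued) control samples raise a degenerate-interval
  error; all-identical expression submatrices make the cluster strategy
  flag nothing, with a warning.
* The planted-network acceptance check scores the planted seed's
  neighborhood at 10^5 permutations; selection is a per-network marginal
  rule, so this is equivalent to running all networks and asking about the
  planted one, at a fraction of the cost.

# Limitations

FCS binary parsing, compensation and gating; microarray preprocessing (RMA,
ComBat); survival endpoints (EFS, CIR, Cox); LASSO selection; and the real
interactome, signature and reference tables are all out of scope — the
package consumes their plain-text stand-ins and synthetic equivalents.
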