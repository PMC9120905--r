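# blastnet

Immunophenotype scoring and PPI subnetwork significance for BCP-ALL
induction response.

In B-cell precursor acute lymphoblastic leukemia (BCP-ALL), the surface
immunophenotype of the leukemic blasts — CD34 in particular — is associated
with the minimal residual disease (MRD) level at end of induction therapy.
blastnet is an R package for analysts working at the interface of flow
cytometry, transcriptomics and outcome data in this setting. It implements:

- **LAIP scoring** (`scoreMarker`, `scorePatient`, `binarizeScore`):
  density-based scoring of per-marker flow-cytometry intensities into the
  four-level negative / dim (PD) / normal (PN) / bright (PB) scale, with
  detection of bimodal (≥ 2 distinct populations, each > 1 % of blasts) and
  broad (single peak spanning ≥ 1.5 score units, or ≥ 1.5 decades for
  cross-lineage markers, at the 10 %-of-peak boundary) expression, and the
  dominant-subpopulation overall score.
- **Moderated differential expression** (`moderatedTTest`, `bhAdjust`):
  two-group comparison with the variance-shrunken t-statistic
  t_g = (x̄_A − x̄_B) / √(s̃²_g (1/n_A + 1/n_B)), where
  s̃²_g = (d₀s₀² + d s²_g)/(d₀ + d), and Benjamini–Hochberg q-values.
- **Network significance** (`runNetworkSignificance`): every protein's
  first-order PPI neighborhood (edges filtered at confidence ≥ 0.119) is
  scored by Edgington integration of its members' p-values — S = Σpᵢ with
  integrated p the Irwin–Hall CDF Pr(Σₙ Uᵢ ≤ S) — and calibrated by
  shuffling the gene→p assignment; a network is selected when fewer than
  `selectionRate × nPerm` permutations score as well (the "< 1000 of 10⁷"
  rule). A label-permutation FDR estimate is provided
  (`estimateNetsigFdr`).
- **Ph-like consensus classification** (`callPhLike`): mock-PAM scoring
  (top 5 %), hierarchical clustering on the full signature, and clustering
  on 25 reference-filtered genes; samples selected by ≥ 2 of 3 strategies.
- **Enrichment statistics** (`prerankedGsea`, `fisherExact2x2`,
  `yatesChi2`, `hypergeomOverrepresentation`).
- **MRD outcome modelling** (`censorMrd`, `fitLogMrdModel`,
  `selectModelAic`, `rocAuc`, `spearmanCor`): sub-LOD values set to 10⁻⁵,
  OLS on log₁₀ MRD with effects as decade-fold ratios 10^β, forward/backward
  AIC selection, and ROC analysis against the MRD ≥ 0.001 cutoff.
- **A synthetic-data module** (`simulatePPIGraph`, `simulateExpression`,
  `simulateFlowCohort`, `simulatePhlikeCohort`, `simulateOutcomeCohort`,
  …) generating every input with known ground truth, since the motivating
  study's patient data are not shared.

## Worked example

Plant a differentially expressed first-order neighborhood in a synthetic
two-group cohort and recover it:

```r
library(blastnet)

g <- simulatePPIGraph(300, confidence = function(m) runif(m, 0.2, 1),
                      seed = 7)
hub <- names(sort(igraph::degree(g), decreasing = TRUE))[3]
sim <- simulateExpression(g, nGenes = 2000, nA = 20, nB = 20,
                          planted = data.frame(seed = hub, log2fc = 2,
                                               fraction = 1),
                          noiseSd = 0.5, seed = 8)
de <- moderatedTTest(sim$se)
length(selectSeedGenes(de))   # 34 genes at q < 0.05
runNetworkSignificance(de, g, nPerm = 1e4, seed = 9)
#> NetworkScoreSet: 300 neighborhoods, 10000 permutations (seed 9)
#> selection rule: permCount < 1 (rate 0.0001); 3 selected
#>    seed  n nExcluded            S         pInt permCount       pEmp selected
#>  G00009 32         0 2.282080e-12 0.000000e+00         0 0.00009999     TRUE
#>  G00236  4         0 4.841744e-02 2.289793e-07         0 0.00009999     TRUE
#>  G00040 11         0 1.988447e+00 4.789675e-05         0 0.00009999     TRUE
#>  ...
```

The planted hub (`G00009`, a 32-member neighborhood shifted by 2 log2
units) tops the list: no permutation of the p-value pool reaches its
Edgington sum, so its empirical p is 1/(nPerm + 1). The two smaller
selected networks overlap the planted members.

The Irwin–Hall integration and the exact 2×2 test at the heart of the
enrichment layer:

```r
edgingtonIntegrate(c(0.1, 0.1, 0.1))
#> $S: 0.3   $n: 3   $pInt: 0.0045        # = 0.3^3 / 3!
fisherExact2x2(matrix(c(18, 8, 8, 16), 2, byrow = TRUE))
#> $oddsRatio: 4.5   $p: 0.02248368
```

MRD outcome modelling on a synthetic cohort whose true CD34-PN effect is a
6.47-fold MRD increase over CD34-negative patients:

```r
oc <- simulateOutcomeCohort(200, seed = 10)
fitLogMrdModel(oc$patients, c("cd34Score", "age"))
#> Log-linear MRD model (outcome log10 MRD), AIC 601.29
#>         term foldEffect     ciLow    ciHigh          p
#>  cd34ScorePD  1.1097235 0.3002739  4.101210 0.87534583
#>  cd34ScorePN  2.6707894 1.0669152  6.685738 0.03601022
#>  cd34ScorePB  4.3371686 1.3380950 14.058069 0.01473850
#>          age  0.5322061 0.2551058  1.110297 0.09232081
```

Fold effects are decade-fold MRD ratios against the CD34-negative
reference. With a residual spread of one decade on log₁₀ MRD, single-cohort
point estimates are noisy — this draw estimates the PN effect at 2.67 —
but the 95 % interval (1.07–6.69) covers the true 6.47, and the test suite
verifies ~95 % CI coverage across 50 replicates.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the pipeline end to end from freshly generated synthetic data:
interactome and two-group expression simulation, differential expression,
network significance with permutation calibration, preranked GSEA on a
planted set, the Fisher worked example, reference-interval derivation and
LAIP scoring of a flow cohort, three-strategy Ph-like consensus calls, and
the log-MRD regression with ROC analysis, logging each stage's result
before writing the JSON report to `--out`. All randomness derives from
`--seed`.
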