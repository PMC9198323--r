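---
title: "Models and methods behind fibrosig"
author: "fibrosig authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fibrosig}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fibrosig)
```

# Scope

`fibrosig` analyses fibrotic remodeling across three data modalities: a
targeted fibrosis gene panel measured in a heart-failure (HF) cohort, a
spliced/unspliced single-cell dataset of cultured cardiac fibroblasts, and
a bulk expression time course after myocardial infarction (MI). Matched
primary datasets of all three kinds are rarely public, so the package
ships synthetic generators that emulate their statistical structure with known
ground truth; the generators are first-class, tested code, and every
pipeline claim in the test suite is checked against generator truth. This
vignette explains the models, the tunable parameters and their defaults,
the numerical choices, and what the synthetic data do and do not show
about real data.

# Panel analysis

## Reference-gene normalization

Nanostring-style panels are normalized against invariant reference genes
(GAPDH, GUSB, PGK1, POLR2A, RPLP0). Per sample the scale is the geometric
mean of the five reference counts; counts are multiplied by
(cohort median scale / sample scale) and transformed by `log2(x + 1)`.
Anchoring at the cohort median keeps values on the count scale instead of
an arbitrary unit. The pseudocount of 1 is needed because panel counts
contain zeros; it breaks exact scale equivariance only for counts near
zero (the property holds exactly in the large-count limit, and the test
suite checks it above 100 counts). We interpret correction for "grouping
caused by reference genes" as this anchoring; no further correction is
applied.

## Age correction

Expression of many fibrosis genes drifts with age, and donor/patient age
distributions differ, so per gene we fit ordinary least squares of the
normalized value on age and return residual + fitted value at the cohort
mean age. This removes the linear age trend exactly (the post-correction
per-gene slope is zero to numerical tolerance) while keeping values on the
original scale. At least 3 samples with distinct ages are required.

## Patient subclustering

Two HF subclusters can be separated by eye in a tSNE plot, but a visual
grouping cannot be tested, so the package uses a
deterministic rule: genes are z-scored across samples and HF patients are
cut into *k* = 2 groups by Ward (ward.D2) hierarchical clustering on
Euclidean distances. Cluster ids are ordered so cluster 2 has the higher
mean over the non-ACE2 signature genes — the severe-fibrosis cluster — so
labels are stable under sample permutation. A 2-D embedding (first two
principal components of the z-scores) is attached for visualization only;
the embedding method is deliberately pluggable because no inference
depends on it.

# Projection-score signature selection

For a samples × genes matrix, a gene subset *S* and projection dimension
*d*, the submatrix is column-standardized (panel genes have heterogeneous
scales) and

`alpha(S, d) = sqrt( sum_{i<=d} lambda_i / sum_j lambda_j )`

over the eigenvalues of its covariance. The projection score is
`tau(S) = alpha(S) - mean(alpha(S_b))` over *B* random subsets of size
|S| drawn from the full gene universe of the supplied matrix (that choice
of null matters: restricting the null to pre-filtered genes would shrink
tau toward zero). Scanning variance-filter thresholds and maximizing tau
selects the subset whose low-dimensional structure most exceeds chance.

Defaults: `d = 2` (the downstream use is 2-D embedding structure),
`B = 100`, threshold grid 0.50–0.95 in steps of 0.05. Ties in tau break
toward the larger subset, then the lower threshold. A scan whose best tau
is within twice the spread (s.d.) of the null alphas is flagged
"no informative subset": under a pure-noise matrix the observed alpha is
itself one draw from that null, so the spread — not the standard error of
the null mean — is the relevant scale.

Two practical notes established by the test suite's brute-force oracles:
the scan only inspects variance-ranked subsets, so scan/enumeration
agreement is guaranteed only when the informative block carries dominant
variance; and with `d = 2` a rank-1 planted block plus one noise gene is
still rank 2, so tau can legitimately favor one extra gene in degenerate
toys. With the two-factor structure of the synthetic cohort (a
donor-vs-HF axis and a subcluster axis) the planted 12-gene block is the
strict optimum.

# Gene-category assignment

Panel genes are assigned to cardiomyocyte / fibroblast+pericyte / both /
other categories from a reference mean-expression matrix (genes × cell
types) with a grouping map that pools fibroblasts with pericytes. Per
gene, the specificity fraction of a group is its share of the gene's
total expression mass (group sum over all cell types). We use mass
fractions rather than means of group means because a gene uniform across
many cell types should never be called group-specific; under mean
pooling, a uniform gene would score 1/3 per group and pass the "both"
threshold. The rule is: cardiomyocyte if `s_CM >= 0.5` and `s_FB < 0.3`
(symmetric for fibroblast/pericyte), both if both fractions are at least
0.3, otherwise other. The thresholds 0.5/0.3 are explicit package
choices; no reference predominance rule is available. The synthetic
reference generator constructs group masses of (0.8, 0.1, 0.1),
(0.1, 0.8, 0.1), (0.42, 0.42, 0.16) and (0.15, 0.15, 0.7) for the four
categories, so the assignment round-trips a partition exactly at noise 0.

# The synthetic culture and its trajectory model

## What is emulated

The culture generator emulates a 15-day primary cardiac-fibroblast
culture: ~8,000 cells in three batches comprising endothelial cells
(0.89%), two macrophage populations (24.9% total, split 60/40), and six
fibroblast subpopulations on a branched activation trajectory
FB2 → FB1 and FB2 → FB3/FB4 → FB5 → FB6. FB3 (25.7% of fibroblasts) and
FB5 (22.3%) are pinned to the target composition; the free shares
(FB1 0.06, FB2 0.14, FB4 0.15, FB6 0.17) were calibrated once so that the
per-cell matrix-producing phenotype covers 76% of fibroblasts, because
that 76/24 split is a per-cell phenotype measurement, not a subpopulation
size.

Expression programs distinguish switch-like genes (population markers,
cell-cycle genes, the FB6-restricted signature genes) with a near-zero
off state (~0.01 counts, i.e. ambient level) and strong on states, from
graded programs (contractile genes high in FB1/FB2 and fading toward FB6;
ECM genes ramping up to FB6 with a ~16-fold collagen amplitude;
Tgfb1 in macrophages vs Tgfb2/Tgfb3 in fibroblasts; Ccl2 and inflammation
genes peaking in FB4; proliferation genes concentrated in FB4 with
Ccnd1/Ccnd2 peaking in FB1). The bimodal marker design is what real
cell-identity genes look like in droplet data and is required for
single-gene z-score typing to be meaningful at all.

## Kinetics

Spliced/unspliced layers are integrated from the two-state model
`du/dt = alpha - beta u`, `ds/dt = beta u - gamma s` along each cell's
lineage path, using exact per-step updates with piecewise-constant
transcription rates. The root FB2 segment ramps continuously from a
quiescent state (freshly plated cells are still activating), later
segments plateau with short boundary ramps (half-width 0.05 segments).
Per-gene rates are lognormal around beta = 80 and gamma = 40 per segment
— mRNA half-lives short relative to the dwell time in a state, which is
what keeps subpopulations transcriptionally discrete while still leaving
a detectable unspliced lead (velocity signal) during induction. Doublets
are appended post hoc as sums of two random cells' counts, matching the
simulated-doublet assumption of the detector. Counts are negative
binomial (dispersion 0.1) with lognormal library factors (sdlog 0.3) and
mild per-batch gene-wise effects (sd 0.1 log2).

## What passing tests do not show

The generator has no ambient RNA, no platform-specific artifacts, no
empty droplets, discrete batch effects only at the gene level, and its
populations are exactly the model the classifiers assume. Recovery of the
planted composition therefore validates the pipeline logic and its
calibration, not robustness to the full messiness of real droplet data.

# Single-cell processing choices

* **QC**: genes need total spliced ≥ 20 AND total unspliced ≥ 20.
* **Doublets**: one synthetic doublet per observed cell (sums of random
  cell pairs), co-embedded by PCA; score = fraction of synthetic cells
  among the k = 30 nearest neighbours, rescaled by the simulation ratio;
  the removal mask flags scores above the 0.99 quantile (the generator's
  default doublet rate is 1%).
* **Normalization**: per-cell scaling of spliced counts to the median
  total, then log1p; PCA on the top 100 variable genes, 30 components;
  kNN graph (k = 20, Euclidean in PC space). Optional per-batch mean
  centring of the PC scores stands in for heavier integration methods,
  which are out of scope.
* **Clustering**: Louvain on the kNN graph; the resolution is a config
  value and `scanResolutions()` reports cluster counts (and adjusted Rand
  index when truth is available). On a disconnected graph each component
  is always its own community, so the "resolution → 0 gives one cluster"
  limit applies to connected graphs.
* **Typing**: z > 1 on the normalized layer defines "high" (no reference
  threshold exists to adopt); rule order endothelial → macrophage →
  fibroblast. The endothelial score averages Emcn, Pecam1 and Cdh5
  because a single rare-population marker cannot beat Poisson noise at
  z > 1. Acta2-high macrophages are flagged; the Lyz2 flag on fibroblasts
  uses a lower threshold (z > 0.5) since Lyz2-high cells are called
  macrophage by precedence.
* **State**: among fibroblasts, mean z of Col1a1/Col1a2/Col3a1 vs mean z
  of Acta2/Tpm2; larger wins; exact ties go to contractile.
* **Cell cycle / proliferation**: phase = argmax of mean z over the S and
  G2M sets if positive, else G1; proliferation score = unweighted mean z
  over 17 genes (the four canonical markers plus 13 cell-cycle
  effectors; only the four anchors are fixed, the rest is a documented
  package choice), "proliferating"
  means score > 0 — a symmetric null in the absence of a published
  threshold.

# Steady-state RNA velocity

The u and s layers are smoothed by first-order kNN averaging (k = 30).
Per gene, `gamma` is the regression-through-origin slope
`sum(u s) / sum(s^2)` over the union of cells in the top and bottom 5%
quantiles of s — cells most likely near the two steady states. Velocity
is `v = u - gamma s`. The velocity graph stores, for each directed kNN
edge, the cosine between the cell's velocity vector and the displacement
to the neighbour in log1p expression space of the fitted genes
(variance-stabilized; zero-velocity cells get cosine 0). Embedding
arrows are `sum_j (pi_ij - 1/k)(e_j - e_i)` with softmax weights
`pi ∝ exp(cos/sigma)`, `sigma = 0.1`.

This is the deterministic first-moment model; the second-moment
("stochastic") variant and full-kinetics likelihood models are not
implemented. Accordingly the package's velocity claims are directional —
on synthetic kinetics, the large majority of FB2 cells' arrows project
positively toward the FB3/FB4 branch — not numerical. A subtlety worth
recording: the mean of `v` inherits the gamma-fit uncertainty, so the
steady-state null check uses `3 * sqrt(var(v)/n + (se(gamma) mean(s))^2)`
rather than the naive standard error.

# Signature matching

Profiles are per-gene group means z-scored across groups with the
population (n) denominator — a deliberate choice so that small-group
profiles are exactly reproducible in tests. Genes constant across groups
are flagged and excluded from correlations (at least 3 usable shared
genes required). Cross-species matching uses the explicit human↔mouse
symbol map bundled with the package; unmapped genes raise an error rather
than being dropped silently. Matching reports the Pearson r of one
profile column (by default the last group, e.g. the severe-fibrosis
cluster) against every subpopulation column, the positive set, and the
argmax.

# Bulk staging

The bulk generator mixes fibroblast subpopulation signatures with
stage-dependent convex weights: FB4 peaks at 3 days post-MI, FB5/FB6 at
7 days, and composition is near-uninjured again from 2 weeks. Four
replicates per stage and NB dispersion 0.02 (biological CV ~14%) reflect
a typical inbred-mouse bulk design; stage-invariant background genes are
appended. The planted stage-varying set is defined as genes whose
expected per-stage log2 range exceeds 0.5.

Staging tools: one-way ANOVA on log1p expression per gene with BH
q-values (DE set at q < 0.05; genes with no within-group variance and
equal means get p = 1 and a flag); hypergeometric upper-tail overlap
tests between marker sets and DE sets (the universe is an explicit
parameter — all genes surviving expression filtering — because overlap
tests are only interpretable once the universe is stated); marker-set PCA scored by the
mean silhouette width of stage labels in the first 2 components ("stages
cluster better" needs a scalar to be testable); and stage × marker-set
heatmaps of per-gene z-scores averaged within set and stage, with the
argmax row as the peak stage.

# Synthetic cohort parameters

Defaults: 10 donors, 65 HF patients, 82 panel genes + 5 reference genes;
HF raises the 35 fibroblast/both panel genes by 1 log2; a 40% subcluster
of HF patients carries an extra 2 log2 on the 12-gene signature with ACE2
reversed (the subcluster share has no reference value and is a free parameter;
the effect size is the smallest round value at which the planted block is
the structural optimum of the projection-score scan rather than a
noise-level boundary). Ages are drawn from the published donor/patient
age distributions; clinical flags are enriched in subcluster 2 (ischemic
0.84 vs 0.46 — severe fibrosis strongly associated with ischemic disease
— with weaker enrichment
for diabetes, BMI and sex). A deterministic subset of panel genes (every
5th) carries a mild age slope of 0.01 log2/year so the age correction has
something to remove. Counts are NB (dispersion 0.05) around lognormal
baselines with a per-sample RNA-content factor that normalization must
remove.

# Problem sizes and determinism

The test suite runs the full single-cell chain at the study scale
(8,000 cells, 250 genes) once and shares it across checks; unit tests use
300–2,500-cell configurations and small hand-built fixtures. All
generators take a single seed and are bit-reproducible; algorithmic
seeds (doublet simulation, Louvain, projection-score nulls) are separate
arguments so study conditions and algorithm randomness can be varied
independently, which is exactly how `scripts/acceptance.R` uses them.

# Known limitations

* The marker-rule cell typer assumes bimodal markers; it is not a
  substitute for cluster-based annotation on noisy real data.
* Velocity output is directional only; no latent time, no per-gene
  kinetic parameters beyond the steady-state ratio.
* The batch model (gene-wise multiplicative shifts, optional PC
  centring) does not emulate nonlinear batch distortions.
* The gene-assignment thresholds and the proliferation gene list beyond
  its four canonical members are package choices with no reference
  values to adopt; the bundled 82-gene panel is likewise a synthetic
  stand-in for a proprietary panel, anchored on the 12-gene signature
  and the four category sizes.
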