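---
title: "Consensus BMF subtyping of smoldering myeloma: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus BMF subtyping of smoldering myeloma: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smmsubtype)
```

Smoldering multiple myeloma (SMM) is the asymptomatic precursor of multiple
myeloma, with roughly a 10%-per-year risk of progression. Clinically it is
staged with the 20-2-20 model; genetically, SMM tumors already carry the
driver lesions of overt myeloma: recurrent SNVs (e.g. *NRAS*, *KRAS*,
*TP53*), arm-level copy-number alterations, IgH translocations, and
hyperdiploidy. This package implements an unsupervised subtyping of SMM
patients from a binary patient x alteration matrix, the characterization of
those subtypes, a classifier for external cohorts, and the clinical layer
that connects subtypes to progression risk.

## The factorization model

The data object is a binary matrix $X \in \{0,1\}^{n \times f}$: patient $i$
carries alteration $j$ or does not. We approximate $X \approx W H$ with
binary $W$ ($n \times K$, cluster memberships) and binary $H$ ($K \times f$,
cluster signatures). Binary factors matter here because features such as
hyperdiploidy are *summative*: they legitimately belong to several subtype
signatures at once, which an NMF on continuous scores does not represent
cleanly, and the input is sparse presence/absence data.

`bmf_fit()` uses a penalty method: continuous non-negative factors are
optimized by multiplicative updates on

$$\lVert X - WH \rVert_F^2 \;+\; \lambda \left( \lVert W \circ W - W
\rVert_F^2 + \lVert H \circ H - H \rVert_F^2 \right),$$

where the second term vanishes exactly when every entry of $W$ and $H$ is 0
or 1. The update for $W$ (and symmetrically $H$) is

$$W \leftarrow W \circ \frac{X H^\top + 3\lambda W^{\circ 2}}
{W H H^\top + 2\lambda W^{\circ 3} + \lambda W},$$

with denominators clamped at $10^{-12}$. The penalty weight starts at
$\lambda = 0.1$ and is multiplied by 10 every 50 iterations up to a cap of
$10^4$, so the factorization first finds structure and is then pushed onto
the binary vertices; convergence is declared only after the penalty reaches
its cap, when the relative objective change drops below $10^{-6}$ (at most
500 iterations). Factors are finally thresholded at 0.5 and the
reconstruction re-binarized as $WH \ge 0.5$, which makes the residual an
integer Hamming count of mismatched cells — small instances can therefore
be checked against exhaustive search exactly, and the test suite does so.
Initialization is i.i.d. Uniform(0.1, 0.9) from a seeded generator
(multiplicative updates need a strictly positive start), so every fit is
bit-reproducible from its seed.

## Consensus clustering and choosing K

A single BMF run can land in a local optimum, so `bmf_subtype()` aggregates
many seeded restarts (default 100): each run labels patients by the argmax
of their continuous loadings (ties to the lowest cluster index; all-zero
loading rows fall back to the nearest signature in Hamming distance and are
flagged), and the consensus matrix records how often each patient pair
co-clusters. The consensus is cut by hierarchical clustering with Euclidean
distance and Ward linkage, and cluster ids are canonicalized by decreasing
size so labels are stable across runs.

`k_diagnostics()` scores a range of K by: mean silhouette width on Dice
dissimilarities of the raw binary profiles ($1 - 2|a \wedge b|/(|a|+|b|)$,
defined as 0 for two all-zero profiles), the best-restart residual and
variance explained, and the generalized Kullback–Leibler divergence
$D(X \,\|\, WH) = \sum x \log(x/y) - x + y$ computed on the *continuous*
reconstruction of the best-restart fit — a binarized reconstruction would
put zero mass on observed cells and make the divergence degenerate.
Optional downsampling (patients sampled without replacement) probes how
stable these diagnostics are at reduced cohort size; in our synthetic
cohorts their replicate-to-replicate variance contracts markedly between
subsamples of 50 and 100 patients, echoing the minimum cohort size the
approach needs.

`select_k()` applies a documented, overridable rule: restrict to K whose
silhouette is at least 90% of the maximum over the range, then take the K
with the largest drop in mean K-L divergence from K-1. The silhouette
screen does the structural work (over-split solutions keep improving K-L
but lose silhouette); the K-L drop locates where added components stop
explaining real signal. The full rationale table is always returned so the
choice can be inspected or overridden.

## Cluster characterization

`enrich_clusters()` tests each (cluster, feature) pair with a one-sided
Fisher exact test — the upper hypergeometric tail $P(A \ge a)$, testing
positive association only — and adjusts per cluster with
Benjamini–Hochberg, calling a feature enriched at $q < 0.1$. The adjustment
family is per cluster because the ranked per-cluster bar lists are the
object of interest; a global family across all pairs is available via
`family = "global"`. Odds ratios use the Haldane–Anscombe 0.5 correction on
zero cells for display; p-values always use the exact counts.

## Subtype classifier

`train_subtype_classifier()` fits a random forest on the features shared
between cohorts and carried by at least 3 training patients
(`select_shared_features()`). Hyperparameters (tree count, features per
split, node size, tree-size cap) are drawn by randomized search — default
50 draws, configurable; on well-separated cohorts accuracy is flat in this
parameter — and scored by stratified five-fold CV accuracy; the best
configuration is refit on all data. Fold assignment, search and forests all
descend from one seed. Prediction returns per-class probability vectors and
argmax labels with ties to the lowest class index; missing model features
are an error unless zero-filling is explicitly allowed.

## Clinical outcome layer

* `stage_20_2_20()`: strict inequalities exactly as the staging rule is
  printed (M-protein > 2 g/dL, FLC ratio > 20, BMPC > 20%); 0/1/2+ factors
  give low/intermediate/high. Boundary values do not count, and any missing
  factor yields a missing stage.
* `detect_evolving_biomarkers()`: eMP requires both a >= 25% relative and a
  >= 0.5 g/dL absolute M-protein rise within 12 months of diagnosis (both
  thresholds inclusive; a measurement at exactly 12 months counts); eHb is
  a >= 0.5 g/dL hemoglobin drop in the same window. All available readings
  in the window are used, not fixed visits. A zero M-protein baseline makes
  the relative rule vacuous; the absolute rule is then applied alone, with
  a warning.
* Survival: Kaplan–Meier with Greenwood-variance 95% CIs, medians as the
  smallest time with $S(t) \le 0.5$, reverse-KM median follow-up; log-rank
  tests; Cox models with Efron tie handling; Harrell's C with a
  Noether-type normal-approximation CI; nested models compared by the
  likelihood-ratio statistic plus both C-indexes. These delegate to the
  survival package; the package's own tests pin them to hand-enumerated
  examples and calibration simulations (type-I error, CI coverage,
  estimator recovery).
* `biomarker_association()`: cross-product odds ratio from the 2x2 table
  (Haldane correction on zero cells) with a two-sided Fisher exact p;
  a logistic-regression odds ratio is available because the published
  estimates do not state which was used. The 2x2 table is the default.

## The synthetic cohort generator

Restricted-access patient data cannot ship with an analysis package, so
`generate_cohort()` produces cohorts with the statistical structure the
analysis assumes, and every downstream claim in the test suite is made
against this generator's planted truth. Defaults are the study conditions:

* 214 patients, six subtypes (HL1–HL4, TL1, TL2) with uniform mixing.
* 42 features named like a myeloma driver panel: 6–7 signature markers per
  subtype, three background-only drivers, five IgH/MYC translocations, and
  a summative `HYPERDIPLOIDY` flag. Signature features appear at Bernoulli
  rate 0.7 in their own subtype and 0.05 elsewhere; translocations use a
  0.005 background because real IgH translocations are sparse and near
  mutually exclusive. Hyperdiploidy spans the four HL subtypes at rate 0.9,
  except 0.69 in HL2, and 0.1 in the TL subtypes.
* The signature map is *balanced by design*: each subtype carries a
  comparable number of markers, named after its reported associations. The
  published per-cluster feature lists are longer than the handful of
  highlighted markers, and a generator whose planted subtypes are
  identifiable is what makes recovery a meaningful test; the map is an
  analog of the published subtype cards, not a frequency table of them.
* Risk groups (TL2 low; HL1/HL4 intermediate; HL2/TL1/HL3 high) get
  exponential progression times with medians 11 / 5.2 / 2.6 years — only
  medians are published, so a one-parameter family is the honest choice —
  and independent uniform administrative censoring on $[0, T_{max}]$, with
  $T_{max}$ solved numerically so the expected censored fraction is 34%.
  The censoring mechanism is unstated in the source material; uniform
  administrative censoring is the simplest mechanism consistent with a
  reported non-progressor fraction.
* Evolving biomarkers: each patient is designated eMP-evolving with
  probability $\mathrm{logit}^{-1}(\mathrm{logit}(0.05) +
  \mathbb{1}\{\text{high risk}\} \log 9.4)$ (eHb analogously with 5.3);
  designated patients receive measurement series constructed to satisfy
  the corresponding rule, all others to violate it (M-protein excursions
  below the 0.5 g/dL absolute minimum; hemoglobin drops below 0.5 g/dL).
* Clinical baselines: log-normal M-protein with a lower location for the
  low-risk (TL2-analog) subtype and a higher one for high-risk patients,
  log-normal FLC ratio and beta-distributed marrow plasmacytosis shifted
  upward in high-risk patients, normal hemoglobin. The mild risk-stage
  coupling makes the 20-2-20 stage an informative but incomplete predictor,
  so genetic risk adds concordance beyond stage — the regime the nested
  Cox comparison is designed to detect.
* Reproducibility: subtype labels, each patient's feature row, and each
  downstream layer use sub-seeds derived from the master seed via a
  counter, so output is bit-identical across runs and independent of
  evaluation order.

What the generator does *not* emulate: co-occurrence structure beyond the
subtype (features are conditionally independent given the subtype),
mutual-exclusivity constraints among translocations, clonal fractions,
expression data, and non-exponential hazards. Passing tests therefore
demonstrate that the machinery recovers the structure it assumes, at the
published effect sizes — not that real SMM cohorts satisfy those
assumptions.

## Numerical choices and degenerate inputs

* Multiplicative-update denominators clamped at $10^{-12}$; reconstruction
  clamped at the same floor inside the K-L divergence, with
  $0 \log 0 := 0$.
* An all-zero input matrix is rejected (degenerate factorization); all-zero
  patient rows are kept and flagged rather than dropped, since dropping
  would silently change the cohort size.
* Ties: argmax assignment breaks to the lowest cluster index; `which.min`
  does the same in the Hamming fallback; canonical cluster ids break size
  ties by the lower original id; classifier prediction ties break to the
  lowest class index.
* Consensus entries are co-assignment counts over `n_runs` (every patient
  appears in every restart); a single-run consensus is an error.
* Clusters with fewer than two patients produce a warning and
  uninformative ($p = 1$) enrichment rows rather than failing the run.

## Problem sizes used by the test and acceptance suites

Exact kernels (Fisher tail, BH, Dice) are compared against exhaustive
enumeration over all 2x2 tables with total at most 40 and all binary
vectors of length up to 10; BMF against brute-force optima up to 4 x 5 at
K = 2. Statistical recovery uses the generator at its default size
(n = 214) over 10 master seeds for clustering and classification, n = 200
with four planted subtypes for K-selection, n = 2000 per risk group for
survival medians and hazard ratios, and n = 5000 for prevalence and
odds-ratio calibration; log-rank type-I error uses 1000 null replicates and
Cox CI coverage 200 replicates. These sizes give the binomial/normal bands
quoted in the tests comfortable power while keeping a full run inside a few
minutes on one core.

## Known limitations

* The BMF penalty method is a heuristic: monotone within fixed-penalty
  phases (asserted in tests) but not guaranteed to reach the global
  optimum; consensus restarts are the mitigation, and brute-force oracles
  guard small instances only.
* The K-selection rule is one defensible reading of "a decrease in
  divergence plus stable silhouettes"; the rationale table exists because
  reasonable analysts can disagree at the margin.
* Harrell's C confidence intervals use a normal approximation; for very few
  events they will be anti-conservative.
* The published cohort-level numbers (C-indexes, hazard ratios, enrichment
  lists) came from restricted-access patient data; nothing here reproduces
  those values, only the statistical behavior of the method at the
  published effect sizes.
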