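# smmsubtype

Genetic subtyping and progression-risk modelling for smoldering multiple
myeloma (SMM).

SMM is the asymptomatic plasma-cell precursor of multiple myeloma, with
about a 10%-per-year risk of progression. Its tumors already carry myeloma
driver lesions — recurrent SNVs, arm-level copy-number alterations, IgH/MYC
translocations, hyperdiploidy — and patients with different constellations
of these drivers progress at very different rates. This package takes a
binary patient × alteration matrix `X ∈ {0,1}^{n×f}` and:

1. **Subtypes patients** by consensus **binary matrix factorization**
   (BMF): `X ≈ W·H` with binary memberships `W` (n × K) and binary
   signatures `H` (K × f), fit by multiplicative updates on
   `‖X − WH‖² + λ(‖W∘W − W‖² + ‖H∘H − H‖²)` under an increasing penalty
   schedule, thresholded at 0.5. Repeated seeded restarts are aggregated
   into a consensus co-clustering matrix, cut with Ward/Euclidean
   hierarchical clustering (`bmf_subtype()`). Binary factors handle the
   sparse presence/absence input and summative features such as
   hyperdiploidy that legitimately span several subtypes.
2. **Chooses K** from silhouette (Dice dissimilarity), factorization
   residual, variance explained and generalized K-L divergence over a K
   range, with optional downsampling stability (`k_diagnostics()`,
   `select_k()`).
3. **Characterizes clusters** with one-sided Fisher exact tests and
   Benjamini–Hochberg control, calling features enriched at q < 0.1
   (`enrich_clusters()`).
4. **Classifies external cohorts** with a seeded random forest trained on
   shared features carried by ≥ 3 patients (`train_subtype_classifier()`,
   `predict()`).
5. **Links subtypes to outcome**: 20-2-20 clinical staging, evolving
   M-protein / hemoglobin detection, Kaplan–Meier (Greenwood CIs),
   log-rank, Cox (Efron ties), Harrell's C, nested-model comparison
   (`stage_20_2_20()`, `detect_evolving_biomarkers()`, `km_fit()`,
   `cox_fit()`, `compare_cox_models()`, `c_index()`).
6. **Simulates calibrated cohorts** so the full pipeline is testable
   without restricted patient data (`generate_cohort()`): six planted
   subtypes (HL1–4, TL1–2), signature features at rate 0.7 vs 0.05
   background (sparse translocations at 0.005), hyperdiploidy at 0.9/0.69/
   0.1 by subtype, risk-group progression medians 11 / 5.2 / 2.6 years
   with ~34% censoring, and evolving-biomarker odds multipliers 9.4 (eMP)
   and 5.3 (eHb) in the high-risk group.

See the methods vignette (`vignettes/smm-subtyping-methods.Rmd`) for the
model, defaults and design rationale.

## Worked example

```r
library(smmsubtype)

cohort <- generate_cohort(cohort_config(seed = 42))   # 214 x 42 binary matrix
fit <- bmf_subtype(cohort$matrix, K = 6, n_runs = 100, seed = 42)
summary(fit)
```

```
Consensus BMF subtyping, K = 6
  cluster 1 (n = 45): MAF, FGFR3, del14q, t(14;16), del8p
  cluster 2 (n = 42): t(14;20), del16q, TP53, del6q, del1p
  cluster 3 (n = 35): t(11;14), CCND1, gain11q, XBP1, HIST1H1E
  cluster 4 (n = 34): NFKBIA, t(8;14), del20q, SP140, gain7
  cluster 5 (n = 34): gain19, TRAF3, gain9, EGR1, NRAS
  cluster 6 (n = 24): gain2p, gain1q, PRKD2, NFKB2, FAM46C
```

Each cluster's top enriched alterations (one-sided Fisher, BH q < 0.1)
recover the planted subtype signatures: cluster 1 is the t(4;14)/t(14;16)
translocation-like subtype, cluster 3 the t(11;14)/CCND1 subtype, cluster 5
the prototypical hyperdiploid cluster, and so on.

```r
km <- km_fit(cohort$clinical$ttp_months, cohort$clinical$progressed,
             cohort$clinical$risk_group)
km
```

```
Kaplan-Meier fit
        group   median   lower    upper
         high  31.9829 29.1812  46.8140
 intermediate  64.1841 36.6606 104.9127
          low 150.8132 85.1973       NA
median follow-up (reverse KM): 107.8246
```

Median time to progression is ~2.7 years in the high-risk genetic group,
~5.3 years in the intermediate group, and ~12.6 years (upper CI open, few
events) in the low-risk group, with a log-rank chi-square of 30.1 on 2 df
(p = 3e-07) — the risk separation the generator plants and the survival
layer measures.

A full file-based run (simulate → cluster → enrich → train → survival →
report, with a JSON manifest) is one call:

```r
run_pipeline(list(K = 6, n_runs = 100), outdir = "smm_run", seed = 1)
```

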