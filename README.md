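# mirpanel

Analysis of focused miRNA RT-qPCR panels profiled from formalin-fixed
paraffin-embedded (FFPE) lymph node tissue, built for the diagnostic
question of separating reactive lymph nodes (RLN) from the two nodal
T-cell lymphoma entities — nodal T-follicular-helper-cell lymphoma
(nTFHL) and nodal peripheral T-cell lymphoma, NOS (nPTCL).

The package implements the complete chain a molecular-pathology group
needs to evaluate such a panel:

1. **Ct preprocessing** — spike-in technical normalization
   (per-sample offset = mean spike-in Ct − cohort median of those means),
   removal of miRNAs expressed in fewer than 10% of samples, and
   global-mean normalization to −ΔCt values
   (`value(i,j) = −(ct(i,j) − mean_i ct(i,j))`), so higher values mean
   higher abundance and group differences read directly as log2 fold
   changes (1 Ct ≈ 1 log2 unit). Exploratory hierarchical clustering
   (Euclidean, complete linkage) and centered PCA summarize cohort
   structure.
2. **Differential expression** — per-miRNA equal-variance Student's *t*
   between each lymphoma group and RLN on the −ΔCt scale, with
   Benjamini–Hochberg FDR per comparison; significance is `q < 0.05`.
3. **Classification** — nested cross-validated, 10-fold inner / 5-fold
   outer, elastic-net logistic regression over the full tuning grid
   (feature percentage ∈ {5, 10, 20}%, inverse regularization
   C ∈ 10^−4…10^4, l1 ratio ∈ {0, 0.25, 0.5, 0.75, 1}; 135 combinations),
   plus a 3-class random forest (depth {2,3,4} × bootstrap {T,F} ×
   max-features {auto, sqrt, log2, none} × criterion axis; 48
   combinations; 500 trees) with a pooled out-of-fold confusion matrix
   and permutation feature importance. Feature ranking, standardization
   and hyperparameter choice are refit inside every training split —
   no validation sample ever leaks into selection.
4. **Target-gene enrichment** — differentially expressed miRNA sets are
   mapped to curated target genes; gene sets are scored by
   hypergeometric overlap and a Kolmogorov–Smirnov statistic, with the
   primary p-value from a miRNA-resampling permutation null
   (`p = (1 + #{perm ≥ obs}) / (B + 1)`), which preserves target
   multiplicity, followed by BH-FDR.
5. **Synthetic cohorts** — a first-class generator
   (`simulate_cohort()`, `simulate_target_map()`,
   `simulate_gene_sets()`) that emulates the study design: 19/49/20
   samples per class, a 376-miRNA panel with 130 low-detection miRNAs,
   spike-in controls, per-sample technical offsets, and planted class
   effects (largely shared between the two lymphoma subtypes) with a
   ground-truth record for parameter-recovery testing.

## Worked example

```r
library(mirpanel)

sim <- simulate_cohort(cohort_config(seed = 1))
sim$ct
#> <ct_matrix> 379 miRNAs (3 spike-in) x 88 samples
#>   detected wells: 67.4%  |  max_ct: 35
#>   provenance: raw

nm <- normalize_chain(sim$ct)$normalized
nm
#> <normalized_matrix> 246 miRNAs x 88 samples (-dCt scale)
#>   provenance: raw -> spikein -> low_detection_filter -> global_mean

de <- differential_expression(nm, sim$annotation, c("nTFHL", "nPTCL"),
                              comparison = "grouped")
de
#> <de_result> comparison grouped vs reference: 246 miRNAs, 22 significant (q < 0.05; 11 up, 11 down)
#>           mirna_id log2fc      t         p         q direction significant
#> 1 hsa-miR-sim-0012 -2.073 -8.624 2.862e-13 7.041e-11      down        TRUE
#> 2 hsa-miR-sim-0006 -1.978 -8.438 6.848e-13 8.423e-11      down        TRUE
#> ...

res <- nested_cv_logistic(nm, sim$annotation, positive = c("nTFHL", "nPTCL"),
                          spec = cv_spec(seed = 1))
res
#> <model_result> elastic_logistic: nTFHL+nPTCL vs RLN
#>   AUC 1.000 +/- 0.000 (95% CI over 5 outer folds), best fold 1.000
```

The 88-sample cohort carries 22 planted lymphoma-shared effects
(|shift| 1.5–2 Ct); after normalization exactly the 130 designated
low-detection miRNAs are removed (246 retained), the differential
analysis recovers exactly the 22 planted miRNAs (11 up, 11 down), and
the nested-CV classifier separates RLN from the pooled lymphomas
perfectly at this signal strength — the mean/CI summarize the five
outer-fold AUCs.

A full run (normalization, QC, three DE tables, three logistic models,
random forest with confusion matrix and importance, enrichment, and a
checksummed manifest) is one call:

```r
cfg <- read_run_config(system.file("extdata", "demo_config.yaml", package = "mirpanel"),
                       out_dir = "demo_out", seed = 5)
run_full_analysis(cfg)
```

or from a shell via the thin CLI wrapper
(`inst/scripts/mirpanel run-all --config demo_config.yaml --seed 5 --out demo_out`).

## Layout

- `R/` — implementation (IO, simulation, normalization, DE,
  classification, enrichment, pipeline).
- `tests/testthat/` — unit, property and end-to-end suites with
  brute-force oracles.
- `vignettes/mirpanel-methods.Rmd` — the model, its assumptions, and
  every numerical design choice.
- `inst/extdata/demo_config.yaml` — small synthetic demo configuration.
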