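---
title: "mirpanel: methods, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{mirpanel: methods, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

mirpanel analyzes focused miRNA RT-qPCR panels measured on FFPE lymph
node tissue, with the diagnostic contrast of reactive lymph nodes (RLN)
against the two nodal T-cell lymphoma entities nTFHL and nPTCL. This
vignette records the statistical model behind each stage and the
reasoning behind every numerical choice that was genuinely open.

## The measurement model

A qPCR threshold cycle (Ct) is, to good approximation, linear in the
negative log2 of transcript abundance: one cycle is one doubling. All
internal statistics therefore operate on the −ΔCt scale, where group
mean differences are log2 fold changes and "up" means more abundant in
the comparison group. Wells that never cross threshold, or cross it
above the detection cutoff, carry no reliable quantity and are treated
as undetected.

**Detection rule.** A well is detected iff a numeric Ct ≤ `max_ct` is
present. The default `max_ct = 35` is the conventional qPCR limit of
reliable quantification; it is a declared convention of this package,
not an inference about any particular instrument's amplification-call
logic.

## Preprocessing chain

The chain is spike-in normalization → low-detection filter →
global-mean normalization, in that order (technical correction first,
then gene filtering, then the sample-level rescaling that the filter
changes).

**Spike-in normalization.** Synthetic spike-in RNA added before
extraction captures per-sample technical variation. No standard formula
exists, so the package declares one: the per-sample offset is the mean
spike-in Ct of that sample minus the *cohort median* of those means,
subtracted from every detected well of the sample. The median (rather
than the mean) keeps a single aberrant sample from shifting the whole
cohort; using a cohort-level reference makes the operation idempotent
(a second application finds zero offsets). Detection calls are made on
the raw values and are not revised by the adjustment.

**Low-detection filter.** miRNAs expressed in fewer than 10% of
samples are removed — strictly fewer, so a miRNA detected in exactly
10% of samples is retained. Spike-in rows are always removed here: they
are controls, not analytes.

**Global-mean normalization.** Each sample's mean Ct (over retained
miRNAs) is subtracted from its wells and the sign flipped. Residual
undetected wells are first imputed at the detection limit (35), the
standard conservative choice for censored qPCR values: it says "at most
this abundant". Two exact guarantees follow, and are tested: every
sample's normalized values average zero (to 1e−9), and any per-sample
additive offset in the input cancels exactly — *on fully detected
data*. Limit-imputed wells are pinned at 35 by construction and cannot
follow a sample shift, so the invariance guarantee is stated for
detected wells; in practice imputed wells are rare after filtering.

**QC summaries.** Hierarchical clustering uses Euclidean distance with
complete linkage (merge heights are then non-decreasing); PCA treats
samples as observations and centers but does not scale the variables,
because all variables already share the Ct scale.

## Differential expression

Per miRNA, the equal-variance Student's *t* between the comparison
group and RLN — equal-variance rather than Welch because the classical
two-sample *t* is the declared test of the pipeline; Welch is available
behind a flag. p-values are BH-adjusted within each comparison's own
family (grouped lymphomas, nTFHL, nPTCL each form one family, matching
the per-comparison result tables), and "differentially expressed" means
q < 0.05 with no fold-change floor. The row-wise *t* is computed in
closed form (vectorized over the panel) and is cross-checked against
`t.test(var.equal = TRUE)` to 1e−10 in the test suite; BH delegates to
`p.adjust` and is cross-checked against the brute-force step-up
definition. Degenerate zero-variance rows get p = 1 when the means are
equal and the p → 0 limit otherwise.

## Nested cross-validated classification

Hyperparameters are tuned in an inner loop and performance estimated in
an outer loop, so the reported AUC never sees the data that chose the
model. Folds are stratified by class; the class imbalance (19 RLN vs 69
lymphomas) is handled by stratification only.

**Logistic regression.** The grid is feature percentage {5, 10, 20}%,
inverse regularization C {1e−4 … 1e4}, l1 ratio {0, 0.25, 0.5, 0.75, 1}
— 135 combinations, searched by a 10-fold inner loop inside each of 5
outer folds. Inside *every* inner training split the full pipeline is
refit: features are ranked by training-fold *t*-test p-value (the
simplest filter consistent with the DE module; the selection statistic
is a package choice), the top `max(1, round(pct/100 × p))` kept, the
kept features standardized with training statistics, and the penalized
model fit. With 246 retained miRNAs, 20% selects 49 features and 5%
selects 12 — `round(12.3)`; the package documents its own rounding and
does not force any other count. The penalty is the elastic net,
`(1/C) · [l1·L1 + (1−l1)/2·L2]` on the cross-entropy objective, fit by
glmnet with `lambda = 1/(C·n)`, `alpha = l1`; glmnet's warm-started
path over all nine C values makes the 6,750-fit search run in seconds.
Ties in mean inner AUC break toward the smaller feature percentage,
then smaller C, then larger l1 ratio — toward sparser, more regularized,
more reproducible models. The winner is refit on the full outer-training
split and scored on the held-out fold; the summary is the mean of the
five outer-fold AUCs with a 95% CI of `t(0.975, df = 4) · SD/√5`, plus
the best single fold ("best AUC"). If glmnet's coordinate descent hits
its iteration cap at an extreme grid corner it warns and the best
available iterate is used.

**Random forest.** Three-class probability forest over the full panel
(no univariate pre-filter), 500 trees (fixed, not searched), grid:
depth {2, 3, 4} × bootstrap {true, false} × max-features
{auto, sqrt, log2, none} × criterion {gini, entropy} = 48 combinations,
tuned by a 3-fold inner loop on mean one-vs-rest macro AUC. "auto" maps
to sqrt (its conventional classification meaning); "none" uses all
features; bootstrap = false trains every tree on the full sample with
only feature-subsampling randomness. Tree induction always uses the
Gini impurity: the backend (ranger) implements Gini splitting for
classification, the practical difference between Gini and entropy
splits is negligible, and the criterion axis is retained in the search
space but distinguishes runs only through the RNG stream. The confusion
matrix pools the out-of-fold predictions of the five outer folds, the
only reading of "averaged over the validation rounds" that yields
integer counts summing to the cohort size, with each sample predicted
exactly once.

**Permutation importance.** The drop in a held-out metric when one
feature column is shuffled (AUC for binary scorers, accuracy for the
3-class forest — the metric for multi-class importance is a package
choice), averaged over repeats and, for the nested forest, over outer
folds. A feature the model ignores scores exactly zero.

**Common panel.** Per binary model, the features selected in ≥ 80% of
outer folds; the common panel is the intersection across the three
comparisons.

## Target-gene enrichment

Differentially expressed miRNA sets (typically the per-subtype *unique*
sets from the DE partition) are mapped to the union of their curated
target genes. Per gene set three statistics are reported:

- the overlap count k with its inclusive upper-tail hypergeometric
  p-value, `P(X ≥ k)` over the chosen universe (diagnostic output);
- the two-sample Kolmogorov–Smirnov D between the targeting scores
  (number of query miRNAs hitting each gene) of set members versus
  non-members — the KS construction is a declared package choice, since
  "KS enrichment" admits several constructions;
- the primary permutation p-value: B same-size miRNA sets are resampled
  uniformly without replacement from the measured panel, each mapped to
  its target union and rescored; `p = (1 + #{perm ≥ obs})/(B + 1)`.
  Resampling *miRNAs* rather than genes preserves the target-multiplicity
  bias of real miRNAs, which is the point of the miRNA-level null.

BH-FDR is applied to the permutation p-values within a collection. One
batch of B draws scores every set in the collection — the null is the
same, and sharing the draws makes the analysis B-fold cheaper. The
default universe is all genes in the target map (a competitive null
over measurable targets); the GMT universe can be chosen instead. The
default B = 1000 (minimum 99) puts the p-value floor at 1/1001.

A subtlety verified by the test suite: with the discrete overlap-count
statistic the permutation p is *conservative* under the null (ties
inflate it), while with the nearly tie-free KS-D statistic it is
uniform on its achievable grid. Analytic hypergeometric and permutation
p-values agree in rank-ordering (Spearman ≥ 0.9 in simulation) but not
in value — the permutation null absorbs miRNA-level multiplicity that
the hypergeometric ignores.

## The synthetic cohort generator

`simulate_cohort()` emulates the study design the pipeline assumes:
88 samples (19 RLN, 49 nTFHL, 20 nPTCL), 376 panel miRNAs plus 3
spike-in rows, 130 low-detection miRNAs, and
`ct(i,j) = baseline_i + class_shift(i, class_j) + offset_j + noise`,
with additive Gaussian noise on the Ct scale (the field's log2-normal
convention; no published noise model exists for this design). Baselines
are uniform on [22, 32] Ct; within-class SD is 1.0 Ct; per-sample
technical offsets are Gaussian with SD 0.5 Ct and are carried
noise-free by the spike-in rows (fixed 20 Ct + offset), so spike-in
normalization can cancel them exactly in the noise-free limit.
Low-detection rows get per-well dropout (detection probability 0.05)
and are rejection-resampled until their realized detected fraction is
below the 10% threshold, so the filter removes exactly the designated
130 rows in every realization.

**Planted effects.** The default signal is 22 effects shared by both
lymphoma subtypes — matching the observed count of grouped-comparison
DE miRNAs and the strong expression similarity between the two lymphoma
entities (the generator's subtype-specific effects are opt-in). Half
the effects are up-, half down-regulated. Magnitudes span 1.5–2.0 Ct:
the generator doubles as a recovery oracle, so its default signal must
be reliably detectable, not borderline — at the default cohort sizes
and noise the weakest effect has a standardized difference of 1.5
against a BH cutoff near |t| ≈ 2.9, i.e. > 99.8% per-effect detection
probability, making "all 22 recovered at q < 0.05" the expected outcome
of essentially every realization. A planted log2 fold change is the
negative of the Ct shift; subtype-specific effects appear diluted by
the subtype's sample share in the grouped comparison, and the ground
truth records the exact expected values.

**What the generator does not emulate.** Pre-amplification chemistry,
primer-efficiency differences, batch structure beyond one additive
offset, correlated miRNA co-regulation, and non-Gaussian heavy tails.
Passing recovery tests therefore demonstrate that the *pipeline* is
correct and leakage-free under the declared model — they do not certify
performance on real FFPE cohorts, where effect sizes and noise are not
under anyone's control.

## Reproducibility machinery

Every stochastic stage draws from a seed derived as a 32-bit hash of
the global seed and the stage name (`derive_seed()`), so single stages
can be rerun in isolation and full reruns are byte-identical; run
manifests record a config hash and a checksum per artifact. Internal
RNG use is wrapped so the caller's `.Random.seed` is never disturbed.

## Problem sizes used by the test suite

Unit tests run on reduced cohorts (20–40 samples, 40–80 miRNAs, reduced
grids) chosen to exercise every code path in seconds; the end-to-end
suite runs the full study geometry — 88 samples, 376-miRNA panel, the
complete 135- and 48-point grids, 20-seed null and recovery
calibrations, and 500-replicate permutation-uniformity checks — sizes
at which each nested cross-validation completes in a few seconds and
the whole suite in a few minutes.

## Known limitations

- The spike-in formula, detection cutoff, KS construction,
  feature-selection statistic, multi-class importance metric and
  permutation count are declared package conventions where the analysis
  design they reproduce is silent; each is documented above and
  configurable where it matters.
- The elastic-net search treats the nine C values as a glmnet path per
  l1 ratio; at extreme corners (huge C, ridge, separable folds) the
  solver may stop at its iteration cap with a warning and use the best
  iterate.
- Offset-invariance of global-mean normalization is exact only for
  detected wells (see above).
- The criterion axis of the forest grid does not change the split
  impurity (Gini throughout).
- No probability calibration, no additional learners, no external
  validation-cohort logic, and no bundled third-party target or
  gene-set content — formats are supported, fixtures are simulated.
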