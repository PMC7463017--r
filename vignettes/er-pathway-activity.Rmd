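---
title: "Measuring ER pathway activity: model, calibration and cohort analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring ER pathway activity: model, calibration and cohort analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eractivity)
```

## The problem

Immunohistochemical (IHC) staining for the oestrogen receptor (ER) measures
whether the receptor protein is present in tumour nuclei. It does not
measure whether the ER transcriptional programme is actually active: the
receptor requires ligand (locally available oestradiol) and co-factors, so
ER can be abundantly expressed yet transcriptionally silent. For hormone
driven tumours such as endometrioid endometrial cancer this distinction
matters — functional pathway activity, not receptor abundance, is the
biology one wants to read out. The approach implemented here infers the
odds that the ER transcription complex is active from the mRNA levels of
its target genes, using a small Bayesian network calibrated on samples of
known pathway state.

## The network and its inference

Three node types form a tree rooted at the transcription-factor node:

* **TF** ∈ {active, inactive}: the ER transcription complex state, with
  prior `prior_active` (default 0.5, so the score is purely evidence
  driven; the prior is a free parameter of `pathway_model()`).
* **R_g** ∈ {up, down} per target gene: the gene's regulation state, linked
  to TF by P(R = up | TF = active) = `regulation_fidelity` (default 0.95)
  and P(R = up | TF = inactive) = 1 − `regulation_fidelity`. The regulation
  layer is knowledge based — it encodes "this gene is an ER target" —
  so a fixed, near-deterministic link is used rather than a fitted one.
* **I_g** ∈ {high, low} per gene: the measured intensity state, linked to
  R_g by the intensity CPTs P(I = high | R), which *are* fitted.

Continuous expression never enters the network directly. Each measurement
is converted to *soft evidence*: a weight `e ∈ [0, 1]` on I = high, the
posterior responsibility of the "high" component of a two-component normal
model fitted per gene on the calibration classes (`fit_intensity_map()`,
`expression_to_evidence()`). With equal component SDs this reduces to a
logistic function of expression, which the tests verify against the closed
form. A virtual-evidence weight was chosen over hard thresholding because
it is monotone, differentiable-in-data, and preserves measurement
uncertainty near the class boundary; how the published commercial model
discretises expression is not public, so this is this package's own design
choice.

Because the graph is a tree, marginalising each gene's R and I nodes gives
a per-gene likelihood ratio (`gene_likelihood_ratio()`), and the posterior
log2 odds are the prior log2 odds plus the sum of per-gene log2 LRs
(`infer_log2_odds()`). An exponential-time joint enumeration over all node
configurations (`brute_force_posterior()`) is kept as an independent test
oracle; the suite checks agreement to 1e-10 on hundreds of random models.
Genes without a measurement contribute LR = 1 — they are ignored, not
imputed — and `n_genes_used` is reported so downstream analyses can flag
thin evidence.

### The 0–100 score

Each gene's LR is monotone in its evidence weight, so the model's reachable
log2-odds extremes are attained with every gene at evidence 0 or 1
(`compute_score_range()`; verified against a grid search). The score is the
affine map of the log2 odds from `[log2_odds_min, log2_odds_max]` onto
[0, 100]: 0 is the lowest and 100 the highest odds the model can infer.
A model whose range is empty (all genes uninformative) is rejected rather
than silently producing constant scores. Scores are clamped to [0, 100]
with a warning if floating-point drift exceeds 1e-9 — by construction
nothing else can leave the range.

## Calibration

`calibrate_model()` wires the stages: fit intensity maps on ground-truth
active/inactive samples (emulating oestradiol-stimulated vs deprived cell
lines), select target genes, estimate CPTs, compute the score range.

* **Gene selection** uses the directional Mann–Whitney AUC
  `max(auc, 1 − auc)` computed by exact pair counting (`rank_auc()`), with
  threshold 0.8 and at most 20 genes, ties broken lexicographically. AUC
  was chosen as the ranking statistic because it is rank based, matches the
  "best-performing gene" selection criterion, and is invariant to monotone
  transforms of expression; the threshold 0.8 keeps only genes that
  individually separate the classes well. Repressed ER targets are
  supported: a gene whose expression falls under activity simply has
  AUC < 0.5 and competes through its directional AUC, with the direction
  flag stored.
* **CPT estimation** (`estimate_cpts()`): P(I = high | R = up) is the
  Laplace-smoothed (pseudocount 1) mean evidence in the active class, and
  P(I = high | R = down) the same in the inactive class. For a repressed
  gene this yields P(high|up) < P(high|down), so its likelihood ratio
  decreases in evidence — direction is carried by the CPTs themselves and
  no evidence flipping is needed at scoring time. Smoothing guarantees all
  probabilities lie strictly in (0, 1), keeping every LR finite.
* **Sigma floor** 0.05 log2 units on the intensity-map SDs prevents a
  zero-variance calibration class from producing infinite certainty.

qPCR data enter through `normalize_qpcr()`: technical replicates averaged
on the Cq scale, per-sample reference level = arithmetic mean of the
reference-gene Cq values (equivalent to the geometric mean on the
expression scale — the standard ΔCq convention), log2 relative expression
= −ΔCq. Models carry a platform tag and refuse matrices of the other
platform.

## The synthetic-data generator

No public expression or outcome data accompany this implementation, so the
generator is first-class, tested code that defines the study conditions end
to end. A single latent activity *a* ∈ [0, 100] per sample drives
everything (shared-latent design):

* **Expression**: informative genes shift linearly with *a*, spanning
  `effect_size` log2 units (default 2) between *a* = 0 and *a* = 100, with
  N(0, `noise_sd` = 1) measurement noise; direction random per gene, fixed
  by seed. The default panel has 60 genes with one third informative —
  a realistic candidate-panel yield, and effect 2 at noise 1 gives a
  per-gene class AUC of Φ(2/√2) ≈ 0.92, a strong but imperfect single
  marker. Calibration classes sit at *a* = 100 and *a* = 0.
* **Tissue groups**: *a* ~ N(group mean, group SD) truncated to [0, 100],
  with the published group parameters as defaults: proliferative
  endometrium (41, 8), hyperplasia (43, 4), stage I EEC (36, 11), stage
  II–IV EEC (31, 9), USC (28, 13); cohort sizes default to the published
  4/20/57/12/14.
* **IHC**: ER and PR staining percentage = clamp(1.5·a − 10 + N(0, 15), 0,
  100). The noise SD of 15 points deliberately reproduces the loose
  coupling between staining and pathway activity; no published correlation
  coefficient exists to match, so the link is tunable and not claimed to
  reproduce unpublished values.
* **Outcomes**: recurrence times are exponential with rate
  `baseline_hazard · exp(hazard_coef · (50 − a)/10)` (defaults 0.002/month
  and 0.8 per 10 activity points), disease-specific death at 0.6× that
  rate, administrative censoring uniform on 36–120 months (the cohort's
  minimum follow-up to its maximum). These defaults give five-year
  recurrence risks of roughly 15% at activity 50 rising towards 50% at
  activity 28 — the right order for the published group rates.
  Histological covariates and residual-disease flags are drawn at the
  published group frequencies (4 USC and 1 stage II–IV EEC exclusions at
  the default sizes).

What the generator does **not** emulate: probe-level microarray artefacts,
batch effects between cohorts, platform-specific dynamic ranges, menstrual
cycle dynamics beyond group means, and correlation between target genes
beyond the shared latent (real ER targets are co-regulated by more than one
factor). Passing tests therefore demonstrate internal consistency of the
pipeline under a faithful-but-idealised data model, not performance on
clinical data.

### Score scale and recalibration

The raw score is a monotone but nonlinear readout of the latent activity:
it compresses near the extremes and its slope depends on noise and panel
size, and measurement noise adds variance on top of the biological spread.
`activity_scale_calibration()` estimates the readout curve by simulating
samples at known activities on a grid (step 5, 400 samples per point) and
`recalibrate_scores()` inverts it by interpolation. The loop-closure
property test checks that recalibrated group means match the configured
(truncated-normal) means within 3 standard errors at 5000 samples per
group, and that group SDs match after subtracting the independently
estimated measurement variance — the raw SD *cannot* equal the latent SD in
the presence of measurement noise, so the deconvolved comparison is the
meaningful one, at an accuracy of 1.5 points dominated by the heterogeneity
of measurement variance across each group's activity range.

## Cohort statistics

`assign_groups()` implements the published grouping rules: IHC bins 0–10 /
11–50 / 51–100% with inclusive upper bounds, ER-low = IHC ≤ 10%, activity
quartiles by sample-quantile cut with ties to the lower quartile
(deterministic; coincident boundaries collapse downwards), combined
high-risk = ER-low AND first quartile. Group comparisons use one-way ANOVA
with Tukey HSD (plus Mann–Whitney for two-group calls and χ² for
categorical tables); survival uses Kaplan–Meier with two-sided log-rank
tests and Cox regression with Efron tie handling (the published analysis
used a standard package without stating its tie method; Efron is the
better approximation and the default here). Patients with residual disease
are excluded from every DFS analysis (`dfs_records()`); DFS and DSS clocks
run from surgery, a choice the source leaves open. Multivariate Cox models
include exactly the covariates with univariate two-sided p ≤ 0.05;
non-estimable covariates (constant, separated, non-converged) are reported
as such, never silently dropped.

## Numerical and testing choices

Evidence responsibilities are computed from log densities through the
logistic function, so extreme expression values saturate gracefully rather
than dividing by zero. All tie-breaks (gene selection, quartiles) are
deterministic. Problem sizes in the test suite are chosen to keep the whole
suite fast while leaving clear statistical margins: 500 random models for
the inference-oracle sweep, n = 500 for CPT recovery (binomial SE ≈ 0.013
against a ±0.05 band), 2000 patients for hazard-coefficient recovery
(±25% band), 1000 replicates for the type-I-error check of the
group-comparison stage (SE ≈ 0.007 against a ±0.02 band), and 5000 samples
per group for the moment-fidelity loop closure.

## Limitations

The gene panel, CPT values and discretisation of the commercial ER test
are proprietary and are not reproduced; this implementation is
panel-agnostic and must be calibrated by the user on their own ground-truth
design. Cross-platform (microarray → qPCR) agreement is demonstrated only
on synthetic paired data. Between-cohort batch shifts in intensity scale
are not modelled — an intensity map fitted on one cohort's scale should not
be applied to another without renormalisation. The clinical conclusions of
the original study are not reproducible here because its cohort is not
public; every quantitative claim in this package is about the synthetic
study conditions its tests construct.
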