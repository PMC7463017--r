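# eractivity

Quantifying oestrogen receptor (ER) pathway *activity* — not just receptor
expression — from target-gene mRNA measurements, and relating it to outcome
in endometrial cancer cohorts.

ER immunohistochemistry (IHC) tells you whether the receptor protein is
present; it does not tell you whether the ER transcriptional programme is
actually running. This package implements the full analysis pipeline for
the functional alternative: a knowledge-based Bayesian network that infers
the odds of an active ER transcription complex from the mRNA levels of its
target genes, calibrated on ground-truth samples of known pathway state
(oestradiol-stimulated vs deprived cell lines), plus the downstream cohort
statistics — group comparisons, IHC and activity-quartile risk grouping,
Kaplan–Meier/log-rank survival and Cox regression — used to evaluate its
prognostic value. It is aimed at computational biologists who want a
transparent, testable, panel-agnostic reimplementation of this class of
pathway test.

## The model

The network has three node types: a transcription-factor activation node
TF ∈ {active, inactive}; per target gene a regulation node R ∈ {up, down};
and per gene an expression-intensity node I ∈ {high, low}. Continuous
expression enters as *soft evidence* — a weight e ∈ [0, 1] on I = high,
computed as the responsibility of the "high" component of a two-component
normal intensity model fitted on the calibration classes. Because the graph
is a tree rooted at TF, the posterior odds factorise:

```
log2 O(active | e) = log2 [P(TF=active) / P(TF=inactive)] + Σ_g log2 LR_g(e_g)

LR_g(e) = Σ_r P(r | active) [e·P(high|r) + (1−e)·P(low|r)]
          ──────────────────────────────────────────────────
          Σ_r P(r | inactive) [e·P(high|r) + (1−e)·P(low|r)]
```

The log2 odds are normalised affinely against the extremes the model can
reach, giving an activity score where 0 is the lowest and 100 the highest
odds the model can infer. Calibration estimates the intensity-layer CPTs
P(I = high | R) as pseudocount-smoothed class-conditional mean evidence;
target genes are selected by directional Mann–Whitney AUC. qPCR input is
supported through reference-gene ΔCq normalisation (log2 relative
expression = reference-mean Cq − target Cq).

## Worked example

The numbered scripts under `analysis/` run the whole study on synthetic
data (simulate → calibrate → score → cohort statistics → survival):

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_calibrate.R
Rscript analysis/03_score.R
Rscript analysis/04_cohort_statistics.R
Rscript analysis/05_survival.R
```

Stage 2 reports the calibrated model:

```
Pathway activity model (array): 20 target genes
  prior P(active) = 0.500; log2-odds range [-31.069, 31.020]
20 of 60 candidate genes selected (directional AUC >= 0.8)
```

i.e. all 20 simulated responsive genes were recovered, none of the 40 noise
genes, and the score range is symmetric because the prior is neutral.
Stage 4 then reports, on the 107-sample synthetic cohort,

```
Recurrent vs non-recurrent mean score: 40.4 (SD 8.7) vs 45.4 (SD 7.4)
```

— recurrent patients have lower pathway activity, the association the
generator builds in through a shared latent activity that drives both
expression and hazard. Stage 5 closes with the survival structure:

```
DFS log-rank by activity quartile:  chi2 = 10.46, p = 0.0151
DFS log-rank combined ER-low & Q1:  chi2 = 3.16, p = 0.0753
End-of-follow-up DFS estimate:  ER-low & Q1: 0.00   other: 0.51
```

Patients combining low ER IHC (0–10%) with a first-quartile activity score
have the worst disease-free survival, and in multivariate Cox regression
the individual markers lose significance — the qualitative pattern the
pipeline is designed to expose. Equivalent calls are available directly in
R (`generate_cohort()`, `calibrate_model()`, `score_cohort()`,
`assign_groups()`, `km_logrank()`, `cox_regression()`); see the vignette.

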