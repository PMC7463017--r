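#!/usr/bin/env Rscript
# Stage 3: score the cohort, blinded.
#
# Applies the calibrated model to the cohort expression matrix. This stage
# never touches the clinical table: per-sample evidence is computed from
# expression alone, fed through the Bayesian network, and the log2 posterior
# odds are normalised to the 0-100 activity score.

library(eractivity)

dir <- "results/pipeline"
scores <- run_score(file.path(dir, "model.json"),
                    file.path(dir, "cohort_expression.tsv"), dir)

cat(sprintf("Scored %d samples; score range [%.1f, %.1f], median %.1f\n",
            nrow(scores), min(scores$score), max(scores$score),
            median(scores$score)))
cat(sprintf("Genes used per sample: %d\n", scores$n_genes_used[1]))
cat("Scores table: ", file.path(dir, "scores.tsv"), "\n")
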