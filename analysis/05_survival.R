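#!/usr/bin/env Rscript
# Stage 5: survival analyses.
#
# Kaplan-Meier / log-rank for DFS by ER IHC cut-off (10%), by activity
# quartile, and for the combined risk group (ER IHC 0-10% AND activity in
# the first quartile); univariate Cox regression of the standard prognostic
# factors plus pathway activity. Residual-disease patients are excluded from
# all DFS analyses. Curve data and Cox tables were written by stage 4's
# run_analyze call; this stage reports them.

library(eractivity)

dir <- "results/pipeline"
res <- run_analyze(file.path(dir, "scores.tsv"),
                   file.path(dir, "cohort_clinical.csv"), dir)

cat(sprintf("DFS log-rank by ER IHC cut-off 10%%: chi2 = %.2f, p = %.3g\n",
            res$km_er$logrank_chisq, res$km_er$logrank_p))
cat(sprintf("DFS log-rank by activity quartile:  chi2 = %.2f, p = %.3g\n",
            res$km_quartiles$logrank_chisq, res$km_quartiles$logrank_p))
cat(sprintf("DFS log-rank combined ER-low & Q1:  chi2 = %.2f, p = %.3g\n",
            res$km_combined$logrank_chisq, res$km_combined$logrank_p))

final <- tapply(res$km_combined$curves$estimate,
                res$km_combined$curves$group, min)
cat("\nEnd-of-follow-up DFS estimate:\n")
print(round(final, 3))

cat("\nUnivariate Cox regression (DFS):\n")
print(res$cox_univariate[, c("term", "hr", "ci_lower", "ci_upper", "p")])
if (!is.null(res$cox_multivariate) && nrow(res$cox_multivariate)) {
  cat("\nMultivariate Cox regression (univariately significant factors):\n")
  print(res$cox_multivariate[, c("term", "hr", "ci_lower", "ci_upper", "p")])
}
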