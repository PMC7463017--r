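#' Score every sample of an expression matrix
#'
#' Pipeline composition: expression to soft evidence
#' (\code{\link{matrix_to_evidence}}), evidence to log2 posterior odds, odds
#' to the 0-100 activity score. Scoring touches only the expression matrix;
#' no clinical field enters (samples are scored blinded).
#'
#' @param model calibrated \code{pathway_model}.
#' @param maps intensity map matching the model's genes.
#' @param matrix genes x samples log2 expression matrix. If it carries a
#'   \code{"platform"} attribute it must match the model's platform.
#' @return data.frame (sample_id, log2_odds, score, n_genes_used).
#' @export
score_cohort <- function(model, maps, matrix) {
  stopifnot(inherits(model, "pathway_model"))
  plat <- attr(matrix, "platform")
  if (!is.null(plat) && !identical(plat, model$platform))
    stop(sprintf("platform mismatch: model is '%s', matrix is '%s'",
                 model$platform, plat))
  ev <- matrix_to_evidence(maps, matrix)
  shared <- intersect(model$genes$gene_id, rownames(ev))
  if (length(shared) == 0L)
    stop("no overlap between model genes and evidence genes")
  g <- model$genes[match(shared, model$genes$gene_id), , drop = FALSE]
  e <- ev[shared, , drop = FALSE]
  b_up   <- e * g$p_high_given_up   + (1 - e) * (1 - g$p_high_given_up)
  b_down <- e * g$p_high_given_down + (1 - e) * (1 - g$p_high_given_down)
  lr <- (g$p_up_given_active   * b_up + (1 - g$p_up_given_active)   * b_down) /
        (g$p_up_given_inactive * b_up + (1 - g$p_up_given_inactive) * b_down)
  l2 <- log2(model$prior_active / (1 - model$prior_active)) +
    colSums(log2(lr), na.rm = TRUE)
  data.frame(sample_id = colnames(matrix),
             log2_odds = unname(l2),
             score = unname(normalize_score(model, l2)),
             n_genes_used = unname(colSums(!is.na(e))),
             stringsAsFactors = FALSE)
}

#' Assign IHC bins, activity quartiles and the combined risk group
#'
#' IHC percentages are binned with inclusive upper bounds as published
#' (0-10, 11-50, 51-100); the low-expression flag uses the 10 percent
#' cut-off. Activity quartiles are a sample-quantile cut of the scores (Q1 =
#' lowest quartile), with boundary ties assigned to the lower quartile. The
#' combined high-risk group is low ER IHC (0-10 percent) together with an
#' activity score in the first quartile.
#'
#' @param records clinical data.frame with \code{er_ihc_pct} (and optionally
#'   \code{pr_ihc_pct}).
#' @param scores numeric activity scores aligned with \code{records} rows.
#' @return \code{records} with added columns er_ihc_bin, pr_ihc_bin (if PR
#'   present), er_low, score, activity_quartile, combined_high_risk. Records
#'   without ER IHC get \code{NA} bins and are counted in attribute
#'   \code{"n_missing_ihc"}.
#' @export
assign_groups <- function(records, scores) {
  stopifnot(nrow(records) == length(scores))
  bin_ihc <- function(p)
    cut(p, breaks = c(-Inf, 10, 50, 100), labels = c("0-10", "11-50", "51-100"))
  out <- records
  out$score <- scores
  out$er_ihc_bin <- bin_ihc(records$er_ihc_pct)
  if ("pr_ihc_pct" %in% names(records))
    out$pr_ihc_bin <- bin_ihc(records$pr_ihc_pct)
  out$er_low <- records$er_ihc_pct <= 10
  qs <- stats::quantile(scores, probs = c(0.25, 0.5, 0.75), na.rm = TRUE,
                        names = FALSE)
  # (a, b] intervals: a score equal to a quartile boundary falls in the
  # lower quartile -- deterministic tie policy. Coincident boundaries (heavy
  # ties) collapse onto the lowest quartile they delimit.
  br <- c(-Inf, qs, Inf)
  lab <- c("Q1", "Q2", "Q3", "Q4")
  keep <- !duplicated(br)
  out$activity_quartile <- factor(
    as.character(cut(scores, breaks = br[keep],
                     labels = lab[keep[-1]])),
    levels = lab)
  out$combined_high_risk <- out$er_low &
    out$activity_quartile == "Q1"
  attr(out, "n_missing_ihc") <- sum(is.na(records$er_ihc_pct))
  out
}

#' Compare activity scores across groups
#'
#' One-way ANOVA omnibus F test with Tukey HSD adjusted pairwise
#' comparisons; for two groups a Mann-Whitney U test is also reported, and
#' \code{\link{chisq_table}} covers categorical tables. Singleton groups are
#' excluded from the pairwise stage with a warning.
#'
#' @param scores numeric response values.
#' @param groups group labels (coerced to factor).
#' @return List of class \code{group_comparison} with the F statistic and
#'   p-value, the Tukey table (diff, lwr, upr, p_adj per pair), group
#'   means/SDs/sizes, and \code{mann_whitney_p} when exactly two groups.
#' @export
group_comparison <- function(scores, groups) {
  groups <- factor(groups)
  keep <- !is.na(scores) & !is.na(groups)
  scores <- scores[keep]; groups <- droplevels(groups[keep])
  sizes <- table(groups)
  if (any(sizes < 2)) {
    warning("singleton group(s) excluded from comparison: ",
            paste(names(sizes)[sizes < 2], collapse = ", "))
    ok <- groups %in% names(sizes)[sizes >= 2]
    scores <- scores[ok]; groups <- droplevels(groups[ok])
  }
  if (nlevels(groups) < 2) stop("need at least two groups of size >= 2")
  fit <- stats::aov(scores ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  tukey <- data.frame(pair = rownames(tk), tk, row.names = NULL,
                      check.names = FALSE)
  names(tukey) <- c("pair", "diff", "lwr", "upr", "p_adj")
  res <- list(f_statistic = an[["F value"]][1],
              p_value = an[["Pr(>F)"]][1],
              tukey = tukey,
              group_stats = data.frame(
                group = levels(groups),
                n = as.integer(table(groups)),
                mean = as.numeric(tapply(scores, groups, mean)),
                sd = as.numeric(tapply(scores, groups, stats::sd)),
                stringsAsFactors = FALSE))
  if (nlevels(groups) == 2) {
    res$mann_whitney_p <- stats::wilcox.test(
      scores[groups == levels(groups)[1]],
      scores[groups == levels(groups)[2]], exact = FALSE)$p.value
  }
  class(res) <- "group_comparison"
  res
}

#' Chi-squared test on a categorical contingency table
#'
#' Thin wrapper kept on the analysis surface so categorical comparisons
#' (e.g. recurrence by tissue group) run through one audited call; the
#' classical statistic without continuity correction is used so hand
#' calculations on published tables match exactly.
#'
#' @param tab contingency table (matrix or table).
#' @return List with statistic, df and p_value.
#' @export
chisq_table <- function(tab) {
  ct <- stats::chisq.test(tab, correct = FALSE)
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, expected = ct$expected)
}

#' Kaplan-Meier curves and log-rank test per group
#'
#' Product-limit survival estimates per group with a two-sided log-rank
#' test. Callers performing disease-free-survival analyses must exclude
#' residual-disease patients first (see \code{\link{dfs_records}}).
#'
#' @param times follow-up times (months, >= 0).
#' @param events event indicators (TRUE/1 = event).
#' @param groups group labels.
#' @return List of class \code{km_result} with \code{curves} (data.frame
#'   group, time, estimate, n_risk, n_event), \code{logrank_chisq},
#'   \code{logrank_df}, \code{logrank_p}; when no event occurred the curves
#'   are flat and the log-rank entries are \code{NA} with
#'   \code{no_events = TRUE}.
#' @export
km_logrank <- function(times, events, groups) {
  stopifnot(all(times >= 0, na.rm = TRUE))
  groups <- factor(groups)
  keep <- !is.na(times) & !is.na(events) & !is.na(groups)
  times <- times[keep]; events <- as.integer(events[keep])
  groups <- droplevels(groups[keep])
  if (any(table(groups) == 0) || nlevels(groups) < 1)
    stop("every group must contain at least one subject")
  fit <- survival::survfit(survival::Surv(times, events) ~ groups)
  strata <- if (is.null(fit$strata)) {
    rep(levels(groups)[1], length(fit$time))
  } else {
    rep(sub("^groups=", "", names(fit$strata)), fit$strata)
  }
  curves <- data.frame(group = strata, time = fit$time,
                       estimate = fit$surv, n_risk = fit$n.risk,
                       n_event = fit$n.event, stringsAsFactors = FALSE)
  res <- list(curves = curves, no_events = sum(events) == 0)
  if (res$no_events || nlevels(groups) < 2) {
    res$logrank_chisq <- NA_real_; res$logrank_df <- NA_integer_
    res$logrank_p <- NA_real_
  } else {
    sd <- survival::survdiff(survival::Surv(times, events) ~ groups)
    df <- length(sd$n) - 1
    res$logrank_chisq <- unname(sd$chisq)
    res$logrank_df <- df
    res$logrank_p <- stats::pchisq(sd$chisq, df, lower.tail = FALSE)
  }
  class(res) <- "km_result"
  res
}

#' Records eligible for disease-free-survival analyses
#'
#' Tumour-group patients without residual disease and with a DFS time.
#'
#' @param clinical clinical data.frame.
#' @return Filtered data.frame.
#' @export
dfs_records <- function(clinical) {
  clinical[!is.na(clinical$dfs_months) &
             !(clinical$residual_disease %in% TRUE), , drop = FALSE]
}

#' Cox proportional-hazards regression, univariate and multivariate
#'
#' Univariate mode fits each covariate alone; multivariate mode refits
#' jointly the covariates whose univariate two-sided p-value is at most
#' \code{alpha}. Ties are handled by the Efron approximation. Covariates
#' that cannot be estimated (constant, separated, or non-converged fits)
#' are reported as non-estimable rather than dropped silently.
#'
#' @param covariates data.frame of covariates (numeric or factor columns).
#' @param times follow-up times.
#' @param events event indicators.
#' @param mode \code{"univariate"} or \code{"multivariate"}.
#' @param alpha univariate inclusion threshold for the multivariate stage.
#' @return data.frame (term, covariate, hr, ci_lower, ci_upper, p,
#'   estimable, mode).
#' @export
cox_regression <- function(covariates, times, events,
                           mode = c("univariate", "multivariate"),
                           alpha = 0.05) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(covariates), nrow(covariates) == length(times))
  if (sum(events, na.rm = TRUE) < 1) stop("need at least one event")
  surv <- survival::Surv(times, as.integer(events))

  fit_one <- function(df, covariate_label, mode_label) {
    bad <- vapply(df, function(x) length(unique(x[!is.na(x)])) < 2, logical(1))
    if (any(bad)) {
      return(data.frame(term = names(df)[bad], covariate = names(df)[bad],
                        hr = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, p = NA_real_,
                        estimable = FALSE, mode = mode_label,
                        stringsAsFactors = FALSE))
    }
    fit <- tryCatch(
      suppressWarnings(survival::coxph(surv ~ ., data = df, ties = "efron")),
      error = function(e) NULL)
    if (is.null(fit) ||
        any(!is.finite(sqrt(diag(as.matrix(fit$var))))) ||
        any(abs(stats::coef(fit)) > 15)) {
      return(data.frame(term = names(df), covariate = names(df),
                        hr = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, p = NA_real_,
                        estimable = FALSE, mode = mode_label,
                        stringsAsFactors = FALSE))
    }
    sm <- summary(fit)
    co <- sm$coefficients
    ci <- sm$conf.int
    terms_to_cov <- function(terms) {
      out <- rep(NA_character_, length(terms))
      for (v in names(df)) out[startsWith(terms, v)] <- v
      out
    }
    data.frame(term = rownames(co),
               covariate = terms_to_cov(rownames(co)),
               hr = unname(co[, "exp(coef)"]),
               ci_lower = unname(ci[, "lower .95"]),
               ci_upper = unname(ci[, "upper .95"]),
               p = unname(co[, "Pr(>|z|)"]),
               estimable = TRUE, mode = mode_label,
               stringsAsFactors = FALSE)
  }

  uni <- do.call(rbind, lapply(names(covariates), function(v)
    fit_one(covariates[, v, drop = FALSE], v, "univariate")))
  if (mode == "univariate") return(uni)

  sig <- unique(uni$covariate[uni$estimable & !is.na(uni$p) & uni$p <= alpha])
  if (length(sig) == 0L) {
    warning("no covariate significant in univariate analysis; ",
            "multivariate model not fitted")
    return(uni[0, ])
  }
  fit_one(covariates[, sig, drop = FALSE],
          paste(sig, collapse = "+"), "multivariate")
}
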