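#' Configuration for the synthetic-data generator
#'
#' The generator emulates every input the pipeline needs: oestradiol
#' stimulated/deprived ground-truth calibration sets, and a clinical cohort
#' in which a latent pathway activity on the 0-100 scale drives target-gene
#' expression, hormone-receptor IHC staining and recurrence/death hazards
#' (shared-latent design, so the association structure is true by
#' construction and recoverable). Group activity distributions default to
#' the published tissue-group means and SDs.
#'
#' @param n_genes number of genes on the simulated panel.
#' @param fraction_informative fraction of genes whose expression responds
#'   to pathway activity.
#' @param effect_size log2 expression shift between the fully active and
#'   fully inactive state for an informative gene.
#' @param noise_sd per-measurement log2 noise SD.
#' @param group_params data.frame (tissue, mean, sd) of latent-activity
#'   distributions per tissue group on the 0-100 scale.
#' @param baseline_hazard recurrence hazard per month at activity 50.
#' @param dss_hazard_frac disease-specific-death hazard as a fraction of the
#'   recurrence hazard.
#' @param hazard_coef log-hazard increase per 10-point decrease of activity
#'   below 50.
#' @param censor_window_months administrative censoring drawn uniformly over
#'   this window (months).
#' @param ihc_slope,ihc_intercept,ihc_noise_sd linear link from activity to
#'   ER/PR IHC percentage, with normal noise, clamped to [0, 100]. The noise
#'   SD of 15 points reproduces the loose coupling between staining and
#'   pathway activity seen in practice.
#' @param seed base RNG seed; identical config and seed give identical
#'   output.
#' @return List of class \code{generator_config}.
#' @export
generator_config <- function(n_genes = 60L,
                             fraction_informative = 1 / 3,
                             effect_size = 2,
                             noise_sd = 1,
                             group_params = default_group_params(),
                             baseline_hazard = 0.002,
                             dss_hazard_frac = 0.6,
                             hazard_coef = 0.8,
                             censor_window_months = c(36, 120),
                             ihc_slope = 1.5,
                             ihc_intercept = -10,
                             ihc_noise_sd = 15,
                             seed = 1L) {
  stopifnot(n_genes >= 1, fraction_informative >= 0, fraction_informative <= 1,
            noise_sd > 0, all(group_params$sd > 0), baseline_hazard > 0,
            length(censor_window_months) == 2L,
            censor_window_months[1] <= censor_window_months[2])
  structure(list(n_genes = as.integer(n_genes),
                 fraction_informative = fraction_informative,
                 effect_size = effect_size,
                 noise_sd = noise_sd,
                 group_params = group_params,
                 baseline_hazard = baseline_hazard,
                 dss_hazard_frac = dss_hazard_frac,
                 hazard_coef = hazard_coef,
                 censor_window_months = censor_window_months,
                 ihc_slope = ihc_slope,
                 ihc_intercept = ihc_intercept,
                 ihc_noise_sd = ihc_noise_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Published tissue-group activity distributions (0-100 scale)
#' @return data.frame with columns tissue, mean, sd.
#' @export
default_group_params <- function() {
  data.frame(tissue = c("proliferative", "hyperplasia", "eec_stage_i",
                        "eec_stage_ii_iv", "usc"),
             mean = c(41, 43, 36, 31, 28),
             sd = c(8, 4, 11, 9, 13),
             stringsAsFactors = FALSE)
}

#' Default cohort group sizes (clinical-cohort structure)
#' @return named integer vector.
#' @export
default_group_sizes <- function() {
  c(proliferative = 4L, hyperplasia = 20L, eec_stage_i = 57L,
    eec_stage_ii_iv = 12L, usc = 14L)
}

# Gene-level panel parameters derive from the config seed alone, so the
# calibration set and any cohort share the same informative genes,
# directions and baselines.
gene_panel <- function(config) {
  set.seed(config$seed)
  n <- config$n_genes
  ids <- sprintf("gene%03d", seq_len(n))
  k <- round(config$fraction_informative * n)
  informative <- logical(n)
  if (k > 0) informative[sample.int(n, k)] <- TRUE
  data.frame(gene_id = ids,
             baseline = stats::runif(n, 4, 10),
             informative = informative,
             direction = ifelse(stats::runif(n) < 0.5, -1L, 1L),
             stringsAsFactors = FALSE)
}

# Expression at latent activity a (0-100): informative genes shift linearly
# with a, spanning effect_size log2 units between a = 0 and a = 100.
panel_expression <- function(panel, activity, noise_sd, effect_size) {
  slope <- ifelse(panel$informative, panel$direction, 0L) * effect_size
  # genes x samples mean; baseline recycles down columns
  mu <- panel$baseline + outer(slope, activity / 100 - 0.5)
  mu + matrix(stats::rnorm(length(mu), 0, noise_sd), nrow(mu))
}

#' Generate a ground-truth calibration set
#'
#' Emulates the stimulated/deprived cell-line design: active samples sit at
#' latent activity 100 and inactive samples at 0, so each informative gene
#' is shifted by plus or minus half the effect size in either class (full
#' between-class shift = \code{effect_size}), with normal measurement noise.
#' Uninformative genes are identically distributed in both classes. The
#' per-gene shift direction is random but fixed by the config seed.
#'
#' @param config a \code{generator_config}.
#' @param n_per_class samples per class (>= 3).
#' @param seed RNG seed for the sample draw (defaults to the config seed
#'   plus one, so the draw is independent of the panel assignment).
#' @return List with \code{matrix} (genes x samples, log2), \code{labels}
#'   and \code{panel} (the gene-level truth table).
#' @export
generate_calibration_set <- function(config, n_per_class = 50L,
                                     seed = config$seed + 1L) {
  stopifnot(n_per_class >= 3L)
  panel <- gene_panel(config)
  set.seed(seed)
  activity <- rep(c(100, 0), each = n_per_class)
  labels <- rep(c("active", "inactive"), each = n_per_class)
  x <- panel_expression(panel, activity, config$noise_sd, config$effect_size)
  dimnames(x) <- list(panel$gene_id,
                      sprintf("calib%03d", seq_along(labels)))
  attr(x, "platform") <- "array"
  list(matrix = x, labels = labels, panel = panel)
}

# inverse-CDF draw from a normal truncated to [lo, hi] (deterministic given
# the RNG stream; no rejection loop)
rtruncnorm_inv <- function(n, mean, sd, lo = 0, hi = 100) {
  p_lo <- stats::pnorm(lo, mean, sd)
  p_hi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(p_lo + stats::runif(n) * (p_hi - p_lo), mean, sd)
}

#' Generate a synthetic clinical cohort
#'
#' Each patient receives a latent pathway activity drawn from their tissue
#' group's truncated-normal distribution; the activity then drives (i)
#' target-gene expression through the shared gene panel, (ii) ER and PR IHC
#' percentages through a noisy linear link clamped to [0, 100], and (iii)
#' recurrence and disease-specific-death times, exponential with rate
#' \code{baseline_hazard * exp(hazard_coef * (50 - activity) / 10)} (deaths
#' at a fraction of that rate), administratively censored uniformly over the
#' censoring window. Histological covariates (grade, FIGO stage, LVSI, deep
#' myometrial invasion) and residual-disease flags are assigned at the
#' published group frequencies; residual-disease counts match the published
#' exclusions (4 USC, 1 stage II-IV EEC at the default group sizes, scaled
#' proportionally otherwise). Tumour outcomes are generated for the three
#' cancer groups only.
#'
#' @param config a \code{generator_config}.
#' @param group_sizes named integer vector of samples per tissue group
#'   (names from \code{\link{default_group_params}}).
#' @param seed RNG seed for the cohort draw (defaults to config seed + 2).
#' @return List with \code{expression} (genes x samples matrix),
#'   \code{clinical} (one row per patient, including the latent
#'   \code{activity_latent} used to generate the data) and \code{panel}.
#' @export
generate_cohort <- function(config, group_sizes = default_group_sizes(),
                            seed = config$seed + 2L) {
  stopifnot(all(group_sizes >= 1L))
  gp <- config$group_params
  if (!all(names(group_sizes) %in% gp$tissue))
    stop("unknown tissue group(s): ",
         paste(setdiff(names(group_sizes), gp$tissue), collapse = ", "))
  panel <- gene_panel(config)
  set.seed(seed)

  tissue <- rep(names(group_sizes), group_sizes)
  n <- length(tissue)
  mu <- gp$mean[match(tissue, gp$tissue)]
  sdv <- gp$sd[match(tissue, gp$tissue)]
  activity <- rtruncnorm_inv(n, mu, sdv)

  x <- panel_expression(panel, activity, config$noise_sd, config$effect_size)
  sample_ids <- sprintf("S%04d", seq_len(n))
  dimnames(x) <- list(panel$gene_id, sample_ids)
  attr(x, "platform") <- "array"

  ihc <- function() pmin(pmax(config$ihc_slope * activity +
                                config$ihc_intercept +
                                stats::rnorm(n, 0, config$ihc_noise_sd),
                              0), 100)
  er <- ihc(); pr <- ihc()

  tumour <- tissue %in% c("eec_stage_i", "eec_stage_ii_iv", "usc")
  rate_rec <- config$baseline_hazard *
    exp(config$hazard_coef * (50 - activity) / 10)
  t_rec <- stats::rexp(n, rate_rec)
  t_death <- stats::rexp(n, rate_rec * config$dss_hazard_frac)
  cens <- stats::runif(n, config$censor_window_months[1],
                       config$censor_window_months[2])
  recurrence <- tumour & (t_rec <= cens)
  ec_death <- tumour & (t_death <= cens)
  dfs <- ifelse(tumour, pmin(t_rec, cens), NA_real_)
  dss <- ifelse(tumour, pmin(t_death, cens), NA_real_)

  # published group frequencies for the histological covariates
  p_high_grade <- c(proliferative = 0, hyperplasia = 0,
                    eec_stage_i = 6 / 57, eec_stage_ii_iv = 5 / 12, usc = 1)
  p_lvsi <- c(proliferative = 0, hyperplasia = 0,
              eec_stage_i = 11 / 57, eec_stage_ii_iv = 9 / 12, usc = 8 / 14)
  p_deep_mi <- c(proliferative = 0, hyperplasia = 0,
                 eec_stage_i = 15 / 57, eec_stage_ii_iv = 9 / 12, usc = 8 / 14)
  grade <- ifelse(tumour,
                  ifelse(stats::runif(n) < p_high_grade[tissue], "high", "low"),
                  NA_character_)
  lvsi <- tumour & (stats::runif(n) < p_lvsi[tissue])
  deep_mi <- tumour & (stats::runif(n) < p_deep_mi[tissue])

  figo <- rep(NA_character_, n)
  figo[tissue == "eec_stage_i"] <- "I"
  ii <- tissue == "eec_stage_ii_iv"
  figo[ii] <- sample(c("II", "III", "IV"), sum(ii), replace = TRUE,
                     prob = c(4, 5, 3))
  uu <- tissue == "usc"
  figo[uu] <- sample(c("I", "III", "IV"), sum(uu), replace = TRUE,
                     prob = c(4, 3, 7))

  # residual disease: published exclusion counts, scaled with group size
  excl_frac <- c(proliferative = 0, hyperplasia = 0, eec_stage_i = 0,
                 eec_stage_ii_iv = 1 / 12, usc = 4 / 14)
  residual <- logical(n)
  for (tg in unique(tissue)) {
    idx <- which(tissue == tg)
    k <- round(excl_frac[tg] * length(idx))
    if (k > 0) residual[sample(idx, k)] <- TRUE
  }

  clinical <- data.frame(sample_id = sample_ids,
                         tissue = tissue,
                         grade = grade,
                         figo = figo,
                         er_ihc_pct = er,
                         pr_ihc_pct = pr,
                         lvsi = lvsi,
                         deep_mi = deep_mi,
                         residual_disease = residual,
                         recurrence = ifelse(tumour, recurrence, NA),
                         ec_death = ifelse(tumour, ec_death, NA),
                         dfs_months = dfs,
                         dss_months = dss,
                         activity_latent = activity,
                         stringsAsFactors = FALSE)
  list(expression = x, clinical = clinical, panel = panel)
}

#' Calibration curve from raw score to the latent activity scale
#'
#' The raw 0-100 score is a monotone but nonlinear readout of the latent
#' activity (it compresses near the extremes and its slope depends on the
#' measurement noise and panel size). This function estimates the readout
#' curve by simulation: samples are generated at fixed latent activities on
#' a grid, scored, and the mean raw score per grid point recorded. Inverting
#' the curve by interpolation maps raw scores back to the activity scale;
#' the residual spread around the curve estimates the measurement SD of the
#' recalibrated score.
#'
#' @param model calibrated \code{pathway_model}.
#' @param maps intensity map matching the model.
#' @param config the \code{generator_config} the cohort is drawn from.
#' @param grid latent activities to simulate at.
#' @param n_per_point simulated samples per grid point.
#' @param seed RNG seed.
#' @return List of class \code{activity_calibration} with the grid, mean raw
#'   score and measurement SD (on the activity scale) per grid point.
#' @export
activity_scale_calibration <- function(model, maps, config,
                                       grid = seq(0, 100, by = 5),
                                       n_per_point = 400L,
                                       seed = config$seed + 3L) {
  panel <- gene_panel(config)
  set.seed(seed)
  activity <- rep(grid, each = n_per_point)
  x <- panel_expression(panel, activity, config$noise_sd, config$effect_size)
  dimnames(x) <- list(panel$gene_id, sprintf("g%05d", seq_along(activity)))
  raw <- score_cohort(model, maps, x)$score
  mean_raw <- tapply(raw, activity, mean)
  sd_raw <- tapply(raw, activity, stats::sd)
  ord <- order(as.numeric(names(mean_raw)))
  curve <- data.frame(activity = as.numeric(names(mean_raw))[ord],
                      mean_raw = as.numeric(mean_raw)[ord],
                      sd_raw = as.numeric(sd_raw)[ord])
  if (any(diff(curve$mean_raw) <= 0))
    warning("raw-score curve is not strictly increasing on the grid; ",
            "inversion uses the monotone hull")
  # measurement SD mapped to the activity scale via the local slope
  slope <- diff(curve$mean_raw) / diff(curve$activity)
  slope_mid <- c(slope[1], (slope[-1] + slope[-length(slope)]) / 2,
                 slope[length(slope)])
  curve$sd_activity <- curve$sd_raw / pmax(slope_mid, 1e-6)
  structure(list(curve = curve), class = "activity_calibration")
}

#' Map raw scores onto the latent activity scale
#'
#' Linear interpolation of the inverted calibration curve from
#' \code{\link{activity_scale_calibration}}; raw scores outside the curve
#' range map to the nearest endpoint.
#'
#' @param calibration an \code{activity_calibration}.
#' @param raw_scores numeric raw 0-100 scores.
#' @return Recalibrated activities on the 0-100 latent scale.
#' @export
recalibrate_scores <- function(calibration, raw_scores) {
  cv <- calibration$curve
  mr <- cummax(cv$mean_raw)  # monotone hull guards against grid noise
  stats::approx(mr, cv$activity, xout = raw_scores, rule = 2, ties = "ordered")$y
}
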