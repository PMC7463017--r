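test_that("generator output is deterministic given config and seed", {
  cfg <- generator_config(seed = 5L)
  c1 <- generate_calibration_set(cfg)
  c2 <- generate_calibration_set(cfg)
  expect_identical(c1, c2)
  k1 <- generate_cohort(cfg)
  k2 <- generate_cohort(cfg)
  expect_identical(k1, k2)
  k3 <- generate_cohort(cfg, seed = 6L)
  expect_false(identical(k1$clinical$activity_latent,
                         k3$clinical$activity_latent))
})

test_that("noiseless limit shifts informative genes by exactly the effect size", {
  cfg <- generator_config(noise_sd = 1e-9, effect_size = 2, seed = 8L)
  calib <- generate_calibration_set(cfg, n_per_class = 5L)
  act <- calib$matrix[, calib$labels == "active"]
  ina <- calib$matrix[, calib$labels == "inactive"]
  d <- rowMeans(act) - rowMeans(ina)
  info <- calib$panel$informative
  expect_equal(unname(d[info]), 2 * calib$panel$direction[info],
               tolerance = 1e-6)
  expect_equal(unname(d[!info]), rep(0, sum(!info)), tolerance = 1e-6)
})

test_that("with no informative genes downstream selection fails", {
  cfg <- generator_config(fraction_informative = 0, seed = 9L)
  calib <- generate_calibration_set(cfg)
  expect_error(calibrate_model(calib), "threshold")
})

test_that("per-gene AUC matches the closed form for two normals", {
  # effect 2, noise 1: AUC = Phi(2 / (sqrt(2) * 1)) ~ 0.921
  cfg <- generator_config(effect_size = 2, noise_sd = 1, seed = 7L)
  calib <- generate_calibration_set(cfg, n_per_class = 100L)
  expected <- pnorm(2 / sqrt(2))
  info <- which(calib$panel$informative)
  auc <- vapply(info, function(i) {
    a <- rank_auc(calib$matrix[i, calib$labels == "active"],
                  calib$matrix[i, calib$labels == "inactive"])
    max(a, 1 - a)
  }, numeric(1))
  # per-gene binomial-style tolerance ~3 SE; the mean over genes is tighter
  expect_true(all(abs(auc - expected) < 0.09))
  expect_lt(abs(mean(auc) - expected), 0.025)
})

test_that("zero hazard coefficient decouples recurrence from activity", {
  cfg <- generator_config(hazard_coef = 0, seed = 10L)
  coh <- generate_cohort(cfg, group_sizes = c(eec_stage_i = 1000L,
                                              eec_stage_ii_iv = 500L,
                                              usc = 500L))
  cl <- coh$clinical
  q <- cut(cl$activity_latent,
           quantile(cl$activity_latent, c(0, 0.25, 0.5, 0.75, 1)),
           include.lowest = TRUE, labels = paste0("Q", 1:4))
  tab <- table(q, cl$recurrence)
  expect_gt(chisq_table(tab)$p_value, 0.05)
})

test_that("vanishing group SD collapses activities onto the group means", {
  gp <- default_group_params()
  gp$sd <- rep(1e-6, nrow(gp))
  cfg <- generator_config(group_params = gp, seed = 12L)
  coh <- generate_cohort(cfg, group_sizes = c(proliferative = 10L, usc = 10L))
  a <- coh$clinical$activity_latent
  expect_equal(a[coh$clinical$tissue == "proliferative"], rep(41, 10),
               tolerance = 1e-4)
  expect_equal(a[coh$clinical$tissue == "usc"], rep(28, 10), tolerance = 1e-4)
})

test_that("survival generation recovers the hazard model", {
  cfg <- generator_config(seed = 11L)
  coh <- generate_cohort(cfg, group_sizes = c(eec_stage_i = 700L,
                                              eec_stage_ii_iv = 650L,
                                              usc = 650L), seed = 11L)
  cl <- coh$clinical
  fit <- survival::coxph(
    survival::Surv(dfs_months, recurrence) ~ I((50 - activity_latent) / 10),
    data = cl, ties = "efron")
  expect_lt(abs(unname(coef(fit)) - cfg$hazard_coef) / cfg$hazard_coef, 0.25)

  q <- cut(cl$activity_latent,
           quantile(cl$activity_latent, c(0, 0.25, 0.5, 0.75, 1)),
           include.lowest = TRUE, labels = paste0("Q", 1:4))
  km <- km_logrank(cl$dfs_months[q %in% c("Q1", "Q4")],
                   cl$recurrence[q %in% c("Q1", "Q4")],
                   droplevels(q[q %in% c("Q1", "Q4")]))
  expect_lt(km$logrank_p, 0.05)
})

test_that("IHC tracks latent activity through the noisy linear link", {
  cfg <- generator_config(seed = 14L)
  coh <- generate_cohort(cfg, group_sizes = c(eec_stage_i = 2000L))
  cl <- coh$clinical
  expect_true(all(cl$er_ihc_pct >= 0 & cl$er_ihc_pct <= 100))
  expect_gt(cor(cl$er_ihc_pct, cl$activity_latent), 0.4)
  fit <- lm(er_ihc_pct ~ activity_latent, data = cl,
            subset = er_ihc_pct > 0 & er_ihc_pct < 100)
  expect_lt(abs(coef(fit)[2] - cfg$ihc_slope), 0.15)
})

test_that("residual-disease flags scale with the published exclusion counts", {
  cfg <- generator_config(seed = 15L)
  coh <- generate_cohort(cfg)  # published group sizes 4/20/57/12/14
  cl <- coh$clinical
  expect_equal(sum(cl$residual_disease[cl$tissue == "usc"]), 4L)
  expect_equal(sum(cl$residual_disease[cl$tissue == "eec_stage_ii_iv"]), 1L)
  expect_equal(sum(cl$residual_disease[cl$tissue %in%
                                         c("eec_stage_i", "proliferative",
                                           "hyperplasia")]), 0L)
})

test_that("scored activity reproduces configured group moments after scale recalibration", {
  # closes the loop generator -> calibration -> scorer: raw scores are a
  # monotone nonlinear readout of latent activity, so they are mapped back
  # to the activity scale via the simulated calibration curve; group means
  # must then match the (truncated-normal) configured means within 3 SE,
  # and the measurement-corrected SDs the configured SDs.
  tn_moments <- function(mu, sd) {
    a <- (0 - mu) / sd; b <- (100 - mu) / sd
    Z <- pnorm(b) - pnorm(a)
    m <- mu + sd * (dnorm(a) - dnorm(b)) / Z
    v <- sd^2 * (1 + (a * dnorm(a) - b * dnorm(b)) / Z -
                   ((dnorm(a) - dnorm(b)) / Z)^2)
    c(mean = m, sd = sqrt(v))
  }
  cfg <- generator_config(seed = 1L)
  cal <- calibrate_model(generate_calibration_set(cfg))
  ac <- activity_scale_calibration(cal$model, cal$intensity_map, cfg)
  gp <- default_group_params()
  coh <- generate_cohort(cfg, group_sizes = setNames(rep(5000L, nrow(gp)),
                                                     gp$tissue), seed = 21L)
  sc <- score_cohort(cal$model, cal$intensity_map, coh$expression)
  rec <- recalibrate_scores(ac, sc$score)
  agrid <- seq(0, 100, 0.5)
  mvar_curve <- approx(ac$curve$activity, ac$curve$sd_activity^2,
                       xout = agrid, rule = 2)$y
  for (i in seq_len(nrow(gp))) {
    idx <- coh$clinical$tissue == gp$tissue[i]
    target <- tn_moments(gp$mean[i], gp$sd[i])
    expect_lt(abs(mean(rec[idx]) - target["mean"]),
              3 * sd(rec[idx]) / sqrt(sum(idx)))
    # measurement variance averaged over the group's latent distribution
    w <- dnorm(agrid, gp$mean[i], gp$sd[i]); w <- w / sum(w)
    sd_deconv <- sqrt(max(var(rec[idx]) - sum(w * mvar_curve), 0))
    # 1.5-point accuracy bound: dominated by heterogeneity of the
    # measurement variance across the group's activity range
    expect_lt(abs(sd_deconv - target["sd"]), 1.5)
  }
})
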