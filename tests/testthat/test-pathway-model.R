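test_that("uninformative CPT rows give likelihood ratio 1 at any evidence", {
  e_grid <- c(0, 0.25, 0.5, 0.75, 1)
  same_regulation <- target_gene("a", 0.7, 0.7, 0.9, 0.1)
  same_intensity <- target_gene("b", 0.95, 0.05, 0.4, 0.4)
  for (e in e_grid) {
    expect_equal(gene_likelihood_ratio(same_regulation, e), 1)
    expect_equal(gene_likelihood_ratio(same_intensity, e), 1)
  }
})

test_that("likelihood ratio rejects evidence outside [0, 1] and bad CPTs", {
  g <- make_gene()
  expect_error(gene_likelihood_ratio(g, -0.1), "\\[0, 1\\]")
  expect_error(gene_likelihood_ratio(g, 1.5), "\\[0, 1\\]")
  expect_error(target_gene("g", 1, 0.05, 0.9, 0.1), "strictly in")
  expect_error(target_gene("g", 0.95, 0.05, 0.9, 0), "strictly in")
})

test_that("single fully informative gene reproduces the hand Bayes result", {
  # gene (0.95, 0.05, 0.9, 0.1), e = 1:
  #   P(high|active)   = 0.95*0.9 + 0.05*0.1 = 0.86
  #   P(high|inactive) = 0.05*0.9 + 0.95*0.1 = 0.14
  #   posterior (prior 0.5) = 0.86 / (0.86 + 0.14) = 0.86
  m <- make_symmetric_model(1)
  expect_equal(gene_likelihood_ratio(m$genes, 1), 0.86 / 0.14)
  expect_equal(brute_force_posterior(m, c(g01 = 1)), 0.86, tolerance = 1e-12)
  res <- infer_log2_odds(m, c(g01 = 1))
  expect_equal(res$log2_odds, log2(0.86 / 0.14), tolerance = 1e-12)
  expect_equal(res$n_genes_used, 1L)
})

test_that("no evidence returns the prior", {
  m <- make_symmetric_model(3)
  expect_equal(brute_force_posterior(m, setNames(numeric(0), character(0))),
               0.5, tolerance = 1e-12)
  res <- infer_log2_odds(m, setNames(numeric(0), character(0)))
  expect_equal(res$log2_odds, 0)
  expect_equal(res$score, 50)
  expect_equal(res$n_genes_used, 0L)

  m2 <- pathway_model(m$genes, prior_active = 0.8)
  expect_equal(brute_force_posterior(m2, setNames(numeric(0), character(0))),
               0.8, tolerance = 1e-12)
})

test_that("factored inference agrees with joint enumeration on random models", {
  set.seed(42)
  for (rep in 1:60) {
    m <- random_model(sample(1:8, 1))
    e <- random_evidence(m, p_missing = 0.25)
    post_joint <- brute_force_posterior(m, e)
    l2 <- infer_log2_odds(m, e)$log2_odds
    post_factored <- 2^l2 / (1 + 2^l2)
    expect_lt(abs(post_joint - post_factored), 1e-10)
  }
  expect_error(brute_force_posterior(random_model(13),
                                     setNames(numeric(0), character(0))),
               "enumeration bound")
})

test_that("score is monotone in a gene's evidence, direction set by its CPTs", {
  set.seed(7)
  for (rep in 1:20) {
    m <- random_model(3)
    g <- m$genes[2, ]
    sgn <- sign((g$p_high_given_up - g$p_high_given_down) *
                  (g$p_up_given_active - g$p_up_given_inactive))
    base <- setNames(runif(3), m$genes$gene_id)
    scores <- sapply(seq(0, 1, by = 0.1), function(e) {
      base[2] <- e
      infer_log2_odds(m, base)$score
    })
    d <- diff(scores)
    if (sgn > 0) expect_true(all(d >= -1e-9))
    if (sgn < 0) expect_true(all(d <= 1e-9))
  }
})

test_that("removing a gene's evidence moves log2 odds at most its LR range", {
  set.seed(11)
  for (rep in 1:20) {
    m <- random_model(5)
    e <- setNames(runif(5), m$genes$gene_id)
    drop <- sample(5, 1)
    full <- infer_log2_odds(m, e)$log2_odds
    part <- infer_log2_odds(m, e[-drop])$log2_odds
    g <- m$genes[drop, ]
    bound <- max(abs(log2(gene_likelihood_ratio(g, 0))),
                 abs(log2(gene_likelihood_ratio(g, 1))))
    expect_lte(abs(full - part), bound + 1e-12)
  }
})

test_that("score range matches a grid search over evidence combinations", {
  set.seed(3)
  m <- random_model(3)
  grid <- expand.grid(e1 = seq(0, 1, 0.1), e2 = seq(0, 1, 0.1),
                      e3 = seq(0, 1, 0.1))
  l2 <- apply(grid, 1, function(e)
    infer_log2_odds(m, setNames(as.numeric(e), m$genes$gene_id))$log2_odds)
  expect_equal(min(l2), m$log2_odds_min, tolerance = 1e-10)
  expect_equal(max(l2), m$log2_odds_max, tolerance = 1e-10)
})

test_that("range is symmetric for symmetric CPTs and ignores uninformative genes", {
  m <- make_symmetric_model(1)
  expect_equal(m$log2_odds_max, -m$log2_odds_min, tolerance = 1e-12)

  with_noise <- rbind(m$genes, target_gene("null", 0.6, 0.6, 0.9, 0.1))
  rng <- compute_score_range(with_noise, 0.5)
  expect_equal(rng[["log2_odds_min"]], m$log2_odds_min, tolerance = 1e-12)
  expect_equal(rng[["log2_odds_max"]], m$log2_odds_max, tolerance = 1e-12)

  all_null <- do.call(rbind, lapply(1:3, function(i)
    target_gene(sprintf("n%d", i), 0.5, 0.5, 0.8, 0.2)))
  expect_error(pathway_model(all_null), "uninformative")
})

test_that("normalisation maps extremes to 0/100, midpoint to 50, and clamps", {
  set.seed(19)
  for (rep in 1:10) {
    m <- random_model(4)
    expect_equal(infer_log2_odds(m, extreme_evidence(m, TRUE))$score, 100,
                 tolerance = 1e-12)
    expect_equal(infer_log2_odds(m, extreme_evidence(m, FALSE))$score, 0,
                 tolerance = 1e-12)
    set.seed(19 + rep)
    expect_equal(normalize_score(m, (m$log2_odds_min + m$log2_odds_max) / 2),
                 50, tolerance = 1e-12)
    e <- random_evidence(m, p_missing = 0)
    s <- infer_log2_odds(m, e)$score
    expect_gte(s, 0); expect_lte(s, 100)
  }
  m <- make_symmetric_model(2)
  expect_warning(s <- normalize_score(m, m$log2_odds_max + 1), "clamped")
  expect_equal(s, 100)
})

test_that("model documents round-trip losslessly", {
  set.seed(23)
  m <- random_model(6, prior = 0.37)
  maps <- data.frame(gene_id = m$genes$gene_id,
                     mu_low = rnorm(6), sigma_low = runif(6, 0.1, 1),
                     mu_high = rnorm(6, 2), sigma_high = runif(6, 0.1, 1),
                     direction = sample(c(-1L, 1L), 6, replace = TRUE))
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path, intensity_map = maps)
  back <- read_model(path)
  for (col in c("p_up_given_active", "p_up_given_inactive",
                "p_high_given_up", "p_high_given_down"))
    expect_equal(back$model$genes[[col]], m$genes[[col]], tolerance = 1e-12)
  expect_identical(back$model$genes$gene_id, m$genes$gene_id)
  expect_equal(back$model$prior_active, m$prior_active, tolerance = 1e-12)
  expect_equal(back$model$log2_odds_min, m$log2_odds_min, tolerance = 1e-12)
  expect_equal(back$intensity_map$mu_high, maps$mu_high, tolerance = 1e-12)
  expect_identical(back$model$platform, m$platform)
})
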