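# shared fixtures: small hand-built and random pathway models

make_gene <- function(id = "g1", pua = 0.95, pui = 0.05,
                      phu = 0.9, phd = 0.1) {
  target_gene(id, pua, pui, phu, phd)
}

# n copies of the symmetric reference gene (CPTs 0.95/0.05, 0.9/0.1)
make_symmetric_model <- function(n = 3, prior = 0.5, platform = "array") {
  genes <- do.call(rbind, lapply(seq_len(n), function(i)
    make_gene(sprintf("g%02d", i))))
  pathway_model(genes, prior_active = prior, platform = platform)
}

random_model <- function(n_genes, prior = NULL) {
  if (is.null(prior)) prior <- runif(1, 0.2, 0.8)
  genes <- do.call(rbind, lapply(seq_len(n_genes), function(i)
    target_gene(sprintf("g%02d", i),
                p_up_given_active = runif(1, 0.55, 0.98),
                p_up_given_inactive = runif(1, 0.02, 0.45),
                p_high_given_up = runif(1, 0.05, 0.95),
                p_high_given_down = runif(1, 0.05, 0.95))))
  pathway_model(genes, prior_active = prior)
}

random_evidence <- function(model, p_missing = 0.2) {
  e <- setNames(runif(nrow(model$genes)), model$genes$gene_id)
  drop <- runif(length(e)) < p_missing
  e[!drop]
}

# evidence vector pushing every gene to its score-maximising (or minimising)
# extreme
extreme_evidence <- function(model, maximise = TRUE) {
  lr1 <- gene_likelihood_ratio(model$genes, rep(1, nrow(model$genes)))
  lr0 <- gene_likelihood_ratio(model$genes, rep(0, nrow(model$genes)))
  hi <- ifelse(lr1 >= lr0, 1, 0)
  e <- if (maximise) hi else 1 - hi
  setNames(e, model$genes$gene_id)
}
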