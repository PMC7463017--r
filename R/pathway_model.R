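#' Two-layer Bayesian network for transcription-factor pathway activity
#'
#' The network has a single transcription-factor (TF) activation node with
#' states active/inactive, one regulation node per target gene with states
#' up/down, and one expression-intensity node per target gene with states
#' high/low. Continuous expression enters as soft (virtual) evidence on the
#' intensity node: a weight in [0, 1] on state "high". Because the graph is a
#' tree rooted at the TF node, the posterior odds factorise over genes, and
#' the log2 posterior odds are an affine function of per-gene log likelihood
#' ratios. The log2 odds are normalised against the extremes the model can
#' reach, giving a pathway activity score between 0 and 100.
#'
#' @name pathway-model
NULL

#' Construct a target-gene specification
#'
#' @param gene_id character gene identifier, unique within a model.
#' @param p_up_given_active probability that the gene's regulation node is
#'   "up" when the TF complex is active.
#' @param p_up_given_inactive probability of "up" when the TF is inactive.
#' @param p_high_given_up probability that measured intensity is "high" when
#'   the gene is up-regulated.
#' @param p_high_given_down probability of "high" intensity when the gene is
#'   down-regulated.
#' @param direction +1 for activated targets, -1 for repressed; informational.
#'
#' @return A one-row data.frame of class \code{target_gene_spec}.
#' @export
target_gene <- function(gene_id, p_up_given_active, p_up_given_inactive,
                        p_high_given_up, p_high_given_down, direction = 1L) {
  probs <- c(p_up_given_active, p_up_given_inactive,
             p_high_given_up, p_high_given_down)
  if (!is.character(gene_id) || length(gene_id) != 1L || is.na(gene_id))
    stop("gene_id must be a single string")
  if (any(!is.finite(probs)) || any(probs <= 0) || any(probs >= 1))
    stop("all four probabilities must lie strictly in (0, 1); apply ",
         "pseudocount smoothing upstream")
  out <- data.frame(gene_id = gene_id,
                    p_up_given_active = p_up_given_active,
                    p_up_given_inactive = p_up_given_inactive,
                    p_high_given_up = p_high_given_up,
                    p_high_given_down = p_high_given_down,
                    direction = as.integer(direction),
                    stringsAsFactors = FALSE)
  class(out) <- c("target_gene_spec", class(out))
  out
}

#' Per-gene likelihood ratio under soft intensity evidence
#'
#' Marginalises the regulation node and weighs the intensity states by the
#' soft evidence e (weight on "high"):
#' \deqn{LR(e) = \frac{\sum_r P(r|active)\,[e P(high|r) + (1-e) P(low|r)]}
#'                   {\sum_r P(r|inactive)\,[e P(high|r) + (1-e) P(low|r)]}}
#'
#' @param gene a \code{target_gene_spec} row (or any list with the four
#'   probability fields).
#' @param evidence_high numeric vector of soft-evidence weights in [0, 1].
#' @return Likelihood ratio(s), finite and positive.
#' @export
gene_likelihood_ratio <- function(gene, evidence_high) {
  e <- evidence_high
  if (any(!is.finite(e)) || any(e < 0) || any(e > 1))
    stop("evidence_high must lie in [0, 1]")
  b_up   <- e * gene$p_high_given_up   + (1 - e) * (1 - gene$p_high_given_up)
  b_down <- e * gene$p_high_given_down + (1 - e) * (1 - gene$p_high_given_down)
  num <- gene$p_up_given_active   * b_up + (1 - gene$p_up_given_active)   * b_down
  den <- gene$p_up_given_inactive * b_up + (1 - gene$p_up_given_inactive) * b_down
  num / den
}

#' Assemble a pathway model from gene specifications
#'
#' Computes and stores the log2-odds range the model can reach (per-gene
#' extremes of the likelihood ratio are attained at evidence 0 or 1 because
#' the LR is monotone in the evidence weight).
#'
#' @param genes a data.frame of target-gene CPT rows (rbind of
#'   \code{\link{target_gene}} rows).
#' @param prior_active prior probability that the TF complex is active;
#'   default 0.5 (neutral odds, score purely evidence-driven).
#' @param platform measurement platform tag, \code{"array"} or \code{"qpcr"}.
#' @return An object of class \code{pathway_model}.
#' @export
pathway_model <- function(genes, prior_active = 0.5, platform = c("array", "qpcr")) {
  platform <- match.arg(platform)
  if (is.null(genes) || nrow(genes) == 0L)
    stop("a pathway model needs at least one target gene")
  if (anyDuplicated(genes$gene_id))
    stop("duplicate gene_id in model")
  if (!is.numeric(prior_active) || prior_active <= 0 || prior_active >= 1)
    stop("prior_active must lie strictly in (0, 1)")
  rng <- compute_score_range(genes, prior_active)
  structure(list(genes = genes,
                 prior_active = prior_active,
                 log2_odds_min = rng[["log2_odds_min"]],
                 log2_odds_max = rng[["log2_odds_max"]],
                 platform = platform),
            class = "pathway_model")
}

#' @export
print.pathway_model <- function(x, ...) {
  cat(sprintf("Pathway activity model (%s): %d target genes\n",
              x$platform, nrow(x$genes)))
  cat(sprintf("  prior P(active) = %.3f; log2-odds range [%.3f, %.3f]\n",
              x$prior_active, x$log2_odds_min, x$log2_odds_max))
  invisible(x)
}

#' Range of log2 odds reachable by a model
#'
#' For each gene the likelihood ratio is evaluated at evidence 0 and 1; the
#' smaller/larger log2 values accumulate into the model minimum/maximum,
#' together with the prior log2 odds. Genes whose LR is 1 at both extremes
#' are uninformative and contribute nothing.
#'
#' @param genes data.frame of target-gene CPT rows.
#' @param prior_active prior probability of the active state.
#' @return Named numeric vector \code{c(log2_odds_min, log2_odds_max)}.
#' @export
compute_score_range <- function(genes, prior_active) {
  lr0 <- log2(gene_likelihood_ratio(genes, rep(0, nrow(genes))))
  lr1 <- log2(gene_likelihood_ratio(genes, rep(1, nrow(genes))))
  prior_term <- log2(prior_active / (1 - prior_active))
  lo <- prior_term + sum(pmin(lr0, lr1))
  hi <- prior_term + sum(pmax(lr0, lr1))
  if (hi <= lo)
    stop("uninformative model: log2-odds range is empty (all genes have ",
         "identical CPT rows)")
  c(log2_odds_min = lo, log2_odds_max = hi)
}

#' Infer log2 posterior odds of pathway activity
#'
#' Adds the prior log2 odds and the per-gene log2 likelihood ratios of the
#' genes present in the evidence vector. Genes without evidence contribute a
#' likelihood ratio of 1 (they are ignored, not imputed).
#'
#' @param model a \code{pathway_model}.
#' @param evidence named numeric vector of soft-evidence weights in [0, 1];
#'   names must be a subset of the model's gene ids. \code{NA} entries are
#'   treated as missing.
#' @return List with \code{log2_odds}, \code{score} (0-100 normalised) and
#'   \code{n_genes_used}.
#' @export
infer_log2_odds <- function(model, evidence) {
  stopifnot(inherits(model, "pathway_model"))
  evidence <- evidence[!is.na(evidence)]
  if (length(evidence)) {
    if (is.null(names(evidence)) || any(!nzchar(names(evidence))))
      stop("evidence must be a named vector")
    unknown <- setdiff(names(evidence), model$genes$gene_id)
    if (length(unknown))
      stop("evidence for genes not in the model: ",
           paste(unknown, collapse = ", "))
  }
  idx <- match(names(evidence), model$genes$gene_id)
  lr <- if (length(idx)) gene_likelihood_ratio(model$genes[idx, , drop = FALSE],
                                               unname(evidence)) else numeric(0)
  l2 <- log2(model$prior_active / (1 - model$prior_active)) + sum(log2(lr))
  list(log2_odds = l2,
       score = normalize_score(model, l2),
       n_genes_used = length(evidence))
}

#' Normalise log2 odds to the 0-100 activity score
#'
#' Affine map of the log2 odds from the model range onto [0, 100]: 0
#' corresponds to the lowest odds the model can infer and 100 to the
#' maximum. Values outside the range (possible only through a construction
#' error) are clamped; drift beyond 1e-9 raises a warning.
#'
#' @param model a \code{pathway_model} with a stored range.
#' @param log2_odds numeric vector of log2 odds.
#' @return Scores in [0, 100].
#' @export
normalize_score <- function(model, log2_odds) {
  lo <- model$log2_odds_min
  hi <- model$log2_odds_max
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo)
    stop("uninformative model: degenerate log2-odds range")
  s <- 100 * (log2_odds - lo) / (hi - lo)
  drift <- pmax(s - 100, -s, 0)
  if (any(drift > 1e-9 * 100))
    warning(sprintf("%d score(s) outside [0, 100] by more than tolerance; clamped",
                    sum(drift > 1e-9 * 100)))
  pmin(pmax(s, 0), 100)
}

#' Brute-force posterior by joint enumeration (test oracle)
#'
#' Computes P(TF = active | evidence) by summing the full joint distribution
#' over every configuration of the TF node, all regulation nodes and all
#' intensity nodes, weighting each intensity state by the soft evidence
#' (e for "high", 1 - e for "low"). Exponential in the number of genes, so
#' it refuses models with more than 12 genes; it exists as an independent
#' check on the factored inference.
#'
#' @param model a \code{pathway_model} with at most 12 genes.
#' @param evidence named numeric evidence vector (subset of model genes).
#' @return Posterior probability of the active state.
#' @export
brute_force_posterior <- function(model, evidence) {
  stopifnot(inherits(model, "pathway_model"))
  g <- model$genes
  n <- nrow(g)
  if (n > 12L) stop("enumeration bound exceeded: oracle limited to 12 genes")
  evidence <- evidence[!is.na(evidence)]
  e <- rep(NA_real_, n)
  e[match(names(evidence), g$gene_id)] <- unname(evidence)

  # per gene, weight of each joint (R, I) state: columns dd, dh, ud, uh
  # (regulation down/up x intensity low/high); missing evidence weights both
  # intensity states fully (weight 1), i.e. the node is marginalised out.
  w_high <- ifelse(is.na(e), 1, e)
  w_low  <- ifelse(is.na(e), 1, 1 - e)
  state_w <- function(p_up) {
    cbind((1 - p_up) * (1 - g$p_high_given_down) * w_low,
          (1 - p_up) * g$p_high_given_down       * w_high,
          p_up       * (1 - g$p_high_given_up)   * w_low,
          p_up       * g$p_high_given_up         * w_high)
  }
  # enumerate all 4^n joint (R, I) configurations
  combos <- as.matrix(expand.grid(rep(list(1:4), n)))
  total <- function(W) {
    per_gene <- matrix(W[cbind(rep(seq_len(n), each = nrow(combos)),
                               as.vector(combos))],
                       nrow = nrow(combos))
    sum(exp(rowSums(log(per_gene))))
  }
  z_active   <- total(state_w(g$p_up_given_active))
  z_inactive <- total(state_w(g$p_up_given_inactive))
  p <- model$prior_active
  p * z_active / (p * z_active + (1 - p) * z_inactive)
}

#' Write a pathway model (with its intensity map) to a JSON document
#'
#' The document is versioned and stores the gene CPTs, prior, platform,
#' score range and, when supplied, the per-gene intensity map, at full
#' double precision so that read/write round-trips are loss-free.
#'
#' @param model a \code{pathway_model}.
#' @param path output file path.
#' @param intensity_map optional intensity map data.frame
#'   (see \code{\link{fit_intensity_map}}).
#' @return \code{path}, invisibly.
#' @export
write_model <- function(model, path, intensity_map = NULL) {
  doc <- list(format = "pathway-activity-model", version = "1.0",
              platform = model$platform,
              prior_active = model$prior_active,
              log2_odds_min = model$log2_odds_min,
              log2_odds_max = model$log2_odds_max,
              genes = model$genes)
  if (!is.null(intensity_map)) doc$intensity_map <- intensity_map
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(path)
}

#' Read a pathway model written by \code{\link{write_model}}
#'
#' @param path JSON model document.
#' @return List with elements \code{model} (a \code{pathway_model}) and
#'   \code{intensity_map} (data.frame or NULL).
#' @export
read_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "pathway-activity-model"))
    stop("not a pathway-activity model document: ", path)
  model <- pathway_model(doc$genes, prior_active = doc$prior_active,
                         platform = doc$platform)
  # stored range wins over the recomputed one only if they disagree beyond
  # round-off; they must agree because the range is determined by the CPTs
  if (abs(model$log2_odds_min - doc$log2_odds_min) > 1e-8 ||
      abs(model$log2_odds_max - doc$log2_odds_max) > 1e-8)
    warning("stored score range disagrees with CPT-derived range; ",
            "using the recomputed range")
  list(model = model,
       intensity_map = if (!is.null(doc$intensity_map)) doc$intensity_map else NULL)
}
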