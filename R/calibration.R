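#' Mann-Whitney AUC by exact pair counting
#'
#' Probability that a randomly drawn value from the first group exceeds a
#' randomly drawn value from the second, counting ties as one half. This is
#' the ranking statistic used to select target genes from the ground-truth
#' calibration classes; it is computed exactly over all pairs, so tie
#' handling is unambiguous at any sample size.
#'
#' @param values_active numeric values from the active class.
#' @param values_inactive numeric values from the inactive class.
#' @return AUC in [0, 1].
#' @export
rank_auc <- function(values_active, values_inactive) {
  a <- values_active[!is.na(values_active)]
  b <- values_inactive[!is.na(values_inactive)]
  if (length(a) == 0L || length(b) == 0L)
    stop("both groups must be non-empty")
  d <- outer(a, b, "-")
  (sum(d > 0) + 0.5 * sum(d == 0)) / length(d)
}

#' Select target genes by directional AUC on a calibration set
#'
#' Each gene is scored by its directional AUC \code{max(auc, 1 - auc)}
#' (so repressed targets, whose expression separates the classes in the
#' opposite direction, compete on equal terms). Genes at or above
#' \code{min_auc} are retained, the top \code{max_genes} kept; ties are
#' broken deterministically by lexicographic gene id.
#'
#' @param calib list with elements \code{matrix} (genes x samples, log2) and
#'   \code{labels} (\code{"active"}/\code{"inactive"} per sample).
#' @param min_auc selection threshold in (0.5, 1] (default 0.8).
#' @param max_genes maximum number of genes retained (default 20).
#' @return data.frame (gene_id, auc, directional_auc, direction, selected),
#'   ordered by decreasing directional AUC then gene id. Errors if nothing
#'   passes, with the report attached as attribute \code{"report"}.
#' @export
select_target_genes <- function(calib, min_auc = 0.8, max_genes = 20L) {
  stopifnot(min_auc > 0.5, min_auc <= 1, max_genes >= 1L)
  m <- calib$matrix
  labels <- as.character(calib$labels)
  auc <- vapply(seq_len(nrow(m)), function(i)
    rank_auc(m[i, labels == "active"], m[i, labels == "inactive"]),
    numeric(1))
  report <- data.frame(gene_id = rownames(m),
                       auc = auc,
                       directional_auc = pmax(auc, 1 - auc),
                       direction = ifelse(auc >= 0.5, 1L, -1L),
                       stringsAsFactors = FALSE)
  report <- report[order(-report$directional_auc, report$gene_id), ]
  rownames(report) <- NULL
  pass <- report$directional_auc >= min_auc
  report$selected <- pass & seq_len(nrow(report)) <= max_genes
  if (!any(report$selected)) {
    err <- simpleError(sprintf(
      "no gene reaches the selection threshold (min_auc = %.2f)", min_auc))
    attr(err, "report") <- report
    stop(err)
  }
  report
}

#' Estimate per-gene conditional probability tables from calibration evidence
#'
#' The intensity-layer CPTs are the pseudocount-smoothed mean soft evidence
#' within each ground-truth class:
#' \deqn{P(I = high | R = up) = (\sum_{active} e + c) / (n_{active} + 2c)}
#' and analogously for the inactive class and \eqn{P(I = high | R = down)}.
#' A repressed gene therefore gets \eqn{P(high|up) < P(high|down)}; no
#' evidence flipping is needed and the likelihood ratio is consistent with
#' the gene's direction. The regulation layer is knowledge-based in this
#' model family, so it is set to a fixed near-deterministic link:
#' \eqn{P(R = up | TF = active) = } \code{regulation_fidelity} and
#' \eqn{P(R = up | TF = inactive) = 1 -} \code{regulation_fidelity}.
#'
#' @param evidence genes x samples evidence matrix on the calibration set.
#' @param labels per-sample class labels.
#' @param pseudocount Laplace smoothing constant, must be > 0 (default 1).
#' @param regulation_fidelity strength of the regulation link in (0.5, 1)
#'   (default 0.95).
#' @param direction optional per-gene direction flags to store.
#' @return data.frame of target-gene CPT rows.
#' @export
estimate_cpts <- function(evidence, labels, pseudocount = 1,
                          regulation_fidelity = 0.95, direction = NULL) {
  stopifnot(pseudocount > 0, regulation_fidelity > 0.5, regulation_fidelity < 1)
  labels <- as.character(labels)
  act <- evidence[, labels == "active", drop = FALSE]
  ina <- evidence[, labels == "inactive", drop = FALSE]
  smooth <- function(e_mat) {
    n <- rowSums(!is.na(e_mat))
    (rowSums(e_mat, na.rm = TRUE) + pseudocount) / (n + 2 * pseudocount)
  }
  p_h_up <- smooth(act)
  p_h_down <- smooth(ina)
  if (is.null(direction)) direction <- ifelse(p_h_up >= p_h_down, 1L, -1L)
  data.frame(gene_id = rownames(evidence),
             p_up_given_active = regulation_fidelity,
             p_up_given_inactive = 1 - regulation_fidelity,
             p_high_given_up = p_h_up,
             p_high_given_down = p_h_down,
             direction = as.integer(direction),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Calibrate a pathway model on a ground-truth calibration set
#'
#' Wires the calibration stages together: fit the per-gene low/high
#' intensity distributions, select target genes by directional AUC, estimate
#' the CPTs from class-conditional evidence, and compute the model's score
#' range. The returned model scores the calibration samples such that the
#' mean active-class score exceeds the mean inactive-class score.
#'
#' @param calib list with \code{matrix} (genes x samples, log2) and
#'   \code{labels}.
#' @param min_auc,max_genes gene-selection parameters
#'   (see \code{\link{select_target_genes}}).
#' @param pseudocount,regulation_fidelity CPT-estimation parameters
#'   (see \code{\link{estimate_cpts}}).
#' @param sigma_floor intensity-map SD floor in log2 units.
#' @param prior_active prior probability of the active state.
#' @param platform platform tag recorded on the model.
#' @return List with \code{model} (\code{pathway_model}),
#'   \code{intensity_map} (selected genes only) and \code{selection}
#'   (the full gene-selection report).
#' @export
calibrate_model <- function(calib, min_auc = 0.8, max_genes = 20L,
                            pseudocount = 1, regulation_fidelity = 0.95,
                            sigma_floor = 0.05, prior_active = 0.5,
                            platform = c("array", "qpcr")) {
  platform <- match.arg(platform)
  selection <- select_target_genes(calib, min_auc = min_auc,
                                   max_genes = max_genes)
  keep <- selection$gene_id[selection$selected]
  maps <- fit_intensity_map(calib$matrix[keep, , drop = FALSE], calib$labels,
                            sigma_floor = sigma_floor)
  ev <- matrix_to_evidence(maps, calib$matrix[keep, , drop = FALSE])
  genes <- estimate_cpts(ev, calib$labels, pseudocount = pseudocount,
                         regulation_fidelity = regulation_fidelity,
                         direction = maps$direction[match(rownames(ev),
                                                          maps$gene_id)])
  model <- pathway_model(genes, prior_active = prior_active,
                         platform = platform)
  list(model = model, intensity_map = maps, selection = selection)
}

#' Write a gene-selection / calibration report as tab-separated text
#'
#' @param selection selection report from \code{\link{select_target_genes}}.
#' @param genes optional CPT table to merge in (matched by gene id).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_calibration_report <- function(selection, path, genes = NULL) {
  out <- selection
  if (!is.null(genes)) {
    cpt_cols <- c("p_up_given_active", "p_up_given_inactive",
                  "p_high_given_up", "p_high_given_down")
    out[cpt_cols] <- genes[match(out$gene_id, genes$gene_id), cpt_cols]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
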