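#' Reproducible pipeline runs
#'
#' Thin orchestration layer tying the stages into reproducible runs: each
#' stage writes its outputs plus a JSON manifest containing the resolved
#' configuration and seed, so any report can be regenerated from its
#' manifest alone. These functions back the numbered driver scripts under
#' \code{analysis/}.
#'
#' @name pipeline
NULL

write_manifest <- function(dir, stage, config) {
  jsonlite::write_json(list(stage = stage,
                            package = "eractivity",
                            package_version =
                              as.character(utils::packageVersion("eractivity")),
                            config = config),
                       file.path(dir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Simulate pipeline inputs to disk
#'
#' Writes a calibration set (expression TSV + labels CSV), a cohort
#' expression matrix (TSV) and clinical table (CSV), and the stage manifest.
#' The same configuration and seed reproduce the files byte for byte.
#'
#' @param config a \code{generator_config}.
#' @param out_dir output directory (created if missing).
#' @param group_sizes cohort group sizes
#'   (default \code{\link{default_group_sizes}}).
#' @param n_per_class calibration samples per ground-truth class.
#' @return Named list of the written file paths, invisibly.
#' @export
run_simulate <- function(config, out_dir,
                         group_sizes = default_group_sizes(),
                         n_per_class = 50L) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  calib <- generate_calibration_set(config, n_per_class = n_per_class)
  cohort <- generate_cohort(config, group_sizes = group_sizes)
  paths <- list(
    calibration_matrix = file.path(out_dir, "calibration_expression.tsv"),
    calibration_labels = file.path(out_dir, "calibration_labels.csv"),
    cohort_matrix = file.path(out_dir, "cohort_expression.tsv"),
    clinical = file.path(out_dir, "cohort_clinical.csv"))
  write_expression_matrix(calib$matrix, paths$calibration_matrix)
  utils::write.csv(data.frame(sample_id = colnames(calib$matrix),
                              label = calib$labels),
                   paths$calibration_labels, row.names = FALSE)
  write_expression_matrix(cohort$expression, paths$cohort_matrix)
  write_clinical(cohort$clinical, paths$clinical)
  write_manifest(out_dir, "simulate",
                 c(unclass(config),
                   list(group_sizes = as.list(group_sizes),
                        n_per_class = n_per_class)))
  invisible(paths)
}

#' Calibrate a model from files on disk
#'
#' Reads the calibration expression matrix and labels, calibrates the
#' model, and writes the model document, the gene-selection report and the
#' stage manifest.
#'
#' @param matrix_path calibration expression TSV.
#' @param labels_path CSV with columns sample_id, label.
#' @param out_dir output directory.
#' @param ... calibration parameters passed to \code{\link{calibrate_model}}.
#' @return The \code{\link{calibrate_model}} result, invisibly.
#' @export
run_calibrate <- function(matrix_path, labels_path, out_dir, ...) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  m <- read_expression_matrix(matrix_path)
  lab <- utils::read.csv(labels_path, stringsAsFactors = FALSE)
  labels <- lab$label[match(colnames(m), lab$sample_id)]
  if (anyNA(labels)) stop("labels missing for some calibration samples")
  cal <- calibrate_model(list(matrix = m, labels = labels), ...)
  write_model(cal$model, file.path(out_dir, "model.json"),
              intensity_map = cal$intensity_map)
  write_calibration_report(cal$selection,
                           file.path(out_dir, "gene_selection.tsv"),
                           genes = cal$model$genes)
  write_manifest(out_dir, "calibrate",
                 list(matrix_path = matrix_path, labels_path = labels_path,
                      parameters = list(...),
                      n_genes_selected = nrow(cal$model$genes),
                      log2_odds_min = cal$model$log2_odds_min,
                      log2_odds_max = cal$model$log2_odds_max))
  invisible(cal)
}

#' Score a cohort from files on disk
#'
#' Scoring reads only the expression matrix — clinical data never enter
#' this stage, so samples are scored blinded by construction.
#'
#' @param model_path model JSON document.
#' @param matrix_path cohort expression TSV.
#' @param out_dir output directory.
#' @param platform platform tag of the matrix file.
#' @return The scores data.frame, invisibly.
#' @export
run_score <- function(model_path, matrix_path, out_dir,
                      platform = c("array", "qpcr")) {
  platform <- match.arg(platform)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  doc <- read_model(model_path)
  m <- read_expression_matrix(matrix_path, platform = platform)
  scores <- score_cohort(doc$model, doc$intensity_map, m)
  utils::write.table(scores, file.path(out_dir, "scores.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_manifest(out_dir, "score",
                 list(model_path = model_path, matrix_path = matrix_path,
                      platform = platform, n_samples = nrow(scores)))
  invisible(scores)
}

#' Run the cohort statistics on scored samples
#'
#' Joins the scores with the clinical table, assigns IHC bins, activity
#' quartiles and the combined risk group, and writes the group-comparison
#' report, Kaplan-Meier curve data (DFS with residual-disease patients
#' excluded, and DSS), the Cox regression tables and the stage manifest.
#'
#' @param scores_path scores TSV from \code{\link{run_score}}.
#' @param clinical_path clinical CSV.
#' @param out_dir output directory.
#' @return List of the computed result objects, invisibly.
#' @export
run_analyze <- function(scores_path, clinical_path, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scores <- utils::read.delim(scores_path, stringsAsFactors = FALSE)
  clinical <- read_clinical(clinical_path)
  ord <- match(clinical$sample_id, scores$sample_id)
  if (anyNA(ord)) stop("scores missing for some clinical samples")
  grouped <- assign_groups(clinical, scores$score[ord])

  comparison <- group_comparison(grouped$score, grouped$tissue)
  utils::write.table(comparison$group_stats,
                     file.path(out_dir, "group_means.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(comparison$tukey,
                     file.path(out_dir, "group_comparison.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  dfs <- dfs_records(grouped)
  km_q <- km_logrank(dfs$dfs_months, dfs$recurrence, dfs$activity_quartile)
  km_er <- km_logrank(dfs$dfs_months, dfs$recurrence,
                      ifelse(dfs$er_low, "ER 0-10%", "ER 11-100%"))
  km_comb <- km_logrank(dfs$dfs_months, dfs$recurrence,
                        ifelse(dfs$combined_high_risk,
                               "ER-low & Q1", "other"))
  for (nm in c("km_q", "km_er", "km_comb")) {
    utils::write.table(get(nm)$curves,
                       file.path(out_dir, paste0("dfs_", nm, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  tumour <- grouped[!is.na(grouped$dfs_months), , drop = FALSE]
  tumour <- tumour[!(tumour$residual_disease %in% TRUE), , drop = FALSE]
  covars <- data.frame(grade_high = as.integer(tumour$grade == "high"),
                       lvsi = as.integer(tumour$lvsi),
                       deep_mi = as.integer(tumour$deep_mi),
                       figo_advanced = as.integer(tumour$figo %in%
                                                    c("III", "IV")),
                       er_ihc_pct = tumour$er_ihc_pct,
                       activity = tumour$score)
  cox_uni <- cox_regression(covars, tumour$dfs_months, tumour$recurrence,
                            mode = "univariate")
  cox_multi <- tryCatch(
    cox_regression(covars, tumour$dfs_months, tumour$recurrence,
                   mode = "multivariate"),
    warning = function(w) NULL)
  utils::write.table(cox_uni, file.path(out_dir, "cox_univariate.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cox_multi) && nrow(cox_multi))
    utils::write.table(cox_multi, file.path(out_dir, "cox_multivariate.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)

  write_manifest(out_dir, "analyze",
                 list(scores_path = scores_path,
                      clinical_path = clinical_path,
                      n_patients = nrow(grouped),
                      n_dfs_analysable = nrow(dfs)))
  invisible(list(grouped = grouped, comparison = comparison,
                 km_quartiles = km_q, km_er = km_er, km_combined = km_comb,
                 cox_univariate = cox_uni, cox_multivariate = cox_multi))
}
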