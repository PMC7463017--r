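#' Read a genes x samples expression matrix from tab-separated text
#'
#' Expected layout: header row of sample ids, first column gene ids, tab
#' separated, values on the log2 scale. Duplicate gene rows are collapsed by
#' their mean (with a warning); non-numeric cells become missing values.
#'
#' @param path TSV file.
#' @param platform platform tag, \code{"array"} or \code{"qpcr"}.
#' @return Numeric matrix with gene rownames, sample colnames and attribute
#'   \code{"platform"}.
#' @export
read_expression_matrix <- function(path, platform = c("array", "qpcr")) {
  platform <- match.arg(platform)
  fields <- utils::count.fields(path, sep = "\t", quote = "\"")
  if (length(unique(fields)) > 1L) {
    bad <- which(fields != fields[1])[1]
    stop(sprintf("ragged TSV: line %d has %d fields, expected %d",
                 bad, fields[bad], fields[1]))
  }
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  gene_ids <- as.character(df[[1]])
  vals <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(vals) <- "double")
  if (anyDuplicated(gene_ids)) {
    warning(sprintf("%d duplicated gene id(s) collapsed by mean",
                    sum(duplicated(gene_ids))))
    vals <- rowsum(vals, gene_ids, na.rm = TRUE) /
      rowsum((!is.na(vals)) + 0, gene_ids)
    vals[!is.finite(vals)] <- NA_real_
    gene_ids <- rownames(vals)
    ord <- match(unique(as.character(df[[1]])), gene_ids)
    vals <- vals[ord, , drop = FALSE]
    gene_ids <- rownames(vals)
  }
  rownames(vals) <- gene_ids
  attr(vals, "platform") <- platform
  vals
}

#' Write an expression matrix as tab-separated text
#'
#' Inverse of \code{\link{read_expression_matrix}}; values are written at
#' full precision so write-then-read round trips are loss-free well beyond
#' 10 significant digits.
#'
#' @param matrix genes x samples numeric matrix with dimnames.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_expression_matrix <- function(matrix, path) {
  stopifnot(is.matrix(matrix), !is.null(rownames(matrix)),
            !is.null(colnames(matrix)))
  df <- data.frame(gene_id = rownames(matrix), matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  old <- options(digits = 17); on.exit(options(old))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reference-gene normalisation of qPCR Cq values
#'
#' Technical replicates are first averaged on the Cq scale. For each sample
#' the reference level is the arithmetic mean of its reference-gene Cq
#' values (equivalent to the geometric mean on the expression scale, the
#' standard delta-Cq convention); each target gene's relative log2
#' expression is then \eqn{-\Delta Cq = \bar{Cq}_{ref} - Cq_{target}}.
#' Samples without any reference measurement cannot be normalised and are
#' dropped, recorded in attribute \code{"dropped_samples"}.
#'
#' @param records data.frame with columns \code{sample_id}, \code{gene_id},
#'   \code{cq} (cycles, in (0, 45]) and \code{role}
#'   (\code{"target"}/\code{"reference"}).
#' @param reference_genes optional character vector overriding the
#'   \code{role} column (genes listed here are the references).
#' @return genes x samples matrix of log2 relative expression with attribute
#'   \code{"platform" = "qpcr"}.
#' @export
normalize_qpcr <- function(records, reference_genes = NULL) {
  need <- c("sample_id", "gene_id", "cq")
  if (!all(need %in% names(records)))
    stop("records must have columns sample_id, gene_id, cq")
  if (!is.null(reference_genes)) {
    records$role <- ifelse(records$gene_id %in% reference_genes,
                           "reference", "target")
  }
  if (!"role" %in% names(records))
    stop("supply a role column or reference_genes")
  if (any(records$cq <= 0 | records$cq > 45, na.rm = TRUE))
    stop("Cq values must lie in (0, 45]")
  # replicate averaging on the Cq scale
  agg <- stats::aggregate(cq ~ sample_id + gene_id + role, data = records,
                          FUN = mean)
  refs <- agg[agg$role == "reference", ]
  ref_mean <- tapply(refs$cq, refs$sample_id, mean)
  targets <- agg[agg$role == "target", ]
  samples <- unique(agg$sample_id)
  dropped <- setdiff(samples, names(ref_mean))
  if (length(dropped))
    warning(sprintf("%d sample(s) without reference genes dropped: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  keep <- setdiff(samples, dropped)
  genes <- unique(targets$gene_id)
  out <- matrix(NA_real_, length(genes), length(keep),
                dimnames = list(genes, keep))
  t2 <- targets[targets$sample_id %in% keep, ]
  out[cbind(match(t2$gene_id, genes), match(t2$sample_id, keep))] <-
    ref_mean[t2$sample_id] - t2$cq
  attr(out, "platform") <- "qpcr"
  attr(out, "dropped_samples") <- dropped
  out
}

#' Read / write clinical annotation tables
#'
#' Columns: sample_id, tissue (proliferative, hyperplasia, eec_stage_i,
#' eec_stage_ii_iv, usc), grade (low/high), figo (I-IV or empty),
#' er_ihc_pct, pr_ihc_pct (0-100), lvsi, deep_mi, residual_disease,
#' recurrence, ec_death (0/1 flags), dfs_months, dss_months. Missing values
#' are empty cells.
#'
#' @param path CSV file.
#' @return data.frame with flags as logicals.
#' @export
read_clinical <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  for (fl in c("lvsi", "deep_mi", "residual_disease", "recurrence", "ec_death"))
    if (fl %in% names(df)) df[[fl]] <- as.logical(df[[fl]])
  df
}

#' @rdname read_clinical
#' @param clinical clinical data.frame.
#' @export
write_clinical <- function(clinical, path) {
  df <- clinical
  for (fl in c("lvsi", "deep_mi", "residual_disease", "recurrence", "ec_death"))
    if (fl %in% names(df)) df[[fl]] <- as.integer(df[[fl]])
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Clinicopathological summary of the endometrial-cancer study cohort
#'
#' Returns the published aggregate counts for the three tumour groups
#' (57 stage I EEC, 12 stage II-IV EEC, 14 USC): treatment, FIGO stage,
#' grade, myometrial invasion, lymphovascular space invasion, recurrence
#' and disease-related mortality, together with the residual-disease
#' exclusions that define the recurrence denominators. Printed percentages
#' are stored verbatim alongside the counts; a few are internally
#' inconsistent as printed (see the fixture file), so computed rates are
#' kept separate (\code{\link{summary_rates}}).
#'
#' @return List of class \code{cohort_summary} with data.frames
#'   \code{groups} (group, n, residual_disease_excluded) and \code{counts}
#'   (group, variable, level, count, printed_pct).
#' @export
load_cohort_summary <- function() {
  dir <- system.file("extdata", package = "eractivity", mustWork = TRUE)
  groups <- utils::read.delim(file.path(dir, "ec_cohort_groups.tsv"),
                              stringsAsFactors = FALSE)
  counts <- utils::read.delim(file.path(dir, "ec_cohort_counts.tsv"),
                              stringsAsFactors = FALSE, comment.char = "#")
  structure(list(groups = groups, counts = counts), class = "cohort_summary")
}

#' Percentages recomputed from cohort summary counts
#'
#' The denominator is the group size, except for the recurrence rows, which
#' are reported among patients without residual disease only; there the
#' denominator is the group size minus the residual-disease exclusions.
#' Percentages are rounded to integer percent, the precision of the
#' published table.
#'
#' @param summary a \code{cohort_summary}
#'   (see \code{\link{load_cohort_summary}}).
#' @return The counts data.frame with added columns \code{denominator},
#'   \code{pct} (exact) and \code{pct_rounded}. Zero denominators yield
#'   \code{NA} with a flag column.
#' @export
summary_rates <- function(summary) {
  stopifnot(inherits(summary, "cohort_summary"))
  counts <- summary$counts
  g <- summary$groups
  n <- g$n[match(counts$group, g$group)]
  excl <- g$residual_disease_excluded[match(counts$group, g$group)]
  denom <- ifelse(counts$variable == "recurrence", n - excl, n)
  counts$denominator <- denom
  counts$undefined <- denom == 0
  counts$pct <- ifelse(counts$undefined, NA_real_, 100 * counts$count / denom)
  counts$pct_rounded <- round(counts$pct)
  counts
}
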