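#' Fit per-gene low/high intensity distributions from ground-truth classes
#'
#' For each gene, location and scale of the expression distribution are
#' estimated separately in the inactive and active calibration classes
#' (mean and SD on the log2 scale, SD floored at \code{sigma_floor} to avoid
#' degenerate certainty). The component with the larger mean becomes the
#' "high" intensity state; the direction flag records whether the active
#' class sits on the high side (+1, activated target) or the low side
#' (-1, repressed target). Genes whose class means coincide are flagged
#' uninformative (direction 0).
#'
#' @param matrix genes x samples numeric matrix, log2 scale.
#' @param labels per-sample class labels, values \code{"active"} /
#'   \code{"inactive"}.
#' @param sigma_floor minimum per-class SD in log2 units (default 0.05).
#' @return data.frame with columns gene_id, mu_low, sigma_low, mu_high,
#'   sigma_high, direction.
#' @export
fit_intensity_map <- function(matrix, labels, sigma_floor = 0.05) {
  stopifnot(is.matrix(matrix), ncol(matrix) == length(labels))
  labels <- as.character(labels)
  if (!all(labels %in% c("active", "inactive")))
    stop("labels must be 'active' or 'inactive'")
  n_act <- sum(labels == "active"); n_inact <- sum(labels == "inactive")
  if (n_act < 3L || n_inact < 3L)
    stop("need at least 3 samples per calibration class")
  act <- matrix[, labels == "active", drop = FALSE]
  ina <- matrix[, labels == "inactive", drop = FALSE]
  mu_a <- rowMeans(act, na.rm = TRUE)
  mu_i <- rowMeans(ina, na.rm = TRUE)
  sd_a <- apply(act, 1, stats::sd, na.rm = TRUE)
  sd_i <- apply(ina, 1, stats::sd, na.rm = TRUE)
  floored <- sum(sd_a < sigma_floor | sd_i < sigma_floor, na.rm = TRUE)
  if (floored > 0)
    warning(sprintf("%d gene/class SDs below %.3g floored", floored, sigma_floor))
  sd_a <- pmax(sd_a, sigma_floor)
  sd_i <- pmax(sd_i, sigma_floor)
  direction <- sign(mu_a - mu_i)
  high_is_active <- mu_a >= mu_i
  out <- data.frame(gene_id = rownames(matrix),
                    mu_low = ifelse(high_is_active, mu_i, mu_a),
                    sigma_low = ifelse(high_is_active, sd_i, sd_a),
                    mu_high = ifelse(high_is_active, mu_a, mu_i),
                    sigma_high = ifelse(high_is_active, sd_a, sd_i),
                    direction = as.integer(direction),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Soft evidence for the "high" intensity state of one gene
#'
#' Posterior responsibility of the high component under equal class priors:
#' \deqn{e(x) = \phi_{high}(x) / (\phi_{high}(x) + \phi_{low}(x))}
#' with normal densities. With equal SDs this reduces to a logistic function
#' of x, monotone increasing; defined for every real x. Computed on the
#' log scale for numerical stability in the far tails.
#'
#' @param map_entry one row of an intensity map (list or data.frame row with
#'   mu_low, sigma_low, mu_high, sigma_high).
#' @param x numeric vector of log2 expression values.
#' @return Evidence weights in [0, 1]; \code{NA} in maps to \code{NA} out.
#' @export
expression_to_evidence <- function(map_entry, x) {
  lh <- stats::dnorm(x, map_entry$mu_high, map_entry$sigma_high, log = TRUE)
  ll <- stats::dnorm(x, map_entry$mu_low,  map_entry$sigma_low,  log = TRUE)
  stats::plogis(lh - ll)
}

#' Convert an expression matrix to per-sample evidence vectors
#'
#' Applies \code{\link{expression_to_evidence}} gene-wise over the overlap
#' between the matrix and the intensity map. Genes absent from the matrix
#' are simply missing from the evidence (the network ignores them); genes in
#' the matrix but not in the map are dropped.
#'
#' @param maps intensity map data.frame from \code{\link{fit_intensity_map}}.
#' @param matrix genes x samples log2 expression matrix.
#' @return Evidence matrix (mapped genes x samples) with values in [0, 1]
#'   and \code{NA} for missing measurements; attribute \code{"overlap"}
#'   holds the number of genes shared by map and matrix.
#' @export
matrix_to_evidence <- function(maps, matrix) {
  stopifnot(is.matrix(matrix))
  shared <- intersect(maps$gene_id, rownames(matrix))
  if (length(shared) == 0L)
    stop("no overlap between intensity map and expression matrix gene ids")
  m <- maps[match(shared, maps$gene_id), , drop = FALSE]
  x <- matrix[shared, , drop = FALSE]
  lh <- stats::dnorm(x, m$mu_high, m$sigma_high, log = TRUE)
  ll <- stats::dnorm(x, m$mu_low,  m$sigma_low,  log = TRUE)
  ev <- stats::plogis(lh - ll)
  dimnames(ev) <- dimnames(x)
  attr(ev, "overlap") <- length(shared)
  ev
}
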