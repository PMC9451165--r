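# Exerkine and assay statistics: AUC induction scoring, Spearman gene
# ranking, comparative delta-delta-Ct, below-detection imputation and IQR
# outlier masking.

trapezoid_auc <- function(y, x) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Area-under-curve induction score of a cytokine time course
#'
#' Trapezoidal integral of the log2 fold change (relative to the baseline
#' timepoint) over time, in logFC x hours. A replicate-by-timepoint matrix
#' is scored per replicate and averaged; by linearity of the trapezoid rule
#' this equals the AUC of the mean trajectory (asserted).
#'
#' @param trajectory Numeric vector (one trajectory) or matrix with one row
#'   per replicate and one column per timepoint.
#' @param times_h Strictly increasing timepoints in hours; the first entry
#'   is the baseline.
#' @param gene,group Optional labels carried into the result.
#' @return A list of class `induction_score`: `gene`, `group`, `auc`,
#'   `mean_trajectory`, `per_replicate_auc`.
#' @examples
#' induction_auc(c(0, 1, 1), times_h = c(0, 0.5, 3.5))$auc  # 3.25
#' @export
induction_auc <- function(trajectory, times_h, gene = NA_character_,
                          group = NA_character_) {
  if (length(times_h) < 2L)
    stop("at least 2 timepoints are required", call. = FALSE)
  if (any(diff(times_h) <= 0))
    stop("times_h must be strictly increasing", call. = FALSE)
  if (is.null(dim(trajectory)))
    trajectory <- matrix(trajectory, nrow = 1L)
  if (ncol(trajectory) != length(times_h))
    stop("trajectory must have one value per timepoint", call. = FALSE)
  per_rep <- apply(trajectory, 1L, trapezoid_auc, x = times_h)
  mean_traj <- colMeans(trajectory)
  auc <- mean(per_rep)
  stopifnot(isTRUE(all.equal(auc, trapezoid_auc(mean_traj, times_h))))
  structure(list(gene = gene, group = group, auc = auc,
                 mean_trajectory = mean_traj, per_replicate_auc = per_rep),
            class = "induction_score")
}

#' Rank genes by Spearman correlation with a target gene
#'
#' Spearman rho (average-rank tie handling) of every other gene's
#' expression with the target gene across samples, sorted in decreasing
#' order; the result feeds [gsea_preranked()].
#'
#' @param x An [expression_matrix()] with at least 3 samples.
#' @param target_gene Gene id present in `x`.
#' @return Named numeric vector of rho values (all genes except the
#'   target), decreasing.
#' @export
spearman_rank_genes <- function(x, target_gene) {
  stopifnot(inherits(x, "expression_matrix"))
  if (!(target_gene %in% x$gene_ids))
    stop("target gene not in matrix: ", target_gene, call. = FALSE)
  if (length(x$sample_ids) < 3L)
    stop("at least 3 samples are required", call. = FALSE)
  target <- x$values[target_gene, ]
  if (sd(target, na.rm = TRUE) == 0 || all(is.na(target)))
    stop("target gene is constant; Spearman rho undefined", call. = FALSE)
  others <- setdiff(x$gene_ids, target_gene)
  rho <- suppressWarnings(
    cor(t(x$values[others, , drop = FALSE]), target,
        method = "spearman", use = "pairwise.complete.obs"))
  sort(setNames(drop(rho), others), decreasing = TRUE, na.last = NA)
}

#' Comparative delta-delta-Ct relative expression
#'
#' `dCt = Ct(target) - mean(Ct(references))` per condition (the arithmetic
#' mean of Ct values realizes the geometric mean of the housekeeping genes
#' in linear expression space), `ddCt = dCt(condition) - dCt(calibrator)`,
#' fold change `2^(-ddCt)`.
#'
#' @param ct_target Named numeric vector of target-gene Ct values, one per
#'   condition.
#' @param ct_references List of named numeric vectors (one per reference
#'   gene, same conditions).
#' @param calibrator_condition Condition name used as calibrator.
#' @return Named numeric vector of fold changes per condition (calibrator
#'   fold is 1).
#' @examples
#' ddct_relative_expression(c(ctrl = 24, trt = 22),
#'   list(c(ctrl = 20, trt = 20)), "ctrl")
#' @export
ddct_relative_expression <- function(ct_target, ct_references,
                                     calibrator_condition) {
  if (!length(ct_references))
    stop("at least one reference gene is required", call. = FALSE)
  conditions <- names(ct_target)
  if (!(calibrator_condition %in% conditions))
    stop("calibrator condition absent: ", calibrator_condition,
         call. = FALSE)
  ref_mat <- vapply(ct_references, function(r) r[conditions],
                    numeric(length(conditions)))
  if (is.null(dim(ref_mat)))
    ref_mat <- matrix(ref_mat, nrow = length(conditions))
  if (any(!is.finite(ct_target)) || any(!is.finite(ref_mat)))
    stop("Ct values must be finite", call. = FALSE)
  ref_value <- rowMeans(ref_mat)
  dct <- ct_target - ref_value
  ddct <- dct - dct[[calibrator_condition]]
  setNames(2^(-ddct), conditions)
}

#' Impute below-detection measurements
#'
#' Flagged values are replaced by the assay's minimum measurable
#' concentration; unflagged values pass through untouched.
#'
#' @param values Numeric vector of measurements.
#' @param below_detection Logical vector marking below-detection entries.
#' @param detection_min Positive kit detection limit.
#' @return List with `values` (imputed vector) and `n_imputed`.
#' @export
impute_below_detection <- function(values, below_detection, detection_min) {
  if (detection_min <= 0)
    stop("detection_min must be positive", call. = FALSE)
  stopifnot(length(values) == length(below_detection))
  values[below_detection] <- detection_min
  list(values = values, n_imputed = sum(below_detection))
}

#' Interquartile-range outlier mask
#'
#' Flags values outside `[Q1 - k*IQR, Q3 + k*IQR]` with
#' linear-interpolation quartiles (R quantile type 7). Mask only: nothing
#' is removed.
#'
#' @param values Numeric vector of at least 4 values.
#' @param k Tukey fence multiplier (default 1.5).
#' @return Logical vector, `TRUE` for outliers.
#' @examples
#' iqr_outlier_mask(c(1, 2, 3, 4, 100))
#' @export
iqr_outlier_mask <- function(values, k = 1.5) {
  if (length(values) < 4L)
    stop("at least 4 values are required", call. = FALSE)
  q <- quantile(values, c(0.25, 0.75), type = 7, names = FALSE)
  iqr <- q[2L] - q[1L]
  values < q[1L] - k * iqr | values > q[2L] + k * iqr
}
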