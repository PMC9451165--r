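# M1/M2 polarization signature derivation and the expression-panel QC and
# filtering rules used by the receptor-expression analysis.

#' Derive M1/M2 polarization signatures from a reference panel
#'
#' Runs three batch-blocked moderated contrasts (M1 vs M0, M2 vs M0,
#' M1 vs M2). A gene joins the M1 signature iff it clears
#' `fdr < fdr_cut` with `logFC > vs_m0_logfc_min` against M0 **and**
#' `fdr < fdr_cut` with `logFC > between_logfc_min` in M1 vs M2; the M2
#' rule is the mirror image (M2 vs M0 up, M1 vs M2 below
#' `-between_logfc_min`). The two signatures are disjoint by construction.
#'
#' @param panel An [expression_matrix()] (log-scale expression).
#' @param metadata [sample_metadata()] with `group` in M0/M1/M2 and
#'   `study_id` identifying the batch; at least 2 batches required.
#' @param fdr_cut FDR threshold for every contrast (default `1e-3`).
#' @param vs_m0_logfc_min Minimum logFC against M0 (default 0).
#' @param between_logfc_min Minimum |logFC| between M1 and M2 (default 2).
#' @return A `signature_definition`: list with `m1_genes`, `m2_genes`, the
#'   thresholds used, and the per-contrast tables in `contrasts`.
#' @export
derive_polarization_signatures <- function(panel, metadata,
                                           fdr_cut = 1e-3,
                                           vs_m0_logfc_min = 0,
                                           between_logfc_min = 2) {
  stopifnot(inherits(panel, "expression_matrix"))
  meta <- metadata[match(panel$sample_ids, metadata$sample_id), ,
                   drop = FALSE]
  states <- c("M0", "M1", "M2")
  missing_state <- setdiff(states, unique(meta$group))
  if (length(missing_state))
    stop("panel lacks polarization state: ",
         paste(missing_state, collapse = ", "), call. = FALSE)
  if (length(unique(meta$study_id)) < 2L)
    stop("at least 2 batches are required for batch blocking",
         call. = FALSE)

  blocked_contrast <- function(num, den) {
    sel <- meta$group %in% c(num, den)
    m <- meta[sel, , drop = FALSE]
    batch <- factor(m$study_id)
    st <- as.integer(m$group == num)
    X <- cbind(model.matrix(~ 0 + batch), state = st)
    colnames(X) <- c(levels(batch), "state")
    rownames(X) <- m$sample_id
    run_de(expression_matrix(panel$values[, m$sample_id, drop = FALSE],
                             panel$value_kind),
           design_spec(X, "state"))
  }
  m1_m0 <- blocked_contrast("M1", "M0")
  m2_m0 <- blocked_contrast("M2", "M0")
  m1_m2 <- blocked_contrast("M1", "M2")

  align <- function(res) res[match(panel$gene_ids, res$gene), ]
  a <- align(m1_m0); b <- align(m2_m0); d <- align(m1_m2)
  in_m1 <- !is.na(a$fdr) & a$fdr < fdr_cut & a$logFC > vs_m0_logfc_min &
    !is.na(d$fdr) & d$fdr < fdr_cut & d$logFC > between_logfc_min
  in_m2 <- !is.na(b$fdr) & b$fdr < fdr_cut & b$logFC > vs_m0_logfc_min &
    !is.na(d$fdr) & d$fdr < fdr_cut & d$logFC < -between_logfc_min
  structure(list(
    m1_genes = panel$gene_ids[in_m1],
    m2_genes = panel$gene_ids[in_m2],
    thresholds = list(fdr_cut = fdr_cut,
                      vs_m0_logfc_min = vs_m0_logfc_min,
                      between_logfc_min = between_logfc_min),
    contrasts = list(m1_vs_m0 = m1_m0, m2_vs_m0 = m2_m0,
                     m1_vs_m2 = m1_m2)
  ), class = "signature_definition")
}

#' @export
print.signature_definition <- function(x, ...) {
  cat(sprintf(
    "signature_definition: %d M1 genes, %d M2 genes (fdr < %g, vs-M0 logFC > %g, between logFC > %g)\n",
    length(x$m1_genes), length(x$m2_genes), x$thresholds$fdr_cut,
    x$thresholds$vs_m0_logfc_min, x$thresholds$between_logfc_min))
  invisible(x)
}

#' Exclude samples with too few detected genes
#'
#' A sample is kept iff the number of genes with count > 0 is at least
#' `min_genes`; strictly fewer drops (a sample at exactly the threshold is
#' kept).
#'
#' @param counts An [expression_matrix()] of kind `"counts"`.
#' @param min_genes Detection threshold (default 15000).
#' @return List with `kept` and `dropped` sample-id vectors and the
#'   per-sample `detected` counts.
#' @export
qc_min_genes_detected <- function(counts, min_genes = 15000) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$value_kind != "counts")
    stop("qc_min_genes_detected requires a counts matrix", call. = FALSE)
  detected <- colSums(counts$values > 0, na.rm = TRUE)
  keep <- detected >= min_genes
  list(kept = counts$sample_ids[keep],
       dropped = counts$sample_ids[!keep],
       detected = detected)
}

#' Filter genes by per-group count sums over arbitrary groups
#'
#' Same contract as [filter_low_counts()] but with arbitrary tissue/cell
#' groups (from the metadata `group` column) and a default per-sample
#' multiplier of 5.
#'
#' @param counts An [expression_matrix()] of kind `"counts"`.
#' @param metadata [sample_metadata()]; its `group` column defines the
#'   groups.
#' @param per_sample_multiplier Per-sample count requirement (default 5).
#' @return The filtered counts matrix.
#' @export
filter_group_expression <- function(counts, metadata,
                                    per_sample_multiplier = 5) {
  meta <- metadata[match(counts$sample_ids, metadata$sample_id), ,
                   drop = FALSE]
  grp <- setNames(meta$group, meta$sample_id)
  group_sum_filter(counts, grp, per_sample_multiplier)
}

#' Depth-adjusted variance-stabilizing expression transform
#'
#' A monotone surrogate for a variance-stabilizing transform:
#' `log2(count / size_factor + 1)` with median-of-ratios size factors.
#' Each sample's size factor is the median, over genes positive in every
#' sample, of the ratio of its count to the geometric mean of the other
#' samples' counts for that gene; the leave-one-out reference makes the
#' size factor exactly equivariant to rescaling a single sample
#' (doubling one column's counts doubles its size factor).
#'
#' @param counts An [expression_matrix()] of kind `"counts"` (filtered).
#' @return An [expression_matrix()] of kind `"expression"`, with the size
#'   factors attached as attribute `size_factors`.
#' @export
stabilize_expression <- function(counts) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$value_kind != "counts")
    stop("stabilize_expression requires a counts matrix", call. = FALSE)
  v <- counts$values
  pos <- rowSums(is.na(v)) == 0L & rowSums(v > 0) == ncol(v)
  if (!any(pos))
    stop("no gene is positive in all samples; cannot form the ",
         "size-factor reference", call. = FALSE)
  lv <- log(v[pos, , drop = FALSE])
  n <- ncol(lv)
  total <- rowSums(lv)
  sf <- vapply(seq_len(n), function(j) {
    ref <- exp((total - lv[, j]) / (n - 1))   # leave-one-out geometric mean
    median(exp(lv[, j]) / ref)
  }, numeric(1))
  names(sf) <- counts$sample_ids
  out <- log2(sweep(v, 2L, sf, `/`) + 1)
  em <- expression_matrix(out, "expression")
  attr(em, "size_factors") <- sf
  em
}
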