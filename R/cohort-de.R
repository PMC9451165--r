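# Cohort analysis: count filtering, logCPM normalization, paired per-group
# contrasts, exercise-by-diagnosis interaction ranking, overlap partition
# and a sample-correlation QC report.

# Shared group-sum filter: keep a gene iff, for at least one group, its
# count sum over that group's samples is >= group size * multiplier
# (equality retains).
group_sum_filter <- function(counts, groups, per_sample_multiplier) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$value_kind != "counts")
    stop("filtering requires a counts matrix", call. = FALSE)
  groups <- groups[counts$sample_ids]
  if (any(is.na(groups)))
    stop("every sample needs a group assignment", call. = FALSE)
  tab <- table(groups)
  empty <- names(tab)[tab == 0]
  if (length(empty))
    stop("group with zero samples: ", paste(empty, collapse = ", "),
         call. = FALSE)
  keep <- rep(FALSE, length(counts$gene_ids))
  for (g in names(tab)) {
    cols <- which(groups == g)
    sums <- rowSums(counts$values[, cols, drop = FALSE], na.rm = TRUE)
    keep <- keep | (sums >= length(cols) * per_sample_multiplier)
  }
  counts$values <- counts$values[keep, , drop = FALSE]
  counts$gene_ids <- counts$gene_ids[keep]
  counts
}

#' Filter cohort counts by per-group abundance
#'
#' A gene is retained iff, in at least one of the six diagnosis-by-timepoint
#' groups, the sum of its counts over that group's samples reaches the
#' group size times `per_sample_multiplier` (equality retains).
#'
#' @param counts An [expression_matrix()] of kind `"counts"`.
#' @param metadata [sample_metadata()] covering all samples, defining
#'   exactly six non-empty groups (NGT/T2D x pre/post/recovery).
#' @param per_sample_multiplier Per-sample count requirement (default 10).
#' @return The filtered counts matrix.
#' @export
filter_low_counts <- function(counts, metadata, per_sample_multiplier = 10) {
  meta <- metadata[match(counts$sample_ids, metadata$sample_id), ,
                   drop = FALSE]
  grp <- setNames(paste(meta$group, meta$timepoint, sep = "."),
                  meta$sample_id)
  if (length(unique(grp)) != 6L)
    stop("metadata must define exactly six diagnosis x timepoint groups, ",
         "found: ", length(unique(grp)), call. = FALSE)
  group_sum_filter(counts, grp, per_sample_multiplier)
}

#' log2 counts-per-million normalization
#'
#' `logCPM = log2((count + 0.5) / (library size + 1) * 1e6)` with the
#' library size the per-sample column sum of the (filtered) counts.
#'
#' @param counts An [expression_matrix()] of kind `"counts"`.
#' @return An [expression_matrix()] of kind `"logcpm"`.
#' @export
normalize_log_cpm <- function(counts) {
  stopifnot(inherits(counts, "expression_matrix"))
  if (counts$value_kind != "counts")
    stop("normalize_log_cpm requires a counts matrix", call. = FALSE)
  lib <- colSums(counts$values, na.rm = TRUE)
  zero <- names(lib)[lib == 0]
  if (length(zero))
    stop("zero library size for sample: ", paste(zero, collapse = ", "),
         call. = FALSE)
  logcpm <- log2(sweep(counts$values + 0.5, 2L, lib + 1, `/`) * 1e6)
  expression_matrix(logcpm, "logcpm")
}

#' Paired within-group timepoint contrast
#'
#' Subject-blocked moderated differential expression of one timepoint
#' against another within a diagnosis group: the design carries one
#' fixed-effect column per subject plus the timepoint indicator, so the
#' contrast estimate is the mean within-subject delta.
#'
#' @param logcpm An [expression_matrix()] (typically logCPM).
#' @param metadata [sample_metadata()].
#' @param group Diagnosis group to analyze (`"NGT"` or `"T2D"`).
#' @param contrast Length-2 character vector `c(numerator, denominator)`
#'   of timepoints, e.g. `c("post", "pre")`.
#' @return A [moderated_test()] data frame (gene, logFC, t, p_value, fdr).
#' @export
paired_contrasts <- function(logcpm, metadata, group,
                             contrast = c("post", "pre")) {
  stopifnot(length(contrast) == 2L)
  meta <- metadata[metadata$group == group &
                     metadata$timepoint %in% contrast, , drop = FALSE]
  if (!nrow(meta))
    stop("group ", group, " absent from metadata", call. = FALSE)
  tp_per_subj <- tapply(meta$timepoint, meta$subject_id,
                        function(z) length(unique(z)))
  unpaired <- names(tp_per_subj)[tp_per_subj < 2L]
  if (length(unpaired))
    stop("subject without both timepoints: ",
         paste(unpaired, collapse = ", "), call. = FALSE)
  subj <- factor(meta$subject_id)
  tp <- as.integer(meta$timepoint == contrast[1L])
  X <- cbind(model.matrix(~ 0 + subj), delta = tp)
  colnames(X) <- c(levels(subj), "delta")
  rownames(X) <- meta$sample_id
  res <- run_de(expression_matrix(
    logcpm$values[, meta$sample_id, drop = FALSE], logcpm$value_kind),
    design_spec(X, "delta"))
  res
}

#' Rank genes by the exercise-by-diagnosis interaction at recovery
#'
#' Per gene, the interaction effect is the paired recovery-vs-pre logFC in
#' T2D minus the paired recovery-vs-pre logFC in NGT (each the mean
#' within-subject delta). Output is sorted by decreasing interaction and
#' feeds [gsea_preranked()].
#'
#' @param logcpm An [expression_matrix()].
#' @param metadata [sample_metadata()] with both diagnosis groups paired at
#'   pre and recovery.
#' @return Data frame `gene`, `interaction_logfc`, sorted descending.
#' @export
interaction_ranking <- function(logcpm, metadata) {
  for (g in c("NGT", "T2D"))
    if (!any(metadata$group == g))
      stop("missing diagnosis group: ", g, call. = FALSE)
  t2d <- paired_contrasts(logcpm, metadata, "T2D",
                          contrast = c("recovery", "pre"))
  ngt <- paired_contrasts(logcpm, metadata, "NGT",
                          contrast = c("recovery", "pre"))
  common <- intersect(t2d$gene, ngt$gene)
  inter <- setNames(t2d$logFC[match(common, t2d$gene)] -
                      ngt$logFC[match(common, ngt$gene)], common)
  inter <- sort(inter, decreasing = TRUE)
  data.frame(gene = names(inter), interaction_logfc = as.numeric(inter),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Partition two gene sets into exclusive and shared members
#'
#' @param set_a,set_b Character vectors of gene ids.
#' @return List with `counts` (`a_only`, `both`, `b_only`) and the member
#'   lists `a_only`, `both`, `b_only`.
#' @export
overlap_partition <- function(set_a, set_b) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  both <- intersect(set_a, set_b)
  a_only <- setdiff(set_a, set_b)
  b_only <- setdiff(set_b, set_a)
  list(counts = c(a_only = length(a_only), both = length(both),
                  b_only = length(b_only)),
       a_only = a_only, both = both, b_only = b_only)
}

#' Inter-sample correlation QC report
#'
#' Flags samples whose median Spearman correlation with all other samples
#' falls below a threshold. Report only: no sample is ever dropped
#' automatically.
#'
#' @param x An [expression_matrix()].
#' @param min_median_rho Flagging threshold (default 0.8).
#' @return Data frame `sample_id`, `median_rho`, `flagged`.
#' @export
qc_sample_correlation <- function(x, min_median_rho = 0.8) {
  stopifnot(inherits(x, "expression_matrix"))
  cm <- cor(x$values, method = "spearman",
            use = "pairwise.complete.obs")
  diag(cm) <- NA
  med <- apply(cm, 2L, median, na.rm = TRUE)
  data.frame(sample_id = x$sample_ids, median_rho = as.numeric(med),
             flagged = as.numeric(med) < min_median_rho,
             row.names = NULL, stringsAsFactors = FALSE)
}
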