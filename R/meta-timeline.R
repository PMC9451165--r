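# Cross-study timeline meta-analysis: per-study pre/post collapse,
# missingness filtering, per-category moderated contrasts, peak-time
# assignment and averaged transcriptional waves.

#' Collapse a study's paired samples to per-gene pre/post deltas
#'
#' For one study, computes per gene the mean over subjects of
#' (post - pre); a subject contributes only where both arms are observed,
#' and a gene with no complete pair in any subject is missing in the output.
#'
#' @param x An [expression_matrix()] holding the study's samples.
#' @param metadata [sample_metadata()] for those samples, with `timepoint`
#'   `"pre"`/`"post"` and one row per sample.
#' @return Named numeric vector of per-gene deltas (`NA` where missing).
#' @export
collapse_study_prepost <- function(x, metadata) {
  stopifnot(inherits(x, "expression_matrix"))
  metadata <- metadata[metadata$sample_id %in% x$sample_ids, , drop = FALSE]
  subj <- unique(metadata$subject_id)
  study <- unique(metadata$study_id)
  pairs <- lapply(subj, function(s) {
    pre <- metadata$sample_id[metadata$subject_id == s &
                                metadata$timepoint == "pre"]
    post <- metadata$sample_id[metadata$subject_id == s &
                                 metadata$timepoint == "post"]
    if (length(pre) == 1L && length(post) == 1L) c(pre, post) else NULL
  })
  pairs <- Filter(Negate(is.null), pairs)
  if (!length(pairs))
    stop("study ", paste(study, collapse = ","),
         " has no complete pre/post pair", call. = FALSE)
  deltas <- vapply(pairs, function(pp) {
    x$values[, pp[2L]] - x$values[, pp[1L]]
  }, numeric(length(x$gene_ids)))
  if (is.null(dim(deltas)))   # single gene: vapply returned one value per pair
    deltas <- matrix(deltas, nrow = length(x$gene_ids))
  out <- rowMeans(deltas, na.rm = TRUE)
  out[rowSums(!is.na(deltas)) == 0L] <- NA_real_
  setNames(out, x$gene_ids)
}

#' Filter timeline genes by cross-study missingness
#'
#' A gene is retained iff its fraction of missing studies is at most
#' `max_missing`: strictly more than the threshold excludes, exactly at the
#' threshold retains (with the 20% default, a gene missing in 2 of 10
#' studies stays, 3 of 10 goes).
#'
#' @param panel A `timeline_panel` (see [simulate_timeline_studies()]).
#' @param max_missing Maximum tolerated missing fraction in `[0, 1)`.
#' @return The panel restricted to surviving genes.
#' @export
filter_missingness <- function(panel, max_missing = 0.2) {
  stopifnot(inherits(panel, "timeline_panel"))
  if (max_missing < 0 || max_missing >= 1)
    stop("max_missing must be in [0, 1)", call. = FALSE)
  if (nrow(panel$deltas) == 0L || ncol(panel$deltas) == 0L)
    stop("empty timeline panel", call. = FALSE)
  frac <- rowMeans(is.na(panel$deltas))
  keep <- frac <= max_missing
  panel$deltas <- panel$deltas[keep, , drop = FALSE]
  panel
}

#' Per-category timeline contrasts
#'
#' For each time category with at least 2 studies, fits a study-level
#' moderated model of the per-study deltas against 0: the per-gene effect
#' is the covariate-adjusted mean of study deltas (intercept of an
#' intercept + mean-centred study-covariate model), tested with the
#' moderated t and Benjamini-Hochberg FDR within the category. Covariates
#' (age, sex, sedentary, weight) are included only when at least 2 residual
#' degrees of freedom remain; categories with fewer than 2 studies are
#' reported as absent (`NA` columns).
#'
#' @param panel A filtered `timeline_panel`.
#' @param fdr_threshold Significance threshold recorded in the result and
#'   used by downstream peak assignment (0.05 by default; 0.1 is a
#'   documented alternative).
#' @return A `timeline_result`: list with gene-by-category matrices
#'   `effects` and `fdr`, `categories_present`, and `fdr_threshold`.
#' @export
timeline_contrasts <- function(panel, fdr_threshold = 0.05) {
  stopifnot(inherits(panel, "timeline_panel"))
  genes <- rownames(panel$deltas)
  effects <- fdr <- matrix(NA_real_, length(genes), length(TIME_CATEGORIES),
                           dimnames = list(genes, TIME_CATEGORIES))
  covars <- intersect(c("age", "sex", "sedentary", "weight"),
                      colnames(panel$studies))
  present <- character()
  for (cat in TIME_CATEGORIES) {
    idx <- which(panel$studies$time_category == cat)
    if (length(idx) < 2L) next
    present <- c(present, cat)
    sub <- panel$deltas[, idx, drop = FALSE]
    em <- expression_matrix(sub, "logfc")
    n <- length(idx)
    X <- matrix(1, n, 1L, dimnames = list(colnames(sub), "intercept"))
    if (length(covars) && n - (1L + length(covars)) >= 2L) {
      cv <- as.matrix(panel$studies[idx, covars, drop = FALSE])
      cv <- scale(cv, center = TRUE, scale = FALSE)
      ok <- apply(cv, 2L, function(col) var(col) > 0)
      if (any(ok))
        X <- cbind(X, cv[, ok, drop = FALSE])
    }
    spec <- design_spec(X, "intercept")
    res <- run_de(em, spec)
    effects[res$gene, cat] <- res$logFC
    fdr[res$gene, cat] <- res$fdr
  }
  if (!length(present))
    stop("no time category has at least 2 studies", call. = FALSE)
  structure(list(effects = effects, fdr = fdr,
                 categories_present = present,
                 fdr_threshold = fdr_threshold),
            class = "timeline_result")
}

#' Assign per-gene peak times
#'
#' A gene is significant iff its FDR falls below the threshold in at least
#' one category; its peak is the category with maximal `|logFC|` among the
#' categories where it is individually significant, ties broken to the
#' earliest category. Non-significant genes are absent from the mapping.
#'
#' @param result A `timeline_result` from [timeline_contrasts()].
#' @param fdr_threshold Per-category significance threshold (defaults to
#'   the threshold recorded in the result).
#' @return Named character vector `gene -> time category`.
#' @export
assign_peak_times <- function(result, fdr_threshold = result$fdr_threshold) {
  stopifnot(inherits(result, "timeline_result"))
  peaks <- character()
  for (g in rownames(result$effects)) {
    sig <- which(!is.na(result$fdr[g, ]) & result$fdr[g, ] < fdr_threshold)
    if (!length(sig)) next
    lfc <- abs(result$effects[g, sig])
    # which.max returns the first maximum; categories are in time order,
    # so ties already break to the earliest category
    peaks[g] <- TIME_CATEGORIES[sig[which.max(lfc)]]
  }
  peaks
}

#' Average transcriptional waves by peak group
#'
#' For each peak category, the wave is the per-category arithmetic mean of
#' logFC over the genes assigned that peak (missing entries excluded from
#' each mean). Peak groups with no genes are omitted.
#'
#' @param result A `timeline_result`.
#' @param peaks Peak mapping from [assign_peak_times()] (computed if
#'   omitted).
#' @return Matrix with one row per occupied peak category and one column
#'   per time category.
#' @export
average_waves <- function(result, peaks = assign_peak_times(result)) {
  stopifnot(inherits(result, "timeline_result"))
  groups <- TIME_CATEGORIES[TIME_CATEGORIES %in% unique(peaks)]
  waves <- matrix(NA_real_, length(groups), length(TIME_CATEGORIES),
                  dimnames = list(groups, TIME_CATEGORIES))
  for (gp in groups) {
    members <- names(peaks)[peaks == gp]
    waves[gp, ] <- colMeans(result$effects[members, , drop = FALSE],
                            na.rm = TRUE)
  }
  waves[is.nan(waves)] <- NA_real_
  waves
}

#' Run the timeline analysis end to end on files
#'
#' Reads a panel (deltas TSV + study metadata TSV), applies the missingness
#' filter, fits the per-category contrasts, assigns peaks, averages waves
#' and writes `effects.tsv`, `fdr.tsv`, `peaks.tsv`, `waves.tsv` and a JSON
#' run report into `out_dir`.
#'
#' @param deltas_path TSV of per-study gene deltas (genes x studies).
#' @param studies_path TSV of study metadata with columns `study_id`,
#'   `time_category` and optional covariates.
#' @param out_dir Output directory (created if needed).
#' @param max_missing,fdr_threshold Stage parameters.
#' @return Invisibly, the `timeline_result` with peaks and waves attached.
#' @export
run_timeline_pipeline <- function(deltas_path, studies_path, out_dir,
                                  max_missing = 0.2, fdr_threshold = 0.05) {
  em <- read_expression_matrix(deltas_path, "logfc")
  studies <- read.delim(studies_path, sep = "\t", check.names = FALSE,
                        stringsAsFactors = FALSE)
  if (!all(c("study_id", "time_category") %in% colnames(studies)))
    stop("study metadata needs columns study_id and time_category",
         call. = FALSE)
  panel <- structure(list(deltas = em$values[, studies$study_id,
                                             drop = FALSE],
                          studies = studies),
                     class = "timeline_panel")
  panel <- filter_missingness(panel, max_missing)
  result <- timeline_contrasts(panel, fdr_threshold)
  peaks <- assign_peak_times(result)
  waves <- average_waves(result, peaks)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(expression_matrix(result$effects, "logfc"),
                          file.path(out_dir, "effects.tsv"))
  write_expression_matrix(
    expression_matrix(result$fdr, "expression"),
    file.path(out_dir, "fdr.tsv"))
  write.table(data.frame(gene = names(peaks), peak_time = peaks,
                         stringsAsFactors = FALSE),
              file.path(out_dir, "peaks.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_expression_matrix(expression_matrix(waves, "logfc"),
                          file.path(out_dir, "waves.tsv"))
  report <- list(
    n_genes_analyzed = nrow(result$effects),
    categories_present = result$categories_present,
    fdr_threshold = fdr_threshold,
    n_significant = length(peaks),
    peak_counts = as.list(table(peaks))
  )
  jsonlite::write_json(report, file.path(out_dir, "timeline_report.json"),
                       auto_unbox = TRUE, digits = NA)
  result$peaks <- peaks
  result$waves <- waves
  invisible(result)
}
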