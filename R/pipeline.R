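# File-based entry points: each writes the TSV/JSON formats of the data-io
# module so that a full run is a chain of directories, mirroring the
# simulate / timeline / cohort-de / signatures / enrich / induction
# subcommands of the command-line wrapper (inst/cli/exerwave.R).

write_truth_json <- function(truth, path) {
  # named atomic vectors must become JSON objects, not nameless arrays
  keep_names <- function(x) {
    if (is.list(x)) lapply(x, keep_names)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  jsonlite::write_json(keep_names(truth), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Simulate a dataset and write it to a directory
#'
#' Dispatches on `kind` to the matching generator, writing the matrix and
#' metadata TSVs plus `truth.json` into `out_dir`.
#'
#' @param kind One of `"timeline"`, `"cohort"`, `"polarization"`,
#'   `"cytokine"`.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param ... Passed to the generator.
#' @return Invisibly, the generator's return value.
#' @export
run_simulate <- function(kind = c("timeline", "cohort", "polarization",
                                  "cytokine"),
                         out_dir, seed = 1L, ...) {
  kind <- match.arg(kind)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- switch(kind,
    timeline = {
      s <- simulate_timeline_studies(seed = seed, ...)
      write_expression_matrix(
        expression_matrix(s$panel$deltas, "logfc"),
        file.path(out_dir, "deltas.tsv"))
      write.table(s$panel$studies, file.path(out_dir, "studies.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      s
    },
    cohort = {
      s <- simulate_cohort_counts(seed = seed, ...)
      write_expression_matrix(s$counts, file.path(out_dir, "counts.tsv"))
      write_sample_metadata(s$metadata, file.path(out_dir, "metadata.tsv"))
      s
    },
    polarization = {
      s <- simulate_polarization_panel(seed = seed, ...)
      write_expression_matrix(s$panel, file.path(out_dir, "panel.tsv"))
      write_sample_metadata(s$metadata, file.path(out_dir, "metadata.tsv"))
      s
    },
    cytokine = {
      s <- simulate_cytokine_timecourse(seed = seed, ...)
      write_expression_matrix(s$logfc, file.path(out_dir, "logfc.tsv"))
      s
    })
  write_truth_json(sim$truth, file.path(out_dir, "truth.json"))
  invisible(sim)
}

#' Run the paired cohort analysis on files
#'
#' Reads counts and metadata, applies the six-group count filter and logCPM
#' normalization, runs the four paired contrasts (post/recovery vs pre in
#' NGT and T2D), the interaction ranking, and the overlap partition of the
#' two recovery significance sets, writing per-contrast TSVs,
#' `interaction_ranking.tsv`, `overlap.json` and `qc_samples.tsv`.
#'
#' @param counts_path,metadata_path Input TSVs.
#' @param out_dir Output directory.
#' @param fdr_threshold Significance threshold for list membership
#'   (default 0.01).
#' @param per_sample_multiplier Count-filter multiplier (default 10).
#' @return Invisibly, a list with the four contrast tables, the ranking and
#'   the overlap partition.
#' @export
run_cohort_pipeline <- function(counts_path, metadata_path, out_dir,
                                fdr_threshold = 0.01,
                                per_sample_multiplier = 10) {
  counts <- read_expression_matrix(counts_path, "counts")
  meta <- read_sample_metadata(metadata_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  filtered <- filter_low_counts(counts, meta, per_sample_multiplier)
  logcpm <- normalize_log_cpm(filtered)
  contrasts <- list()
  for (g in c("NGT", "T2D")) {
    for (tp in c("post", "recovery")) {
      nm <- sprintf("%s_%s_vs_pre", g, tp)
      res <- paired_contrasts(logcpm, meta, g, contrast = c(tp, "pre"))
      write.table(res, file.path(out_dir, paste0(nm, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      contrasts[[nm]] <- res
    }
  }
  ranking <- interaction_ranking(logcpm, meta)
  write.table(ranking, file.path(out_dir, "interaction_ranking.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  sig <- function(res) res$gene[res$fdr < fdr_threshold]
  ov <- overlap_partition(sig(contrasts$NGT_recovery_vs_pre),
                          sig(contrasts$T2D_recovery_vs_pre))
  jsonlite::write_json(
    list(fdr_threshold = fdr_threshold,
         ngt_only = ov$counts[["a_only"]], both = ov$counts[["both"]],
         t2d_only = ov$counts[["b_only"]]),
    file.path(out_dir, "overlap.json"), auto_unbox = TRUE, digits = NA)
  write.table(qc_sample_correlation(logcpm),
              file.path(out_dir, "qc_samples.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(list(contrasts = contrasts, ranking = ranking, overlap = ov))
}

#' Derive polarization signatures from files
#'
#' @param panel_path,metadata_path Input TSVs (log-scale expression panel).
#' @param out_dir Output directory; writes `signatures.gmt` and a JSON
#'   derivation report.
#' @param ... Passed to [derive_polarization_signatures()].
#' @return Invisibly, the `signature_definition`.
#' @export
run_signatures_pipeline <- function(panel_path, metadata_path, out_dir,
                                    ...) {
  panel <- read_expression_matrix(panel_path, "expression")
  meta <- read_sample_metadata(metadata_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sig <- derive_polarization_signatures(panel, meta, ...)
  sets <- list()
  if (length(sig$m1_genes)) sets$M1 <- sig$m1_genes
  if (length(sig$m2_genes)) sets$M2 <- sig$m2_genes
  if (length(sets))
    write_gene_sets_gmt(
      gene_set_collection(sets,
                          setNames(rep("polarization signature",
                                       length(sets)), names(sets))),
      file.path(out_dir, "signatures.gmt"))
  jsonlite::write_json(
    list(n_m1 = length(sig$m1_genes), n_m2 = length(sig$m2_genes),
         thresholds = sig$thresholds),
    file.path(out_dir, "signatures_report.json"),
    auto_unbox = TRUE, digits = NA)
  invisible(sig)
}

#' Run enrichment on files
#'
#' `mode = "gsea"` expects a two-column ranking TSV (gene, score) and a GMT
#' file; `mode = "ora"` expects a one-column gene-list TSV, a GMT file and
#' a universe TSV. Results are written as `enrichment.tsv`.
#'
#' @param input_path Ranking or gene-list TSV.
#' @param gmt_path GMT gene sets.
#' @param out_dir Output directory.
#' @param mode `"gsea"` or `"ora"`.
#' @param universe_path Universe gene list (required for `"ora"`).
#' @param seed Integer seed for the GSEA permutation stream.
#' @param ... Passed to [gsea_preranked()].
#' @return Invisibly, the enrichment data frame.
#' @export
run_enrich_pipeline <- function(input_path, gmt_path, out_dir,
                                mode = c("gsea", "ora"),
                                universe_path = NULL, seed = 1L, ...) {
  mode <- match.arg(mode)
  sets <- read_gene_sets_gmt(gmt_path)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (mode == "gsea") {
    rk <- read.delim(input_path, sep = "\t", stringsAsFactors = FALSE)
    scores <- setNames(as.numeric(rk[[2L]]), rk[[1L]])
    res <- gsea_preranked(scores, sets, seed = seed, ...)
  } else {
    if (is.null(universe_path))
      stop("ora mode requires universe_path", call. = FALSE)
    query <- read.delim(input_path, sep = "\t",
                        stringsAsFactors = FALSE)[[1L]]
    universe <- read.delim(universe_path, sep = "\t",
                           stringsAsFactors = FALSE)[[1L]]
    rows <- lapply(names(sets$sets), function(nm) {
      r <- fisher_overrepresentation(query, sets$sets[[nm]], universe)
      r$set_name <- nm
      r
    })
    res <- do.call(rbind, rows)
    res$fdr <- bh_fdr(res$p_value)
  }
  write.table(res, file.path(out_dir, "enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(res)
}

#' Score induction AUCs from a time-course file
#'
#' Reads a logFC matrix whose columns are named `rep<r>_t<time>` (as
#' written by the cytokine simulator), scores each gene's replicate
#' trajectories with [induction_auc()] and writes `induction.tsv`.
#'
#' @param logfc_path Input TSV.
#' @param out_dir Output directory.
#' @return Invisibly, the data frame of AUC scores.
#' @export
run_induction_pipeline <- function(logfc_path, out_dir) {
  em <- read_expression_matrix(logfc_path, "logfc")
  parts <- regmatches(em$sample_ids,
                      regexec("^rep([0-9]+)_t([0-9.]+)$", em$sample_ids))
  if (any(lengths(parts) != 3L))
    stop("column names must follow rep<r>_t<time>", call. = FALSE)
  reps <- as.integer(vapply(parts, `[`, character(1), 2L))
  times <- as.numeric(vapply(parts, `[`, character(1), 3L))
  times_h <- sort(unique(times))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  scores <- lapply(em$gene_ids, function(g) {
    traj <- matrix(NA_real_, length(unique(reps)), length(times_h))
    for (i in seq_along(em$sample_ids))
      traj[reps[i], match(times[i], times_h)] <- em$values[g, i]
    s <- induction_auc(traj, times_h, gene = g)
    data.frame(gene = g, auc = s$auc,
               t(setNames(s$mean_trajectory,
                          sprintf("mean_t%g", times_h))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, scores)
  write.table(out, file.path(out_dir, "induction.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
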