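cohort_meta <- function(n_per_group) {
  g <- expand.grid(timepoint = c("pre", "post", "recovery"),
                   subject = seq_len(n_per_group),
                   group = c("NGT", "T2D"), stringsAsFactors = FALSE)
  sample_metadata(data.frame(
    sample_id = sprintf("%s_s%02d_%s", g$group, g$subject, g$timepoint),
    study_id = "cohort",
    subject_id = sprintf("%s_s%02d", g$group, g$subject),
    group = g$group, timepoint = g$timepoint, time_category = "none",
    stringsAsFactors = FALSE))
}

test_that("count filter applies the group-sum rule with equality retained", {
  meta <- cohort_meta(3)   # six groups of 3, threshold 30 per group
  v <- matrix(0L, 3, 18, dimnames = list(
    c("allzero", "boundary", "below"), meta$sample_id))
  # per-sample values giving group sums (29,29,29,29,29,30): one qualifying
  groups <- paste(meta$group, meta$timepoint)
  sums <- c(29, 29, 29, 29, 29, 30)
  for (i in seq_along(unique(groups))) {
    cols <- which(groups == unique(groups)[i])
    v["boundary", cols] <- c(10, 10, sums[i] - 20)
    v["below", cols] <- c(9, 10, 10)   # all groups sum 29 < 30
  }
  em <- expression_matrix(v, "counts")
  kept <- filter_low_counts(em, meta, 10)
  expect_identical(kept$gene_ids, "boundary")
})

test_that("count filter matches a brute-force recount and is idempotent", {
  set.seed(9)
  meta <- cohort_meta(3)
  v <- matrix(rnbinom(50 * 18, mu = 8, size = 2), 50, 18,
              dimnames = list(sprintf("g%02d", 1:50), meta$sample_id))
  em <- expression_matrix(v, "counts")
  kept <- filter_low_counts(em, meta, 10)
  groups <- paste(meta$group, meta$timepoint)
  manual <- apply(v, 1, function(row) {
    any(vapply(unique(groups), function(g) {
      cols <- groups == g
      sum(row[cols]) >= sum(cols) * 10
    }, logical(1)))
  })
  expect_identical(kept$gene_ids, rownames(v)[manual])
  again <- filter_low_counts(kept, meta, 10)
  expect_identical(again$values, kept$values)
  # surviving set never contains a failing gene (direct recount)
  for (g in kept$gene_ids) {
    sums <- tapply(v[g, ], groups, sum)
    sizes <- tapply(v[g, ], groups, length)
    expect_true(any(sums >= sizes * 10))
  }
})

test_that("count filter validates the six-group design", {
  meta <- cohort_meta(2)
  v <- matrix(5L, 2, 12, dimnames = list(c("g1", "g2"), meta$sample_id))
  em <- expression_matrix(v, "counts")
  meta_bad <- meta
  meta_bad$timepoint[meta_bad$timepoint == "recovery"] <- "post"
  expect_error(filter_low_counts(em, meta_bad, 10), "six")
})

test_that("logCPM is scale-invariant, matches its closed form, and is monotone", {
  # proportional columns: identical logCPM up to the 0.5 prior count,
  # negligible at these depths
  v <- matrix(c(4e5, 6e5, 8e5, 12e5), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  lc <- normalize_log_cpm(expression_matrix(v, "counts"))
  expect_equal(lc$values[, "s1"], lc$values[, "s2"], tolerance = 1e-5)

  big <- matrix(c(0, 1e6 - 0), 2, 1,
                dimnames = list(c("zero", "rest"), "s1"))
  lc2 <- normalize_log_cpm(expression_matrix(big, "counts"))
  expect_equal(unname(lc2$values["zero", 1]),
               log2(0.5 / (1e6 + 1) * 1e6), tolerance = 1e-12)
  expect_lt(abs(lc2$values["zero", 1] + 1), 1e-5)

  set.seed(2)
  v3 <- matrix(rnbinom(40, mu = 50, size = 1), 20, 2,
               dimnames = list(sprintf("g%d", 1:20), c("s1", "s2")))
  lc3 <- normalize_log_cpm(expression_matrix(v3, "counts"))
  ord <- order(v3[, 1])
  expect_true(all(diff(lc3$values[ord, 1]) >= 0))

  zero_lib <- matrix(c(1L, 0L), 1, 2,
                     dimnames = list("g1", c("ok", "empty")))
  expect_error(normalize_log_cpm(expression_matrix(zero_lib, "counts")),
               "empty")
})

test_that("paired contrasts are null on identical arms and antisymmetric", {
  meta <- cohort_meta(4)
  set.seed(8)
  v <- matrix(rnorm(30 * nrow(meta), 6), 30,
              dimnames = list(sprintf("g%d", 1:30), meta$sample_id))
  pre <- meta$sample_id[meta$timepoint == "pre"]
  post <- meta$sample_id[meta$timepoint == "post"]
  v[, post] <- v[, pre]   # identical pre and post columns per subject
  em <- expression_matrix(v, "logcpm")
  res <- paired_contrasts(em, meta, "NGT", c("post", "pre"))
  expect_lt(max(abs(res$logFC)), 1e-10)
  expect_gt(min(res$fdr), 0.01)   # nothing significant on identical arms

  v[, post] <- v[, pre] + rnorm(length(v[, post]), 0.5)
  em2 <- expression_matrix(v, "logcpm")
  fwd <- paired_contrasts(em2, meta, "NGT", c("post", "pre"))
  rev <- paired_contrasts(em2, meta, "NGT", c("pre", "post"))
  expect_equal(fwd$logFC, -rev$logFC, tolerance = 1e-12)
  expect_equal(fwd$p_value, rev$p_value, tolerance = 1e-12)
})

test_that("paired contrasts name unpaired subjects", {
  meta <- cohort_meta(3)
  meta <- meta[!(meta$subject_id == "NGT_s02" & meta$timepoint == "pre"), ]
  v <- matrix(rnorm(5 * nrow(meta)), 5,
              dimnames = list(sprintf("g%d", 1:5), meta$sample_id))
  expect_error(
    paired_contrasts(expression_matrix(v, "logcpm"), meta, "NGT",
                     c("post", "pre")),
    "NGT_s02")
})

test_that("planted exercise genes are recovered at FDR < 0.01", {
  sim <- simulate_cohort_counts(n_per_group = 8, n_genes = 600,
                                planted_exercise_genes = 40,
                                planted_interaction_genes = 0,
                                effect_logfc = 2, seed = 23)
  lc <- normalize_log_cpm(filter_low_counts(sim$counts, sim$metadata))
  for (g in c("NGT", "T2D")) {
    de <- paired_contrasts(lc, sim$metadata, g, c("post", "pre"))
    sig <- de$gene[de$fdr < 0.01]
    recall <- mean(sim$truth$planted_exercise_genes %in% sig)
    expect_gte(recall, 0.8)
  }
})

test_that("interaction ranking cancels symmetric responses and flips with labels", {
  meta <- cohort_meta(4)
  set.seed(14)
  v <- matrix(rnorm(20 * nrow(meta), 5), 20,
              dimnames = list(sprintf("g%d", 1:20), meta$sample_id))
  # recovery = that subject's pre + 1 in both groups: identical paired
  # responses, so the interaction cancels exactly
  rec_ids <- meta$sample_id[meta$timepoint == "recovery"]
  pre_of <- function(ids) {
    vapply(ids, function(id) {
      subj <- meta$subject_id[meta$sample_id == id]
      meta$sample_id[meta$subject_id == subj & meta$timepoint == "pre"]
    }, character(1))
  }
  v[, rec_ids] <- v[, pre_of(rec_ids)] + 1
  em <- expression_matrix(v, "logcpm")
  rk <- interaction_ranking(em, meta)
  expect_lt(max(abs(rk$interaction_logfc)), 1e-10)

  t2d_rec <- meta$sample_id[meta$timepoint == "recovery" &
                              meta$group == "T2D"]
  v[, t2d_rec] <- v[, t2d_rec] + 2
  em2 <- expression_matrix(v, "logcpm")
  rk2 <- interaction_ranking(em2, meta)
  meta_sw <- meta
  meta_sw$group <- ifelse(meta$group == "T2D", "NGT", "T2D")
  meta_sw$sample_id <- meta$sample_id
  rk_sw <- interaction_ranking(em2, meta_sw)
  expect_equal(sort(rk2$interaction_logfc),
               sort(-rk_sw$interaction_logfc), tolerance = 1e-10)

  meta_missing <- meta[meta$group == "NGT", ]
  expect_error(interaction_ranking(em2, meta_missing), "T2D")
})

test_that("planted interaction genes rank in the top decile", {
  sim <- simulate_cohort_counts(n_per_group = 8, n_genes = 600,
                                planted_exercise_genes = 0,
                                planted_interaction_genes = 25,
                                effect_logfc = 2, seed = 29)
  lc <- normalize_log_cpm(filter_low_counts(sim$counts, sim$metadata))
  rk <- interaction_ranking(lc, sim$metadata)
  ranks <- match(sim$truth$planted_interaction_genes, rk$gene)
  expect_lte(median(ranks, na.rm = TRUE), 0.1 * nrow(rk))
})

test_that("overlap_partition enumerates exclusive and shared members", {
  ov <- overlap_partition(c("x", "y"), c("y", "z"))
  expect_identical(unname(ov$counts), c(1L, 1L, 1L))
  expect_identical(ov$both, "y")
  same <- overlap_partition(c("a", "b"), c("a", "b"))
  expect_identical(unname(same$counts), c(0L, 2L, 0L))
  disjoint <- overlap_partition(c("a", "b"), c("c"))
  expect_identical(unname(disjoint$counts), c(2L, 0L, 1L))
})

test_that("sample-correlation QC flags a scrambled sample without dropping it", {
  set.seed(4)
  base <- rnorm(200, 8, 2)
  v <- vapply(1:6, function(i) base + rnorm(200, 0, 0.2),
              numeric(200))
  dimnames(v) <- list(sprintf("g%d", 1:200), sprintf("s%d", 1:6))
  v[, "s6"] <- sample(v[, "s6"])   # destroy the shared structure
  qc <- qc_sample_correlation(expression_matrix(v, "expression"), 0.8)
  expect_identical(qc$sample_id[qc$flagged], "s6")
  expect_identical(nrow(qc), 6L)
})
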