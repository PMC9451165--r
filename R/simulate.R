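# Synthetic data with planted ground truth. Each generator is a pure
# function of (config, seed): it runs on a private RNG stream and restores
# the caller's RNG state on exit.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Simulate a panel of acute-exercise timeline studies
#'
#' Emulates a collection of acute-exercise studies, each contributing one
#' per-gene mean pre/post log2 fold change at a single post-exercise time
#' category, with study-level covariates and gene-by-study missingness.
#' Planted genes follow a transient pulse: `effect_size` at the planted
#' category, `effect_size / 2` at adjacent categories, 0 elsewhere; the
#' remaining genes are null everywhere. The observed delta adds Gaussian
#' noise with standard deviation `noise_sd / sqrt(n_subjects)` per study.
#'
#' @param n_studies Number of studies; categories are assigned round-robin
#'   over the five time categories.
#' @param n_genes Total genes.
#' @param peak_plan Named integer vector `time_category -> gene count` of
#'   planted peaking genes; must sum to at most `n_genes`.
#' @param effect_size Peak log2 fold change of planted genes.
#' @param noise_sd Between-subject noise sd; per-study noise is
#'   `noise_sd / sqrt(n_subjects)`.
#' @param missing_frac Probability that a gene is missing from a study,
#'   independently per gene and study; must be in `[0, 1)`.
#' @param subjects_range Integer range the per-study subject count is drawn
#'   from (uniformly).
#' @param covariate_ranges Named list of `c(lo, hi)` ranges for the
#'   study-level covariates `age` (years), `sex` (fraction female),
#'   `sedentary` (fraction sedentary) and `weight` (kg).
#' @param seed Integer seed; identical seeds give identical output.
#' @return A list with `panel` (a `timeline_panel`: `deltas` gene-by-study
#'   logFC matrix with `NA` missing marker, `studies` metadata data frame)
#'   and `truth` (the planted parameters: peak times, effect sizes, seed).
#' @examples
#' sim <- simulate_timeline_studies(n_studies = 10, n_genes = 50,
#'   peak_plan = c(h2_3 = 5), seed = 1)
#' table(sim$truth$planted_peak_times)
#' @export
simulate_timeline_studies <- function(n_studies = 20,
                                      n_genes = 500,
                                      peak_plan = c(h0_1 = 40, h2_3 = 40,
                                                    h4_6 = 40, h24 = 40,
                                                    h48 = 40),
                                      effect_size = 1,
                                      noise_sd = 1,
                                      missing_frac = 0.1,
                                      subjects_range = c(8L, 12L),
                                      covariate_ranges = list(
                                        age = c(20, 45),
                                        sex = c(0, 1),
                                        sedentary = c(0, 1),
                                        weight = c(60, 95)),
                                      seed = 1L) {
  if (!all(names(peak_plan) %in% TIME_CATEGORIES))
    stop("peak_plan names must be time categories: ",
         paste(TIME_CATEGORIES, collapse = ", "), call. = FALSE)
  if (sum(peak_plan) > n_genes)
    stop("peak_plan gene counts exceed n_genes", call. = FALSE)
  if (missing_frac >= 1 || missing_frac < 0)
    stop("missing_frac must be in [0, 1)", call. = FALSE)
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    peaks <- setNames(rep(NA_character_, n_genes), genes)
    idx <- 1L
    for (cat in names(peak_plan)) {
      k <- peak_plan[[cat]]
      if (k > 0) {
        peaks[idx:(idx + k - 1L)] <- cat
        idx <- idx + k
      }
    }
    studies <- data.frame(
      study_id = sprintf("study%02d", seq_len(n_studies)),
      time_category = rep_len(TIME_CATEGORIES, n_studies),
      n_subjects = sample(seq(subjects_range[1L], subjects_range[2L]),
                          n_studies, replace = TRUE),
      stringsAsFactors = FALSE
    )
    for (cv in c("age", "sex", "sedentary", "weight")) {
      rg <- covariate_ranges[[cv]]
      studies[[cv]] <- runif(n_studies, rg[1L], rg[2L])
    }
    # expected pulse value of gene g in a study at category position j
    cat_pos <- match(studies$time_category, TIME_CATEGORIES)
    peak_pos <- match(peaks, TIME_CATEGORIES)   # NA for null genes
    expected <- matrix(0, n_genes, n_studies,
                       dimnames = list(genes, studies$study_id))
    for (s in seq_len(n_studies)) {
      d <- abs(peak_pos - cat_pos[s])
      expected[, s] <- ifelse(is.na(d), 0,
                              ifelse(d == 0, effect_size,
                                     ifelse(d == 1, effect_size / 2, 0)))
    }
    noise <- matrix(rnorm(n_genes * n_studies), n_genes, n_studies)
    noise <- sweep(noise, 2, noise_sd / sqrt(studies$n_subjects), `*`)
    deltas <- expected + noise
    if (missing_frac > 0) {
      mask <- matrix(runif(n_genes * n_studies) < missing_frac,
                     n_genes, n_studies)
      deltas[mask] <- NA_real_
    }
    panel <- structure(list(deltas = deltas, studies = studies),
                       class = "timeline_panel")
    truth <- list(
      seed = seed,
      planted_peak_times = peaks[!is.na(peaks)],
      planted_effect_sizes = setNames(
        rep(effect_size, sum(!is.na(peaks))), genes[!is.na(peaks)]),
      noise_sd = noise_sd,
      missing_frac = missing_frac,
      design = list(n_studies = n_studies, n_genes = n_genes,
                    peak_plan = as.list(peak_plan))
    )
    list(panel = panel, truth = truth)
  })
}

#' @export
print.timeline_panel <- function(x, ...) {
  cat(sprintf("timeline_panel: %d genes x %d studies (%d missing entries)\n",
              nrow(x$deltas), ncol(x$deltas), sum(is.na(x$deltas))))
  invisible(x)
}

#' Simulate a paired two-group three-timepoint RNA-seq count cohort
#'
#' Emulates a cohort with two diagnosis groups (NGT, T2D), three biopsies
#' per subject (pre, post, recovery) and negative-binomial counts around
#' subject- and gene-level means (log-normal subject random effects).
#' Planted exercise genes shift the post and recovery means by
#' `effect_logfc` (log2 units) in both groups; planted interaction genes
#' shift the recovery mean by `effect_logfc` only in T2D.
#'
#' @param n_per_group Subjects per diagnosis group (at least 3).
#' @param n_genes Number of genes.
#' @param nb_dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); the limit 0 is Poisson.
#' @param lib_size_range Range library sizes are drawn from (uniformly).
#' @param planted_exercise_genes,planted_interaction_genes Counts of planted
#'   genes of each kind (disjoint sets).
#' @param effect_logfc Planted effect, log2 units.
#' @param subject_sd SD of the log-normal (base e) subject random effect.
#' @param seed Integer seed.
#' @return A list with `counts` (an [expression_matrix()] of kind
#'   `"counts"`), `metadata` (a [sample_metadata()] data frame) and `truth`
#'   (planted exercise/interaction gene lists and parameters).
#' @export
simulate_cohort_counts <- function(n_per_group = 8,
                                   n_genes = 1000,
                                   nb_dispersion = 0.1,
                                   lib_size_range = c(5e5, 1e6),
                                   planted_exercise_genes = 50,
                                   planted_interaction_genes = 20,
                                   effect_logfc = 2,
                                   subject_sd = 0.1,
                                   seed = 1L) {
  if (n_per_group < 3)
    stop("n_per_group must be at least 3", call. = FALSE)
  if (nb_dispersion < 0)
    stop("nb_dispersion must be non-negative", call. = FALSE)
  if (any(lib_size_range <= 0))
    stop("library sizes must be positive", call. = FALSE)
  if (planted_exercise_genes + planted_interaction_genes > n_genes)
    stop("planted gene counts exceed n_genes", call. = FALSE)
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    ex_genes <- genes[seq_len(planted_exercise_genes)]
    int_genes <- genes[planted_exercise_genes +
                         seq_len(planted_interaction_genes)]
    groups <- c("NGT", "T2D")
    timepoints <- c("pre", "post", "recovery")
    meta <- expand.grid(timepoint = timepoints,
                        subject = seq_len(n_per_group), group = groups,
                        stringsAsFactors = FALSE)
    meta <- data.frame(
      sample_id = sprintf("%s_s%02d_%s", meta$group, meta$subject,
                          meta$timepoint),
      study_id = "cohort",
      subject_id = sprintf("%s_s%02d", meta$group, meta$subject),
      group = meta$group,
      timepoint = meta$timepoint,
      time_category = "none",
      stringsAsFactors = FALSE
    )
    n_samples <- nrow(meta)
    # relative gene abundances: log-normal, normalized to proportions
    base_abund <- exp(rnorm(n_genes, 0, 1.5))
    base_prop <- base_abund / sum(base_abund)
    subj_effect <- setNames(
      exp(rnorm(2 * n_per_group, 0, subject_sd)),
      unique(meta$subject_id))
    lib_sizes <- runif(n_samples, lib_size_range[1L], lib_size_range[2L])
    log2fc <- matrix(0, n_genes, n_samples,
                     dimnames = list(genes, meta$sample_id))
    exercised <- meta$timepoint %in% c("post", "recovery")
    log2fc[ex_genes, exercised] <- effect_logfc
    int_cols <- meta$group == "T2D" & meta$timepoint == "recovery"
    log2fc[int_genes, int_cols] <- log2fc[int_genes, int_cols] + effect_logfc
    mu <- outer(base_prop, lib_sizes * subj_effect[meta$subject_id]) *
      2^log2fc
    counts <- matrix(
      if (nb_dispersion == 0) stats::rpois(length(mu), as.vector(mu))
      else rnbinom(length(mu), mu = as.vector(mu), size = 1 / nb_dispersion),
      n_genes, n_samples, dimnames = dimnames(log2fc))
    truth <- list(
      seed = seed,
      planted_exercise_genes = ex_genes,
      planted_interaction_genes = int_genes,
      planted_effect_sizes = setNames(
        rep(effect_logfc, length(c(ex_genes, int_genes))),
        c(ex_genes, int_genes)),
      nb_dispersion = nb_dispersion,
      design = list(n_per_group = n_per_group, n_genes = n_genes)
    )
    list(counts = expression_matrix(counts, "counts"),
         metadata = sample_metadata(meta), truth = truth)
  })
}

#' Simulate a multi-batch M0/M1/M2 macrophage polarization panel
#'
#' Each batch contributes samples of all three polarization states on a
#' log2 expression scale: per-gene baselines, additive per-gene batch
#' offsets shared across states within a batch, and Gaussian sample noise.
#' Planted M1 markers are elevated by `marker_logfc` in M1 samples only
#' (hence vs both M0 and M2); M2 markers symmetrically in M2 samples.
#'
#' @param n_batches Number of batches/studies (at least 2 for blocking).
#' @param n_per_state Samples per state per batch.
#' @param n_genes Number of genes.
#' @param n_m1_markers,n_m2_markers Planted marker counts (disjoint).
#' @param marker_logfc Planted marker elevation, log2 units; must exceed 2
#'   for markers to be recoverable under the between-state threshold rule.
#' @param batch_sd SD of the per-gene additive batch offset.
#' @param noise_sd SD of per-sample Gaussian noise.
#' @param seed Integer seed.
#' @return A list with `panel` (an [expression_matrix()] of kind
#'   `"expression"`), `metadata` and `truth` (planted marker lists).
#' @export
simulate_polarization_panel <- function(n_batches = 3,
                                        n_per_state = 20,
                                        n_genes = 1000,
                                        n_m1_markers = 50,
                                        n_m2_markers = 50,
                                        marker_logfc = 3,
                                        batch_sd = 1,
                                        noise_sd = 1,
                                        seed = 1L) {
  if (n_m1_markers + n_m2_markers >= n_genes)
    stop("marker counts must sum to less than n_genes", call. = FALSE)
  with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    m1 <- genes[seq_len(n_m1_markers)]
    m2 <- genes[n_m1_markers + seq_len(n_m2_markers)]
    states <- c("M0", "M1", "M2")
    meta <- expand.grid(rep = seq_len(n_per_state), group = states,
                        batch = seq_len(n_batches), stringsAsFactors = FALSE)
    meta <- data.frame(
      sample_id = sprintf("b%02d_%s_r%02d", meta$batch, meta$group,
                          meta$rep),
      study_id = sprintf("batch%02d", meta$batch),
      subject_id = sprintf("b%02d_%s_r%02d", meta$batch, meta$group,
                           meta$rep),
      group = meta$group,
      timepoint = "none",
      time_category = "none",
      stringsAsFactors = FALSE
    )
    n_samples <- nrow(meta)
    baseline <- rnorm(n_genes, 7, 2)
    expr <- matrix(baseline, n_genes, n_samples,
                   dimnames = list(genes, meta$sample_id))
    batch_offsets <- matrix(rnorm(n_genes * n_batches, 0, batch_sd),
                            n_genes, n_batches)
    batch_idx <- match(meta$study_id, sprintf("batch%02d",
                                              seq_len(n_batches)))
    expr <- expr + batch_offsets[, batch_idx]
    expr[m1, meta$group == "M1"] <- expr[m1, meta$group == "M1"] +
      marker_logfc
    expr[m2, meta$group == "M2"] <- expr[m2, meta$group == "M2"] +
      marker_logfc
    expr <- expr + matrix(rnorm(n_genes * n_samples, 0, noise_sd),
                          n_genes, n_samples)
    truth <- list(
      seed = seed,
      planted_m1_markers = m1,
      planted_m2_markers = m2,
      marker_logfc = marker_logfc,
      batch_sd = batch_sd, noise_sd = noise_sd,
      design = list(n_batches = n_batches, n_per_state = n_per_state,
                    n_genes = n_genes)
    )
    list(panel = expression_matrix(expr, "expression"),
         metadata = sample_metadata(meta), truth = truth)
  })
}

#' Simulate replicate cytokine induction time courses
#'
#' Each gene has an expected log2 fold-change profile over `times_h`
#' relative to the baseline (first) timepoint, whose expected value must be
#' 0 by construction; replicate trajectories add Gaussian noise (the
#' baseline entry included, representing measurement error around 0).
#'
#' @param genes Character vector of gene ids.
#' @param times_h Strictly increasing numeric timepoints in hours; the
#'   first entry is the baseline.
#' @param profiles Named list `gene -> numeric expected logFC profile` of
#'   length `length(times_h)` with first entry 0.
#' @param noise_sd Gaussian noise sd; 0 reproduces the profiles exactly.
#' @param n_replicates Replicate trajectories per gene.
#' @param seed Integer seed.
#' @return A list with `logfc` (an [expression_matrix()] of kind `"logfc"`,
#'   columns named `rep<r>_t<time>`), `times_h`, `n_replicates` and `truth`.
#' @export
simulate_cytokine_timecourse <- function(genes,
                                         times_h,
                                         profiles,
                                         noise_sd = 0.2,
                                         n_replicates = 4,
                                         seed = 1L) {
  if (any(diff(times_h) <= 0))
    stop("times_h must be strictly increasing", call. = FALSE)
  if (!all(genes %in% names(profiles)))
    stop("every gene needs a profile", call. = FALSE)
  for (g in genes) {
    p <- profiles[[g]]
    if (length(p) != length(times_h))
      stop("profile for ", g, " must have one entry per timepoint",
           call. = FALSE)
    if (p[1L] != 0)
      stop("profile for ", g, " must start at baseline logFC 0",
           call. = FALSE)
  }
  with_seed(seed, {
    cols <- as.vector(outer(seq_len(n_replicates), times_h,
                            function(r, t) sprintf("rep%d_t%g", r, t)))
    vals <- matrix(NA_real_, length(genes), length(cols),
                   dimnames = list(genes, cols))
    for (g in genes) {
      expected <- rep(profiles[[g]], each = n_replicates)
      vals[g, ] <- expected + rnorm(length(expected), 0, noise_sd)
    }
    truth <- list(seed = seed, times_h = times_h,
                  profiles = profiles[genes], noise_sd = noise_sd,
                  n_replicates = n_replicates)
    list(logfc = expression_matrix(vals, "logfc"),
         times_h = times_h, n_replicates = n_replicates, truth = truth)
  })
}
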