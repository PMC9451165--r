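paired_fixture <- function(n_subj = 5, n_genes = 20, seed = 31,
                           delta = 0) {
  set.seed(seed)
  samples <- as.vector(outer(c("pre", "post"), seq_len(n_subj),
                             function(t, s) sprintf("s%d_%s", s, t)))
  y <- matrix(rnorm(n_genes * 2 * n_subj), n_genes,
              dimnames = list(sprintf("g%d", seq_len(n_genes)), samples))
  post <- grepl("post", samples)
  y[, post] <- y[, post] + delta
  subj <- factor(rep(seq_len(n_subj), each = 2))
  X <- cbind(model.matrix(~ 0 + subj), delta = as.integer(post))
  colnames(X) <- c(levels(subj), "delta")
  rownames(X) <- samples
  list(em = expression_matrix(y, "logcpm"), spec = design_spec(X, "delta"),
       post = post, subj = subj)
}

test_that("paired contrast estimate equals the mean within-subject delta", {
  fx <- paired_fixture()
  fit <- fit_blocked_model(fx$em, fx$spec)
  y <- fx$em$values
  manual <- rowMeans(y[, fx$post][, order(fx$subj[fx$post])] -
                       y[, !fx$post][, order(fx$subj[!fx$post])])
  expect_equal(unname(fit$contrast_estimate), unname(manual),
               tolerance = 1e-12)
})

test_that("a response lying in the design column space has zero residual variance", {
  fx <- paired_fixture(n_genes = 2)
  X <- fx$spec$design
  fx$em$values[1, ] <- X %*% c(rep(1, 5), 2)   # exact linear combination
  fit <- fit_blocked_model(fx$em, fx$spec)
  expect_equal(unname(fit$sigma2["g1"]), 0, tolerance = 1e-20)
  expect_equal(unname(fit$contrast_estimate["g1"]), 2, tolerance = 1e-12)
})

test_that("coefficients match an explicit normal-equations solve", {
  set.seed(7)
  X <- cbind(intercept = 1, x1 = rnorm(5), x2 = rnorm(5))
  rownames(X) <- sprintf("s%d", 1:5)
  y <- matrix(rnorm(10), 2, 5,
              dimnames = list(c("g1", "g2"), rownames(X)))
  fit <- fit_blocked_model(expression_matrix(y, "expression"),
                           design_spec(X, "x1"))
  for (g in c("g1", "g2"))
    expect_equal(unname(fit$coefficients[g, ]),
                 unname(normal_equations_oracle(X, y[g, ])),
                 tolerance = 1e-10)
})

test_that("rank-deficient designs fail naming the collinear column", {
  X <- cbind(intercept = 1, a = 1:4, twice_a = 2 * (1:4))
  rownames(X) <- sprintf("s%d", 1:4)
  expect_error(design_spec(X, "a"), "twice_a")
})

test_that("genes with insufficient observed samples are skipped with reasons", {
  fx <- paired_fixture(n_subj = 3, n_genes = 3)
  fx$em$values[2, 1:4] <- NA   # 2 samples left, p = 4 -> rank-deficient
  fit <- fit_blocked_model(fx$em, fx$spec)
  expect_false("g2" %in% fit$genes)
  expect_identical(fit$skipped$gene, "g2")
  expect_match(fit$skipped$reason, "rank-deficient|residual")
})

test_that("equal sample variances give a degenerate moment fit with s0sq = v", {
  s2 <- setNames(rep(1.7, 6), sprintf("g%d", 1:6))
  m <- moderate_variances(s2, 4)
  expect_identical(m$d0, Inf)
  expect_equal(m$s0sq, 1.7)
  expect_equal(unname(m$posterior_var), rep(1.7, 6))
})

test_that("posterior variances interpolate between gene and prior variance", {
  set.seed(13)
  s2 <- setNames(rchisq(40, 3) * runif(40, 0.5, 2), sprintf("g%d", 1:40))
  m <- moderate_variances(s2, 5)
  lo <- pmin(s2, m$s0sq); hi <- pmax(s2, m$s0sq)
  expect_true(all(m$posterior_var >= lo - 1e-12 &
                    m$posterior_var <= hi + 1e-12))
  # d0 = Inf contract: posterior collapses onto s0sq
  minf <- moderation_fit(Inf, m$s0sq, s2, 5)
  expect_true(all(minf$posterior_var == m$s0sq))
})

test_that("moment matching agrees with an independent root-find", {
  s2 <- setNames(c(0.5, 1.0, 2.0, 4.0), sprintf("g%d", 1:4))
  m <- moderate_variances(s2, 4)
  oracle <- moment_match_oracle(unname(s2), rep(4, 4))
  expect_equal(m$d0, oracle$d0, tolerance = 1e-6)
  expect_equal(m$s0sq, oracle$s0sq, tolerance = 1e-6)
})

test_that("moderation matches limma::squeezeVar on heterogeneous variances", {
  skip_if_not_installed("limma")
  set.seed(5)
  s2 <- rchisq(80, 4) / 4 * exp(rnorm(80, 0, 0.8))
  m <- moderate_variances(setNames(s2, sprintf("g%d", 1:80)), 6)
  sq <- limma::squeezeVar(s2, 6)
  expect_equal(m$d0, sq$df.prior, tolerance = 1e-8)
  expect_equal(m$s0sq, sq$var.prior, tolerance = 1e-8)
  expect_equal(unname(m$posterior_var), as.vector(sq$var.post),
               tolerance = 1e-8)
})

test_that("moderated t reduces to the ordinary t when d0 = 0", {
  fx <- paired_fixture(n_genes = 15, delta = 0.5)
  fit <- fit_blocked_model(fx$em, fx$spec)
  m0 <- moderation_fit(0, 1, fit$sigma2, fit$df)
  res <- moderated_test(fit, m0)
  ordinary <- fit$contrast_estimate /
    (sqrt(fit$sigma2) * fit$contrast_se_unscaled)
  expect_equal(res$t, unname(ordinary), tolerance = 1e-12)
  expect_equal(res$p_value,
               unname(2 * pt(-abs(ordinary), fit$df)), tolerance = 1e-12)
})

test_that("moderated t handles the null point and the zero-variance boundary", {
  # exact-arithmetic fit: g1 has zero contrast, g2 a perfect-fit nonzero
  # contrast, both with exactly zero residual variance
  fit <- structure(list(
    genes = c("g1", "g2"),
    coefficients = matrix(c(0, 1), 2, 1,
                          dimnames = list(c("g1", "g2"), "delta")),
    sigma2 = c(g1 = 0, g2 = 0),
    df = c(g1 = 3, g2 = 3),
    contrast_estimate = c(g1 = 0, g2 = 1),
    contrast_se_unscaled = c(g1 = 0.5, g2 = 0.5),
    skipped = data.frame(gene = character(), reason = character())),
    class = "blocked_fit")
  m <- moderation_fit(0, 1, fit$sigma2, fit$df)
  res <- moderated_test(fit, m)
  expect_equal(res$t[res$gene == "g1"], 0)
  expect_equal(res$p_value[res$gene == "g1"], 1)
  expect_equal(res$p_value[res$gene == "g2"], 0)
  expect_true(res$boundary[res$gene == "g2"])
  expect_false(res$boundary[res$gene == "g1"])
})

test_that("full engine matches limma lmFit/eBayes on a paired fixture", {
  skip_if_not_installed("limma")
  fx <- paired_fixture(n_genes = 60, delta = 0.3, seed = 77)
  mine <- run_de(fx$em, fx$spec)
  lfit <- limma::eBayes(limma::lmFit(fx$em$values, fx$spec$design))
  expect_equal(mine$t, unname(lfit$t[, "delta"]), tolerance = 1e-8)
  # p-values agree up to limma's pooled-df cap on the total degrees of
  # freedom, which only matters for very large prior df
  expect_equal(mine$p_value, unname(lfit$p.value[, "delta"]),
               tolerance = 1e-2)
  expect_equal(mine$logFC, unname(lfit$coefficients[, "delta"]),
               tolerance = 1e-10)
})

test_that("bh_fdr reproduces the step-up construction", {
  expect_equal(bh_fdr(rep(0.03, 5)), rep(0.03, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.5)),
               c(0.04, 0.04, 0.04, 0.5))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(3)
  p <- runif(25)
  q <- bh_fdr(p)
  expect_equal(q, bh_stepup_oracle(p))
  # monotone in p and order-equivariant
  o <- order(p)
  expect_true(all(diff(q[o]) >= 0))
  perm <- sample(25)
  expect_equal(bh_fdr(p[perm]), q[perm])
})

test_that("recovered logFC of planted cohort genes is close to truth", {
  # generous sequencing depth so the 0.5 logCPM prior count does not
  # attenuate fold changes of low-abundance genes
  sim <- simulate_cohort_counts(n_per_group = 8, n_genes = 300,
                                planted_exercise_genes = 30,
                                planted_interaction_genes = 0,
                                effect_logfc = 1.5,
                                lib_size_range = c(2e6, 3e6), seed = 19)
  lc <- normalize_log_cpm(filter_low_counts(sim$counts, sim$metadata))
  de <- paired_contrasts(lc, sim$metadata, "T2D", c("post", "pre"))
  planted <- de$logFC[de$gene %in% sim$truth$planted_exercise_genes]
  expect_lt(abs(mean(planted) - 1.5), 0.2)
})
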