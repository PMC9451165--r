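# Shared statistical engine: per-gene least squares with fixed-effect
# blocking, scaled-F empirical-Bayes variance moderation, moderated t tests
# and Benjamini-Hochberg FDR.

#' Specify a per-gene linear model design
#'
#' @param design Numeric design matrix (samples x coefficients) with sample
#'   ids as rownames and coefficient names as colnames. Blocking factors
#'   (subject, study) enter as ordinary fixed-effect columns.
#' @param contrast Either a single coefficient name or a numeric contrast
#'   vector over the design columns.
#' @return An object of class `design_spec`.
#' @export
design_spec <- function(design, contrast) {
  if (!is.matrix(design) || !is.numeric(design))
    stop("'design' must be a numeric matrix", call. = FALSE)
  if (is.null(rownames(design)) || is.null(colnames(design)))
    stop("'design' needs sample rownames and coefficient colnames",
         call. = FALSE)
  p <- ncol(design)
  qrd <- qr(design)
  if (qrd$rank < p) {
    bad <- colnames(design)[qrd$pivot[(qrd$rank + 1L):p]]
    stop("design matrix is rank-deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.character(contrast)) {
    if (length(contrast) != 1L || !(contrast %in% colnames(design)))
      stop("contrast name not found among design columns", call. = FALSE)
    contrast <- as.numeric(colnames(design) == contrast)
  }
  if (length(contrast) != p)
    stop("contrast length must equal the number of design columns",
         call. = FALSE)
  structure(list(design = design, contrast = as.numeric(contrast)),
            class = "design_spec")
}

#' Fit per-gene blocked linear models
#'
#' Ordinary least squares per gene on the samples named by the design's
#' rownames. Genes with missing values are fitted on their observed samples
#' only; genes left with fewer than one residual degree of freedom, or with
#' a rank-deficient reduced design, are skipped and reported.
#'
#' @param x An [expression_matrix()] covering all design samples.
#' @param spec A [design_spec()].
#' @return An object of class `blocked_fit` with per-gene `coefficients`,
#'   residual variances `sigma2`, residual degrees of freedom `df`,
#'   `contrast_estimate`, unscaled contrast standard errors
#'   `contrast_se_unscaled`, and a `skipped` data frame (gene, reason).
#' @export
fit_blocked_model <- function(x, spec) {
  stopifnot(inherits(x, "expression_matrix"), inherits(spec, "design_spec"))
  X <- spec$design
  cvec <- spec$contrast
  samples <- rownames(X)
  missing_s <- setdiff(samples, x$sample_ids)
  if (length(missing_s))
    stop("design samples absent from matrix: ",
         paste(missing_s, collapse = ", "), call. = FALSE)
  Y <- x$values[, samples, drop = FALSE]
  n <- nrow(X); p <- ncol(X)
  genes <- rownames(Y)

  coefs <- matrix(NA_real_, length(genes), p,
                  dimnames = list(genes, colnames(X)))
  sigma2 <- df <- est <- seu <- setNames(rep(NA_real_, length(genes)), genes)
  skipped <- list()

  complete <- rowSums(is.na(Y)) == 0L
  if (any(complete) && n - p >= 1L) {
    qrd <- qr(X)
    Yc <- t(Y[complete, , drop = FALSE])
    beta <- qr.coef(qrd, Yc)
    res <- qr.resid(qrd, Yc)
    XtXinv <- chol2inv(chol(crossprod(X)))
    cse <- sqrt(drop(t(cvec) %*% XtXinv %*% cvec))
    g <- genes[complete]
    coefs[g, ] <- t(beta)
    sigma2[g] <- colSums(res^2) / (n - p)
    df[g] <- n - p
    est[g] <- drop(crossprod(cvec, beta))
    seu[g] <- cse
  } else if (any(complete)) {
    for (g in genes[complete])
      skipped[[g]] <- "insufficient residual degrees of freedom"
  }

  for (g in genes[!complete]) {
    y <- Y[g, ]
    obs <- !is.na(y)
    Xo <- X[obs, , drop = FALSE]
    if (qr(Xo)$rank < p) {
      skipped[[g]] <- "design rank-deficient on observed samples"
      next
    }
    dfo <- sum(obs) - p
    if (dfo < 1L) {
      skipped[[g]] <- "insufficient residual degrees of freedom"
      next
    }
    fit <- stats::lm.fit(Xo, y[obs])
    coefs[g, ] <- fit$coefficients
    sigma2[g] <- sum(fit$residuals^2) / dfo
    df[g] <- dfo
    est[g] <- sum(cvec * fit$coefficients)
    XtXinv <- chol2inv(chol(crossprod(Xo)))
    seu[g] <- sqrt(drop(t(cvec) %*% XtXinv %*% cvec))
  }

  kept <- genes[!is.na(df)]
  if (!length(kept))
    stop("no gene could be fitted with at least 1 residual df",
         call. = FALSE)
  structure(list(
    genes = kept,
    coefficients = coefs[kept, , drop = FALSE],
    sigma2 = sigma2[kept],
    df = df[kept],
    contrast_estimate = est[kept],
    contrast_se_unscaled = seu[kept],
    skipped = data.frame(gene = names(skipped),
                         reason = unlist(skipped, use.names = FALSE),
                         stringsAsFactors = FALSE),
    spec = spec
  ), class = "blocked_fit")
}

# Newton inversion of the trigamma function, used by the moment fit.
trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, deriv = 2L)
    y <- y + dif
    if (-dif / y < 1e-8) break
  }
  y
}

#' Construct a variance-moderation fit from given hyperparameters
#'
#' The posterior variance of each gene is the convex combination
#' `(d0 * s0sq + df * s2) / (d0 + df)`; `d0 = 0` reproduces the ordinary
#' per-gene variances and `d0 = Inf` replaces every variance by `s0sq`.
#'
#' @param d0 Prior degrees of freedom (may be `Inf`).
#' @param s0sq Prior variance.
#' @param sample_variances Named per-gene residual variances.
#' @param residual_df Per-gene residual degrees of freedom.
#' @return An object of class `moderation_fit`.
#' @export
moderation_fit <- function(d0, s0sq, sample_variances, residual_df) {
  if (length(residual_df) == 1L)
    residual_df <- rep(residual_df, length(sample_variances))
  post <- if (is.infinite(d0)) {
    setNames(rep(s0sq, length(sample_variances)), names(sample_variances))
  } else {
    (d0 * s0sq + residual_df * sample_variances) / (d0 + residual_df)
  }
  structure(list(d0 = d0, s0sq = s0sq,
                 posterior_var = post,
                 sample_variances = sample_variances,
                 df = setNames(residual_df, names(sample_variances))),
            class = "moderation_fit")
}

#' Empirical-Bayes moderation of per-gene variances
#'
#' Estimates the hyperparameters of a scaled-F prior on the true variances
#' by matching the first two moments of the bias-corrected log sample
#' variances: `e = log(s2) - digamma(df/2) + log(df/2)` has mean
#' `log(s0sq) + digamma(d0/2) - log(d0/2)` and excess variance
#' `trigamma(d0/2)` beyond `trigamma(df/2)`. When the excess variance is
#' non-positive the fit degenerates to `d0 = Inf` with `s0sq = mean(s2)`.
#' Exact-zero variances are excluded from moment estimation (their log is
#' undefined) but still receive a posterior variance.
#'
#' @param sample_variances Named non-negative per-gene residual variances
#'   (at least 2).
#' @param residual_df Per-gene residual degrees of freedom (recycled if
#'   scalar).
#' @return A [moderation_fit()] with estimated `d0` and `s0sq`.
#' @export
moderate_variances <- function(sample_variances, residual_df) {
  s2 <- sample_variances
  if (length(s2) < 2L)
    stop("at least 2 genes are required to moderate variances",
         call. = FALSE)
  if (any(s2 < 0))
    stop("sample variances must be non-negative", call. = FALSE)
  if (length(residual_df) == 1L)
    residual_df <- rep(residual_df, length(s2))
  if (any(residual_df <= 0))
    stop("residual df must be positive", call. = FALSE)

  if (all(s2 == s2[1L]))
    return(moderation_fit(Inf, unname(s2[1L]), s2, residual_df))

  pos <- s2 > 0
  if (sum(pos) < 2L)
    return(moderation_fit(Inf, mean(s2), s2, residual_df))
  z <- log(s2[pos])
  dfp <- residual_df[pos]
  e <- z - digamma(dfp / 2) + log(dfp / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(dfp / 2))
  if (evar > 0) {
    d0 <- 2 * trigamma_inverse(evar)
    s0sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    moderation_fit(d0, s0sq, s2, residual_df)
  } else {
    moderation_fit(Inf, mean(s2), s2, residual_df)
  }
}

#' Moderated t tests for a fitted contrast
#'
#' `t = contrast estimate / (posterior sd * unscaled contrast se)`, with
#' `d0 + df` degrees of freedom and a two-sided p-value. A gene with zero
#' posterior variance and a nonzero estimate is reported at the `p = 0`
#' boundary with `boundary = TRUE` rather than raising an error; a zero
#' estimate always gives `t = 0`, `p = 1`.
#'
#' @param fit A [fit_blocked_model()] result.
#' @param moderation A [moderation_fit()] covering all fitted genes.
#' @return A data frame with columns `gene`, `logFC`, `t`, `p_value`,
#'   `fdr` (Benjamini-Hochberg within this result) and `boundary`.
#' @export
moderated_test <- function(fit, moderation) {
  stopifnot(inherits(fit, "blocked_fit"),
            inherits(moderation, "moderation_fit"))
  g <- fit$genes
  if (!all(g %in% names(moderation$posterior_var)))
    stop("moderation fit does not cover all fitted genes", call. = FALSE)
  post <- moderation$posterior_var[g]
  se <- sqrt(post) * fit$contrast_se_unscaled
  est <- fit$contrast_estimate
  tt <- ifelse(se > 0, est / se, ifelse(est == 0, 0, sign(est) * Inf))
  df_tot <- moderation$d0 + fit$df
  p <- ifelse(is.infinite(tt), 0, 2 * pt(-abs(tt), df = df_tot))
  data.frame(gene = g, logFC = est, t = tt, p_value = p,
             fdr = bh_fdr(p), boundary = is.infinite(tt),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return q-values in the input order: monotone non-decreasing in p and
#'   equal to the classical step-up adjusted values.
#' @export
bh_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p_values, method = "BH")
}

#' One-call moderated differential expression
#'
#' Convenience wrapper: [fit_blocked_model()], [moderate_variances()] and
#' [moderated_test()] in sequence.
#'
#' @inheritParams fit_blocked_model
#' @return The [moderated_test()] data frame, with the fit and moderation
#'   objects attached as attributes `fit` and `moderation`.
#' @export
run_de <- function(x, spec) {
  fit <- fit_blocked_model(x, spec)
  mod <- moderate_variances(fit$sigma2, fit$df)
  res <- moderated_test(fit, mod)
  attr(res, "fit") <- fit
  attr(res, "moderation") <- mod
  res
}
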