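# Overrepresentation (Fisher/hypergeometric), preranked GSEA with a
# gene-label permutation null, and signature enrichment.

#' Fisher / hypergeometric overrepresentation test
#'
#' One-sided hypergeometric tail probability of an overlap at least as
#' large as observed between a query list and a target set within a
#' universe, plus the 2x2-table odds ratio (Haldane 0.5 correction when any
#' cell is zero). Query or target members outside the universe are trimmed
#' with a warning.
#'
#' @param query,target,universe Character vectors of gene ids.
#' @param alternative Only `"greater"` (enrichment) is offered.
#' @return One-row data frame: `set_name`, `overlap_count`, `odds_ratio`,
#'   `p_value`, `direction`.
#' @examples
#' fisher_overrepresentation(letters[1:5], letters[1:5], letters[1:10])
#' @export
fisher_overrepresentation <- function(query, target, universe,
                                      alternative = "greater") {
  alternative <- match.arg(alternative, "greater")
  universe <- unique(universe)
  if (!length(universe))
    stop("universe must be non-empty", call. = FALSE)
  query <- unique(query); target <- unique(target)
  if (any(!(query %in% universe))) {
    warning("query members outside the universe were trimmed",
            call. = FALSE)
    query <- intersect(query, universe)
  }
  if (any(!(target %in% universe))) {
    warning("target members outside the universe were trimmed",
            call. = FALSE)
    target <- intersect(target, universe)
  }
  N <- length(universe); K <- length(target); k <- length(query)
  x <- length(intersect(query, target))
  # P(X >= x) for X ~ Hypergeometric(N, K, k)
  p <- phyper(x - 1, K, N - K, k, lower.tail = FALSE)
  a <- x; b <- k - x; cc <- K - x; d <- N - K - b
  if (any(c(a, b, cc, d) == 0)) {
    a <- a + 0.5; b <- b + 0.5; cc <- cc + 0.5; d <- d + 0.5
  }
  data.frame(set_name = NA_character_, overlap_count = x,
             odds_ratio = (a * d) / (b * cc), p_value = p,
             direction = "up", stringsAsFactors = FALSE)
}

# Weighted Kolmogorov-Smirnov-style running sum for one set of hit
# positions within a ranked score vector; returns the signed maximal
# deviation.
running_sum_es <- function(scores, hit_idx, weight_p) {
  n <- length(scores)
  inc <- numeric(n)
  w <- abs(scores[hit_idx])^weight_p
  if (sum(w) == 0) w <- rep(1, length(hit_idx))   # all-zero scores in set
  inc[hit_idx] <- w / sum(w)
  inc[-hit_idx] <- -1 / (n - length(hit_idx))
  rs <- cumsum(inc)
  rs[which.max(abs(rs))]
}

#' Preranked gene set enrichment analysis
#'
#' Classic weighted running-sum enrichment: walking down the ranking, hits
#' increment the sum proportionally to `|score|^weight_p` (normalized over
#' the set) and misses decrement uniformly; the enrichment score (ES) is
#' the signed maximal deviation. The null is gene-label permutation:
#' `n_perm` random draws of equally-sized hit sets. `NES` is
#' `ES / mean(|null ES| of the matching sign)` and the permutation p-value
#' uses the plus-one estimator `(1 + #{|null ES| >= |ES|}) / (n_perm + 1)`,
#' so it is never below `1/(n_perm+1)`. FDR is Benjamini-Hochberg across
#' the tested sets.
#'
#' @param scores Named numeric vector of finite per-gene scores (any order;
#'   ranked internally in decreasing order).
#' @param sets A [gene_set_collection()].
#' @param weight_p Score weighting exponent (default 1; 0 gives the
#'   unweighted Kolmogorov-Smirnov statistic).
#' @param n_perm Number of permutations (default 1000).
#' @param min_size Sets with fewer present members are skipped with a
#'   warning, as are sets covering the entire ranking.
#' @param seed Integer seed for the permutation stream.
#' @return Data frame: `set_name`, `overlap_count` (present members),
#'   `es`, `nes`, `p_value`, `fdr`, `direction`.
#' @export
gsea_preranked <- function(scores, sets, weight_p = 1, n_perm = 1000,
                           min_size = 5, seed = 1L) {
  if (is.null(names(scores)))
    stop("scores must be a named vector", call. = FALSE)
  if (any(!is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  stopifnot(inherits(sets, "gene_set_collection"))
  scores <- sort(scores, decreasing = TRUE)
  genes <- names(scores)
  n <- length(genes)
  with_seed(seed, {
    rows <- list()
    for (nm in names(sets$sets)) {
      hit_idx <- which(genes %in% sets$sets[[nm]])
      if (length(hit_idx) < min_size) {
        warning(sprintf("set '%s' has fewer than %d members present; skipped",
                        nm, min_size), call. = FALSE)
        next
      }
      if (length(hit_idx) == n) {
        warning(sprintf("set '%s' covers the whole ranking; skipped", nm),
                call. = FALSE)
        next
      }
      es <- running_sum_es(scores, hit_idx, weight_p)
      null_es <- vapply(seq_len(n_perm), function(i) {
        running_sum_es(scores, sample.int(n, length(hit_idx)), weight_p)
      }, numeric(1))
      p <- (1 + sum(abs(null_es) >= abs(es))) / (n_perm + 1)
      same_sign <- null_es[sign(null_es) == sign(es)]
      nes <- if (length(same_sign)) es / mean(abs(same_sign)) else NA_real_
      rows[[nm]] <- data.frame(
        set_name = nm, overlap_count = length(hit_idx), es = es, nes = nes,
        p_value = p, direction = if (es >= 0) "up" else "down",
        stringsAsFactors = FALSE)
    }
    if (!length(rows))
      return(data.frame(set_name = character(), overlap_count = integer(),
                        es = numeric(), nes = numeric(),
                        p_value = numeric(), fdr = numeric(),
                        direction = character(),
                        stringsAsFactors = FALSE))
    out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
    out$fdr <- bh_fdr(out$p_value)
    out[, c("set_name", "overlap_count", "es", "nes", "p_value", "fdr",
            "direction")]
  })
}

#' Signature overrepresentation in a DE gene list
#'
#' One Fisher overrepresentation test per polarization signature (M1, M2)
#' against a differential-expression gene list, with Benjamini-Hochberg
#' correction across the two tests.
#'
#' @param de_genes Character vector of significant genes.
#' @param signatures A `signature_definition` (see
#'   [derive_polarization_signatures()]).
#' @param universe Background gene ids.
#' @return Data frame with one row per signature: `set_name`,
#'   `overlap_count`, `odds_ratio`, `p_value`, `fdr`, `direction`.
#' @export
signature_enrichment <- function(de_genes, signatures, universe) {
  stopifnot(inherits(signatures, "signature_definition"))
  res <- rbind(
    fisher_overrepresentation(de_genes, signatures$m1_genes, universe),
    fisher_overrepresentation(de_genes, signatures$m2_genes, universe))
  res$set_name <- c("M1", "M2")
  res$fdr <- bh_fdr(res$p_value)
  res[, c("set_name", "overlap_count", "odds_ratio", "p_value", "fdr",
          "direction")]
}
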