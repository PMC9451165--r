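# Independent oracles used across the suite. Each is a deliberately
# naive, direct implementation kept separate from the package's code path.

# Classical step-up FDR by direct enumeration of the step-up rule.
bh_stepup_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    val <- min(prev, n * p[o[i]] / i)
    q[o[i]] <- val
    prev <- val
  }
  q
}

# Rejection set of the classical BH step-up procedure at level alpha.
bh_reject_oracle <- function(p, alpha) {
  n <- length(p)
  o <- order(p)
  k <- 0
  for (i in 1:n) if (p[o[i]] <= alpha * i / n) k <- i
  if (k == 0) integer() else sort(o[1:k])
}

# Upper-tail hypergeometric probability by direct combinatorial summation.
hyper_tail_oracle <- function(N, K, k, x) {
  js <- x:min(K, k)
  js <- js[js >= max(0, k - (N - K))]
  if (!length(js)) return(0)
  sum(choose(K, js) * choose(N - K, k - js)) / choose(N, k)
}

# Weighted running-sum enrichment score by an explicit walk.
gsea_es_oracle <- function(scores_desc, hit_idx, weight_p) {
  scores_desc <- unname(scores_desc)
  n <- length(scores_desc)
  nh <- length(hit_idx)
  w <- abs(scores_desc[hit_idx])^weight_p
  wsum <- sum(w)
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    if (i %in% hit_idx) {
      run <- run + abs(scores_desc[i])^weight_p / wsum
    } else {
      run <- run - 1 / (n - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Position of the running-sum extremum (for construction checks).
gsea_argmax_oracle <- function(scores_desc, hit_idx, weight_p) {
  n <- length(scores_desc)
  nh <- length(hit_idx)
  w <- abs(scores_desc[hit_idx])^weight_p
  inc <- numeric(n)
  inc[hit_idx] <- abs(scores_desc[hit_idx])^weight_p / sum(w)
  inc[-hit_idx] <- -1 / (n - nh)
  which.max(abs(cumsum(inc)))
}

# Normal-equations least squares by direct solve.
normal_equations_oracle <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Moment-matching for the scaled-F variance prior by independent
# root-finding on the trigamma equation.
moment_match_oracle <- function(s2, df) {
  e <- log(s2) - digamma(df / 2) + log(df / 2)
  excess <- var(e) - mean(trigamma(df / 2))
  stopifnot(excess > 0)
  half_d0 <- uniroot(function(y) trigamma(y) - excess,
                     lower = 1e-8, upper = 1e8, tol = 1e-12)$root
  d0 <- 2 * half_d0
  s0sq <- exp(mean(e) + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0sq = s0sq)
}

# Spearman rho as explicit average-rank followed by Pearson correlation.
spearman_oracle <- function(x, y) {
  cor(rank(x), rank(y))
}
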