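# Independent brute-force oracles used across tests. These deliberately avoid
# the package's own code paths: pair enumeration, explicit matrix algebra,
# exhaustive tail sums.

# Mann-Whitney U by exhaustive pair enumeration: count pairs (x_i > y_j) plus
# half-ties. Also returns the AUC.
bf_u_statistic <- function(x, y) {
  u <- 0
  for (xi in x) for (yj in y) {
    u <- u + (xi > yj) + 0.5 * (xi == yj)
  }
  list(U = u, auc = u / (length(x) * length(y)))
}

# Benjamini-Hochberg step-up from its definition.
bf_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# One-tailed hypergeometric overenrichment p by exhaustive tail sum:
# universe N, m in-locus, k hits drawn, observed overlap a.
bf_hyper_tail <- function(a, m, N, k) {
  amax <- min(m, k)
  sum(vapply(a:amax, function(j) {
    choose(m, j) * choose(N - m, k - j) / choose(N, k)
  }, numeric(1)))
}

# All permutations of seq_len(n), independent of the package's generator.
bf_permutations <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (pm in bf_permutations(n - 1L)) {
    for (pos in seq_len(n)) {
      out[[length(out) + 1L]] <- append(pm, n, after = pos - 1L)
    }
  }
  out
}

# Two-sample Welch t statistic, closed form.
bf_welch_t <- function(x, y) {
  (mean(x) - mean(y)) / sqrt(var(x) / length(x) + var(y) / length(y))
}
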