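# Shared internals: vectorized rank-sum statistics, clipping, Dirichlet draws.

clip01 <- function(x) {
  x[which(x < 0)] <- 0
  x[which(x > 1)] <- 1
  x
}

#' Rank-sum statistics for one numeric vector
#'
#' Mann-Whitney U for group-1 (target) observations against the rest, with the
#' tie-corrected normal approximation and continuity correction. Returns one-
#' sided p-values in both directions plus the AUC (probability that a target
#' value exceeds a rest value, ties counted half).
#'
#' @param x numeric vector, `NA` allowed (dropped).
#' @param target logical vector, same length as `x`; `TRUE` marks group 1.
#' @return named numeric: `U`, `p_greater`, `p_less`, `auc`, `n1`, `n2`.
#' @keywords internal
#' @noRd
rank_sum_stats <- function(x, target) {
  ok <- !is.na(x)
  x <- x[ok]
  g <- target[ok]
  n1 <- sum(g)
  n2 <- sum(!g)
  if (n1 == 0L || n2 == 0L) {
    return(c(U = NA_real_, p_greater = NA_real_, p_less = NA_real_,
             auc = NA_real_, n1 = n1, n2 = n2))
  }
  N <- n1 + n2
  r <- rank(x)
  U <- sum(r[g]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  tie_counts <- table(r)
  tie_term <- sum(tie_counts^3 - tie_counts)
  sig2 <- n1 * n2 / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  auc <- U / (n1 * n2)
  if (sig2 <= 0) {
    # all values tied: no evidence either way
    return(c(U = U, p_greater = 1, p_less = 1, auc = auc, n1 = n1, n2 = n2))
  }
  sig <- sqrt(sig2)
  p_greater <- pnorm((U - mu - 0.5) / sig, lower.tail = FALSE)
  p_less <- pnorm((U - mu + 0.5) / sig)
  c(U = U, p_greater = p_greater, p_less = p_less, auc = auc, n1 = n1, n2 = n2)
}

# Row-wise rank-sum over a matrix (features x observations); returns a
# data.frame with one row per matrix row.
rowwise_rank_sum <- function(X, target) {
  stopifnot(is.logical(target), length(target) == ncol(X))
  out <- t(apply(X, 1L, rank_sum_stats, target = target))
  out <- as.data.frame(out)
  out$feature <- rownames(X)
  out
}

# Dirichlet draws via normalized gammas; n x K matrix with rows summing to 1.
rdirichlet <- function(n, alpha) {
  K <- length(alpha)
  g <- matrix(rgamma(n * K, shape = alpha, rate = 1), nrow = n, ncol = K,
              byrow = TRUE)
  sums <- rowSums(g)
  zero <- sums <= 0
  if (any(zero)) { # numerically possible for tiny alpha
    g[zero, ] <- 1 / K
    sums[zero] <- 1
  }
  g / sums
}

# Per-cell-type medians of a genes x cells matrix; genes x K.
type_medians <- function(values, labels) {
  types <- levels(labels)
  med <- vapply(types, function(k) {
    apply(values[, labels == k, drop = FALSE], 1L, median)
  }, numeric(nrow(values)))
  rownames(med) <- rownames(values)
  med
}

# All permutations of 1..n as an n! x n matrix (used for exhaustive nulls).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = factorial(n), ncol = n)
  row <- 1L
  for (i in seq_len(n)) {
    rest <- seq_len(n)[-i]
    block <- cbind(i, matrix(rest[sub], nrow = nrow(sub)))
    out[row:(row + nrow(sub) - 1L), ] <- block
    row <- row + nrow(sub)
  }
  out
}

# Stable short hash of an R object (for run logging); not cryptographic.
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2)
  v <- as.integer(raw)
  h <- 0
  for (i in seq_along(v)) h <- (h * 31 + v[i]) %% 2147483647
  sprintf("%08x", as.integer(h))
}
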