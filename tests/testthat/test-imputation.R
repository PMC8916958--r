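# Imputability screen, gamma-mixture EM, reference imputation, weights.

# Compendium with controllable per-gene expression/beta relationships.
toy_compendium <- function(genes, rel, n = 40, seed = 1) {
  set.seed(seed)
  expr <- matrix(rlnorm(length(genes) * n), length(genes), n,
                 dimnames = list(genes, paste0("s", seq_len(n))))
  beta <- matrix(runif(length(genes) * n, 0.3, 0.7), length(genes), n,
                 dimnames = dimnames(expr))
  for (g in names(rel)) {
    if (rel[[g]] == "anti") beta[g, ] <- clip01(0.9 - 0.1 * expr[g, ] +
                                                  rnorm(n, 0, 0.02))
    if (rel[[g]] == "pos") beta[g, ] <- clip01(0.1 + 0.1 * expr[g, ] +
                                                 rnorm(n, 0, 0.02))
  }
  matched_compendium(expr, beta)
}
clip01 <- function(x) pmin(1, pmax(0, x))

test_that("imputable genes must anticorrelate in both compendia", {
  genes <- c("g1", "g2", "g3")
  cA <- toy_compendium(genes, list(g1 = "anti", g2 = "anti"), seed = 41)
  cB <- toy_compendium(genes, list(g1 = "anti", g2 = "pos"), seed = 42)
  keep <- select_imputable(genes, cA, cB, rho_max = -0.3)
  expect_identical(as.character(keep), "g1")
  log <- attr(keep, "log")
  expect_true("g2" %in% log$gene)       # anticorrelated in one only
  expect_true("g3" %in% log$gene)
})

test_that("genes absent from a compendium are excluded with a logged reason", {
  cA <- toy_compendium(c("g1", "g2"), list(g1 = "anti"), seed = 43)
  cB <- toy_compendium(c("g1"), list(g1 = "anti"), seed = 44)
  keep <- select_imputable(c("g1", "g2"), cA, cB)
  expect_identical(as.character(keep), "g1")
  expect_match(attr(keep, "log")$reason[attr(keep, "log")$gene == "g2"],
               "absent")
})

test_that("the imputable set is invariant under sample permutation", {
  genes <- paste0("g", 1:10)
  rel <- setNames(as.list(rep(c("anti", "none"), 5)), genes)
  cA <- toy_compendium(genes, rel, seed = 45)
  cB <- toy_compendium(genes, rel, seed = 46)
  set.seed(47)
  perm <- sample(ncol(cA$expr))
  cA2 <- matched_compendium(cA$expr[, perm], cA$beta[, perm])
  expect_identical(as.character(select_imputable(genes, cA, cB)),
                   as.character(select_imputable(genes, cA2, cB)))
})

test_that("selected fraction lands in the 10-30% band at 20% planted", {
  cfg <- sim_config(seed = 48)
  genes <- paste0("g", sprintf("%03d", 1:300))
  comp <- simulate_compendium(cfg, genes, frac_anticorrelated = 0.2)
  keep <- select_imputable(genes, comp$compA, comp$compB)
  frac <- length(keep) / length(genes)
  expect_gte(frac, 0.10)
  expect_lte(frac, 0.30)
  # and with no planted anticorrelation, nothing is imputable
  comp0 <- simulate_compendium(sim_config(seed = 49), genes,
                               frac_anticorrelated = 0)
  expect_length(select_imputable(genes, comp0$compA, comp0$compB), 0L)
})

test_that("EM responsibilities normalize and the log-likelihood never drops", {
  set.seed(51)
  x <- c(rgamma(300, 4, 40), rgamma(300, 50, 60))
  fit <- fit_gamma_mixture(x)
  expect_equal(rowSums(fit$responsibilities), rep(1, length(x)))
  expect_true(all(diff(fit$trace) > -1e-8))
  expect_error(fit_gamma_mixture(rep(0.5, 30)), "identical")
  expect_error(fit_gamma_mixture(runif(10)), "20")
})

test_that("EM recovers a known mixture within 10% of a grid-search oracle", {
  set.seed(52)
  n <- 2000
  true_means <- c(0.2, 0.8)
  x <- c(rgamma(n / 2, 20, 100), rgamma(n / 2, 64, 80))
  fit <- fit_gamma_mixture(x)

  # independent oracle: direct likelihood maximization over a parameter grid
  grid <- expand.grid(m1 = seq(0.10, 0.30, 0.02), m2 = seq(0.6, 1.0, 0.02),
                      cv = c(0.1, 0.2, 0.3), pi = c(0.3, 0.5, 0.7))
  ll <- vapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    s1 <- 1 / g$cv^2; s2 <- 1 / g$cv^2
    sum(log(g$pi * dgamma(x, s1, s1 / g$m1) +
              (1 - g$pi) * dgamma(x, s2, s2 / g$m2)))
  }, numeric(1))
  best <- grid[which.max(ll), ]
  expect_gte(fit$loglik, max(ll))                 # EM at least as good
  expect_lt(abs(fit$means[1] - best$m1) / best$m1, 0.10)
  expect_lt(abs(fit$means[2] - best$m2) / best$m2, 0.10)
  expect_lt(abs(fit$means[1] - true_means[1]) / true_means[1], 0.10)
  expect_lt(abs(fit$means[2] - true_means[2]) / true_means[2], 0.10)
})

test_that("random restarts agree on the best log-likelihood", {
  set.seed(53)
  x <- c(rgamma(500, 10, 50), rgamma(500, 80, 100))
  fits <- lapply(1:5, function(s) fit_gamma_mixture(x, seed = s * 100,
                                                    restarts = 1))
  lls <- vapply(fits, function(f) f$loglik, numeric(1))
  expect_lt(max(lls) - min(lls), 1e-3)
})

make_expr_ref <- function(values) {
  types <- colnames(values)
  marker_type <- apply(values, 1, function(v) types[which.max(v)])
  structure(list(values = values, cell_types = types,
                 marker_type = marker_type,
                 mss = setNames(rep(1L, nrow(values)), rownames(values))),
            class = "expression_reference")
}

test_that("imputation zeroes expressed entries and recovers silent betas", {
  cfg <- sim_config(seed = 54)
  genes <- paste0("g", sprintf("%03d", 1:60))
  comp <- simulate_compendium(cfg, genes, frac_anticorrelated = 1,
                              silent_sd = 0.02)
  # expression reference: each gene expressed in exactly one of 3 types
  ev <- matrix(0, 60, 3, dimnames = list(genes, c("A", "B", "C")))
  ev[cbind(seq_len(60), rep(1:3, length.out = 60))] <- 5
  expr_ref <- make_expr_ref(ev)
  ref <- impute_dnam_reference(expr_ref, genes, comp$compA, comp$compB)
  expect_s3_class(ref, "dnam_reference")
  expect_true(all(ref$values >= 0 & ref$values <= 1))
  # expressed entries exactly zero
  expressed <- ev[rownames(ref$values), ] > 0
  expect_true(all(ref$values[expressed] == 0))
  # unexpressed entries near the planted silent-state beta
  truth <- setNames(comp$truth$silent_beta, comp$truth$gene)
  imputed_silent <- ref$values[!expressed]
  planted <- truth[rownames(ref$values)][row(ref$values)[!expressed]]
  expect_lt(max(abs(imputed_silent - planted)), 0.1)
})

test_that("markers imputable in neither compendium are absent; empty set errors", {
  ev <- matrix(c(5, 0, 0, 5), 2, 2,
               dimnames = list(c("g1", "gX"), c("A", "B")))
  expr_ref <- make_expr_ref(ev)
  cfg <- sim_config(seed = 55)
  comp <- simulate_compendium(cfg, "g1", frac_anticorrelated = 1)
  ref <- impute_dnam_reference(expr_ref, "g1", comp$compA, comp$compB)
  expect_false("gX" %in% rownames(ref$values))
  expect_error(impute_dnam_reference(expr_ref, character(0),
                                     comp$compA, comp$compB), "empty")
})

test_that("weights average imputed betas over unexpressed types", {
  values <- rbind(g1 = c(0, 0.9, 0.8, 0.85),
                  g2 = c(0, 0, 0, 0),
                  g3 = c(0.2, 0.3, 0.4, 0.5))
  colnames(values) <- LETTERS[1:4]
  ev <- rbind(g1 = c(5, 0, 0, 0), g2 = c(5, 0, 0, 0), g3 = c(1, 2, 3, 4))
  colnames(ev) <- LETTERS[1:4]
  ref <- dnam_reference(values)
  w <- compute_weights(ref, make_expr_ref(ev))
  expect_equal(unname(w["g1"]), 0.85)   # mean of {0.9, 0.8, 0.85}
  expect_equal(unname(w["g2"]), 0)      # uninformative marker
  expect_equal(unname(w["g3"]), 1)      # expressed everywhere
})
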