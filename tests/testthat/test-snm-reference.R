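# Single-nucleus aggregation, marker derivation, reference comparison.

clip01_test <- function(x) { x[x < 0] <- 0; x[x > 1] <- 1; x }

toy_calls <- function() {
  # gene GA has cpg a1, a2; gene GB has cpg b1. Nuclei n1..n6.
  data.frame(
    site_id = c("a1", "a1", "a1", "a1", "a1", "a2", "a2", "a2", "a2", "a2",
                "b1", "b1", "b1", "b1"),
    nucleus_id = c("n1", "n2", "n3", "n4", "n5", "n1", "n2", "n3", "n4", "n5",
                   "n1", "n2", "n3", "n4"),
    call = c(1, 0, 1, 1, 0, 0, 0, 1, 0, 1, 1, 1, 0, 0),
    stringsAsFactors = FALSE)
}
toy_map <- data.frame(site_id = c("a1", "a2", "b1"),
                      gene = c("GA", "GA", "GB"), stringsAsFactors = FALSE)

test_that("promoter aggregation averages covered Bernoulli calls", {
  gbn <- aggregate_nucleus_promoters(toy_calls(), toy_map, min_nuclei = 2)
  expect_equal(gbn["GA", "n1"], 0.5)     # calls {1, 0}
  expect_equal(gbn["GB", "n1"], 1)
  expect_true(is.na(gbn["GB", "n5"]))    # no covered CpG
  expect_true(all(gbn >= 0 & gbn <= 1, na.rm = TRUE))
})

test_that("CpGs below the nucleus-coverage floor are dropped", {
  gbn <- aggregate_nucleus_promoters(toy_calls(), toy_map, min_nuclei = 5)
  # b1 covered in only 4 nuclei -> dropped, gene GB disappears
  expect_false("GB" %in% rownames(gbn))
  expect_true("GA" %in% rownames(gbn))
  expect_error(aggregate_nucleus_promoters(toy_calls(),
                                           toy_map[0, ], min_nuclei = 5),
               "empty")
})

test_that("aggregation is invariant to call-row ordering", {
  calls <- toy_calls()
  set.seed(81)
  gbn1 <- aggregate_nucleus_promoters(calls, toy_map, min_nuclei = 1)
  gbn2 <- aggregate_nucleus_promoters(calls[sample(nrow(calls)), ], toy_map,
                                      min_nuclei = 1)
  expect_equal(gbn1, gbn2)
})

test_that("simulated sparse data reproduces per-gene means within binomial error", {
  cfg <- sim_config(seed = 82, markers_per_type = 5, K = 3,
                    nuclei_per_type = 150, coverage = 0.1)
  ref <- block_reference(K = 3, markers_per_type = 5, other_beta = 0.8)
  snm <- simulate_snm(ref, cfg)
  gbn <- aggregate_nucleus_promoters(snm$calls, snm$cpg_map, min_nuclei = 1)
  labels <- snm$labels[colnames(gbn)]
  for (k in colnames(ref$values)) {
    means <- rowMeans(gbn[, labels == k, drop = FALSE], na.rm = TRUE)
    target <- ref$values[names(means), k]
    # each per-gene mean pools >= ~75 Bernoulli calls: 3 binomial sds
    n_eff <- 75
    tol <- 3 * sqrt(pmax(target * (1 - target), 0.05) / n_eff)
    expect_true(all(abs(means - target) < tol))
  }
})

test_that("AUC matches brute-force pair counting and separates perfectly", {
  # 12-nucleus toy, 2 types
  labels <- rep(c("A", "B"), each = 6)
  vals <- rbind(
    sep = c(rep(0, 6), rep(1, 6)),                      # perfect separation
    tie = c(0.1, 0.2, 0.2, 0.5, 0.4, 0.3, 0.2, 0.2, 0.6, 0.5, 0.4, 0.9))
  colnames(vals) <- paste0("n", 1:12)
  res <- suppressWarnings(derive_snm_reference(vals, labels, top_n = 2,
                                               min_nonmissing = 3, fdr = 0.5))
  tabA <- res$auc_table[res$auc_table$cell_type == "A", ]
  expect_equal(tabA$auc[tabA$gene == "sep"], 1)
  expect_identical(tabA$gene[which.max(tabA$auc)], "sep")
  # oracle: AUC toward low DNAm in target = P(target < rest) + half-ties
  oracle <- bf_u_statistic(vals["tie", 7:12], vals["tie", 1:6])
  expect_equal(tabA$auc[tabA$gene == "tie"], oracle$auc)
})

test_that("derivation respects top_n, coverage rule, and warns on empty types", {
  cfg <- sim_config(seed = 83, markers_per_type = 20, nuclei_per_type = 100)
  ref <- block_reference(K = 6, markers_per_type = 20, other_beta = 0.8,
                         n_background = 60)
  snm <- simulate_snm(ref, cfg)
  gbn <- aggregate_nucleus_promoters(snm$calls, snm$cpg_map)
  res <- derive_snm_reference(gbn, snm$labels[colnames(gbn)], top_n = 10)
  per_type <- table(res$auc_table$cell_type[res$auc_table$selected])
  expect_true(all(per_type <= 10))
  expect_lte(nrow(res$reference$values), 6 * 10)
  # a type whose nuclei carry no qualifying gene triggers a warning but the
  # other types' markers are still derived
  vals <- rbind(g1 = c(rep(0.1, 10), rep(0.9, 10), rep(NA, 10)),
                g2 = c(rep(0.9, 10), rep(0.1, 10), rep(NA, 10)))
  colnames(vals) <- paste0("n", 1:30)
  labels3 <- rep(c("A", "B", "C"), each = 10)
  expect_warning(res3 <- derive_snm_reference(vals, labels3,
                                              min_nonmissing = 5),
                 "coverage rule")
  sel3 <- res3$auc_table[res3$auc_table$selected, ]
  expect_setequal(sel3$cell_type, c("A", "B"))
})

test_that("marker hypomethylation t-tests match the closed form", {
  labels <- rep(c("A", "B"), c(3, 3))
  gbn <- rbind(m1 = c(0.1, 0.2, 0.15, 0.8, 0.7, 0.75),
               m2 = c(0.5, 0.55, 0.45, 0.5, 0.52, 0.48))
  colnames(gbn) <- paste0("n", 1:6)
  ref <- dnam_reference(rbind(m1 = c(A = 0.15, B = 0.75),
                              m2 = c(A = 0.5, B = 0.5)),
                        marker_type = c(m1 = "A", m2 = "A"))
  res <- marker_hypomethylation_test(gbn, labels, ref)
  expect_equal(res$t[res$gene == "m1"],
               bf_welch_t(gbn["m1", 1:3], gbn["m1", 4:6]), tolerance = 1e-12)
  expect_lt(res$t[res$gene == "m1"], 0)
  expect_lt(abs(res$t[res$gene == "m2"]), 1)  # null marker: t near 0
  expect_gt(res$p[res$gene == "m2"], 0.1)
})

test_that("planted hypomethylation is significant at n = 50 per group", {
  set.seed(84)
  n <- 50
  gbn <- rbind(mk = c(rnorm(n, 0.2, 0.1), rnorm(n, 0.8, 0.1)))
  gbn <- clip01_test(gbn)
  colnames(gbn) <- paste0("n", 1:(2 * n))
  labels <- rep(c("A", "B"), each = n)
  ref <- dnam_reference(rbind(mk = c(A = 0.2, B = 0.8)),
                        marker_type = c(mk = "A"))
  res <- marker_hypomethylation_test(gbn, labels, ref)
  expect_lt(res$fdr, 0.05)
  expect_lt(res$t, 0)
})

test_that("comparing a reference to itself gives MAD 0, PCC 1, small p", {
  set.seed(89)
  vals <- matrix(runif(40), 20, 2,
                 dimnames = list(paste0("g", 1:20), c("A", "B")))
  ref <- dnam_reference(vals)
  res <- compare_references(ref, ref, n_mc = 200, seed = 85)
  expect_equal(res$mad, 0)
  expect_equal(res$pcc, 1)
  expect_lte(res$p_mad, 1 / (res$n_perm))
  expect_gt(res$p_mad, 0)                      # add-one rule keeps p > 0
})

test_that("permutation p matches exhaustive enumeration on a 5-gene toy", {
  set.seed(86)
  genes <- paste0("g", 1:5)
  A <- matrix(runif(10), 5, 2, dimnames = list(genes, c("A", "B")))
  B <- clip01_test(A + matrix(rnorm(10, 0, 0.1), 5, 2))
  res <- compare_references(A, B, n_mc = 200, min_shared = 5)
  expect_identical(res$method, "exhaustive")
  expect_identical(res$n_perm, 120L)
  # oracle: direct enumeration over all 120 permutations
  obs_mad <- median(abs(A - B))
  obs_pcc <- cor(as.vector(A), as.vector(B))
  null <- t(vapply(bf_permutations(5), function(pm) {
    c(median(abs(A - B[pm, ])), cor(as.vector(A), as.vector(B[pm, ])))
  }, numeric(2)))
  expect_equal(res$p_mad, mean(null[, 1] <= obs_mad))
  expect_equal(res$p_pcc, mean(null[, 2] >= obs_pcc))
})

test_that("re-drawn random references are not called similar", {
  set.seed(87)
  genes <- paste0("g", 1:30)
  A <- matrix(runif(60), 30, 2, dimnames = list(genes, c("A", "B")))
  B <- matrix(runif(60), 30, 2, dimnames = list(genes, c("A", "B")))
  res <- compare_references(A, B, n_mc = 300, seed = 88)
  expect_gt(res$p_pcc, 0.01)
  expect_error(compare_references(A[1:5, ], B[1:5, ]), "10")
})
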