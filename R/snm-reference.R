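# DNAm reference derivation from sparse single-nucleus methylomes.

#' Aggregate single-nucleus CpG calls to gene-promoter betas
#'
#' Drops CpGs covered in fewer than `min_nuclei` nuclei, then averages the
#' Bernoulli calls of each gene's TSS200 CpGs within every nucleus. Entries
#' with no covered CpG stay missing.
#'
#' @param calls data.frame of covered calls with columns `site_id`,
#'   `nucleus_id`, `call` (0/1). Uncovered site/nucleus pairs are simply
#'   absent.
#' @param cpg_map data.frame mapping CpGs to genes: columns `site_id`, `gene`
#'   (TSS200 assignment).
#' @param min_nuclei minimum nuclei covering a CpG for it to be kept
#'   (default 5).
#' @return numeric matrix, genes x nuclei, betas in `[0,1]` with `NA` for
#'   missing entries.
#' @export
aggregate_nucleus_promoters <- function(calls, cpg_map, min_nuclei = 5L) {
  stopifnot(is.data.frame(calls),
            all(c("site_id", "nucleus_id", "call") %in% names(calls)))
  if (!is.data.frame(cpg_map) || nrow(cpg_map) == 0L ||
      !all(c("site_id", "gene") %in% names(cpg_map)))
    stop("cpg_map must be a non-empty data.frame with columns site_id, gene")
  if (!all(calls$call %in% c(0, 1))) stop("calls must be Bernoulli (0/1)")

  coverage <- table(calls$site_id)
  keep_sites <- names(coverage)[coverage >= min_nuclei]
  calls <- calls[calls$site_id %in% keep_sites, , drop = FALSE]
  calls <- merge(calls, cpg_map[, c("site_id", "gene")], by = "site_id")
  if (nrow(calls) == 0L) {
    return(matrix(NA_real_, 0L, 0L))
  }
  genes <- sort(unique(calls$gene))
  nuclei <- sort(unique(calls$nucleus_id))
  gi <- match(calls$gene, genes)
  ni <- match(calls$nucleus_id, nuclei)
  sums <- Matrix::sparseMatrix(i = gi, j = ni, x = calls$call,
                               dims = c(length(genes), length(nuclei)))
  counts <- Matrix::sparseMatrix(i = gi, j = ni, x = rep(1, nrow(calls)),
                                 dims = c(length(genes), length(nuclei)))
  out <- as.matrix(sums) / as.matrix(counts)
  out[as.matrix(counts) == 0] <- NA_real_
  dimnames(out) <- list(genes, nuclei)
  out
}

#' Derive a DNAm reference from single-nucleus promoter betas
#'
#' Per cell type, genes with at least `min_nonmissing` non-missing values in
#' the target nuclei are tested by Wilcoxon rank-sum (alternative: lower DNAm
#' in the target type). Genes with BH-FDR < `fdr` are ranked by AUC (AUC near
#' 1 means lower DNAm in the target type) and the top `top_n` kept per type.
#' The reference entry of a selected gene in each type is its mean beta over
#' that type's non-missing nuclei; all markers carry unit weight.
#'
#' @param gene_by_nucleus genes x nuclei beta matrix with `NA` for missing,
#'   as produced by [aggregate_nucleus_promoters()].
#' @param labels nucleus cell-type label per column.
#' @param top_n markers kept per type (default 20).
#' @param min_nonmissing minimum non-missing target values (default 10).
#' @param fdr BH-FDR threshold (default 0.05).
#' @return list with `reference` (a [dnam_reference()] with `marker_type`
#'   set) and `auc_table` (per gene and type: `p`, `fdr`, `auc`, `n_target`,
#'   `selected`).
#' @export
derive_snm_reference <- function(gene_by_nucleus, labels, top_n = 20L,
                                 min_nonmissing = 10L, fdr = 0.05) {
  stopifnot(is.matrix(gene_by_nucleus),
            length(labels) == ncol(gene_by_nucleus))
  labels <- droplevels(factor(labels))
  types <- levels(labels)
  if (length(types) < 2L) stop("at least two cell types are required")

  tabs <- list()
  selected <- list()
  for (k in types) {
    in_k <- labels == k
    n_target <- rowSums(!is.na(gene_by_nucleus[, in_k, drop = FALSE]))
    cand <- rownames(gene_by_nucleus)[n_target >= min_nonmissing]
    if (length(cand) == 0L) {
      warning("no gene meets the coverage rule for cell type ", k)
      next
    }
    st <- rowwise_rank_sum(gene_by_nucleus[cand, , drop = FALSE], in_k)
    tab <- data.frame(gene = cand, cell_type = k,
                      p = st$p_less,
                      auc = 1 - st$auc,   # toward 1 = lower DNAm in target
                      n_target = n_target[cand],
                      stringsAsFactors = FALSE)
    tab$fdr <- p.adjust(tab$p, method = "BH")
    sig <- tab[!is.na(tab$fdr) & tab$fdr < fdr, , drop = FALSE]
    sig <- sig[order(-sig$auc, sig$p, sig$gene), , drop = FALSE]
    picked <- utils::head(sig$gene, top_n)
    if (length(picked) == 0L)
      warning("no significant marker gene for cell type ", k)
    tab$selected <- tab$gene %in% picked
    tabs[[k]] <- tab
    selected[[k]] <- picked
  }
  auc_table <- do.call(rbind, tabs)
  rownames(auc_table) <- NULL
  genes <- unique(unlist(selected))
  if (length(genes) == 0L) stop("no marker gene selected for any cell type")

  values <- pseudo_bulk(gene_by_nucleus[genes, , drop = FALSE], labels)
  # rare fully-missing cells: fall back to the gene's overall mean
  if (anyNA(values)) {
    gm <- rowMeans(values, na.rm = TRUE)
    for (i in which(rowSums(is.na(values)) > 0L))
      values[i, is.na(values[i, ])] <- gm[i]
  }
  marker_type <- stats::setNames(rep(NA_character_, length(genes)), genes)
  for (k in rev(names(selected))) marker_type[selected[[k]]] <- k
  ref <- dnam_reference(clip01(values), marker_type = marker_type)
  list(reference = ref, auc_table = auc_table)
}

#' Test marker hypomethylation in their own cell type
#'
#' For each reference marker, a one-tailed two-sample t-test of promoter beta
#' in the marker's own cell type against all other nuclei (alternative: lower
#' in the own type), with BH-FDR across markers.
#'
#' @param gene_by_nucleus genes x nuclei beta matrix (`NA` for missing).
#' @param labels nucleus cell-type labels.
#' @param dnam_ref a [dnam_reference()] whose `marker_type` is set.
#' @return data.frame: `gene`, `cell_type`, `t`, `p`, `fdr`, `n_target`,
#'   `n_other`.
#' @export
marker_hypomethylation_test <- function(gene_by_nucleus, labels, dnam_ref) {
  stopifnot(inherits(dnam_ref, "dnam_reference"))
  if (is.null(dnam_ref$marker_type))
    stop("dnam_ref must carry marker_type assignments")
  labels <- droplevels(factor(labels))
  genes <- intersect(names(dnam_ref$marker_type), rownames(gene_by_nucleus))
  rows <- lapply(genes, function(g) {
    k <- dnam_ref$marker_type[[g]]
    x <- gene_by_nucleus[g, labels == k]
    yv <- gene_by_nucleus[g, labels != k]
    x <- x[!is.na(x)]; yv <- yv[!is.na(yv)]
    if (length(x) < 2L || length(yv) < 2L ||
        (var(x) == 0 && var(yv) == 0)) {
      tt <- list(statistic = NA_real_, p.value = NA_real_)
    } else {
      tt <- t.test(x, yv, alternative = "less")
    }
    data.frame(gene = g, cell_type = k, t = unname(tt$statistic),
               p = tt$p.value, n_target = length(x), n_other = length(yv),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, method = "BH")
  out[, c("gene", "cell_type", "t", "p", "fdr", "n_target", "n_other")]
}

#' Compare two DNAm reference matrices
#'
#' Over shared (gene, cell-type) entries, computes the median absolute
#' deviation (MAD) and Pearson correlation (PCC), with significance from a
#' gene-row permutation null of the second reference: `n_mc` Monte-Carlo
#' permutations with the add-one rule `p = (1 + #null >= obs) / (1 + n_mc)`,
#' or, when the number of shared genes is small enough that all permutations
#' fit within `n_mc`, exhaustive enumeration (`p = #null >= obs / n!`,
#' identity included).
#'
#' @param refA,refB [dnam_reference()] objects (or plain matrices) sharing at
#'   least `min_shared` marker genes.
#' @param n_mc Monte-Carlo permutations (default 1000).
#' @param seed RNG seed (default 0).
#' @param min_shared minimum shared markers (default 10; lower it only for
#'   toy problems).
#' @return list: `mad`, `pcc`, `p_mad`, `p_pcc`, `n_shared`, `n_perm`,
#'   `method` ("exhaustive" or "monte-carlo").
#' @export
compare_references <- function(refA, refB, n_mc = 1000L, seed = 0L,
                               min_shared = 10L) {
  A <- if (inherits(refA, "dnam_reference")) refA$values else as.matrix(refA)
  B <- if (inherits(refB, "dnam_reference")) refB$values else as.matrix(refB)
  genes <- intersect(rownames(A), rownames(B))
  types <- intersect(colnames(A), colnames(B))
  if (length(genes) < min_shared)
    stop(sprintf("only %d shared markers; at least %d required",
                 length(genes), min_shared))
  if (length(types) < 1L) stop("no shared cell types")
  A <- A[genes, types, drop = FALSE]
  B <- B[genes, types, drop = FALSE]

  stat <- function(Bperm) {
    d <- as.vector(A) - as.vector(Bperm)
    c(mad = median(abs(d)),
      pcc = suppressWarnings(cor(as.vector(A), as.vector(Bperm))))
  }
  obs <- stat(B)
  n <- length(genes)
  exhaustive <- is.finite(factorial(n)) && factorial(n) <= n_mc
  if (exhaustive) {
    perms <- all_permutations(n)
    null <- t(apply(perms, 1L, function(pm) stat(B[pm, , drop = FALSE])))
    p_mad <- mean(null[, "mad"] <= obs["mad"])
    p_pcc <- mean(null[, "pcc"] >= obs["pcc"])
    n_perm <- nrow(perms)
    method <- "exhaustive"
  } else {
    set.seed(seed)
    null <- t(vapply(seq_len(n_mc), function(i) {
      stat(B[sample.int(n), , drop = FALSE])
    }, numeric(2)))
    p_mad <- (1 + sum(null[, 1] <= obs["mad"])) / (1 + n_mc)
    p_pcc <- (1 + sum(null[, 2] >= obs["pcc"])) / (1 + n_mc)
    n_perm <- n_mc
    method <- "monte-carlo"
  }
  list(mad = unname(obs["mad"]), pcc = unname(obs["pcc"]),
       p_mad = p_mad, p_pcc = p_pcc, n_shared = n,
       n_perm = n_perm, method = method)
}
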