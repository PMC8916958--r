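# Expression reference construction from annotated scRNA-seq.

#' Annotated single-cell expression matrix
#'
#' Container pairing a non-negative genes x cells expression matrix with one
#' cell-type label per cell. At least two cell types are required.
#'
#' @param values numeric matrix, genes x cells, non-negative, unique dimnames.
#' @param labels character or factor of cell-type labels, one per cell (or a
#'   named vector matched to `colnames(values)`).
#' @return object of class `sc_expression`: list with `values` and `labels`
#'   (a factor aligned to the columns of `values`).
#' @export
sc_expression <- function(values, labels) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (any(values < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("gene identifiers must be present and unique")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("cell identifiers must be present and unique")
  if (!is.null(names(labels))) {
    miss <- setdiff(colnames(values), names(labels))
    if (length(miss) > 0L)
      stop("unlabeled cell(s): ", paste(utils::head(miss, 3L), collapse = ", "))
    labels <- labels[colnames(values)]
  }
  if (length(labels) != ncol(values))
    stop("every cell must carry a label")
  if (anyNA(labels)) stop("every cell must carry a label")
  labels <- droplevels(factor(labels))
  if (nlevels(labels) < 2L) stop("at least two cell types are required")
  structure(list(values = values, labels = labels), class = "sc_expression")
}

#' @export
print.sc_expression <- function(x, ...) {
  cat(sprintf("sc_expression: %d genes x %d cells, %d cell types\n",
              nrow(x$values), ncol(x$values), nlevels(x$labels)))
  print(table(x$labels))
  invisible(x)
}

#' Rank and select cell-type marker genes
#'
#' One-vs-rest Wilcoxon rank-sum tests (alternative: greater in the target
#' type, normal approximation with tie correction) identify genes
#' over-expressed in each cell type. Each gene's target type is the type with
#' maximal median expression (ties broken by smaller Wilcoxon p, then
#' lexicographic type name). The marker specificity score (MSS) counts the
#' other cell types in which the gene's median expression is zero; the ideal
#' marker attains MSS = K - 1. Genes are retained when BH-FDR < `fdr` (FDR
#' computed per type, across genes) and MSS >= `mss_min`.
#'
#' When fewer than `min_markers` genes survive and `relax = TRUE`, `mss_min`
#' is lowered stepwise by 1 until at least `min_markers` markers are selected
#' or `mss_min` reaches `ceiling((K - 1) / 2)`, whichever happens first.
#'
#' @param sc an [sc_expression()] object.
#' @param mss_min minimum marker specificity score; default `K - 1`.
#' @param fdr BH-FDR threshold (default 0.05).
#' @param relax logical; lower `mss_min` when markers are scarce (default TRUE).
#' @param min_markers marker count triggering relaxation (default 100).
#' @return data.frame with one row per selected marker: `gene`, `cell_type`,
#'   `p`, `fdr`, `mss`, `median_target`; attributes `medians` (genes x K
#'   median matrix), `mss_used`, and `K`.
#' @export
rank_markers <- function(sc, mss_min = NULL, fdr = 0.05, relax = TRUE,
                         min_markers = 100L) {
  stopifnot(inherits(sc, "sc_expression"))
  labels <- sc$labels
  types <- levels(labels)
  K <- length(types)
  n_per <- table(labels)
  if (any(n_per < 2L))
    stop("cell type(s) with fewer than 2 cells: ",
         paste(names(n_per)[n_per < 2L], collapse = ", "))
  if (is.null(mss_min)) mss_min <- K - 1L

  med <- type_medians(sc$values, labels)
  colnames(med) <- types

  # one-vs-rest Wilcoxon per type
  pmat <- vapply(types, function(k) {
    rowwise_rank_sum(sc$values, labels == k)$p_greater
  }, numeric(nrow(sc$values)))
  fdrmat <- apply(pmat, 2L, p.adjust, method = "BH")
  dimnames(pmat) <- dimnames(fdrmat) <- list(rownames(sc$values), types)

  # target type: maximal median, ties by smaller p then type name
  target_idx <- vapply(seq_len(nrow(med)), function(i) {
    cand <- which(med[i, ] == max(med[i, ]))
    if (length(cand) > 1L) cand <- cand[order(pmat[i, cand], types[cand])]
    cand[1L]
  }, integer(1))
  mss <- vapply(seq_len(nrow(med)), function(i) {
    sum(med[i, -target_idx[i]] == 0)
  }, integer(1))

  tab <- data.frame(
    gene = rownames(sc$values),
    cell_type = types[target_idx],
    p = pmat[cbind(seq_len(nrow(med)), target_idx)],
    fdr = fdrmat[cbind(seq_len(nrow(med)), target_idx)],
    mss = mss,
    median_target = med[cbind(seq_len(nrow(med)), target_idx)],
    stringsAsFactors = FALSE
  )

  floor_mss <- ceiling((K - 1L) / 2)
  mss_used <- mss_min
  repeat {
    sel <- tab[tab$fdr < fdr & tab$mss >= mss_used & tab$median_target > 0, ,
               drop = FALSE]
    if (!relax || nrow(sel) >= min_markers || mss_used <= floor_mss) break
    mss_used <- mss_used - 1L
  }
  sel <- sel[order(sel$cell_type, sel$p, sel$gene), ]
  rownames(sel) <- NULL
  attr(sel, "medians") <- med
  attr(sel, "mss_used") <- mss_used
  attr(sel, "K") <- K
  sel
}

#' Build a cell-type expression reference matrix
#'
#' Reference entry (g, k) is the median expression of marker g over all cells
#' of type k. Fewer than 100 markers triggers a warning (small references make
#' fraction estimation unstable) but is not an error.
#'
#' @param sc an [sc_expression()] object.
#' @param markers marker table from [rank_markers()].
#' @return object of class `expression_reference`: list with `values` (markers
#'   x K median matrix), `cell_types`, `marker_type` (named character: each
#'   marker's target type) and `mss` (named integer).
#' @export
build_expression_reference <- function(sc, markers) {
  stopifnot(inherits(sc, "sc_expression"), is.data.frame(markers))
  if (nrow(markers) == 0L) stop("markers table is empty")
  missing_genes <- setdiff(markers$gene, rownames(sc$values))
  if (length(missing_genes) > 0L)
    stop("marker gene(s) absent from expression matrix: ",
         paste(utils::head(missing_genes, 3L), collapse = ", "))
  if (nrow(markers) < 100L)
    warning(sprintf("only %d marker genes; at least 100 are recommended",
                    nrow(markers)))
  med <- type_medians(sc$values[markers$gene, , drop = FALSE], sc$labels)
  marker_type <- stats::setNames(markers$cell_type, markers$gene)
  mss <- stats::setNames(as.integer(markers$mss), markers$gene)
  structure(list(values = med, cell_types = colnames(med),
                 marker_type = marker_type, mss = mss),
            class = "expression_reference")
}

#' @export
print.expression_reference <- function(x, ...) {
  cat(sprintf("expression_reference: %d markers x %d cell types\n",
              nrow(x$values), length(x$cell_types)))
  print(table(x$marker_type))
  invisible(x)
}

#' Validate an expression reference on annotated cells
#'
#' Estimates a cell-type fraction vector for every cell of a validation
#' scRNA-seq dataset by (unweighted) robust partial correlations against the
#' reference, then scores the share of cells whose arg-max fraction matches
#' their annotated label. Cells of a type absent from the reference are still
#' assigned an arg-max type; they can only be flagged through a low maximal
#' fraction.
#'
#' @param sc_val an [sc_expression()] validation dataset.
#' @param ref an `expression_reference`.
#' @param min_overlap minimum share of reference markers that must be present
#'   in `sc_val` (default 0.3).
#' @return list with `fractions` (cells x K), `predicted` (character),
#'   `accuracy` (overall arg-max accuracy), `per_type_accuracy`, and
#'   `confusion` (true type x predicted type counts).
#' @export
validate_reference_on_cells <- function(sc_val, ref, min_overlap = 0.3) {
  stopifnot(inherits(sc_val, "sc_expression"),
            inherits(ref, "expression_reference"))
  shared <- intersect(rownames(ref$values), rownames(sc_val$values))
  if (length(shared) == 0L) stop("no overlapping markers between reference and dataset")
  if (length(shared) < min_overlap * nrow(ref$values))
    stop(sprintf("only %d of %d reference markers present (< %.0f%%)",
                 length(shared), nrow(ref$values), 100 * min_overlap))
  R <- ref$values[shared, , drop = FALSE]
  Y <- sc_val$values[shared, , drop = FALSE]
  frac <- t(apply(Y, 2L, function(y) {
    wrpc_fit(R, y, weights = rep(1, length(y)), robust = TRUE)
  }))
  colnames(frac) <- colnames(R)
  predicted <- colnames(R)[max.col(frac, ties.method = "first")]
  truth <- as.character(sc_val$labels)
  confusion <- table(true = factor(truth, unique(c(truth, colnames(R)))),
                     predicted = factor(predicted, unique(c(truth, colnames(R)))))
  per_type <- vapply(split(predicted == truth, truth), mean, numeric(1))
  list(fractions = frac, predicted = predicted,
       accuracy = mean(predicted == truth),
       per_type_accuracy = per_type, confusion = confusion)
}
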