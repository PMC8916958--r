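# Derived sample-level scores: tumor purity, immune fraction, and
# two-phenotype proxy panels.

#' Tumor purity from estimated cell-type fractions
#'
#' Purity is one minus the summed fractions of the stromal cell types
#' (typically all immune cells, endothelial cells and fibroblasts), clipped
#' to `[0,1]`.
#'
#' @param fractions numeric matrix, samples x cell types.
#' @param stromal character vector of stromal cell-type names (must exist in
#'   the fraction columns).
#' @return named numeric vector, one purity per sample.
#' @export
tumor_purity <- function(fractions, stromal) {
  stopifnot(is.matrix(fractions))
  missing <- setdiff(stromal, colnames(fractions))
  if (length(missing) > 0L)
    stop("unknown cell type(s) in stromal group: ",
         paste(missing, collapse = ", "))
  clip01(1 - rowSums(fractions[, stromal, drop = FALSE]))
}

#' Total immune cell score
#'
#' The summed estimated fractions of the immune cell types.
#'
#' @param fractions numeric matrix, samples x cell types.
#' @param immune character vector of immune cell-type names.
#' @return named numeric vector, one score per sample.
#' @export
immune_score <- function(fractions, immune) {
  stopifnot(is.matrix(fractions))
  if (length(immune) == 0L) {
    warning("empty immune group; returning zero scores")
    return(stats::setNames(rep(0, nrow(fractions)), rownames(fractions)))
  }
  missing <- setdiff(immune, colnames(fractions))
  if (length(missing) > 0L)
    stop("unknown cell type(s) in immune group: ",
         paste(missing, collapse = ", "))
  rowSums(fractions[, immune, drop = FALSE])
}

#' Build a phenotype proxy marker panel
#'
#' Screens pre-computed phenotype markers (differentially expressed between
#' two phenotypes of the same cell type, e.g. differentiated vs proliferative
#' smooth muscle cells) for consistent promoter hypermethylation in the
#' tissue's other cell types: a marker is kept when its promoter beta exceeds
#' `beta_thresh` in at least `min_other` of the other cell types' profiles.
#' The panel's proxy score for a sample is the mean TSS200 promoter beta over
#' the panel genes; because the markers belong to phenotype A, a higher proxy
#' beta indicates a lower phenotype-A fraction (the sign convention is stored
#' in the panel).
#'
#' @param markers character vector of phenotype-A marker genes (FDR-screened
#'   differential markers with positive median in phenotype A and zero median
#'   in phenotype B; see [phenotype_markers()]).
#' @param other_betas numeric matrix, genes x other cell types, promoter
#'   betas of the candidate markers in the tissue's other cell types.
#' @param beta_thresh hypermethylation threshold (default 0.6).
#' @param min_other minimum number of other cell types exceeding the
#'   threshold (default 3).
#' @return object of class `proxy_panel`: list with `genes`, `evidence`
#'   (other-type betas of the kept markers), `beta_thresh`, `min_other`,
#'   `direction`.
#' @export
build_proxy_panel <- function(markers, other_betas, beta_thresh = 0.6,
                              min_other = 3L) {
  stopifnot(is.character(markers), is.matrix(other_betas))
  markers <- intersect(markers, rownames(other_betas))
  if (length(markers) == 0L)
    stop("no marker has promoter data in the other cell types")
  n_hyper <- rowSums(other_betas[markers, , drop = FALSE] > beta_thresh,
                     na.rm = TRUE)
  kept <- markers[n_hyper >= min_other]
  if (length(kept) == 0L)
    stop("empty proxy panel; consider relaxing beta_thresh or min_other")
  structure(list(genes = kept,
                 evidence = other_betas[kept, , drop = FALSE],
                 beta_thresh = beta_thresh, min_other = min_other,
                 direction = "higher proxy beta = lower phenotype-A fraction"),
            class = "proxy_panel")
}

#' @export
print.proxy_panel <- function(x, ...) {
  cat(sprintf("proxy_panel: %d markers (beta > %.2f in >= %d other types)\n",
              length(x$genes), x$beta_thresh, x$min_other))
  cat(" ", paste(x$genes, collapse = ", "), "\n")
  cat(" direction:", x$direction, "\n")
  invisible(x)
}

#' Proxy score of bulk samples
#'
#' Mean promoter beta over the panel genes, per sample.
#'
#' @param bulk numeric matrix, genes x samples, promoter betas.
#' @param panel a [build_proxy_panel()] object.
#' @return named numeric vector of proxy scores.
#' @export
proxy_score <- function(bulk, panel) {
  stopifnot(inherits(panel, "proxy_panel"), is.matrix(bulk))
  genes <- intersect(panel$genes, rownames(bulk))
  if (length(genes) == 0L) stop("no panel gene present in bulk")
  colMeans(bulk[genes, , drop = FALSE], na.rm = TRUE)
}

#' Differential markers between two phenotypes of one cell type
#'
#' Convenience screen matching the proxy-panel precondition: one-vs-one
#' Wilcoxon rank-sum test between the two phenotypes' cells, keeping genes
#' with BH-FDR < `fdr`, positive median expression in one phenotype and zero
#' median in the other.
#'
#' @param sc an [sc_expression()] object whose labels include `typeA` and
#'   `typeB`.
#' @param typeA,typeB the two phenotype labels.
#' @param fdr BH-FDR threshold (default 0.05).
#' @return list with character vectors `markers_a` and `markers_b`.
#' @export
phenotype_markers <- function(sc, typeA, typeB, fdr = 0.05) {
  stopifnot(inherits(sc, "sc_expression"))
  keep <- sc$labels %in% c(typeA, typeB)
  X <- sc$values[, keep, drop = FALSE]
  g <- sc$labels[keep] == typeA
  if (sum(g) < 2L || sum(!g) < 2L)
    stop("each phenotype needs at least 2 cells")
  st <- rowwise_rank_sum(X, g)
  medA <- apply(X[, g, drop = FALSE], 1L, median)
  medB <- apply(X[, !g, drop = FALSE], 1L, median)
  fdr_a <- p.adjust(st$p_greater, method = "BH")
  fdr_b <- p.adjust(st$p_less, method = "BH")
  list(markers_a = rownames(X)[fdr_a < fdr & medA > 0 & medB == 0],
       markers_b = rownames(X)[fdr_b < fdr & medB > 0 & medA == 0])
}
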