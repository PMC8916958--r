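# Cell-type-specific differential methylation via fraction x phenotype
# interaction models, and locus-set enrichment.

#' Call cell-type-specific differentially methylated cytosines (DMCTs)
#'
#' Per site c, fits the ordinary least-squares model
#' \deqn{\beta_c = \sum_k \mu_{ck} f_k + \sum_k \beta^{(I)}_{ck} f_k y +
#'   \gamma' C + \epsilon}
#' with no global intercept (the fraction terms absorb it because fractions
#' sum to one). The per-cell-type interaction coefficients are t-tested, BH
#' FDR is computed per cell type across sites, and a site is flagged a DMCT in
#' cell type k when FDR < `fdr`, with the direction given by the sign of the
#' interaction coefficient (hyper if positive in cases).
#'
#' @param beta numeric matrix of betas, sites x samples.
#' @param fractions numeric matrix, samples x K, rows summing to 1.
#' @param pheno binary phenotype (0/1), one per sample; both classes required.
#' @param covariates optional data.frame of per-sample covariates; factors and
#'   characters are one-hot encoded dropping the first level.
#' @param fdr DMCT significance threshold (default 0.05).
#' @return object of class `dmct_result`: list with matrices (sites x K)
#'   `baseline` (mu), `interaction` (beta^(I)), `t`, `p`, `fdr`, `dmct`
#'   (-1 hypo / 0 / +1 hyper), plus `covariate_coef`, `df`, `cell_types`.
#' @export
call_dmcts <- function(beta, fractions, pheno, covariates = NULL, fdr = 0.05) {
  stopifnot(is.matrix(beta), is.matrix(fractions))
  n <- ncol(beta)
  if (nrow(fractions) != n || length(pheno) != n)
    stop("beta columns, fraction rows and phenotype entries must align")
  if (!all(pheno %in% c(0, 1))) stop("phenotype must be binary 0/1")
  if (length(unique(pheno)) < 2L) stop("phenotype is constant; both classes required")
  K <- ncol(fractions)
  types <- colnames(fractions)
  if (is.null(types)) types <- paste0("CT", seq_len(K))

  low_var <- apply(fractions, 2L, var) < 1e-8
  if (any(low_var))
    warning("cell type(s) with near-zero fraction variance (collinear): ",
            paste(types[low_var], collapse = ", "))

  C <- NULL
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates), nrow(covariates) == n)
    C <- stats::model.matrix(~ ., data = covariates)[, -1L, drop = FALSE]
  }
  X <- cbind(fractions, fractions * pheno, C)
  colnames(X) <- c(types, paste0(types, ":pheno"), colnames(C))
  p_terms <- ncol(X)
  if (n <= p_terms)
    stop(sprintf("need more samples (%d) than model terms (%d)", n, p_terms))

  qx <- qr(X)
  if (qx$rank < p_terms)
    warning("design matrix is rank deficient; some coefficients are aliased")
  coefs <- qr.coef(qx, t(beta))                    # p_terms x sites
  coefs[is.na(coefs)] <- 0
  resid <- t(beta) - X %*% coefs
  df <- n - qx$rank
  sigma2 <- colSums(resid^2) / df
  xtx_inv_diag <- diag(chol2inv(qr.R(qx)[seq_len(qx$rank), seq_len(qx$rank)]))
  # map back through pivoting
  var_scale <- rep(NA_real_, p_terms)
  var_scale[qx$pivot[seq_len(qx$rank)]] <- xtx_inv_diag
  se <- sqrt(outer(var_scale, sigma2))             # p_terms x sites
  tmat <- coefs / se
  pmat <- 2 * pt(-abs(tmat), df = df)

  i_idx <- K + seq_len(K)
  interaction <- t(coefs[i_idx, , drop = FALSE])
  t_int <- t(tmat[i_idx, , drop = FALSE])
  p_int <- t(pmat[i_idx, , drop = FALSE])
  fdr_int <- apply(p_int, 2L, p.adjust, method = "BH")
  dimnames(interaction) <- dimnames(t_int) <- dimnames(p_int) <-
    dimnames(fdr_int) <- list(rownames(beta), types)
  dmct <- matrix(0L, nrow(beta), K, dimnames = list(rownames(beta), types))
  dmct[fdr_int < fdr & interaction > 0] <- 1L
  dmct[fdr_int < fdr & interaction < 0] <- -1L

  baseline <- t(coefs[seq_len(K), , drop = FALSE])
  dimnames(baseline) <- list(rownames(beta), types)
  cov_coef <- if (!is.null(C))
    t(coefs[-(seq_len(2L * K)), , drop = FALSE]) else NULL
  if (!is.null(cov_coef)) dimnames(cov_coef) <- list(rownames(beta), colnames(C))

  structure(list(baseline = baseline, interaction = interaction, t = t_int,
                 p = p_int, fdr = fdr_int, dmct = dmct,
                 covariate_coef = cov_coef, df = df, cell_types = types,
                 fdr_threshold = fdr),
            class = "dmct_result")
}

#' @export
print.dmct_result <- function(x, ...) {
  cat(sprintf("dmct_result: %d sites x %d cell types (FDR < %g)\n",
              nrow(x$dmct), length(x$cell_types), x$fdr_threshold))
  counts <- rbind(hyper = colSums(x$dmct == 1L), hypo = colSums(x$dmct == -1L))
  print(counts)
  invisible(x)
}

#' One-tailed Fisher enrichment of a hit set in a locus set
#'
#' Builds the 2x2 table of hit/non-hit by in-locus/not over a declared
#' background universe and tests for overenrichment with the hypergeometric
#' (one-tailed Fisher) tail. The odds ratio is the sample odds ratio ad/bc.
#'
#' @param hits character vector of hit identifiers (subset of `background`).
#' @param loci character vector of locus identifiers (subset of `background`).
#' @param background character vector, the declared universe.
#' @return list with `odds_ratio`, `p_value`, and `table` (2x2 counts).
#' @export
fisher_enrichment <- function(hits, loci, background) {
  background <- unique(background)
  if (length(background) == 0L) stop("background universe is empty")
  hits <- unique(hits); loci <- unique(loci)
  if (!all(hits %in% background)) stop("hits must be a subset of the background")
  if (!all(loci %in% background)) stop("loci must be a subset of the background")
  a <- length(intersect(hits, loci))
  b <- length(hits) - a
  cc <- length(loci) - a
  d <- length(background) - a - b - cc
  or <- if (a == 0) 0 else if (b * cc == 0) Inf else (a * d) / (b * cc)
  p <- phyper(a - 1, m = length(loci), n = length(background) - length(loci),
              k = length(hits), lower.tail = FALSE)
  tab <- matrix(c(a, b, cc, d), 2L, 2L,
                dimnames = list(c("hit", "non-hit"), c("in_locus", "outside")))
  list(odds_ratio = or, p_value = p, table = tab)
}
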