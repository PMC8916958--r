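# Weighted robust partial-correlation (wRPC) deconvolution: weighted Huber
# regression of a bulk promoter-beta profile on reference columns, followed
# by non-negativity and sum-to-one projection.

#' Estimate cell-type fractions in bulk promoter-DNAm profiles
#'
#' For every sample, the bulk marker-beta vector is regressed (no intercept)
#' on the K reference columns: Huber's robust M-estimator when
#' `robust = TRUE`, weighted least squares otherwise, with the per-marker
#' reference weights as observation weights. Negative coefficients are set to
#' zero and the rest rescaled to sum to one; if no coefficient is positive the
#' sample gets an all-zero row and a warning.
#'
#' @param bulk numeric matrix of promoter betas, genes x samples (`NA`
#'   allowed; a missing marker is dropped for that sample only).
#' @param ref a [dnam_reference()] or plain markers x K numeric matrix.
#' @param weights per-marker observation weights; defaults to the reference's
#'   weights (or 1).
#' @param robust use the Huber M-estimator (default TRUE).
#' @param huber_k Huber tuning constant (default 1.345, the standard
#'   95%-efficiency choice).
#' @param min_overlap minimum share of reference markers that must be present
#'   in `bulk` (default 0.3).
#' @param maxit maximum IRLS iterations (default 50).
#' @return numeric matrix, samples x K, rows non-negative summing to 1
#'   (all-zero rows only in the documented degenerate case).
#' @export
estimate_fractions <- function(bulk, ref, weights = NULL, robust = TRUE,
                               huber_k = 1.345, min_overlap = 0.3,
                               maxit = 50L) {
  if (inherits(ref, "dnam_reference")) {
    if (is.null(weights)) weights <- ref$weights
    R_full <- ref$values
  } else {
    R_full <- as.matrix(ref)
  }
  if (is.null(weights))
    weights <- stats::setNames(rep(1, nrow(R_full)), rownames(R_full))
  if (is.null(names(weights))) names(weights) <- rownames(R_full)

  # collinear reference columns make the regression unidentifiable
  dup <- which(duplicated(t(R_full)))
  if (length(dup) > 0L) {
    first <- which(duplicated(t(R_full), fromLast = TRUE))[1L]
    stop("reference columns are collinear (identical): ",
         paste(colnames(R_full)[c(first, dup[1L])], collapse = ", "))
  }

  shared <- intersect(rownames(R_full), rownames(bulk))
  if (length(shared) < max(1L, ceiling(min_overlap * nrow(R_full))))
    stop(sprintf("only %d of %d reference markers present in bulk (< %.0f%%)",
                 length(shared), nrow(R_full), 100 * min_overlap))
  R <- R_full[shared, , drop = FALSE]
  w <- weights[shared]
  B <- bulk[shared, , drop = FALSE]

  out <- matrix(0, ncol(B), ncol(R),
                dimnames = list(colnames(B), colnames(R)))
  for (j in seq_len(ncol(B))) {
    y <- B[, j]
    ok <- !is.na(y) & !is.na(w)
    out[j, ] <- wrpc_fit(R[ok, , drop = FALSE], y[ok], weights = w[ok],
                         robust = robust, huber_k = huber_k, maxit = maxit,
                         sample_id = colnames(B)[j])
  }
  out
}

# Single-profile fit + projection. Returns the fraction vector.
wrpc_fit <- function(R, y, weights, robust = TRUE, huber_k = 1.345,
                     maxit = 50L, sample_id = NULL) {
  if (length(y) <= ncol(R)) stop("too few observed markers for the regression")
  ls_fit <- stats::lm.wfit(x = R, y = y, w = weights)
  coefs <- ls_fit$coefficients
  # with (near-)zero residual scale the Huber M-estimate equals least squares
  # and IRLS cannot estimate a scale, so keep the LS solution
  if (robust && median(abs(ls_fit$residuals)) > 1e-10) {
    fit <- suppressWarnings(
      MASS::rlm(x = R, y = y, weights = weights, psi = MASS::psi.huber,
                k = huber_k, maxit = maxit, acc = 1e-8)
    )
    if (!anyNA(fit$coefficients)) coefs <- fit$coefficients
  }
  coefs[is.na(coefs)] <- 0
  coefs[coefs < 0] <- 0
  s <- sum(coefs)
  if (s <= 0) {
    warning("all regression coefficients non-positive",
            if (!is.null(sample_id)) paste0(" for sample ", sample_id) else "",
            "; returning an all-zero fraction row")
    return(stats::setNames(rep(0, ncol(R)), colnames(R)))
  }
  stats::setNames(as.numeric(coefs / s), colnames(R))
}

#' Per-cell-type pseudo-bulk profiles
#'
#' Averages single-cell or single-nucleus profiles over all columns annotated
#' to each cell type, gene-wise over non-missing values. Genes missing in all
#' profiles of a type stay missing in the pseudo-bulk.
#'
#' @param profiles numeric matrix, genes x cells (`NA` allowed).
#' @param labels cell-type label per column.
#' @return numeric matrix, genes x cell types.
#' @export
pseudo_bulk <- function(profiles, labels) {
  stopifnot(is.matrix(profiles), length(labels) == ncol(profiles))
  labels <- droplevels(factor(labels))
  out <- vapply(levels(labels), function(k) {
    v <- rowMeans(profiles[, labels == k, drop = FALSE], na.rm = TRUE)
    v[is.nan(v)] <- NA_real_
    v
  }, numeric(nrow(profiles)))
  rownames(out) <- rownames(profiles)
  out
}

#' Reference-corruption tolerance simulation
#'
#' Quantifies how much error in the DNAm reference matrix the deconvolution
#' tolerates. A block reference (own-type beta `own_beta`, other-type beta
#' `other_beta`) generates noiseless Dirichlet(1,...,1) mixtures; a fraction
#' `q` of reference entries is then replaced by Uniform(0,1) values before
#' fractions are re-estimated with unit weights and the Huber loss. Per cell
#' type, the Pearson correlation between true and estimated fractions across
#' mixtures is recorded. The tolerated corruption rate is the largest grid
#' `q` whose minimum correlation across cell types and replicates stays at or
#' above `min_r`.
#'
#' @param q_grid corruption fractions to scan (default `seq(0, 0.5, 0.05)`).
#' @param n_rep fixed-seed replicates per grid point (default 10).
#' @param n_types,markers_per_type reference geometry (default 6 x 100).
#' @param n_mixtures mixtures per replicate (default 200).
#' @param own_beta,other_beta block reference betas (default 0.1 / 0.9).
#' @param min_r correlation threshold defining tolerance (default 0.8).
#' @param seed base seed; replicate r uses `seed * 1000 + r`.
#' @return list with `tolerated_pct` (100 x largest tolerated q), `min_r`
#'   (matrix: grid x replicate minimum per-type correlation), `q_grid`.
#' @export
corruption_tolerance <- function(q_grid = seq(0, 0.5, by = 0.05), n_rep = 10L,
                                 n_types = 6L, markers_per_type = 100L,
                                 n_mixtures = 200L, own_beta = 0.1,
                                 other_beta = 0.9, min_r = 0.8, seed = 1L) {
  ref <- block_reference(K = n_types, markers_per_type = markers_per_type,
                         own_beta = own_beta, other_beta = other_beta)
  V <- ref$values
  n_entries <- length(V)
  min_r_mat <- matrix(NA_real_, length(q_grid), n_rep,
                      dimnames = list(sprintf("q%.2f", q_grid), NULL))
  for (r in seq_len(n_rep)) {
    set.seed(seed * 1000L + r)
    f_true <- rdirichlet(n_mixtures, rep(1, n_types))
    colnames(f_true) <- colnames(V)
    bulk <- V %*% t(f_true)
    colnames(bulk) <- sprintf("mix%03d", seq_len(n_mixtures))
    for (qi in seq_along(q_grid)) {
      q <- q_grid[qi]
      Vc <- V
      n_corrupt <- round(q * n_entries)
      if (n_corrupt > 0L) {
        idx <- sample.int(n_entries, n_corrupt)
        Vc[idx] <- runif(n_corrupt)
      }
      est <- estimate_fractions(bulk, Vc, weights = NULL, robust = TRUE)
      rs <- vapply(seq_len(n_types),
                   function(k) suppressWarnings(cor(f_true[, k], est[, k])),
                   numeric(1))
      min_r_mat[qi, r] <- min(rs)
    }
  }
  ok <- apply(min_r_mat >= min_r, 1L, all)
  tolerated <- if (any(ok)) max(q_grid[ok]) else NA_real_
  list(tolerated_pct = 100 * tolerated, min_r = min_r_mat, q_grid = q_grid)
}
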