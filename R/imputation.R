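# Promoter-DNAm imputation from an expression reference via matched
# DNAm/expression compendia and a two-state gamma mixture model.

#' Matched DNAm/expression compendium
#'
#' Pairs a promoter-beta matrix and an expression matrix over identical gene
#' and sample index sets. Used to decide which marker genes are "imputable",
#' i.e. show the promoter-DNAm/expression anticorrelation that licenses
#' imputing promoter DNAm from expression.
#'
#' @param expr numeric matrix, genes x samples, non-negative expression.
#' @param beta numeric matrix, genes x samples, promoter betas in `[0,1]`.
#' @return object of class `matched_compendium`.
#' @export
matched_compendium <- function(expr, beta) {
  if (!is.matrix(expr) || !is.matrix(beta)) stop("expr and beta must be matrices")
  if (!identical(dimnames(expr), dimnames(beta)))
    stop("expr and beta must share identical gene and sample index sets")
  if (is.null(rownames(expr))) stop("gene identifiers required")
  if (any(expr < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  beta <- validate_beta_matrix(beta, what = "compendium beta")
  structure(list(expr = expr, beta = beta), class = "matched_compendium")
}

#' Select imputable marker genes
#'
#' A marker is imputable when its promoter DNAm and expression are
#' anticorrelated (Pearson r at most `rho_max`) in \emph{both} matched
#' compendia. Genes absent from a compendium are excluded with a logged
#' reason, not an error.
#'
#' @param markers character vector of marker genes, or an
#'   `expression_reference` (its rownames are used).
#' @param compA,compB [matched_compendium()] objects.
#' @param rho_max correlation ceiling, a negative fraction (default -0.3).
#' @return character vector of imputable genes, with attribute `log`: a
#'   data.frame of excluded genes and reasons.
#' @export
select_imputable <- function(markers, compA, compB, rho_max = -0.3) {
  if (inherits(markers, "expression_reference")) markers <- rownames(markers$values)
  stopifnot(is.character(markers),
            inherits(compA, "matched_compendium"),
            inherits(compB, "matched_compendium"))
  if (rho_max >= 0) stop("rho_max must be negative")
  gene_cor <- function(comp, g) {
    suppressWarnings(cor(comp$expr[g, ], comp$beta[g, ],
                         use = "pairwise.complete.obs"))
  }
  keep <- character(0)
  log <- list()
  for (g in markers) {
    inA <- g %in% rownames(compA$expr)
    inB <- g %in% rownames(compB$expr)
    if (!inA || !inB) {
      log[[g]] <- sprintf("absent from compendium %s",
                          paste(c("A", "B")[!c(inA, inB)], collapse = ","))
      next
    }
    rA <- gene_cor(compA, g)
    rB <- gene_cor(compB, g)
    if (is.na(rA) || is.na(rB)) {
      log[[g]] <- "correlation undefined (constant values)"
    } else if (rA <= rho_max && rB <= rho_max) {
      keep <- c(keep, g)
    } else {
      log[[g]] <- sprintf("anticorrelation too weak (r = %.2f, %.2f)", rA, rB)
    }
  }
  if (length(markers) > 0L && length(keep) == 0L && length(log) == length(markers) &&
      all(grepl("absent", unlist(log))))
    stop("markers overlap neither compendium")
  attr(keep, "log") <- data.frame(gene = names(log),
                                  reason = unlist(unname(log)),
                                  stringsAsFactors = FALSE)
  keep
}

#' Fit a two-state gamma mixture by EM
#'
#' Models strictly positive values (promoter betas; zeros are shifted to a
#' small epsilon) as a mixture of two gamma densities. Initialization splits
#' the data at the median and uses per-half method-of-moments estimates;
#' optional random restarts (seeded) keep the best log-likelihood. Components
#' are ordered by increasing mean, so component 2 is the high-methylation
#' state.
#'
#' @param values numeric, at least 20 strictly positive values (non-positive
#'   values are shifted to `eps`).
#' @param max_iter maximum EM iterations (default 500).
#' @param tol log-likelihood convergence tolerance (default 1e-8).
#' @param seed integer seed for random restarts (default 0).
#' @param restarts number of additional random-assignment restarts (default 0).
#' @param eps shift applied to non-positive values (default 1e-4).
#' @return object of class `gamma_mixture`: list with `pi` (mixing weights,
#'   length 2), `shape`, `rate`, `means`, `loglik`, `trace` (per-iteration
#'   log-likelihood), `responsibilities` (n x 2), `converged`, `n_iter`.
#' @export
fit_gamma_mixture <- function(values, max_iter = 500L, tol = 1e-8, seed = 0L,
                              restarts = 0L, eps = 1e-4) {
  values <- values[!is.na(values)]
  values <- pmax(values, eps)
  if (length(values) < 20L) stop("at least 20 positive values are required")
  if (diff(range(values)) < .Machine$double.eps^0.5)
    stop("degenerate input: all values identical")

  best <- gamma_mix_em(values, z1 = values <= median(values),
                       max_iter = max_iter, tol = tol)
  if (restarts > 0L) {
    for (r in seq_len(restarts)) {
      set.seed(seed + r)
      z1 <- runif(length(values)) < 0.5
      if (all(z1) || !any(z1)) z1[1L] <- !z1[1L]
      fit <- tryCatch(gamma_mix_em(values, z1, max_iter, tol),
                      error = function(e) NULL)
      if (!is.null(fit) && fit$loglik > best$loglik) best <- fit
    }
  }
  best
}

# EM core; z1 is the initial hard assignment of component 1.
gamma_mix_em <- function(x, z1, max_iter, tol) {
  n <- length(x)
  mom <- function(v) {
    m <- mean(v); s2 <- var(v)
    if (!is.finite(s2) || s2 <= 0) s2 <- (m * 0.1)^2 + 1e-8
    shape <- min(m^2 / s2, 1e4)
    c(shape = shape, rate = shape / m)
  }
  p1 <- mom(x[z1]); p2 <- mom(x[!z1])
  shape <- c(p1["shape"], p2["shape"]); rate <- c(p1["rate"], p2["rate"])
  pi_k <- c(mean(z1), 1 - mean(z1))
  pi_k <- pmin(pmax(pi_k, 1e-6), 1 - 1e-6)

  trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  resp <- NULL
  for (it in seq_len(max_iter)) {
    ld <- cbind(log(pi_k[1]) + dgamma(x, shape[1], rate[1], log = TRUE),
                log(pi_k[2]) + dgamma(x, shape[2], rate[2], log = TRUE))
    m <- pmax(ld[, 1], ld[, 2])
    ll <- sum(m + log(exp(ld[, 1] - m) + exp(ld[, 2] - m)))
    resp <- exp(ld - m)
    resp <- resp / rowSums(resp)
    trace <- c(trace, ll)
    if (is.finite(ll_old) && abs(ll - ll_old) < tol) { converged <- TRUE; break }
    ll_old <- ll
    # M-step: weighted gamma MLE per component (Newton on the shape)
    for (k in 1:2) {
      w <- resp[, k]
      sw <- sum(w)
      if (sw < 1e-8) next
      wm <- sum(w * x) / sw
      wml <- sum(w * log(x)) / sw
      s <- log(wm) - wml
      if (s <= 0) s <- 1e-8
      a <- (3 - s + sqrt((s - 3)^2 + 24 * s)) / (12 * s)
      for (j in 1:25) {
        step <- (log(a) - digamma(a) - s) / (1 / a - trigamma(a))
        a_new <- a - step
        if (!is.finite(a_new) || a_new <= 0) a_new <- a / 2
        if (abs(a_new - a) < 1e-10 * a) { a <- a_new; break }
        a <- a_new
      }
      shape[k] <- min(a, 1e6)
      rate[k] <- shape[k] / wm
    }
    pi_k <- pmin(pmax(colSums(resp) / n, 1e-6), 1 - 1e-6)
    pi_k <- pi_k / sum(pi_k)
  }
  means <- shape / rate
  ord <- order(means)
  structure(list(pi = unname(pi_k[ord]), shape = unname(shape[ord]),
                 rate = unname(rate[ord]), means = unname(means[ord]),
                 loglik = trace[length(trace)], trace = trace,
                 responsibilities = resp[, ord, drop = FALSE],
                 converged = converged, n_iter = length(trace)),
            class = "gamma_mixture")
}

#' @export
print.gamma_mixture <- function(x, ...) {
  cat(sprintf(paste0("gamma_mixture: pi = (%.3f, %.3f), means = (%.3f, %.3f), ",
                     "loglik = %.3f (%d iterations%s)\n"),
              x$pi[1], x$pi[2], x$means[1], x$means[2], x$loglik, x$n_iter,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' Cell-type DNAm reference matrix
#'
#' Marker-gene x cell-type matrix of expected promoter beta values, with a
#' per-marker confidence weight in `[0,1]` and (optionally) each marker's
#' target cell type.
#'
#' @param values numeric matrix, markers x cell types, betas in `[0,1]`.
#' @param weights per-marker weights in `[0,1]` (default all 1).
#' @param marker_type optional named character mapping markers to their target
#'   cell type.
#' @return object of class `dnam_reference`.
#' @export
dnam_reference <- function(values, weights = NULL, marker_type = NULL) {
  values <- validate_beta_matrix(values, what = "reference")
  if (is.null(weights)) weights <- stats::setNames(rep(1, nrow(values)), rownames(values))
  if (is.null(names(weights))) names(weights) <- rownames(values)
  weights <- weights[rownames(values)]
  if (any(is.na(weights) | weights < 0 | weights > 1))
    stop("weights must be defined for every marker and lie in [0,1]")
  if (!is.null(marker_type)) marker_type <- marker_type[rownames(values)]
  structure(list(values = values, weights = weights, marker_type = marker_type,
                 cell_types = colnames(values)),
            class = "dnam_reference")
}

#' @export
print.dnam_reference <- function(x, ...) {
  cat(sprintf("dnam_reference: %d markers x %d cell types, mean weight %.2f\n",
              nrow(x$values), ncol(x$values), mean(x$weights)))
  invisible(x)
}

#' Impute a DNAm reference matrix from an expression reference
#'
#' For each imputable marker, entries of cell types where the gene is
#' expressed (positive reference median) are set to promoter beta 0, since
#' high expression implies an unmethylated promoter. For cell types where the
#' gene is unexpressed, the entry is the mean of the high-methylation
#' component of a two-state gamma mixture fitted to the gene's compendium
#' promoter betas, restricted to compendium samples where the gene is
#' unexpressed (lower tertile of its expression), clipped to `[0,1]`.
#'
#' @param expr_ref an `expression_reference`.
#' @param imputable character vector from [select_imputable()].
#' @param compA,compB [matched_compendium()] objects.
#' @param min_samples minimum pooled compendium samples needed for the mixture
#'   fit; markers below it are dropped with a logged reason (default 20).
#' @param min_component minimum mixing weight for the high-methylation
#'   component to count as a genuine second state; below it the betas are
#'   treated as single-state and their mixture mean is imputed (default 0.1).
#' @param seed seed forwarded to [fit_gamma_mixture()] restarts (default 0).
#' @return a [dnam_reference()] whose weights are filled by
#'   [compute_weights()]; attribute `log` records dropped markers and
#'   fallbacks.
#' @export
impute_dnam_reference <- function(expr_ref, imputable, compA, compB,
                                  min_samples = 20L, min_component = 0.1,
                                  seed = 0L) {
  stopifnot(inherits(expr_ref, "expression_reference"))
  genes <- intersect(imputable, rownames(expr_ref$values))
  if (length(genes) == 0L) stop("imputable set is empty")
  comps <- list(compA, compB)
  log <- list()
  rows <- list()
  for (g in genes) {
    betas <- unlist(lapply(comps, function(cmp) {
      if (!g %in% rownames(cmp$expr)) return(numeric(0))
      e <- cmp$expr[g, ]
      cutoff <- quantile(e, 1 / 3, na.rm = TRUE, names = FALSE)
      cmp$beta[g, e <= cutoff]
    }))
    betas <- betas[!is.na(betas)]
    if (length(betas) < min_samples) {
      log[[g]] <- sprintf("only %d compendium samples with the gene unexpressed",
                          length(betas))
      next
    }
    high_mean <- tryCatch({
      fit <- fit_gamma_mixture(betas, seed = seed)
      # a near-zero-weight high component is tail noise, not a second state
      if (fit$pi[2L] >= min_component) fit$means[2L]
      else sum(fit$pi * fit$means)
    }, error = function(e) {
      log[[g]] <<- paste("mixture fit degenerate; fell back to mean:",
                         conditionMessage(e))
      mean(betas)
    })
    expressed <- expr_ref$values[g, ] > 0
    rows[[g]] <- ifelse(expressed, 0, clip01(high_mean))
  }
  if (length(rows) == 0L) stop("no marker survived imputation")
  values <- do.call(rbind, rows)
  colnames(values) <- expr_ref$cell_types
  ref <- dnam_reference(values, marker_type = expr_ref$marker_type[rownames(values)])
  ref$weights <- compute_weights(ref, expr_ref)
  attr(ref, "log") <- if (length(log) > 0L)
    data.frame(gene = names(log), reason = unlist(unname(log)),
               stringsAsFactors = FALSE)
  else data.frame(gene = character(0), reason = character(0))
  ref
}

#' Per-marker confidence weights
#'
#' A marker is informative when its promoter is methylated in the cell types
#' that do not express it: the weight is the mean imputed beta over those cell
#' types, clipped to `[0,1]`. Markers expressed in every type carry weight 1.
#'
#' @param dnam_ref a [dnam_reference()].
#' @param expr_ref the matching `expression_reference`.
#' @return named numeric vector of weights in `[0,1]`.
#' @export
compute_weights <- function(dnam_ref, expr_ref) {
  stopifnot(inherits(dnam_ref, "dnam_reference"),
            inherits(expr_ref, "expression_reference"))
  genes <- rownames(dnam_ref$values)
  if (!all(genes %in% rownames(expr_ref$values)))
    stop("dnam_ref markers must all appear in expr_ref")
  w <- vapply(genes, function(g) {
    unexpr <- expr_ref$values[g, ] == 0
    if (!any(unexpr)) return(1)
    clip01(mean(dnam_ref$values[g, unexpr]))
  }, numeric(1))
  stats::setNames(w, genes)
}
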