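# Synthetic-data generators: every input kind with known ground truth.
# Defaults mirror a brain-like study design: K = 6 cell types, >= 100
# markers, 90% nucleus-level missingness. Every generator is a pure function
# of its configuration and seed.

#' Simulation configuration
#'
#' Bundles the knobs shared by the generators. All counts must be positive,
#' the coverage rate lies in (0, 1], and a seed is mandatory.
#'
#' @param K number of cell types (default 6, brain-like).
#' @param markers_per_type planted markers per type (default 100).
#' @param n_background non-marker background genes (default 500).
#' @param cells_per_type cells per type for scRNA-seq simulation (default 100).
#' @param n_mixtures bulk mixtures (default 200).
#' @param dirichlet_alpha concentration of the mixture fractions (default 1).
#' @param beta_sd additive truncated-Gaussian beta noise sd (default 0.05).
#' @param coverage nucleus-level per-call observation probability
#'   (default 0.1, i.e. 90% missingness).
#' @param nuclei_per_type nuclei per type (default 100).
#' @param cpgs_per_gene TSS200 CpGs per gene promoter (default 10).
#' @param n_sites EWAS sites (default 2000).
#' @param n_samples EWAS samples (default 200).
#' @param effect_size planted interaction effect (default 0.2).
#' @param seed RNG seed (mandatory).
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(K = 6L, markers_per_type = 100L, n_background = 500L,
                       cells_per_type = 100L, n_mixtures = 200L,
                       dirichlet_alpha = 1, beta_sd = 0.05, coverage = 0.1,
                       nuclei_per_type = 100L, cpgs_per_gene = 10L,
                       n_sites = 2000L, n_samples = 200L, effect_size = 0.2,
                       seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  cfg <- list(K = as.integer(K), markers_per_type = as.integer(markers_per_type),
              n_background = as.integer(n_background),
              cells_per_type = as.integer(cells_per_type),
              n_mixtures = as.integer(n_mixtures),
              dirichlet_alpha = dirichlet_alpha, beta_sd = beta_sd,
              coverage = coverage, nuclei_per_type = as.integer(nuclei_per_type),
              cpgs_per_gene = as.integer(cpgs_per_gene),
              n_sites = as.integer(n_sites), n_samples = as.integer(n_samples),
              effect_size = effect_size, seed = as.integer(seed))
  counts <- c(cfg$K, cfg$markers_per_type, cfg$cells_per_type, cfg$n_mixtures,
              cfg$nuclei_per_type, cfg$cpgs_per_gene, cfg$n_sites,
              cfg$n_samples)
  if (any(counts <= 0)) stop("all counts must be positive")
  if (cfg$n_background < 0) stop("n_background must be >= 0")
  if (cfg$coverage <= 0 || cfg$coverage > 1) stop("coverage must lie in (0,1]")
  if (cfg$K < 2L) stop("K must be at least 2")
  structure(cfg, class = "sim_config")
}

sim_types <- function(K) sprintf("CT%d", seq_len(K))

#' Block DNAm reference with planted markers
#'
#' Builds a markers x K reference where each planted marker is hypomethylated
#' in its own type (`own_beta`) and methylated elsewhere (`other_beta`);
#' optional background genes carry a flat `background_beta` in every type.
#'
#' @param K cell types (default 6).
#' @param markers_per_type planted markers per type (default 100).
#' @param own_beta,other_beta marker betas in own/other types
#'   (default 0.1 / 0.9).
#' @param n_background background genes (default 0).
#' @param background_beta flat background beta (default 0.5).
#' @return a [dnam_reference()] with `marker_type` set (background genes get
#'   `NA`).
#' @export
block_reference <- function(K = 6L, markers_per_type = 100L, own_beta = 0.1,
                            other_beta = 0.9, n_background = 0L,
                            background_beta = 0.5) {
  types <- sim_types(K)
  genes <- unlist(lapply(seq_len(K), function(k)
    sprintf("mk%s_%03d", types[k], seq_len(markers_per_type))))
  V <- matrix(other_beta, length(genes), K, dimnames = list(genes, types))
  marker_type <- stats::setNames(rep(types, each = markers_per_type), genes)
  for (k in seq_len(K)) V[marker_type == types[k], k] <- own_beta
  if (n_background > 0L) {
    bg <- sprintf("bg_%04d", seq_len(n_background))
    V <- rbind(V, matrix(background_beta, n_background, K,
                         dimnames = list(bg, types)))
    marker_type <- c(marker_type,
                     stats::setNames(rep(NA_character_, n_background), bg))
  }
  dnam_reference(V, marker_type = marker_type)
}

#' Simulate annotated scRNA-seq counts with planted markers
#'
#' Negative-binomial counts: each planted marker is expressed only in its own
#' type (high mean there, near-zero mean elsewhere so its cross-type median is
#' zero and its true MSS is K - 1); background genes are expressed at a
#' common moderate level in every type.
#'
#' @param cfg a [sim_config()].
#' @return list with `sc` (an [sc_expression()]) and `truth` (data.frame:
#'   `gene`, `cell_type` of the planted markers).
#' @export
simulate_sc_counts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  K <- cfg$K
  types <- sim_types(K)
  n_cells <- K * cfg$cells_per_type
  labels <- factor(rep(types, each = cfg$cells_per_type), levels = types)
  markers <- unlist(lapply(types, function(k)
    sprintf("mk%s_%03d", k, seq_len(cfg$markers_per_type))))
  marker_type <- rep(types, each = cfg$markers_per_type)
  bg <- if (cfg$n_background > 0L) sprintf("bg_%04d", seq_len(cfg$n_background))
        else character(0)
  genes <- c(markers, bg)

  mu <- matrix(0.05, length(genes), K, dimnames = list(genes, types))
  for (k in seq_len(K)) mu[marker_type == types[k], k] <- 5
  if (length(bg) > 0L) mu[bg, ] <- 2

  counts <- matrix(0L, length(genes), n_cells,
                   dimnames = list(genes,
                                   sprintf("cell%04d", seq_len(n_cells))))
  for (k in seq_len(K)) {
    cols <- which(labels == types[k])
    counts[, cols] <- rnbinom(length(genes) * length(cols),
                              mu = mu[, k], size = 1)
  }
  list(sc = sc_expression(counts, labels),
       truth = data.frame(gene = markers, cell_type = marker_type,
                          stringsAsFactors = FALSE))
}

#' Simulate a pair of matched DNAm/expression compendia
#'
#' A planted fraction of genes is anticorrelated: their promoter beta decays
#' logistically with expression, from a per-gene silent-state level (drawn
#' from a high-mean gamma component and shared by both compendia) toward
#' zero, plus truncated Gaussian noise. The remaining genes have expression
#' and beta drawn independently.
#'
#' @param cfg a [sim_config()].
#' @param genes character vector of gene names to simulate.
#' @param frac_anticorrelated fraction of anticorrelated genes (default 0.2).
#' @param n_samples samples per compendium (default 60).
#' @param silent_mean,silent_sd gamma component for per-gene silent-state
#'   betas (default mean 0.8, sd 0.05).
#' @return list with `compA`, `compB` ([matched_compendium()] objects) and
#'   `truth` (data.frame: `gene`, `anticorrelated`, `silent_beta`).
#' @export
simulate_compendium <- function(cfg, genes, frac_anticorrelated = 0.2,
                                n_samples = 60L, silent_mean = 0.8,
                                silent_sd = 0.05) {
  stopifnot(inherits(cfg, "sim_config"), is.character(genes))
  set.seed(cfg$seed + 1L)
  n_anti <- round(frac_anticorrelated * length(genes))
  anti <- rep(FALSE, length(genes))
  if (n_anti > 0L) anti[sample.int(length(genes), n_anti)] <- TRUE
  shape <- (silent_mean / silent_sd)^2
  silent_beta <- ifelse(anti,
                        clip01(rgamma(length(genes), shape = shape,
                                      rate = shape / silent_mean)),
                        NA_real_)

  one_compendium <- function(tag) {
    samples <- sprintf("%s_s%02d", tag, seq_len(n_samples))
    expr <- matrix(0, length(genes), n_samples,
                   dimnames = list(genes, samples))
    beta <- matrix(0, length(genes), n_samples,
                   dimnames = list(genes, samples))
    for (i in seq_along(genes)) {
      if (anti[i]) {
        silent <- runif(n_samples) < 0.5
        e <- ifelse(silent, 0, rlnorm(n_samples, meanlog = 2, sdlog = 0.5))
        b <- silent_beta[i] * (1 - stats::plogis(e, location = 2, scale = 0.6))
      } else {
        e <- rlnorm(n_samples, meanlog = 1, sdlog = 0.8)
        b <- rep(runif(1, 0.3, 0.7), n_samples)
      }
      expr[i, ] <- e
      beta[i, ] <- clip01(b + rnorm(n_samples, sd = cfg$beta_sd))
    }
    matched_compendium(expr, beta)
  }
  list(compA = one_compendium("A"), compB = one_compendium("B"),
       truth = data.frame(gene = genes, anticorrelated = anti,
                          silent_beta = silent_beta,
                          stringsAsFactors = FALSE))
}

#' Simulate bulk mixtures from a DNAm reference
#'
#' Mixture profiles are the reference columns mixed with Dirichlet(alpha)
#' fractions, plus truncated Gaussian beta noise, clipped to `[0,1]`.
#'
#' @param ref a [dnam_reference()] or genes x K matrix.
#' @param cfg a [sim_config()] (uses `n_mixtures`, `dirichlet_alpha`,
#'   `beta_sd`, `seed`).
#' @param noise_sd overrides `cfg$beta_sd` when given.
#' @return list with `bulk` (genes x mixtures beta matrix) and `fractions`
#'   (mixtures x K true fractions; rows sum to 1 exactly).
#' @export
simulate_bulk_mixtures <- function(ref, cfg, noise_sd = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  V <- if (inherits(ref, "dnam_reference")) ref$values else as.matrix(ref)
  if (is.null(noise_sd)) noise_sd <- cfg$beta_sd
  set.seed(cfg$seed + 2L)
  f <- rdirichlet(cfg$n_mixtures, rep(cfg$dirichlet_alpha, ncol(V)))
  dimnames(f) <- list(sprintf("mix%03d", seq_len(cfg$n_mixtures)), colnames(V))
  bulk <- V %*% t(f)
  if (noise_sd > 0)
    bulk <- bulk + matrix(rnorm(length(bulk), sd = noise_sd), nrow(bulk))
  bulk <- clip01(bulk)
  colnames(bulk) <- rownames(f)
  list(bulk = bulk, fractions = f)
}

#' Simulate a sparse single-nucleus methylome
#'
#' Each gene promoter carries `cpgs_per_gene` CpGs. For a nucleus of type k,
#' every CpG of gene g gets a Bernoulli call with success probability equal
#' to the reference beta of (g, k); each call is observed with probability
#' `coverage` (default 0.1, i.e. 90% missingness).
#'
#' @param ref a [dnam_reference()] or genes x K matrix.
#' @param cfg a [sim_config()] (uses `nuclei_per_type`, `cpgs_per_gene`,
#'   `coverage`, `seed`).
#' @return list with `calls` (long data.frame: `site_id`, `nucleus_id`,
#'   `call`, covered entries only), `cpg_map` (data.frame: `site_id`,
#'   `gene`), `labels` (named character per nucleus).
#' @export
simulate_snm <- function(ref, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  V <- if (inherits(ref, "dnam_reference")) ref$values else as.matrix(ref)
  set.seed(cfg$seed + 3L)
  K <- ncol(V)
  types <- colnames(V)
  genes <- rownames(V)
  n_nuc <- K * cfg$nuclei_per_type
  nuclei <- sprintf("nuc%04d", seq_len(n_nuc))
  labels <- stats::setNames(rep(types, each = cfg$nuclei_per_type), nuclei)
  cpg_map <- data.frame(
    site_id = sprintf("%s_cpg%02d", rep(genes, each = cfg$cpgs_per_gene),
                      rep(seq_len(cfg$cpgs_per_gene), length(genes))),
    gene = rep(genes, each = cfg$cpgs_per_gene),
    stringsAsFactors = FALSE)

  n_cpg <- nrow(cpg_map)
  out <- vector("list", n_nuc)
  gene_idx <- match(cpg_map$gene, genes)
  for (j in seq_len(n_nuc)) {
    p <- V[gene_idx, labels[j]]
    covered <- which(runif(n_cpg) < cfg$coverage)
    if (length(covered) == 0L) next
    out[[j]] <- data.frame(site_id = cpg_map$site_id[covered],
                           nucleus_id = nuclei[j],
                           call = rbinom(length(covered), 1L, p[covered]),
                           stringsAsFactors = FALSE)
  }
  calls <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  rownames(calls) <- NULL
  list(calls = calls, cpg_map = cpg_map, labels = labels)
}

#' Simulate an EWAS dataset from the interaction generative model
#'
#' Betas follow the cell-type interaction model: per site, baseline per-type
#' levels mixed by the sample fractions, planted fraction-by-phenotype
#' interaction effects at chosen sites, a small age effect, and i.i.d.
#' Gaussian noise, clipped to `[0,1]`.
#'
#' @param cfg a [sim_config()] (uses `n_sites`, `n_samples`, `K`,
#'   `dirichlet_alpha`, `beta_sd`, `effect_size`, `seed`).
#' @param n_dmct number of planted interaction sites (default 50; 0 gives a
#'   null simulation with an empty truth table).
#' @param effect_size planted interaction coefficient (default
#'   `cfg$effect_size`).
#' @param dmct_types cell type(s) carrying the planted effects; `NULL`
#'   (default) assigns each planted site a random type, a single type name
#'   concentrates all effects there (the typical disease pattern, where one
#'   cell type dominates the differential signal).
#' @return list with `beta` (sites x samples), `fractions` (samples x K),
#'   `pheno` (0/1), `covariates` (data.frame with `age`), `truth`
#'   (data.frame: `site`, `cell_type`, `effect`).
#' @export
simulate_ewas <- function(cfg, n_dmct = 50L, effect_size = NULL,
                          dmct_types = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (is.null(effect_size)) effect_size <- cfg$effect_size
  if (n_dmct > cfg$n_sites)
    stop("n_dmct cannot exceed the number of sites")
  set.seed(cfg$seed + 4L)
  n <- cfg$n_samples
  K <- cfg$K
  types <- sim_types(K)
  sites <- sprintf("cg%05d", seq_len(cfg$n_sites))
  f <- rdirichlet(n, rep(cfg$dirichlet_alpha, K))
  dimnames(f) <- list(sprintf("s%03d", seq_len(n)), types)
  pheno <- rep(c(0, 1), length.out = n)
  age <- rnorm(n, 50, 10)

  Mu <- matrix(runif(cfg$n_sites * K, 0.2, 0.8), cfg$n_sites, K,
               dimnames = list(sites, types))
  BI <- matrix(0, cfg$n_sites, K, dimnames = list(sites, types))
  truth <- data.frame(site = character(0), cell_type = character(0),
                      effect = numeric(0), stringsAsFactors = FALSE)
  if (n_dmct > 0L) {
    planted_sites <- sample(sites, n_dmct)
    planted_types <- if (is.null(dmct_types)) sample(types, n_dmct, replace = TRUE)
                     else rep_len(match.arg(dmct_types, types, several.ok = TRUE),
                                  n_dmct)
    BI[cbind(planted_sites, planted_types)] <- effect_size
    # keep planted effects expressible: baselines low enough that adding the
    # effect never clips at 1 (clipping would silently attenuate the signal)
    Mu[planted_sites, ] <- runif(n_dmct * K, 0.2,
                                 max(0.25, min(0.8, 1 - abs(effect_size) - 0.02)))
    truth <- data.frame(site = planted_sites, cell_type = planted_types,
                        effect = effect_size, stringsAsFactors = FALSE)
  }
  gamma_age <- runif(cfg$n_sites, -1e-3, 1e-3)
  B <- Mu %*% t(f) + BI %*% t(f * pheno) +
    outer(gamma_age, age - mean(age)) +
    matrix(rnorm(cfg$n_sites * n, sd = cfg$beta_sd), cfg$n_sites, n)
  B <- clip01(B)
  dimnames(B) <- list(sites, rownames(f))
  list(beta = B, fractions = f, pheno = pheno,
       covariates = data.frame(age = age, row.names = rownames(f)),
       truth = truth)
}
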