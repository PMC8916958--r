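# Probe-level beta matrices -> gene-promoter beta matrices.

REGION_GROUPS <- c("TSS200", "FirstExon", "Other")

#' Summarize probe-level DNAm to gene-promoter level
#'
#' Assigns each gene a promoter beta value per sample as the mean beta over its
#' TSS200 probes (CpGs within 200 bp upstream of the transcription start
#' site). Genes with no TSS200 probe carrying data fall back to the mean over
#' first-exon probes; genes with neither are omitted. Missing probe values are
#' excluded from the means, never treated as zero.
#'
#' @param probes numeric matrix of beta values in `[0,1]`, probes as rows
#'   (unique rownames), samples as columns (unique colnames); `NA` allowed.
#' @param manifest data.frame with columns `probe_id`, `gene`, `region_group`
#'   (values `TSS200`, `FirstExon`, `Other`); one row per (probe, gene) pair.
#'   A probe may map to several genes; see [read_manifest()] for parsing
#'   Illumina-style multi-valued annotation columns.
#' @return numeric matrix, genes x samples, betas in `[0,1]` (`NA` where a
#'   gene has no covered probe in a sample), with attribute `provenance`: a
#'   named character vector giving the region class used per gene.
#' @examples
#' probes <- rbind(p1 = c(s1 = 0.2), p2 = c(s1 = 0.4), p3 = c(s1 = 0.6))
#' man <- data.frame(probe_id = c("p1", "p2", "p3"),
#'                   gene = c("G", "G", "H"),
#'                   region_group = c("TSS200", "TSS200", "FirstExon"))
#' summarize_promoter_dnam(probes, man)
#' @export
summarize_promoter_dnam <- function(probes, manifest) {
  probes <- validate_beta_matrix(probes, what = "probes")
  manifest <- validate_manifest(manifest)

  # all-missing probe rows behave as absent probes
  has_data <- rowSums(!is.na(probes)) > 0L
  probes <- probes[has_data, , drop = FALSE]

  manifest <- manifest[manifest$probe_id %in% rownames(probes), , drop = FALSE]
  # TSS200 beats FirstExon when a probe maps to a gene under both
  manifest <- manifest[order(match(manifest$region_group, REGION_GROUPS)), ]
  manifest <- manifest[!duplicated(manifest[, c("probe_id", "gene")]), ]

  aggregate_region <- function(region) {
    m <- manifest[manifest$region_group == region, , drop = FALSE]
    if (nrow(m) == 0L) return(NULL)
    idx <- split(match(m$probe_id, rownames(probes)), m$gene)
    vals <- do.call(rbind, lapply(idx, function(i) {
      block <- probes[i, , drop = FALSE]
      v <- colMeans(block, na.rm = TRUE)
      v[is.nan(v)] <- NA_real_
      v
    }))
    rownames(vals) <- names(idx)
    vals[rowSums(!is.na(vals)) > 0L, , drop = FALSE]
  }

  tss <- aggregate_region("TSS200")
  fex <- aggregate_region("FirstExon")
  fex <- fex[setdiff(rownames(fex), rownames(tss)), , drop = FALSE]

  out <- rbind(tss, fex)
  if (is.null(out) || nrow(out) == 0L) {
    out <- matrix(numeric(0), 0L, ncol(probes),
                  dimnames = list(NULL, colnames(probes)))
    attr(out, "provenance") <- character(0)
    return(out)
  }
  out <- out[order(rownames(out)), , drop = FALSE]
  prov <- ifelse(rownames(out) %in% rownames(tss), "TSS200", "FirstExon")
  names(prov) <- rownames(out)
  attr(out, "provenance") <- prov
  out
}

validate_beta_matrix <- function(x, what = "beta matrix") {
  if (!is.matrix(x) || !is.numeric(x))
    stop(what, " must be a numeric matrix")
  if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
    stop(what, ": row identifiers must be present and unique")
  if (is.null(colnames(x)) || anyDuplicated(colnames(x)))
    stop(what, ": sample identifiers must be present and unique")
  if (ncol(x) < 1L) stop(what, ": at least one sample required")
  bad <- which(!is.na(x) & (x < 0 | x > 1), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("%s: value %.4g out of [0,1] at row '%s', column '%s'",
                 what, x[bad[1L, 1L], bad[1L, 2L]],
                 rownames(x)[bad[1L, 1L]], colnames(x)[bad[1L, 2L]]))
  x
}

validate_manifest <- function(manifest) {
  req <- c("probe_id", "gene", "region_group")
  if (!is.data.frame(manifest) || !all(req %in% names(manifest)))
    stop("manifest must be a data.frame with columns probe_id, gene, region_group")
  if (nrow(manifest) == 0L) stop("manifest is empty")
  bad <- setdiff(unique(manifest$region_group), REGION_GROUPS)
  if (length(bad) > 0L)
    stop("unknown region_group value(s): ", paste(bad, collapse = ", "))
  dup <- manifest[, c("probe_id", "gene")]
  if (anyDuplicated(dup)) {
    # duplicates allowed only when they disagree on region_group (resolved by
    # the TSS200-wins rule); identical triples are collapsed silently
    manifest <- unique(manifest[, req])
  }
  manifest
}
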