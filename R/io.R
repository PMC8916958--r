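# Readers and writers for the tabular formats: TSV matrices (gzip accepted),
# MTX triplets for sparse expression, manifests, labels, groupings.

read_tsv_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   row.names = NULL, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate row identifier(s) in ", path, ": ",
         paste(utils::head(unique(ids[duplicated(ids)]), 3L), collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read a beta-value matrix from TSV
#'
#' Rows are probes or genes, the header row holds sample IDs; values must lie
#' in `[0,1]` (`NA` allowed). Gzip-compressed files are accepted.
#'
#' @param path TSV path.
#' @return validated numeric matrix.
#' @export
read_beta_matrix <- function(path) {
  validate_beta_matrix(read_tsv_matrix(path), what = basename(path))
}

#' Read an expression matrix (dense TSV or MTX triplet)
#'
#' @param path dense TSV path, or an MTX file (MatrixMarket triplet) when
#'   `genes` and `cells` index files are supplied.
#' @param genes,cells one-column TSV paths with row/column identifiers
#'   (required for MTX input).
#' @return numeric matrix, genes x cells.
#' @export
read_expression_matrix <- function(path, genes = NULL, cells = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.mtx(\\.gz)?$", path)) {
    if (is.null(genes) || is.null(cells))
      stop("MTX input requires genes and cells index files")
    m <- as.matrix(Matrix::readMM(path))
    rownames(m) <- readLines(genes)
    colnames(m) <- readLines(cells)
    return(m)
  }
  m <- read_tsv_matrix(path)
  if (any(m < 0, na.rm = TRUE)) stop("expression values must be >= 0")
  m
}

#' Write a numeric matrix as TSV
#'
#' Row identifiers go in the first column (header `id`); values keep full
#' double precision so a write-then-read round trip is exact at 10
#' significant digits.
#'
#' @param mat numeric matrix with dimnames.
#' @param path output TSV path.
#' @export
write_tsv_matrix <- function(mat, path) {
  df <- data.frame(id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a probe manifest
#'
#' Accepts a plain manifest (columns `probe_id`, `gene`, `region_group`) or
#' an Illumina-style annotation with multi-valued, semicolon-separated gene
#' and region-group columns (e.g. `UCSC_RefGene_Name = "A;B"`,
#' `UCSC_RefGene_Group = "TSS200;Body"`), which is exploded to one row per
#' (probe, gene, group). Region groups `TSS200` and `1stExon` map to
#' `TSS200` / `FirstExon`; everything else becomes `Other`. When a probe maps
#' to one gene under several groups, `TSS200` wins, then `FirstExon`.
#'
#' @param path TSV path.
#' @return data.frame with columns `probe_id`, `gene`, `region_group`.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  plain <- all(c("probe_id", "gene", "region_group") %in% names(df))
  if (!plain) {
    probe_col <- intersect(c("probe_id", "IlmnID", "Name"), names(df))[1L]
    gene_col <- grep("RefGene_Name|^gene", names(df), value = TRUE)[1L]
    group_col <- grep("RefGene_Group|^region", names(df), value = TRUE)[1L]
    if (is.na(probe_col) || is.na(gene_col) || is.na(group_col))
      stop("cannot identify probe/gene/region columns in ", path)
    rows <- lapply(seq_len(nrow(df)), function(i) {
      g <- strsplit(df[[gene_col]][i], ";", fixed = TRUE)[[1L]]
      r <- strsplit(df[[group_col]][i], ";", fixed = TRUE)[[1L]]
      if (length(g) == 0L) return(NULL)
      n <- max(length(g), length(r))
      data.frame(probe_id = df[[probe_col]][i],
                 gene = rep_len(g, n), region_group = rep_len(r, n),
                 stringsAsFactors = FALSE)
    })
    df <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  }
  df <- df[, c("probe_id", "gene", "region_group")]
  df$region_group <- ifelse(df$region_group == "TSS200", "TSS200",
                            ifelse(df$region_group %in% c("1stExon", "FirstExon"),
                                   "FirstExon", "Other"))
  # multi-valued columns can repeat a (probe, gene) pair: TSS200 wins
  df <- df[order(match(df$region_group, REGION_GROUPS)), ]
  df <- df[!duplicated(df[, c("probe_id", "gene")]), ]
  rownames(df) <- NULL
  df
}

#' Read a two-column label table
#'
#' @param path TSV with columns (id, label); a header row is accepted.
#' @return named character vector of labels.
#' @export
read_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Read a cell-type grouping configuration
#'
#' YAML mapping of group name to a list of cell types, e.g.
#' `stromal: [Fib, EC, Immune]`.
#'
#' @param path YAML path.
#' @return named list of character vectors.
#' @export
read_grouping <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  g <- yaml::read_yaml(path)
  lapply(g, as.character)
}

#' Write / read a DNAm reference (values + sidecars)
#'
#' `write_dnam_reference` emits `<prefix>.tsv` (markers x cell types),
#' `<prefix>_weights.tsv` (marker, weight) and, when marker types are known,
#' `<prefix>_types.tsv`. `read_dnam_reference` reassembles the object.
#'
#' @param ref a [dnam_reference()].
#' @param prefix output path prefix.
#' @return the prefix (write) or a `dnam_reference` (read).
#' @export
write_dnam_reference <- function(ref, prefix) {
  stopifnot(inherits(ref, "dnam_reference"))
  write_tsv_matrix(ref$values, paste0(prefix, ".tsv"))
  write.table(data.frame(marker = names(ref$weights), weight = ref$weights),
              paste0(prefix, "_weights.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(ref$marker_type))
    write.table(data.frame(marker = names(ref$marker_type),
                           cell_type = ref$marker_type),
                paste0(prefix, "_types.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
  invisible(prefix)
}

#' @rdname write_dnam_reference
#' @export
read_dnam_reference <- function(prefix) {
  values <- read_beta_matrix(paste0(prefix, ".tsv"))
  wpath <- paste0(prefix, "_weights.tsv")
  weights <- if (file.exists(wpath)) {
    w <- read.delim(wpath, stringsAsFactors = FALSE)
    stats::setNames(w$weight, w$marker)
  } else NULL
  tpath <- paste0(prefix, "_types.tsv")
  marker_type <- if (file.exists(tpath)) {
    tt <- read.delim(tpath, stringsAsFactors = FALSE)
    stats::setNames(tt$cell_type, tt$marker)
  } else NULL
  dnam_reference(values, weights = weights, marker_type = marker_type)
}

#' Read long-format single-nucleus methylation calls
#'
#' @param path TSV with columns `site_id`, `nucleus_id`, `call`.
#' @return data.frame of covered calls.
#' @export
read_snm_calls <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("site_id", "nucleus_id", "call") %in% names(df)))
    stop("calls file needs columns site_id, nucleus_id, call")
  df
}
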