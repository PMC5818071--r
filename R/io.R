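#' Read a tab-delimited expression matrix
#'
#' Expects gene identifiers in the first column and one column per sample
#' with sample ids in the header row.
#'
#' @param path Path to a TSV file.
#' @return Numeric matrix, genes x samples, with dimnames.
#' @export
read_expression <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("expression file must have a gene-id column plus >=1 sample",
         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate gene ids in ", path, call. = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Write an expression matrix as TSV
#'
#' @param expr Genes x samples numeric matrix with dimnames.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr), expr,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(df, path)
  invisible(path)
}

#' Read a sample-metadata table
#'
#' Requires at least the columns `sample_id`, `group` and `timepoint`.
#'
#' @param path Path to a TSV file.
#' @return data.frame of sample metadata.
#' @export
read_samples <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("sample_id", "group", "timepoint")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("sample table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (anyNA(df$group) || anyNA(df$timepoint))
    stop("sample table has missing group/timepoint values", call. = FALSE)
  df
}

#' Read a planted-truth table written by [write_fixture()]
#'
#' @param path Path to a TSV file.
#' @return Truth list with `module_of_gene`, `perturbation_of_module`,
#'   `de_gene_ids` and `de_direction` (see [generate_dataset()]).
#' @export
read_truth <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  pert <- df[df$module != "background", c("module", "perturbation")]
  pert <- pert[!duplicated(pert$module), ]
  de <- df[df$de, , drop = FALSE]
  list(
    module_of_gene = setNames(df$module, df$gene_id),
    perturbation_of_module = setNames(pert$perturbation, pert$module),
    de_gene_ids = de$gene_id,
    de_direction = setNames(de$de_direction, de$gene_id)
  )
}

#' Read a two-column probe-to-gene mapping table
#'
#' @param path Path to a TSV file whose first two columns are probe id and
#'   gene id (header row required).
#' @return Named character vector: probe id -> gene id.
#' @export
read_probe_map <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2)
    stop("probe map needs two columns (probe, gene)", call. = FALSE)
  setNames(as.character(df[[2]]), as.character(df[[1]]))
}

# Plain TSV writer shared by all outputs: no quoting, no row names.
write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
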