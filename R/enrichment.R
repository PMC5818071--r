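# Over-representation analysis against GMT gene-set collections.

#' Read a GMT gene-set file
#'
#' Standard tab-separated GMT: one set per line as
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate members
#' within a set are dropped.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (the sets) with attribute
#'   `description` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0)
    stop("empty GMT file: ", path, call. = FALSE)
  sets <- vector("list", length(lines))
  desc <- character(length(lines))
  nm <- character(length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3)
      stop("malformed GMT line ", i, ": need name, description, >=1 gene",
           call. = FALSE)
    nm[i] <- fields[1]
    desc[i] <- fields[2]
    sets[[i]] <- unique(fields[-(1:2)])
  }
  if (anyDuplicated(nm))
    stop("duplicate set names in ", path, call. = FALSE)
  names(sets) <- nm
  structure(sets, description = setNames(desc, nm))
}

#' Write a gene-set collection as GMT
#'
#' @param sets Named list of character vectors (optionally with a
#'   `description` attribute as produced by [read_gmt()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description")
  if (is.null(desc)) desc <- setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation analysis
#'
#' Upper-tail hypergeometric p-value for the overlap between a query gene
#' list and each gene set. A set is significant when p <= `p_cutoff`
#' (default 0.05) AND the overlap contains at least `min_overlap` genes
#' (default 3). No multiple-testing correction is applied; raw p-values
#' plus the overlap filter define the reporting rule.
#'
#' @param query Character vector of gene ids.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param universe Background gene ids; default is the union of all set
#'   members. Query genes outside the universe are dropped with a
#'   message.
#' @param p_cutoff Significance cutoff on the raw p-value.
#' @param min_overlap Minimum overlap size for significance.
#' @return data.frame sorted by p-value: set, set_size, overlap, p_value,
#'   significant, overlap_genes (comma-separated). Empty query returns a
#'   zero-row frame.
#' @export
overrepresentation <- function(query, sets, universe = NULL,
                               p_cutoff = 0.05, min_overlap = 3) {
  if (is.null(universe)) universe <- unique(unlist(sets))
  universe <- unique(universe)
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    message(length(outside), " query gene(s) outside the universe dropped")
    query <- intersect(query, universe)
  }
  empty <- data.frame(set = character(0), set_size = integer(0),
                      overlap = integer(0), p_value = numeric(0),
                      significant = logical(0),
                      overlap_genes = character(0),
                      stringsAsFactors = FALSE)
  if (length(query) == 0) return(empty)

  N <- length(universe)
  n_query <- length(query)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    K <- length(members)
    hits <- intersect(query, members)
    k <- length(hits)
    p <- phyper(k - 1, K, N - K, n_query, lower.tail = FALSE)
    data.frame(set = nm, set_size = K, overlap = k, p_value = p,
               significant = (p <= p_cutoff) && (k >= min_overlap),
               overlap_genes = paste(sort(hits), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$p_value, out$set), ]
  rownames(out) <- NULL
  out
}

#' Gene counts and percentages per function group
#'
#' Groups significant enrichment results into broader function
#' categories, counts the union of overlap genes per group, and reports
#' percentages over all counted genes (a gene contributing to several
#' groups is counted once per group).
#'
#' @param results Enrichment table from [overrepresentation()].
#' @param grouping Named character vector mapping set name -> function
#'   group; sets without a group are ignored.
#' @return data.frame with function_group, n_genes, percentage, sorted by
#'   decreasing count.
#' @export
function_gene_counts <- function(results, grouping) {
  sig <- results[results$significant, , drop = FALSE]
  if (nrow(sig) == 0)
    stop("no significant enrichment results to summarize", call. = FALSE)
  sig <- sig[sig$set %in% names(grouping), , drop = FALSE]
  groups <- split(sig, grouping[sig$set])
  counts <- vapply(groups, function(g)
    length(unique(unlist(strsplit(g$overlap_genes, ",", fixed = TRUE)))),
    integer(1))
  out <- data.frame(function_group = names(counts),
                    n_genes = unname(counts),
                    percentage = unname(100 * counts / sum(counts)),
                    stringsAsFactors = FALSE)
  out[order(-out$n_genes, out$function_group), , drop = FALSE]
}
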