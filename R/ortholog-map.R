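# Ortholog table handling and cross-species projection of gene sets.

#' Read a two-column ortholog table
#'
#' Reads a tab-separated file whose first two columns are source (e.g. human)
#' and target (e.g. worm) gene identifiers, tags every pair with a source
#' database label, and collapses duplicated rows. One-to-many mappings (one
#' source gene, several targets) are preserved as separate pairs.
#'
#' @param path path to a TSV file with at least two columns; a header row is
#'   detected when the first line matches common column names.
#' @param source_label label recorded as the evidence source for every pair.
#' @return data frame with columns `source_gene`, `target_gene`, `evidence`.
#' @export
read_ortholog_table <- function(path, source_label) {
  if (!file.exists(path)) stop2("cannot read ortholog table: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop2("empty ortholog table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(vapply(fields, length, integer(1)) < 2L))
    stop2("ortholog table rows must have at least 2 columns: ", path)
  start <- if (grepl("source|human|gene", fields[[1L]][1L],
                     ignore.case = TRUE)) 2L else 1L
  if (start > length(fields)) stop2("empty ortholog table: ", path)
  src <- vapply(fields[start:length(fields)], `[`, character(1), 1L)
  tgt <- vapply(fields[start:length(fields)], `[`, character(1), 2L)
  out <- unique(data.frame(source_gene = src, target_gene = tgt,
                           stringsAsFactors = FALSE))
  out$evidence <- source_label
  out
}

#' Merge ortholog tables from several sources
#'
#' Unions pairs across tables; a pair present in several sources keeps one
#' row whose `evidence` field is the comma-joined sorted union of the source
#' labels. Merging is idempotent.
#'
#' @param tables list of ortholog pair data frames (from
#'   [read_ortholog_table()] or previous merges).
#' @return merged pair data frame sorted by source then target gene.
#' @export
merge_ortholog_tables <- function(tables) {
  if (!is.list(tables) || length(tables) == 0L)
    stop2("need at least one ortholog table")
  all <- do.call(rbind, lapply(tables, function(t)
    t[, c("source_gene", "target_gene", "evidence")]))
  key <- paste(all$source_gene, all$target_gene, sep = "\r")
  ev <- tapply(all$evidence, key, function(e)
    paste(sort(unique(unlist(strsplit(e, ",", fixed = TRUE)))),
          collapse = ","))
  first <- !duplicated(key)
  out <- all[first, , drop = FALSE]
  out$evidence <- as.character(ev[key[first]])
  out <- out[order(out$source_gene, out$target_gene), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Project a gene set through an ortholog table
#'
#' Expands every query gene to all of its targets (no best-hit collapsing:
#' one human gene may legitimately map to several worm genes) and reports the
#' mapping bookkeeping.
#'
#' @param query character vector of source-species genes.
#' @param table merged ortholog pair data frame.
#' @param min_sources optional minimum number of evidence sources a pair must
#'   carry to be used (default 1: no filter).
#' @return list with `genes` (sorted target-species gene set) and `report`
#'   (list: `n_query`, `mapped`, `unmapped`, `n_targets`).
#' @export
project_genes <- function(query, table, min_sources = 1L) {
  query <- unique(as.character(query))
  tab <- table
  if (min_sources > 1L) {
    ns <- vapply(strsplit(tab$evidence, ",", fixed = TRUE), length, integer(1))
    tab <- tab[ns >= min_sources, , drop = FALSE]
  }
  hit <- tab[tab$source_gene %in% query, , drop = FALSE]
  mapped <- unique(hit$source_gene)
  genes <- sort(unique(hit$target_gene))
  list(genes = genes,
       report = list(n_query = length(query),
                     mapped = length(mapped),
                     unmapped = length(query) - length(mapped),
                     n_targets = length(genes)))
}
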