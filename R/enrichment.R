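# Hypergeometric gene-set over-representation analysis and cross-species
# comparison of enriched terms.

#' Read gene sets in GMT format
#'
#' GMT dialect: one term per row — term identifier, description, then member
#' genes, tab-separated. Duplicate members within a term are collapsed; rows
#' with fewer than three fields are skipped with a warning; a duplicated term
#' identifier is an error.
#'
#' @param path path to a GMT file.
#' @param category category label attached to every term (e.g. `"BP"`,
#'   `"CC"`, `"MF"`, `"pathway"`); the description field is used when `NULL`
#'   and it matches a known category, else `"pathway"`.
#' @return list of terms; each term is a list with `term_id`, `name`,
#'   `category`, `members`.
#' @export
read_gmt <- function(path, category = NULL) {
  if (!file.exists(path)) stop2("cannot read GMT file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(short)) {
    warning("skipped GMT rows with <3 fields at line(s): ",
            paste(short, collapse = ", "), call. = FALSE)
    fields <- fields[-short]
  }
  if (length(fields) == 0L) stop2("no valid gene-set rows in: ", path)
  ids <- vapply(fields, `[`, character(1), 1L)
  if (anyDuplicated(ids))
    stop2("duplicate term identifier(s) in GMT: ",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  lapply(fields, function(f) {
    desc <- f[2L]
    cat_ <- category %||%
      (if (desc %in% c("BP", "CC", "MF", "pathway")) desc else "pathway")
    list(term_id = f[1L], name = desc, category = cat_,
         members = unique(f[-(1:2)]))
  })
}

#' Write gene sets as GMT
#'
#' @param terms term list (as from [read_gmt()] or [generate_annotations()]).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(terms, path) {
  rows <- vapply(terms, function(t)
    paste(c(t$term_id, t$name, t$members), collapse = "\t"), character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up adjusted p-values, monotone-enforced and capped at 1. Input values
#' must lie in (0, 1].
#'
#' @param p_values numeric vector of raw p-values.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values <= 0) || any(p_values > 1))
    stop2("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-set over-representation analysis
#'
#' For each term, the p-value is the upper-tail hypergeometric probability of
#' observing at least the attained overlap when drawing the query from the
#' background with the term's members marked. With `ease = TRUE` the overlap
#' is decremented by one (floored at 0) before the tail computation — the
#' conservative EASE-score variant. Fold enrichment is
#' (k / n) / (K / M). BH adjustment is applied within each term category.
#'
#' @param query character vector of genes of interest.
#' @param terms term list (see [read_gmt()]).
#' @param background background gene universe; default is the union of all
#'   term members. Query genes outside the background are dropped with a
#'   warning.
#' @param ease use the EASE-score variant.
#' @return data frame sorted by p ascending with columns `term_id`, `name`,
#'   `category`, `k_overlap`, `n_query`, `K_term`, `M_background`,
#'   `fold_enrichment`, `p_value`, `adj_p`.
#' @export
enrich <- function(query, terms, background = NULL, ease = FALSE) {
  query <- unique(as.character(query))
  if (is.null(background))
    background <- unique(unlist(lapply(terms, `[[`, "members"),
                                use.names = FALSE))
  background <- unique(as.character(background))
  if (length(background) < 2L) stop2("background must contain >= 2 genes")
  outside <- setdiff(query, background)
  if (length(outside)) {
    warning(length(outside), " query gene(s) not in background; dropped",
            call. = FALSE)
    query <- intersect(query, background)
  }
  if (length(query) == 0L) {
    warning("empty query; returning no enrichment records", call. = FALSE)
    return(data.frame(term_id = character(0), name = character(0),
                      category = character(0), k_overlap = integer(0),
                      n_query = integer(0), K_term = integer(0),
                      M_background = integer(0), fold_enrichment = numeric(0),
                      p_value = numeric(0), adj_p = numeric(0)))
  }
  M <- length(background)
  n <- length(query)
  recs <- lapply(terms, function(t) {
    members <- intersect(t$members, background)
    K <- length(members)
    k <- length(intersect(query, members))
    k_test <- if (ease) max(k - 1L, 0L) else k
    p <- stats::phyper(k_test - 1L, K, M - K, n, lower.tail = FALSE)
    p <- min(max(p, .Machine$double.xmin), 1)
    data.frame(term_id = t$term_id, name = t$name, category = t$category,
               k_overlap = k, n_query = n, K_term = K, M_background = M,
               fold_enrichment = if (K > 0) (k / n) / (K / M) else 0,
               p_value = p, adj_p = NA_real_, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  for (cat_ in unique(out$category)) {
    i <- out$category == cat_
    out$adj_p[i] <- bh_adjust(out$p_value[i])
  }
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strip the species prefix from KEGG-style identifiers
#'
#' Maps e.g. `"hsa04010"` and `"cel04010"` to the shared numeric suffix
#' `"04010"`, the canonical crosswalk between species-specific KEGG pathway
#' identifiers.
#'
#' @param ids character vector of term identifiers.
#' @return identifiers with a leading 3-4 letter species prefix removed.
#' @export
kegg_suffix <- function(ids) sub("^[A-Za-z]{3,4}(?=[0-9])", "", ids, perl = TRUE)

#' Cross-species comparison of enriched terms
#'
#' Returns the terms significant in both species, with the two p-values side
#' by side. The crosswalk maps term identifiers of collection A to those of
#' collection B; for KEGG pathways use
#' `kegg_crosswalk(results_a$term_id, results_b$term_id)`, which matches
#' identifiers on their numeric suffix.
#'
#' @param results_a,results_b enrichment data frames from [enrich()].
#' @param crosswalk named character vector: names are A term ids, values the
#'   corresponding B term ids.
#' @param alpha significance threshold applied in each species (default
#'   0.05).
#' @param use_adjusted gate on BH-adjusted p-values instead of raw p.
#' @return data frame with columns `term_a`, `term_b`, `name`, `p_a`, `p_b`,
#'   `adj_p_a`, `adj_p_b`, sorted by `p_a`.
#' @export
compare_species <- function(results_a, results_b, crosswalk, alpha = 0.05,
                            use_adjusted = FALSE) {
  if (is.null(crosswalk) || length(crosswalk) == 0L)
    stop2("crosswalk is empty; supply a term-id mapping")
  pa <- if (use_adjusted) results_a$adj_p else results_a$p_value
  pb <- if (use_adjusted) results_b$adj_p else results_b$p_value
  sig_a <- results_a[pa <= alpha, , drop = FALSE]
  sig_b <- results_b[pb <= alpha, , drop = FALSE]
  mapped <- crosswalk[names(crosswalk) %in% sig_a$term_id]
  mapped <- mapped[mapped %in% sig_b$term_id]
  if (length(mapped) == 0L)
    return(data.frame(term_a = character(0), term_b = character(0),
                      name = character(0), p_a = numeric(0), p_b = numeric(0),
                      adj_p_a = numeric(0), adj_p_b = numeric(0)))
  ia <- match(names(mapped), results_a$term_id)
  ib <- match(unname(mapped), results_b$term_id)
  out <- data.frame(term_a = names(mapped), term_b = unname(mapped),
                    name = results_a$name[ia],
                    p_a = results_a$p_value[ia], p_b = results_b$p_value[ib],
                    adj_p_a = results_a$adj_p[ia],
                    adj_p_b = results_b$adj_p[ib],
                    stringsAsFactors = FALSE)
  out <- out[order(out$p_a, out$term_a), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build a KEGG identifier crosswalk between two collections
#'
#' Matches identifiers whose numeric suffixes agree after stripping the
#' species prefix (see [kegg_suffix()]).
#'
#' @param ids_a,ids_b character vectors of term identifiers.
#' @return named character vector mapping A ids to B ids.
#' @export
kegg_crosswalk <- function(ids_a, ids_b) {
  sa <- kegg_suffix(ids_a)
  sb <- kegg_suffix(ids_b)
  hit <- match(sa, sb)
  keep <- !is.na(hit)
  stats::setNames(ids_b[hit[keep]], ids_a[keep])
}
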