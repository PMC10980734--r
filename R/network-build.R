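#' Read a scored interaction edge table
#'
#' Parses a STRING-export-like tab-separated file with at least three columns
#' (protein a, protein b, confidence score in \[0, 1\]) and keeps rows whose
#' score passes `score_min`. A header row is detected automatically (a first
#' row whose third field is not numeric). Malformed rows (fewer than three
#' fields, or an unparseable score) are skipped with a warning that lists
#' their line numbers.
#'
#' @param path path to a tab-separated edge file.
#' @param score_min minimum confidence score to retain an edge. Default 0.4,
#'   the conventional "medium confidence" STRING cutoff.
#' @return data frame with columns `gene_a`, `gene_b`, `score`, input order
#'   preserved.
#' @export
read_edge_table <- function(path, score_min = 0.4) {
  if (!file.exists(path)) stop2("cannot read edge table: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop2("no parseable rows in edge table: ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  start <- 1L
  if (length(fields[[1L]]) >= 3L &&
      is.na(suppressWarnings(as.numeric(fields[[1L]][3L])))) {
    start <- 2L  # header row
  }
  rows <- vector("list", length(lines))
  bad <- integer(0)
  for (i in seq(from = start, length.out = max(0L, length(lines) - start + 1L))) {
    f <- fields[[i]]
    sc <- if (length(f) >= 3L) suppressWarnings(as.numeric(f[3L])) else NA_real_
    if (length(f) < 3L || is.na(sc)) {
      bad <- c(bad, i)
      next
    }
    rows[[i]] <- data.frame(gene_a = f[1L], gene_b = f[2L], score = sc,
                            stringsAsFactors = FALSE)
  }
  if (length(bad))
    warning("skipped malformed edge rows at line(s): ",
            paste(bad, collapse = ", "), call. = FALSE)
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L)
    stop2("no parseable rows in edge table: ", path)
  out[out$score >= score_min, , drop = FALSE]
}

new_ppi_network <- function(edges, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(edges$gene_a, edges$gene_b)))
  adj <- vector("list", length(nodes))
  names(adj) <- nodes
  if (length(nodes)) {
    ia <- match(edges$gene_a, nodes)
    ib <- match(edges$gene_b, nodes)
    idx <- split(c(ib, ia), c(ia, ib))
    for (k in names(idx)) adj[[as.integer(k)]] <- sort(unique(idx[[k]]))
    adj <- lapply(adj, function(v) if (is.null(v)) integer(0) else v)
  }
  structure(list(nodes = nodes, edges = edges, adj = adj),
            class = "ppi_network")
}

#' Build a cleaned simple undirected PPI network
#'
#' Applies the cleanup rules used for interaction networks: optional
#' restriction to a gene whitelist, removal of self-loops, collapse of
#' duplicate unordered pairs (keeping the maximum score), and removal of
#' isolated nodes (every retained node has degree >= 1). An empty result is
#' returned as an empty network, not an error.
#'
#' @param edges data frame with columns `gene_a`, `gene_b`, `score` (as from
#'   [read_edge_table()]).
#' @param node_whitelist optional character vector; only edges with both
#'   endpoints in the whitelist are kept.
#' @param uppercase if `TRUE`, gene symbols (and the whitelist) are
#'   upper-cased before matching — the convention for human symbols. Worm
#'   gene names are conventionally lower-case and should be left verbatim.
#' @return a `ppi_network` object (nodes, edges, adjacency) with a `cleanup`
#'   attribute counting rows dropped per rule.
#' @export
build_network <- function(edges, node_whitelist = NULL, uppercase = FALSE) {
  stopifnot(all(c("gene_a", "gene_b", "score") %in% names(edges)))
  a <- as.character(edges$gene_a)
  b <- as.character(edges$gene_b)
  s <- as.numeric(edges$score)
  if (uppercase) {
    a <- toupper(a); b <- toupper(b)
    if (!is.null(node_whitelist)) node_whitelist <- toupper(node_whitelist)
  }
  n_input <- length(a)
  n_wl <- 0L
  if (!is.null(node_whitelist)) {
    keep <- a %in% node_whitelist & b %in% node_whitelist
    n_wl <- sum(!keep)
    a <- a[keep]; b <- b[keep]; s <- s[keep]
  }
  self <- a == b
  n_self <- sum(self)
  a <- a[!self]; b <- b[!self]; s <- s[!self]
  lo <- pmin(a, b); hi <- pmax(a, b)
  key <- paste(lo, hi, sep = "\r")
  n_dup <- 0L
  if (anyDuplicated(key)) {
    n_dup <- sum(duplicated(key))
    smax <- tapply(s, key, max)
    first <- !duplicated(key)
    lo <- lo[first]; hi <- hi[first]
    s <- as.numeric(smax[key[first]])
  }
  clean <- data.frame(gene_a = lo, gene_b = hi, score = s,
                      stringsAsFactors = FALSE)
  net <- new_ppi_network(clean)
  n_iso <- if (is.null(node_whitelist)) 0L else
    sum(!(node_whitelist %in% net$nodes))
  attr(net, "cleanup") <- list(
    n_input = n_input, whitelist_removed = n_wl, self_loops = n_self,
    duplicates_collapsed = n_dup, isolated_removed = n_iso)
  net
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("<ppi_network> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Network size helpers
#'
#' @param net a `ppi_network`.
#' @return `n_nodes()`: node count; `n_edges()`: edge count;
#'   `network_degree()`: named integer vector of node degrees.
#' @export
n_nodes <- function(net) length(net$nodes)

#' @rdname n_nodes
#' @export
n_edges <- function(net) nrow(net$edges)

#' @rdname n_nodes
#' @export
network_degree <- function(net) {
  k <- vapply(net$adj, length, integer(1))
  names(k) <- net$nodes
  k
}

#' Convert a ppi_network to an igraph graph
#'
#' @param net a `ppi_network`.
#' @return an undirected `igraph` graph with a `score` edge attribute.
#' @export
as_igraph <- function(net) {
  g <- igraph::graph_from_data_frame(
    net$edges[, c("gene_a", "gene_b")], directed = FALSE,
    vertices = net$nodes)
  igraph::E(g)$score <- net$edges$score
  g
}
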