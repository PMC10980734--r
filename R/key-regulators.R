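# Multi-centrality ranking, top-N intersection and neighbourhood extraction.

VALID_METRICS <- c("degree", "betweenness", "closeness", "bottleneck")

#' Top-N genes by a centrality metric
#'
#' Orders nodes by metric value descending with lexicographic gene-symbol
#' ascent as the tie rule, and returns the first `n` (all nodes when `n`
#' exceeds the node count).
#'
#' @param metrics node-metrics data frame from [compute_node_metrics()].
#' @param metric one of `"degree"`, `"betweenness"`, `"closeness"`,
#'   `"bottleneck"`.
#' @param n list length (default 20, the usual hub-list size).
#' @return a `ranked_list`: list with `metric`, `n`, and ordered `genes`.
#' @export
top_n_genes <- function(metrics, metric, n = 20) {
  if (!metric %in% VALID_METRICS)
    stop2("unknown metric '", metric, "'; valid metrics: ",
          paste(VALID_METRICS, collapse = ", "))
  if (!metric %in% names(metrics))
    stop2("metrics table has no column '", metric, "'")
  n <- assert_count(n, "n")
  ord <- order(-metrics[[metric]], metrics$gene)
  genes <- metrics$gene[ord][seq_len(min(n, nrow(metrics)))]
  structure(list(metric = metric, n = n, genes = genes),
            class = "ranked_list")
}

#' Intersect top-ranked lists into a key-regulator set
#'
#' Key regulators (KRs) are the genes common to every supplied ranked list —
#' the nodes that score among the top N for all chosen centrality metrics.
#' An empty intersection is a valid result.
#'
#' @param lists a list of two or more `ranked_list` objects from
#'   [top_n_genes()].
#' @return a `key_regulator_set`: list with sorted `genes`, `metrics_used`,
#'   and `n` (the per-list length).
#' @export
intersect_top <- function(lists) {
  if (!is.list(lists) || length(lists) < 2L)
    stop2("need at least 2 ranked lists to intersect")
  genes <- Reduce(intersect, lapply(lists, function(l) l$genes))
  structure(list(
    genes = sort(genes),
    metrics_used = vapply(lists, function(l) l$metric, character(1)),
    n = max(vapply(lists, function(l) l$n, integer(1)))),
    class = "key_regulator_set")
}

#' @export
print.key_regulator_set <- function(x, ...) {
  cat(sprintf("<key_regulator_set> %d genes (top %d of: %s)\n",
              length(x$genes), x$n, paste(x$metrics_used, collapse = ", ")))
  if (length(x$genes)) cat(" ", paste(x$genes, collapse = ", "), "\n")
  invisible(x)
}

#' Closed first neighbourhood of a seed gene set
#'
#' Returns the seeds present in the network together with every node directly
#' adjacent to any seed (the closed neighbourhood). Seeds absent from the
#' network are reported with a warning but are not fatal; the result size is
#' |seeds in network| + |non-seed neighbours|.
#'
#' @param net a `ppi_network`.
#' @param seeds character vector of seed genes.
#' @return sorted character vector of genes.
#' @export
closed_first_neighborhood <- function(net, seeds) {
  seeds <- unique(as.character(seeds))
  if (length(seeds) == 0L) {
    warning("empty seed set; returning empty neighbourhood", call. = FALSE)
    return(character(0))
  }
  present <- seeds[seeds %in% net$nodes]
  missing <- setdiff(seeds, present)
  if (length(missing))
    warning(length(missing), " seed(s) not in network: ",
            paste(missing, collapse = ", "), call. = FALSE)
  idx <- match(present, net$nodes)
  nbrs <- unique(unlist(net$adj[idx], use.names = FALSE))
  sort(unique(c(present, net$nodes[nbrs])))
}
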