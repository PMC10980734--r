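# Molecular-complex detection (MCODE): k-core based vertex weighting, seeded
# greedy complex expansion, post-processing, and density x N scoring.

#' MCODE parameters
#'
#' Defaults are the conventional Cytoscape-app defaults: degree cut-off 2,
#' node score cut-off 0.2, k-core 2, maximum expansion depth 100, haircut on,
#' fluff off.
#'
#' @param degree_cutoff minimum degree for a node to receive a weight.
#' @param node_score_cutoff fraction in \[0, 1\]; a neighbour joins a cluster
#'   when its weight is at least `seed_weight * (1 - node_score_cutoff)`.
#' @param k_core clusters lacking a k-core of this order are discarded.
#' @param max_depth maximum breadth-first expansion depth from the seed.
#' @param haircut drop singly-connected nodes from each cluster.
#' @param fluff add boundary nodes whose closed-neighbourhood density exceeds
#'   `fluff_density`.
#' @param fluff_density density threshold used when `fluff` is on.
#' @return a list of class `mcode_params`.
#' @export
mcode_params <- function(degree_cutoff = 2L, node_score_cutoff = 0.2,
                         k_core = 2L, max_depth = 100L,
                         haircut = TRUE, fluff = FALSE, fluff_density = 0.5) {
  structure(list(
    degree_cutoff = assert_count(degree_cutoff, "degree_cutoff", min = 0L),
    node_score_cutoff = assert_fraction(node_score_cutoff, "node_score_cutoff"),
    k_core = assert_count(k_core, "k_core", min = 0L),
    max_depth = assert_count(max_depth, "max_depth"),
    haircut = isTRUE(haircut), fluff = isTRUE(fluff),
    fluff_density = assert_fraction(fluff_density, "fluff_density")),
    class = "mcode_params")
}

# Core numbers by the standard peeling algorithm, on an integer adjacency
# list restricted to `sub` (integer node ids). Returns named-by-position core
# numbers for the nodes of `sub`.
core_numbers <- function(adj, sub = seq_along(adj)) {
  pos <- integer(length(adj))
  pos[sub] <- seq_along(sub)
  deg <- vapply(sub, function(v) sum(adj[[v]] %in% sub), integer(1))
  core <- integer(length(sub))
  alive <- rep(TRUE, length(sub))
  k <- 0L
  remaining <- length(sub)
  while (remaining > 0L) {
    repeat {
      drop <- which(alive & deg <= k)
      if (length(drop) == 0L) break
      for (i in drop) {
        alive[i] <- FALSE
        core[i] <- k
        remaining <- remaining - 1L
        for (w in adj[[sub[i]]]) {
          j <- pos[w]
          if (j > 0L && alive[j]) deg[j] <- deg[j] - 1L
        }
      }
    }
    k <- k + 1L
  }
  core
}

induced_edge_count <- function(adj, sub) {
  insub <- logical(length(adj))
  insub[sub] <- TRUE
  sum(vapply(sub, function(v) sum(insub[adj[[v]]]), integer(1))) / 2L
}

graph_density <- function(n, e) if (n < 2L) 0 else 2 * e / (n * (n - 1))

#' MCODE vertex weights
#'
#' For every node v with degree at least `degree_cutoff`, the highest k-core
#' of the subgraph induced by v's closed neighbourhood is located; the weight
#' of v is that core's order k multiplied by the core subgraph's density.
#' Nodes below the degree cut-off weigh 0.
#'
#' @param net a `ppi_network`.
#' @param degree_cutoff minimum degree (default 2).
#' @return named numeric vector of weights in node order.
#' @export
mcode_vertex_weights <- function(net, degree_cutoff = 2L) {
  adj <- net$adj
  n <- length(adj)
  w <- numeric(n)
  deg <- vapply(adj, length, integer(1))
  for (v in seq_len(n)) {
    if (deg[v] < degree_cutoff) next
    nbhd <- c(v, adj[[v]])
    core <- core_numbers(adj, nbhd)
    kmax <- max(core)
    core_nodes <- nbhd[core == kmax]
    e <- induced_edge_count(adj, core_nodes)
    w[v] <- kmax * graph_density(length(core_nodes), e)
  }
  stats::setNames(w, net$nodes)
}

#' MCODE cluster score
#'
#' Score of a detected complex: graph density times node count,
#' 2 E / (N (N - 1)) * N. A clique of size n scores exactly n.
#'
#' @param n_nodes number of nodes (>= 2).
#' @param n_edges number of edges induced in the parent network.
#' @return the score (report to three decimals in outputs).
#' @export
module_score <- function(n_nodes, n_edges) {
  n_nodes <- assert_count(n_nodes, "n_nodes", min = 0L)
  n_edges <- assert_count(n_edges, "n_edges", min = 0L)
  if (n_nodes < 2L) stop2("module score is undefined for fewer than 2 nodes")
  if (n_edges > n_nodes * (n_nodes - 1L) / 2L)
    stop2("n_edges exceeds the simple-graph maximum C(n_nodes, 2)")
  graph_density(n_nodes, n_edges) * n_nodes
}

#' Detect dense network modules (MCODE)
#'
#' Implements molecular-complex detection: nodes are weighted by the density
#' of the highest k-core of their closed neighbourhood
#' ([mcode_vertex_weights()]); complexes are grown breadth-first from the
#' highest-weight unassigned seed, admitting neighbours whose weight is at
#' least `seed_weight * (1 - node_score_cutoff)` (never revisiting a node,
#' never crossing `max_depth`); post-processing discards clusters lacking a
#' `k_core`-core, optionally removes singly-connected nodes (haircut) and
#' optionally adds dense boundary nodes (fluff). Clusters are scored density
#' x node count and returned sorted by score descending.
#'
#' Candidate order among equal weights is lexicographic by gene symbol, so
#' results are deterministic. With fluff off, returned clusters are
#' vertex-disjoint.
#'
#' @param net a `ppi_network`.
#' @param params an [mcode_params()] list.
#' @return list of modules; each module is a list with `module_id`, `nodes`
#'   (sorted gene symbols), `n_nodes`, `n_edges` (induced in the parent
#'   network), `score`, `seed_gene`. See [module_table()] for a data-frame
#'   view and [filter_modules()] for score filtering.
#' @export
mcode <- function(net, params = mcode_params()) {
  stopifnot(inherits(params, "mcode_params"))
  adj <- net$adj
  n <- length(adj)
  if (n == 0L) return(list())
  w <- mcode_vertex_weights(net, params$degree_cutoff)
  assigned <- logical(n)
  # seeds in weight-descending order, gene symbol ascending among ties
  seed_order <- order(-w, net$nodes)
  clusters <- list()
  for (s in seed_order) {
    if (assigned[s] || w[s] <= 0) next
    thr <- w[s] * (1 - params$node_score_cutoff)
    in_cluster <- logical(n)
    in_cluster[s] <- TRUE
    frontier <- s
    depth <- 0L
    while (length(frontier) > 0L && depth < params$max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in adj[[v]]) {
          if (!in_cluster[u] && !assigned[u] && w[u] >= thr) {
            in_cluster[u] <- TRUE
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- sort(unique(nxt))
      depth <- depth + 1L
    }
    members <- which(in_cluster)
    assigned[members] <- TRUE
    # post-processing: k-core requirement, then haircut / fluff
    core <- core_numbers(adj, members)
    if (max(core) < params$k_core) next
    if (params$haircut) {
      keep <- vapply(members, function(v)
        sum(adj[[v]] %in% members) >= 2L, logical(1))
      members <- members[keep]
    }
    if (params$fluff) {
      boundary <- setdiff(unique(unlist(adj[members], use.names = FALSE)),
                          members)
      add <- boundary[vapply(boundary, function(v) {
        nbhd <- c(v, adj[[v]])
        graph_density(length(nbhd), induced_edge_count(adj, nbhd)) >
          params$fluff_density
      }, logical(1))]
      members <- sort(c(members, add))
    }
    if (length(members) < 2L) next
    e <- induced_edge_count(adj, members)
    clusters[[length(clusters) + 1L]] <- list(
      nodes = net$nodes[sort(members)],
      n_nodes = length(members),
      n_edges = as.integer(e),
      score = module_score(length(members), e),
      seed_gene = net$nodes[s])
  }
  ord <- order(-vapply(clusters, `[[`, numeric(1), "score"),
               vapply(clusters, `[[`, character(1), "seed_gene"))
  clusters <- clusters[ord]
  for (i in seq_along(clusters)) clusters[[i]]$module_id <- i
  clusters
}

#' Filter modules by minimum score
#'
#' @param modules module list from [mcode()].
#' @param min_score minimum score to keep (default 5, the usual significance
#'   cut for complexes).
#' @return filtered module list, rank order preserved.
#' @export
filter_modules <- function(modules, min_score = 5) {
  modules[vapply(modules, function(m) m$score >= min_score, logical(1))]
}

#' Module list as a data frame
#'
#' @param modules module list from [mcode()].
#' @return data frame with columns `module_id`, `n_nodes`, `n_edges`,
#'   `score` (3 decimals), `seed_gene`, `members` (comma-joined).
#' @export
module_table <- function(modules) {
  if (length(modules) == 0L)
    return(data.frame(module_id = integer(0), n_nodes = integer(0),
                      n_edges = integer(0), score = numeric(0),
                      seed_gene = character(0), members = character(0)))
  data.frame(
    module_id = vapply(modules, `[[`, integer(1), "module_id"),
    n_nodes = vapply(modules, `[[`, integer(1), "n_nodes"),
    n_edges = vapply(modules, `[[`, integer(1), "n_edges"),
    score = round(vapply(modules, `[[`, numeric(1), "score"), 3),
    seed_gene = vapply(modules, `[[`, character(1), "seed_gene"),
    members = vapply(modules, function(m)
      paste(m$nodes, collapse = ","), character(1)),
    stringsAsFactors = FALSE)
}
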