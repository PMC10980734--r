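# Per-node centralities and degree-indexed profiles. All algorithms operate
# on integer adjacency lists; node indices follow the lexicographic order of
# gene symbols, which fixes every tie-break deterministically.

#' Node centralities of a PPI network
#'
#' Computes, for every node: degree `k`; betweenness centrality by Brandes'
#' single-source accumulation over shortest-path DAGs, normalized by the
#' undirected pair count (n-1)(n-2)/2 so values lie in \[0, 1\]; closeness
#' centrality as (number of reachable nodes) / (sum of shortest-path
#' distances to reachable nodes) — the reciprocal mean distance within the
#' node's component, 0 for nodes with no reachable partner; and bottleneck
#' centrality (see [bottleneck_scores()]).
#'
#' @param net a `ppi_network` from [build_network()].
#' @return data frame with columns `gene`, `degree`, `betweenness`,
#'   `closeness`, `bottleneck`, one row per node in lexicographic order.
#' @export
compute_node_metrics <- function(net) {
  n <- length(net$nodes)
  if (n == 0L)
    return(data.frame(gene = character(0), degree = integer(0),
                      betweenness = numeric(0), closeness = numeric(0),
                      bottleneck = integer(0)))
  adj <- net$adj
  data.frame(
    gene = net$nodes,
    degree = vapply(adj, length, integer(1)),
    betweenness = brandes_betweenness(adj),
    closeness = closeness_centrality(adj),
    bottleneck = bottleneck_scores(net),
    row.names = NULL, stringsAsFactors = FALSE)
}

# Brandes (2001) betweenness for unweighted undirected graphs; endpoints
# excluded, each unordered pair counted once, divided by (n-1)(n-2)/2.
brandes_betweenness <- function(adj) {
  n <- length(adj)
  bc <- numeric(n)
  if (n < 3L) return(bc)
  for (s in seq_len(n)) {
    sigma <- numeric(n); sigma[s] <- 1
    dist <- rep(-1L, n);  dist[s] <- 0L
    preds <- vector("list", n)
    order_visited <- integer(n); nv <- 0L
    queue <- integer(n); head <- 1L; tail <- 1L
    queue[1L] <- s
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      nv <- nv + 1L; order_visited[nv] <- v
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L; queue[tail] <- w
        }
        if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
          preds[[w]] <- c(preds[[w]], v)
        }
      }
    }
    delta <- numeric(n)
    for (i in rev(seq_len(nv))) {
      w <- order_visited[i]
      coef <- (1 + delta[w]) / sigma[w]
      for (v in preds[[w]]) delta[v] <- delta[v] + sigma[v] * coef
      if (w != s) bc[w] <- bc[w] + delta[w]
    }
  }
  # each unordered pair accumulated from both endpoints -> halve
  bc / 2 / (  (n - 1) * (n - 2) / 2 )
}

closeness_centrality <- function(adj) {
  n <- length(adj)
  cc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- bfs_distances(adj, s)
    reach <- which(dist > 0L)
    cc[s] <- if (length(reach)) length(reach) / sum(dist[reach]) else 0
  }
  cc
}

bfs_distances <- function(adj, s) {
  n <- length(adj)
  dist <- rep(-1L, n); dist[s] <- 0L
  queue <- integer(n); queue[1L] <- s
  head <- 1L; tail <- 1L
  while (head <= tail) {
    v <- queue[head]; head <- head + 1L
    for (w in adj[[v]]) if (dist[w] < 0L) {
      dist[w] <- dist[v] + 1L
      tail <- tail + 1L; queue[tail] <- w
    }
  }
  dist
}

#' Bottleneck centrality
#'
#' For each root s, one breadth-first shortest-path tree is grown over s's
#' component, each node's parent being the first neighbour (in lexicographic
#' node order) that discovers it. A node v != s is a bottleneck of that tree
#' when its subtree (nodes whose tree path from s passes through v, v
#' inclusive) contains more than |V(T_s)|/4 nodes. BN(v) counts the roots for
#' which v is a bottleneck. Unreachable nodes are outside the tree, so BN is
#' accumulated within components only.
#'
#' @param net a `ppi_network`.
#' @return named integer vector of BN scores in node order.
#' @export
bottleneck_scores <- function(net) {
  adj <- net$adj
  n <- length(adj)
  bn <- integer(n)
  if (n == 0L) return(stats::setNames(bn, net$nodes))
  for (s in seq_len(n)) {
    parent <- rep(0L, n)
    dist <- rep(-1L, n); dist[s] <- 0L
    queue <- integer(n); queue[1L] <- s
    head <- 1L; tail <- 1L
    while (head <= tail) {
      v <- queue[head]; head <- head + 1L
      for (w in adj[[v]]) if (dist[w] < 0L) {  # adj pre-sorted -> lexicographic
        dist[w] <- dist[v] + 1L
        parent[w] <- v
        tail <- tail + 1L; queue[tail] <- w
      }
    }
    tree_size <- tail
    sub <- rep(1L, n)
    for (i in seq(from = tail, to = 1L)) {  # reverse BFS order
      v <- queue[i]
      if (v != s) sub[parent[v]] <- sub[parent[v]] + sub[v]
    }
    thr <- tree_size / 4
    for (i in seq_len(tail)) {
      v <- queue[i]
      if (v != s && sub[v] > thr) bn[v] <- bn[v] + 1L
    }
  }
  stats::setNames(bn, net$nodes)
}

#' Degree-indexed topology profiles P(k), C(k), C_N(k)
#'
#' P(k) is the fraction of nodes with degree k; C(k) the mean clustering
#' coefficient of degree-k nodes, where the clustering coefficient of a node
#' v is 2 e(N(v)) / (k_v (k_v - 1)) (0 by convention when k_v < 2); C_N(k)
#' the mean over degree-k nodes of the mean degree of their neighbours
#' (neighbour connectivity).
#'
#' @param net a `ppi_network`.
#' @return data frame with columns `k`, `p_k`, `c_k`, `cn_k`, one row per
#'   observed degree value, increasing in `k`. `sum(p_k)` is 1.
#' @export
compute_degree_profiles <- function(net) {
  adj <- net$adj
  n <- length(adj)
  if (n == 0L)
    return(data.frame(k = integer(0), p_k = numeric(0),
                      c_k = numeric(0), cn_k = numeric(0)))
  deg <- vapply(adj, length, integer(1))
  clust <- vapply(seq_len(n), function(v) {
    k <- deg[v]
    if (k < 2L) return(0)
    nb <- adj[[v]]
    e <- 0L
    for (i in seq_len(k - 1L)) {
      e <- e + sum(nb[(i + 1L):k] %in% adj[[nb[i]]])
    }
    2 * e / (k * (k - 1))
  }, numeric(1))
  nbr_deg <- vapply(seq_len(n), function(v) mean(deg[adj[[v]]]), numeric(1))
  ks <- sort(unique(deg))
  data.frame(
    k = ks,
    p_k = vapply(ks, function(k) sum(deg == k) / n, numeric(1)),
    c_k = vapply(ks, function(k) mean(clust[deg == k]), numeric(1)),
    cn_k = vapply(ks, function(k) mean(nbr_deg[deg == k]), numeric(1)))
}
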