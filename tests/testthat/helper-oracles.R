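# Independent oracles and fixture builders. The centrality oracle combines
# pairwise Floyd-Warshall distances with dynamic-programming path counts --
# a formulation disjoint from the package's single-source Brandes
# accumulation. The hypergeometric oracle enumerates every possible draw.

edge_df <- function(a, b, score = 1) {
  n <- max(length(a), length(b))
  data.frame(gene_a = rep_len(a, n), gene_b = rep_len(b, n),
             score = rep_len(score, n), stringsAsFactors = FALSE)
}

clique_edges <- function(nodes, score = 1) {
  pr <- utils::combn(nodes, 2L)
  edge_df(pr[1L, ], pr[2L, ], score)
}

rand_net <- function(n, p, seed) {
  set.seed(seed)
  pairs <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
  hit <- stats::runif(nrow(pairs)) < p
  if (!any(hit)) hit[1L] <- TRUE
  nm <- sprintf("n%03d", seq_len(n))
  build_network(edge_df(nm[pairs[hit, 1L]], nm[pairs[hit, 2L]]))
}

adjacency_matrix <- function(net) {
  n <- length(net$nodes)
  A <- matrix(0L, n, n)
  ia <- match(net$edges$gene_a, net$nodes)
  ib <- match(net$edges$gene_b, net$nodes)
  A[cbind(ia, ib)] <- 1L
  A[cbind(ib, ia)] <- 1L
  A
}

# All-pairs exhaustive centralities: Floyd-Warshall distances, path counts by
# DP over nodes in distance order, betweenness by summing pair-dependency
# sigma(s,v) * sigma(v,t) / sigma(s,t) over all unordered reachable pairs.
oracle_centralities <- function(net) {
  A <- adjacency_matrix(net)
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  D[A == 1L] <- 1
  diag(D) <- 0
  for (k in seq_len(n)) D <- pmin(D, outer(D[, k], D[k, ], "+"))
  S <- matrix(0, n, n)
  for (s in seq_len(n)) {
    S[s, s] <- 1
    for (t in order(D[s, ])) {
      if (t == s || !is.finite(D[s, t])) next
      pred <- which(A[, t] == 1L & D[s, ] == D[s, t] - 1)
      S[s, t] <- sum(S[s, pred])
    }
  }
  btw <- numeric(n)
  for (v in seq_len(n)) {
    through <- is.finite(D) & (outer(D[, v], D[v, ], "+") == D)
    contrib <- (S[, v] %o% S[v, ]) / S
    contrib[!through] <- 0
    contrib[v, ] <- 0
    contrib[, v] <- 0
    btw[v] <- sum(contrib[upper.tri(contrib)])
  }
  clo <- vapply(seq_len(n), function(s) {
    d <- D[s, -s]
    d <- d[is.finite(d)]
    if (length(d)) length(d) / sum(d) else 0
  }, numeric(1))
  list(betweenness = btw / ((n - 1) * (n - 2) / 2), closeness = clo)
}

# Exhaustive hypergeometric upper tail: probability of >= k marked among all
# C(M, n) equally likely draws of size n from M with K marked.
hyper_tail_oracle <- function(M, K, n, k) {
  draws <- utils::combn(M, n)
  overlap <- colSums(matrix(draws %in% seq_len(K), nrow = n))
  mean(overlap >= k)
}

# MCODE vertex-weight oracle through igraph's coreness.
weights_oracle <- function(net, degree_cutoff = 2L) {
  g <- as_igraph(net)
  deg <- igraph::degree(g)
  vapply(seq_along(net$nodes), function(i) {
    if (deg[i] < degree_cutoff) return(0)
    nb <- c(i, as.integer(igraph::neighbors(g, i)))
    sub <- igraph::induced_subgraph(g, nb)
    core <- igraph::coreness(sub)
    kmax <- max(core)
    csub <- igraph::induced_subgraph(sub, which(core == kmax))
    kmax * igraph::edge_density(csub)
  }, numeric(1))
}
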