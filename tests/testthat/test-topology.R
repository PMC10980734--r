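test_that("small-graph centralities match hand computation", {
  # path A-B-C: B carries the single intermediate pair
  path3 <- compute_node_metrics(build_network(edge_df(c("A", "B"),
                                                      c("B", "C"))))
  b <- path3[path3$gene == "B", ]
  expect_equal(b$degree, 2)
  expect_equal(b$betweenness, 1)
  expect_equal(b$closeness, 1)
  expect_equal(path3$betweenness[path3$gene == "A"], 0)

  # triangle: no intermediates anywhere
  tri <- compute_node_metrics(build_network(clique_edges(c("A", "B", "C"))))
  expect_equal(tri$betweenness, rep(0, 3))
  expect_equal(tri$closeness, rep(1, 3))
  expect_equal(tri$degree, rep(2, 3))
})

test_that("star centres score exactly 1 in betweenness for any size", {
  for (n in c(3, 5, 8, 12)) {
    net <- build_network(edge_df("cen", sprintf("l%02d", seq_len(n - 1))))
    m <- compute_node_metrics(net)
    expect_equal(m$betweenness[m$gene == "cen"], 1)
    expect_equal(m$betweenness[m$gene != "cen"], rep(0, n - 1))
  }
})

test_that("Brandes betweenness and closeness match the exhaustive oracle", {
  for (seed in 1:8) {
    net <- rand_net(10 + 3 * seed, 0.12, seed)
    m <- compute_node_metrics(net)
    o <- oracle_centralities(net)
    expect_lt(max(abs(m$betweenness - o$betweenness)), 1e-9)
    expect_lt(max(abs(m$closeness - o$closeness)), 1e-9)
  }
})

test_that("centralities agree with igraph on connected graphs", {
  for (seed in 1:4) {
    base <- rand_net(25, 0.2, seed)
    nm <- sprintf("n%03d", 1:25)
    # a spanning path guarantees connectivity
    net <- build_network(rbind(base$edges, edge_df(nm[-25], nm[-1])))
    g <- as_igraph(net)
    m <- compute_node_metrics(net)
    ib <- igraph::betweenness(g, directed = FALSE, normalized = TRUE)
    expect_equal(m$betweenness, unname(ib), tolerance = 1e-10)
    ic <- igraph::closeness(g)
    expect_equal(m$closeness / (n_nodes(net) - 1), unname(ic),
                 tolerance = 1e-10)
  }
})

test_that("bottleneck scores count quarter-dominating subtrees per root", {
  # star: the centre dominates the tree from every leaf root
  star <- build_network(edge_df("cen", sprintf("l%02d", 1:10)))
  bn <- bottleneck_scores(star)
  expect_equal(unname(bn["cen"]), 10)
  expect_equal(unname(bn[names(bn) != "cen"]), rep(0, 10))

  # single edge: each endpoint is the whole subtree of the other's tree
  bn2 <- bottleneck_scores(build_network(edge_df("A", "B")))
  expect_equal(unname(bn2), c(1, 1))

  # disconnected components are scored independently
  two <- build_network(edge_df(c("A", "x"), c("B", "y")))
  bn3 <- bottleneck_scores(two)
  expect_equal(unname(bn3), c(1, 1, 1, 1))

  # BN values are integers within [0, n-1]
  net <- rand_net(40, 0.08, 5)
  bn4 <- bottleneck_scores(net)
  expect_true(all(bn4 == round(bn4)))
  expect_true(all(bn4 >= 0 & bn4 <= n_nodes(net) - 1))
})

test_that("degree profiles normalize and match closed forms", {
  tri <- compute_degree_profiles(build_network(clique_edges(c("A", "B",
                                                              "C"))))
  expect_equal(tri, data.frame(k = 2L, p_k = 1, c_k = 1, cn_k = 2))

  star <- compute_degree_profiles(
    build_network(edge_df("C", c("A", "B", "D", "E"))))
  expect_equal(star$k, c(1L, 4L))
  expect_equal(star$p_k, c(0.8, 0.2))
  expect_equal(star$c_k, c(0, 0))
  expect_equal(star$cn_k, c(4, 1))

  for (seed in 1:4) {
    prof <- compute_degree_profiles(rand_net(50, 0.08, seed))
    expect_equal(sum(prof$p_k), 1)
    expect_true(all(prof$c_k >= 0 & prof$c_k <= 1))
    expect_true(all(prof$cn_k >= 1))
  }
})

test_that("adding an edge never decreases a degree", {
  net <- rand_net(20, 0.1, 3)
  k1 <- network_degree(net)
  extra <- rbind(net$edges, edge_df(net$nodes[1], net$nodes[2]))
  k2 <- network_degree(build_network(extra))
  expect_true(all(k2[names(k1)] >= k1))
})
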