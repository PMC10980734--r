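test_that("expression generator plants the stated effect and is seed-pure", {
  # nothing planted
  g0 <- generate_expression(100, 5, 5, n_de = 0, seed = 1)
  expect_length(g0$truth$de_genes, 0)

  # seed determinism, byte for byte
  a <- generate_expression(200, 10, 10, n_de = 20, seed = 7)
  b <- generate_expression(200, 10, 10, n_de = 20, seed = 7)
  expect_identical(a$dataset$matrix, b$dataset$matrix)
  expect_identical(a$truth$de_genes, b$truth$de_genes)

  # Monte-Carlo check of the generative model: mean estimated log2FC over
  # planted up-genes ~ effect_size within 3 * (sigma * sqrt(2/20)) / sqrt(100)
  g <- generate_expression(1000, 20, 20, n_de = 100, effect_size = 1,
                           sigma = 0.5, seed = 7)
  st <- compute_gene_stats(g$dataset)
  up <- names(g$truth$de_direction)[g$truth$de_direction > 0]
  est <- st$log2fc[match(up, st$gene)]
  tol <- 3 * (0.5 * sqrt(2 / 20)) / sqrt(100)
  expect_lt(abs(mean(est) - 1), tol)
})

test_that("expression generator validates its arguments", {
  expect_error(generate_expression(0, 5, 5), "n_genes")
  expect_error(generate_expression(10, 5, 5, n_de = 11), "n_de")
  expect_error(generate_expression(10, 5, 5, sigma = 0), "sigma")
})

test_that("network generator produces clean edge tables with exact truth", {
  # a 5-clique alone is C(5,2) = 10 pairs
  g5 <- generate_network(5, "planted_modules",
                         params = list(module_sizes = 5L, noise_p = 0),
                         seed = 1)
  expect_equal(nrow(g5$edges), 10)

  # planted 24-clique + noise: the planted nodes induce exactly 276 edges
  g <- generate_network(224, "planted_modules",
                        params = list(module_sizes = 24L, noise_p = 0.02),
                        seed = 11)
  clique <- g$truth$planted_modules[[1]]
  expect_length(clique, 24)
  in_clique <- g$edges$gene_a %in% clique & g$edges$gene_b %in% clique
  expect_equal(sum(in_clique), 276)

  # degree distribution of any generated network normalizes to 1
  sf <- generate_network(500, "scale_free", seed = 3)
  prof <- compute_degree_profiles(build_network(sf$edges))
  expect_equal(sum(prof$p_k), 1)

  # no self-pairs, no duplicate unordered pairs, scores in [0, 1] (property)
  for (seed in 1:5) {
    e <- generate_network(60, "planted_modules",
                          params = list(module_sizes = c(8L, 5L),
                                        noise_p = 0.05), seed = seed)$edges
    expect_false(any(e$gene_a == e$gene_b))
    key <- paste(pmin(e$gene_a, e$gene_b), pmax(e$gene_a, e$gene_b))
    expect_false(anyDuplicated(key) > 0)
    expect_true(all(e$score >= 0 & e$score <= 1))
  }

  expect_error(generate_network(10, "smallworld"), "unknown network model")
  expect_error(generate_network(10, "scale_free", params = list(m = 0)),
               "attachment")
})

test_that("ortholog table generator honours coverage and one-to-many rate", {
  src <- sprintf("G%02d", 1:10)
  expect_equal(nrow(generate_ortholog_table(src, coverage = 0, seed = 1)), 0)

  t10 <- generate_ortholog_table(src, coverage = 1, one_to_many_rate = 0,
                                 seed = 1)
  expect_equal(nrow(t10), 10)
  expect_equal(length(unique(t10$target_gene)), 10)

  t20 <- generate_ortholog_table(src, coverage = 1, one_to_many_rate = 1,
                                 seed = 1)
  expect_equal(nrow(t20), 20)
  expect_false(anyDuplicated(paste(t20$source_gene, t20$target_gene)) > 0)
})

test_that("annotation generator plants over-represented terms", {
  universe <- sprintf("G%03d", 1:200)
  target <- universe[1:40]

  g0 <- generate_annotations(universe, 10, planted_terms = 0, seed = 1)
  expect_length(g0$truth$enriched_terms, 0)

  expect_error(generate_annotations(universe, 5, planted_terms = 6,
                                    target_set = target, seed = 1),
               "planted_terms")

  # identical seed twice -> identical GMT files
  g1 <- generate_annotations(universe, 15, planted_terms = 3,
                             target_set = target, seed = 9)
  g2 <- generate_annotations(universe, 15, planted_terms = 3,
                             target_set = target, seed = 9)
  f1 <- tempfile(); f2 <- tempfile()
  write_gmt(g1$terms, f1); write_gmt(g2$terms, f2)
  expect_identical(readLines(f1), readLines(f2))

  # planted terms overlap the target set far above their uniform share
  for (id in g1$truth$enriched_terms) {
    t <- g1$terms[[which(vapply(g1$terms, `[[`, character(1),
                                "term_id") == id)]]
    frac <- length(intersect(t$members, target)) / length(t$members)
    expect_gt(frac, 2 * length(target) / length(universe))
  }

  # a term equal to the target set: fold enrichment is M / |target| when the
  # query is the target set itself
  term <- list(list(term_id = "hsa09999", name = "pathway",
                    category = "pathway", members = target))
  r <- enrich(target, term, background = universe)
  expect_equal(r$fold_enrichment, length(universe) / length(target))
})
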