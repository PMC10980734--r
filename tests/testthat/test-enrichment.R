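term <- function(id, members, category = "pathway")
  list(term_id = id, name = category, category = category, members = members)

test_that("GMT parsing collapses duplicates and rejects bad collections", {
  f <- tempfile()
  writeLines(c("T1\tdesc\tA\tB\tA", "T2\tdesc\tC\tD"), f)
  terms <- read_gmt(f)
  expect_setequal(terms[[1]]$members, c("A", "B"))

  writeLines(c("T1\tdesc\tA", "short\trow"), f)
  expect_warning(t2 <- read_gmt(f), "<3 fields")
  expect_length(t2, 1)

  writeLines(character(0), f)
  expect_error(read_gmt(f), "no valid gene-set rows")

  writeLines(c("T1\td\tA", "T1\td\tB"), f)
  expect_error(read_gmt(f), "T1")
})

test_that("hypergeometric p-values match closed form and enumeration", {
  bg <- paste0("g", 1:20)
  r <- enrich(paste0("g", 1:5), list(term("T", paste0("g", 1:5))),
              background = bg)
  expect_equal(r$p_value, 1 / choose(20, 5), tolerance = 1e-12)
  expect_equal(r$fold_enrichment, 4)

  # zero overlap is never significant
  r0 <- enrich(paste0("g", 6:10), list(term("T", paste0("g", 1:5))),
               background = bg)
  expect_equal(r0$p_value, 1)

  # exhaustive enumeration over all draws, small random instances
  set.seed(1)
  for (i in 1:20) {
    M <- sample(6:15, 1)
    K <- sample(1:(M - 1), 1)
    n <- sample(1:(M - 1), 1)
    genes <- paste0("g", seq_len(M))
    q <- sample(genes, n)
    r <- enrich(q, list(term("T", genes[seq_len(K)])), background = genes)
    expect_equal(r$p_value, hyper_tail_oracle(M, K, n, r$k_overlap),
                 tolerance = 1e-9)
  }
})

test_that("p-values shrink with overlap and EASE is conservative", {
  bg <- paste0("g", 1:40)
  p_at_k <- vapply(1:8, function(k) {
    q <- c(paste0("g", seq_len(k)),
           if (k < 8) paste0("g", 30 + seq_len(8 - k)))
    enrich(q, list(term("T", paste0("g", 1:8))), background = bg)$p_value
  }, numeric(1))
  expect_true(all(diff(p_at_k) <= 0))

  for (k in 1:5) {
    q <- c(paste0("g", seq_len(k)),
           if (k < 5) paste0("g", 30 + seq_len(5 - k)))
    std <- enrich(q, list(term("T", paste0("g", 1:8))), background = bg)
    ease <- enrich(q, list(term("T", paste0("g", 1:8))), background = bg,
                   ease = TRUE)
    expect_gte(ease$p_value, std$p_value)
  }
})

test_that("fold enrichment centres on 1 for uniform random queries", {
  set.seed(7)
  bg <- paste0("g", 1:500)
  terms <- list(term("T", bg[1:100]))
  fe <- vapply(1:200, function(i)
    enrich(sample(bg, 50), terms, background = bg)$fold_enrichment,
    numeric(1))
  se <- stats::sd(fe) / sqrt(length(fe))
  expect_lt(abs(mean(fe) - 1), 3 * se)
})

test_that("BH adjustment reproduces the step-up computation", {
  expect_equal(bh_adjust(0.05), 0.05)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  p <- stats::runif(50)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))
  ord <- order(p)
  expect_true(all(diff(adj[ord]) >= -1e-15))
  expect_error(bh_adjust(c(0.5, 0)), "0, 1")
  expect_error(bh_adjust(1.2), "0, 1")
})

test_that("cross-species comparison keeps terms significant in both", {
  mk <- function(ids, ps) data.frame(
    term_id = ids, name = "pathway", category = "pathway",
    k_overlap = 5L, n_query = 50L, K_term = 20L, M_background = 500L,
    fold_enrichment = 2, p_value = ps, adj_p = bh_adjust(ps),
    stringsAsFactors = FALSE)
  ids_h <- sprintf("hsa%05d", 4001:4015)
  ids_w <- sprintf("cel%05d", 4001:4015)
  # exactly 9 shared significant pathways; 04010-like pattern
  p_h <- c(rep(1e-4, 9), rep(1e-4, 3), rep(0.5, 3))
  p_w <- c(rep(1e-3, 9), rep(0.5, 3), rep(1e-3, 3))
  res <- compare_species(mk(ids_h, p_h), mk(ids_w, p_w),
                         kegg_crosswalk(ids_h, ids_w))
  expect_equal(nrow(res), 9)
  expect_setequal(res$term_a, ids_h[1:9])
  expect_true(all(res$p_a <= 0.05 & res$p_b <= 0.05))

  expect_error(compare_species(mk(ids_h, p_h), mk(ids_w, p_w),
                               character(0)), "crosswalk is empty")
})

test_that("KEGG identifiers crosswalk on their numeric suffix", {
  expect_equal(kegg_suffix(c("hsa04010", "cel04010", "map01100")),
               c("04010", "04010", "01100"))
  cw <- kegg_crosswalk(c("hsa04010", "hsa99999"), c("cel04010", "cel00020"))
  expect_equal(unname(cw), "cel04010")
  expect_equal(names(cw), "hsa04010")
})
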