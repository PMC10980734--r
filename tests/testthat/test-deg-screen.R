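make_dataset <- function(case, ctrl, genes = NULL, id = "d1") {
  m <- cbind(case, ctrl)
  if (is.null(genes)) genes <- sprintf("G%03d", seq_len(nrow(m)))
  rownames(m) <- genes
  colnames(m) <- c(sprintf("c%02d", seq_len(ncol(case))),
                   sprintf("h%02d", seq_len(ncol(ctrl))))
  expression_dataset(m, c(rep("case", ncol(case)),
                          rep("control", ncol(ctrl))), dataset_id = id)
}

test_that("gene statistics give difference-of-means fold changes", {
  ds <- make_dataset(matrix(c(2, 2, 1, 1), 2, 2, byrow = TRUE),
                     matrix(c(1, 1, 1, 1), 2, 2, byrow = TRUE))
  st <- compute_gene_stats(ds)
  expect_equal(st$log2fc, c(1, 0))
  # identical case and control values -> zero effect, p = 1 by convention
  expect_equal(st$p_value[2], 1)
  expect_equal(st$direction, c("none", "none"))
})

test_that("groups with fewer than 2 samples are rejected by name", {
  m <- matrix(rnorm(12), 3, 4,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  ds <- expression_dataset(m, c("case", "control", "control", "control"))
  expect_error(compute_gene_stats(ds), "'case'")
})

test_that("null simulation holds the nominal type-I error", {
  g <- generate_expression(4000, 10, 10, n_de = 0, sigma = 0.5, seed = 42)
  st <- compute_gene_stats(g$dataset)
  frac <- mean(st$p_value <= 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 4000))
})

test_that("the screen applies the p threshold and fold-change band", {
  st <- data.frame(gene = c("A", "B", "C", "D"),
                   log2fc = c(0.5, 0.5, -2.0, 0.1),
                   p_value = c(0.01, 0.2, 0.001, 0.01),
                   adj_p = c(0.04, 0.4, 0.004, 0.04),
                   direction = "none", stringsAsFactors = FALSE)
  kept <- screen_degs(st)
  expect_equal(kept$gene, "A")        # B: p too large; C: |lfc| above band;
  expect_equal(kept$direction, "up")  # D: |lfc| below band
  wide <- screen_degs(st, lfc_max = Inf)
  expect_setequal(wide$gene, c("A", "C"))
  expect_equal(wide$direction[wide$gene == "C"], "down")
  expect_error(screen_degs(st, lfc_min = 2, lfc_max = 1), "lfc_min")
})

test_that("planted effects are recovered with matching directions", {
  g <- generate_expression(1000, 20, 20, n_de = 100, effect_size = 1,
                           sigma = 0.5, seed = 11)
  st <- compute_gene_stats(g$dataset)
  kept <- screen_degs(st)
  recovered <- intersect(kept$gene, g$truth$de_genes)
  expect_gte(length(recovered) / length(g$truth$de_genes), 0.9)
  dir_est <- kept$direction[match(recovered, kept$gene)]
  dir_true <- ifelse(g$truth$de_direction[recovered] > 0, "up", "down")
  expect_equal(dir_est, unname(dir_true))
})

test_that("merging de-duplicates, records provenance, and flags conflicts", {
  t1 <- data.frame(gene = c("GENE1", "GENE2"), direction = c("up", "up"),
                   stringsAsFactors = FALSE)
  attr(t1, "dataset_id") <- "ds1"
  t2 <- data.frame(gene = c("GENE1", "GENE2"), direction = c("up", "down"),
                   stringsAsFactors = FALSE)
  attr(t2, "dataset_id") <- "ds2"
  m <- merge_deg_tables(list(t1, t2))
  expect_equal(nrow(m), 2)
  expect_equal(m$datasets[m$gene == "GENE1"], "ds1,ds2")
  expect_equal(m$direction[m$gene == "GENE1"], "up")
  expect_true(m$conflict[m$gene == "GENE2"])
  expect_equal(m$direction[m$gene == "GENE2"], "conflict")

  # disjoint tables of sizes 3 and 4 merge to 7
  t3 <- data.frame(gene = paste0("A", 1:3), direction = "up")
  t4 <- data.frame(gene = paste0("B", 1:4), direction = "down")
  expect_equal(nrow(merge_deg_tables(list(t3, t4))), 7)

  # idempotence: merging a merged table with itself changes nothing
  expect_identical(merge_deg_tables(list(m)), m)
  expect_identical(merge_deg_tables(list(m, m)), m)

  expect_error(merge_deg_tables(list()), "at least one")
})
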