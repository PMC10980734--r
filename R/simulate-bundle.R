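# One-call emission of a complete synthetic input bundle: expression
# matrices, group files, human and worm edge tables, an ortholog table, and
# two GMT collections, together with the ground truth and a ready-to-run
# pipeline configuration.

#' Write an expression dataset as TSV files
#'
#' @param dataset an `expression_dataset`.
#' @param matrix_path,groups_path output paths.
#' @return invisibly, the two paths.
#' @export
write_expression <- function(dataset, matrix_path, groups_path) {
  tab <- data.frame(gene = rownames(dataset$matrix), dataset$matrix,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(tab, matrix_path)
  write_tsv(data.frame(sample = colnames(dataset$matrix),
                       group = dataset$groups), groups_path)
  invisible(c(matrix_path, groups_path))
}

#' Generate and write a complete synthetic pipeline bundle
#'
#' Emulates, at desk scale and with known ground truth, the inputs of a
#' cross-species disease-network study: two case/control expression datasets
#' with planted DE genes; a hub-dominated (preferential-attachment) human
#' interaction network over the gene universe; an ortholog table projecting
#' human genes onto worm-style gene names; a worm interaction network with
#' planted dense modules (the largest a 24-clique) among the ortholog
#' targets; and KEGG-style annotation collections for both species with
#' matched planted pathways.
#'
#' @param dir output directory (created if missing).
#' @param seed integer master seed; stage seeds are derived from it.
#' @param n_genes gene universe size per dataset (default 600).
#' @param n_de planted DE genes per dataset (default 80).
#' @param n_samples samples per group per dataset (default 12).
#' @param effect_size,sigma planted log2 effect and noise sd (defaults 1
#'   and 0.5).
#' @param module_sizes planted worm module sizes (default `c(24, 12, 8)`).
#' @param noise_p worm network background edge probability (default 0.02).
#' @param n_terms terms per annotation collection (default 40).
#' @param planted_terms planted (enriched) terms per collection (default 9).
#' @return list with `config` (ready for [run_pipeline()]), `truth`
#'   (per-stage `synthetic_truth` objects) and `paths`.
#' @export
simulate_bundle <- function(dir, seed = 1L, n_genes = 600L, n_de = 80L,
                            n_samples = 12L, effect_size = 1, sigma = 0.5,
                            module_sizes = c(24L, 12L, 8L), noise_p = 0.02,
                            n_terms = 40L, planted_terms = 9L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(dir, ...)
  truth <- list()

  # expression: two datasets over the same universe, planted DE genes
  ds <- lapply(1:2, function(i) {
    generate_expression(n_genes, n_samples, n_samples, n_de = n_de,
                        effect_size = effect_size, sigma = sigma,
                        seed = seed + i, dataset_id = sprintf("sim%02d", i))
  })
  for (i in 1:2)
    write_expression(ds[[i]]$dataset,
                     p(sprintf("expr%02d.tsv", i)),
                     p(sprintf("groups%02d.tsv", i)))
  truth$expression <- lapply(ds, `[[`, "truth")
  genes <- rownames(ds[[1]]$dataset$matrix)

  # human network: preferential attachment over the gene universe; dense
  # enough that its restriction to the screened DEG list keeps the
  # hub-dominated shape of disease PPI networks
  hn <- generate_network(n_genes, "scale_free", params = list(m = 10L),
                         seed = seed + 11L, node_names = genes)
  write_tsv(hn$edges, p("human_edges.tsv"))
  truth$human_network <- hn$truth

  # ortholog table over the human universe
  ot <- generate_ortholog_table(genes, coverage = 0.8,
                                one_to_many_rate = 0.25, seed = seed + 21L,
                                evidence = "simdb")
  write_tsv(ot, p("orthologs.tsv"))

  # Replay the human half of the analysis so the worm inputs are planted
  # inside the gene set the pipeline will actually reach: DEG screen ->
  # merge -> human network -> key regulators -> closed neighbourhood ->
  # ortholog projection.
  deg_tables <- lapply(ds, function(d)
    screen_degs(compute_gene_stats(d$dataset)))
  merged <- merge_deg_tables(deg_tables)
  human_net <- build_network(hn$edges, node_whitelist = merged$gene,
                             uppercase = TRUE)
  hm <- compute_node_metrics(human_net)
  kr <- intersect_top(lapply(c("degree", "betweenness", "closeness"),
                             function(m) top_n_genes(hm, m, 20L)))
  hood <- suppressWarnings(closed_first_neighborhood(human_net, kr$genes))
  projected <- project_genes(hood, ot)$genes

  # worm network: planted cliques + noise over the projected genes
  if (sum(module_sizes) > length(projected))
    stop2("projected gene set too small for the requested planted modules")
  wn <- generate_network(length(projected), "planted_modules",
                         params = list(module_sizes = module_sizes,
                                       noise_p = noise_p),
                         seed = seed + 31L, node_names = projected)
  write_tsv(wn$edges, p("worm_edges.tsv"))
  truth$worm_network <- wn$truth

  # annotations: matched planted pathways in both species. Human terms are
  # built over the planted DE genes; worm terms over their projected
  # orthologs, so the same numeric pathway ids light up in both species.
  de_union <- sort(unique(unlist(lapply(truth$expression,
                                        `[[`, "de_genes"))))
  ga_h <- generate_annotations(genes, n_terms,
                               term_size_range = c(10L, 40L),
                               planted_terms = planted_terms,
                               target_set = de_union, seed = seed + 41L,
                               id_prefix = "hsa")
  worm_targets <- sort(unique(intersect(
    ot$target_gene[ot$source_gene %in% de_union], projected)))
  # annotation universe = all ortholog targets, wider than the projected
  # query set, so the enrichment background is a proper superset
  worm_universe <- sort(unique(ot$target_gene))
  ga_w <- generate_annotations(worm_universe, n_terms,
                               term_size_range = c(10L, 40L),
                               planted_terms = planted_terms,
                               target_set = worm_targets, seed = seed + 42L,
                               id_prefix = "cel")
  write_gmt(ga_h$terms, p("human.gmt"))
  write_gmt(ga_w$terms, p("worm.gmt"))
  truth$annotations <- list(human = ga_h$truth, worm = ga_w$truth)

  config <- pipeline_config(
    datasets = lapply(1:2, function(i) list(
      id = sprintf("sim%02d", i),
      matrix = p(sprintf("expr%02d.tsv", i)),
      groups = p(sprintf("groups%02d.tsv", i)))),
    human_edges = p("human_edges.tsv"),
    ortholog_tables = list(list(path = p("orthologs.tsv"),
                                label = "simdb")),
    worm_edges = p("worm_edges.tsv"),
    gmt_human = p("human.gmt"),
    gmt_worm = p("worm.gmt"),
    outdir = p("out"))
  list(config = config, truth = truth,
       paths = list(dir = dir))
}
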