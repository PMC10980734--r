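# End-to-end orchestration: DEG screen -> merge -> human network ->
# centralities -> key regulators -> closed neighbourhood -> ortholog
# projection -> worm network -> worm centralities (incl. bottleneck) -> worm
# key regulators -> MCODE modules -> dual enrichment -> cross-species
# comparison. Every stage writes its table; a JSON manifest records counts
# and effective parameters.

#' Pipeline configuration
#'
#' Collects all file paths and stage parameters. Defaults follow the
#' conventional thresholds of the analysis: DEG screen p <= 0.05 with
#' |log2fc| in \[0.25, 1.5\]; edge score >= 0.4; top-N 20; human key
#' regulators from 3 metrics (degree, betweenness, closeness) and worm key
#' regulators from 4 (adding bottleneck); MCODE 2 / 0.2 / 2 / 100 with module
#' score >= 5; enrichment alpha 0.05 on raw p.
#'
#' @param datasets list of dataset descriptors, each a list with `id`,
#'   `matrix` (expression TSV path) and `groups` (group TSV path).
#' @param human_edges path to the human scored edge table.
#' @param ortholog_tables list of descriptors with `path` and `label`.
#' @param worm_edges path to the model-organism scored edge table.
#' @param gmt_human,gmt_worm paths to the two GMT collections.
#' @param outdir output directory.
#' @param params named list overriding any default parameter (see Details).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(datasets, human_edges, ortholog_tables,
                            worm_edges, gmt_human, gmt_worm,
                            outdir = "pipeline_out", params = list()) {
  defaults <- list(
    p_max = 0.05, lfc_min = 0.25, lfc_max = 1.5, use_adjusted = FALSE,
    score_min = 0.4, top_n = 20L,
    human_metrics = c("degree", "betweenness", "closeness"),
    worm_metrics = c("degree", "betweenness", "closeness", "bottleneck"),
    mcode = mcode_params(), min_module_score = 5,
    enrich_alpha = 0.05, enrich_use_adjusted = FALSE, ease = FALSE,
    uppercase_human = TRUE)
  unknown <- setdiff(names(params), names(defaults))
  if (length(unknown))
    stop2("unknown pipeline parameter(s): ", paste(unknown, collapse = ", "))
  defaults[names(params)] <- params
  structure(list(datasets = datasets, human_edges = human_edges,
                 ortholog_tables = ortholog_tables, worm_edges = worm_edges,
                 gmt_human = gmt_human, gmt_worm = gmt_worm,
                 outdir = outdir, params = defaults),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with the fields of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  pars <- y$params %||% list()
  if (!is.null(pars$mcode)) pars$mcode <- do.call(mcode_params, pars$mcode)
  pipeline_config(datasets = y$datasets, human_edges = y$human_edges,
                  ortholog_tables = y$ortholog_tables,
                  worm_edges = y$worm_edges, gmt_human = y$gmt_human,
                  gmt_worm = y$gmt_worm,
                  outdir = y$outdir %||% "pipeline_out", params = pars)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop2(sprintf("pipeline stage '%s' failed: %s", name,
                  conditionMessage(e))))
}

#' Run the full cross-species analysis pipeline
#'
#' Executes every stage in order, writes all intermediate tables under
#' `config$outdir`, and returns a `pipeline_result` whose `manifest` records
#' stage counts, effective parameters and input checksums. Any stage failure
#' aborts with the stage name; tables already written are retained.
#'
#' @param config a [pipeline_config()].
#' @return a `pipeline_result` list: `manifest`, per-stage tables, and the
#'   path of the written manifest JSON.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  pars <- config$params
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  op <- function(...) file.path(out, ...)

  input_files <- c(
    vapply(config$datasets, function(d) d$matrix, character(1)),
    vapply(config$datasets, function(d) d$groups, character(1)),
    config$human_edges,
    vapply(config$ortholog_tables %||% list(), function(t) t$path,
           character(1)),
    config$worm_edges, config$gmt_human, config$gmt_worm)
  checksums <- run_stage("inputs", {
    missing <- input_files[!file.exists(input_files)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "))
    md5 <- tools::md5sum(input_files)
    stats::setNames(unname(md5), basename(input_files))
  })

  # 1. per-dataset DEG screen
  deg_tables <- run_stage("deg_screen", lapply(config$datasets, function(d) {
    ds <- read_expression(d$matrix, d$groups, dataset_id = d$id)
    st <- compute_gene_stats(ds)
    kept <- screen_degs(st, p_max = pars$p_max, lfc_min = pars$lfc_min,
                        lfc_max = pars$lfc_max,
                        use_adjusted = pars$use_adjusted)
    write_tsv(kept[, c("gene", "log2fc", "p_value", "adj_p", "direction")],
              op(sprintf("deg_%s.tsv", d$id)))
    kept
  }))

  # 2. merge
  merged <- run_stage("deg_merge", merge_deg_tables(deg_tables))
  write_tsv(merged, op("deg_merged.tsv"))

  # 3. human network restricted to the merged DEG list
  human_net <- run_stage("human_network", {
    e <- read_edge_table(config$human_edges, score_min = pars$score_min)
    build_network(e, node_whitelist = merged$gene,
                  uppercase = pars$uppercase_human)
  })
  write_tsv(human_net$edges, op("human_network_edges.tsv"))

  # 4. human centralities
  human_metrics <- run_stage("human_metrics", compute_node_metrics(human_net))
  write_tsv(human_metrics, op("human_metrics.tsv"))

  # 5. human key regulators
  human_lists <- run_stage("human_kr", lapply(
    pars$human_metrics, function(m)
      top_n_genes(human_metrics, m, n = pars$top_n)))
  human_kr <- intersect_top(human_lists)
  write_tsv(data.frame(gene = human_kr$genes), op("human_kr.tsv"))

  # 6. closed first neighbourhood of the KRs
  neighborhood <- run_stage("neighborhood",
                            closed_first_neighborhood(human_net,
                                                      human_kr$genes))
  writeLines(neighborhood, op("human_kr_neighborhood.txt"))

  # 7. ortholog projection
  projection <- run_stage("ortholog_projection", {
    if (is.null(config$ortholog_tables) ||
        length(config$ortholog_tables) == 0L)
      stop("no ortholog table configured")
    tabs <- lapply(config$ortholog_tables, function(t)
      read_ortholog_table(t$path, t$label))
    project_genes(neighborhood, merge_ortholog_tables(tabs))
  })
  writeLines(projection$genes, op("worm_genes.txt"))

  # 8. worm network restricted to the projected genes
  worm_net <- run_stage("worm_network", {
    e <- read_edge_table(config$worm_edges, score_min = pars$score_min)
    build_network(e, node_whitelist = projection$genes, uppercase = FALSE)
  })
  write_tsv(worm_net$edges, op("worm_network_edges.tsv"))

  # 9-10. worm centralities and key regulators (4 metrics incl. bottleneck)
  worm_metrics <- run_stage("worm_metrics", compute_node_metrics(worm_net))
  write_tsv(worm_metrics, op("worm_metrics.tsv"))
  worm_lists <- run_stage("worm_kr", lapply(
    pars$worm_metrics, function(m)
      top_n_genes(worm_metrics, m, n = pars$top_n)))
  worm_kr <- intersect_top(worm_lists)
  write_tsv(data.frame(gene = worm_kr$genes), op("worm_kr.tsv"))

  # 11. MCODE modules on the worm network + score filter
  modules <- run_stage("mcode", mcode(worm_net, pars$mcode))
  modules_kept <- filter_modules(modules, pars$min_module_score)
  write_tsv(module_table(modules), op("modules_all.tsv"))
  write_tsv(module_table(modules_kept), op("modules_significant.tsv"))

  # 12. dual enrichment
  terms_h <- run_stage("enrichment_human", read_gmt(config$gmt_human))
  terms_w <- run_stage("enrichment_worm", read_gmt(config$gmt_worm))
  enr_h <- run_stage("enrichment_human",
                     enrich(merged$gene, terms_h, ease = pars$ease))
  enr_w <- run_stage("enrichment_worm",
                     enrich(projection$genes, terms_w, ease = pars$ease))
  write_tsv(enr_h, op("enrichment_human.tsv"))
  write_tsv(enr_w, op("enrichment_worm.tsv"))

  # 13. cross-species comparison
  common <- run_stage("compare_species", {
    cw <- kegg_crosswalk(enr_h$term_id, enr_w$term_id)
    compare_species(enr_h, enr_w, cw, alpha = pars$enrich_alpha,
                    use_adjusted = pars$enrich_use_adjusted)
  })
  write_tsv(common, op("common_terms.tsv"))

  kr_in_modules <- lapply(modules_kept, function(m)
    intersect(worm_kr$genes, m$nodes))

  manifest <- list(
    parameters = list(
      p_max = pars$p_max, lfc_band = c(pars$lfc_min, pars$lfc_max),
      use_adjusted = pars$use_adjusted, score_min = pars$score_min,
      top_n = pars$top_n, human_metrics = pars$human_metrics,
      worm_metrics = pars$worm_metrics,
      mcode = unclass(pars$mcode),
      min_module_score = pars$min_module_score,
      enrich_alpha = pars$enrich_alpha),
    input_checksums = as.list(checksums),
    counts = list(
      degs_per_dataset = stats::setNames(
        vapply(deg_tables, nrow, integer(1)),
        vapply(config$datasets, function(d) d$id, character(1))),
      merged_degs = nrow(merged),
      merged_up = sum(merged$direction == "up"),
      merged_down = sum(merged$direction == "down"),
      direction_conflicts = sum(merged$conflict),
      human_nodes = n_nodes(human_net), human_edges = n_edges(human_net),
      human_kr = length(human_kr$genes),
      neighborhood = length(neighborhood),
      neighborhood_non_seed = length(neighborhood) -
        sum(human_kr$genes %in% human_net$nodes),
      orthologs_mapped = projection$report$mapped,
      orthologs_unmapped = projection$report$unmapped,
      worm_genes = projection$report$n_targets,
      worm_nodes = n_nodes(worm_net), worm_edges = n_edges(worm_net),
      worm_kr = length(worm_kr$genes),
      modules_total = length(modules),
      modules_kept = length(modules_kept),
      common_terms = nrow(common)),
    human_kr = human_kr$genes,
    worm_kr = worm_kr$genes,
    top_modules = lapply(modules_kept, function(m)
      list(module_id = m$module_id, n_nodes = m$n_nodes,
           n_edges = m$n_edges, score = round(m$score, 3),
           seed_gene = m$seed_gene)),
    kr_in_modules = kr_in_modules)

  manifest_path <- op("manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  structure(list(
    manifest = manifest, manifest_path = manifest_path, outdir = out,
    tables = list(merged_degs = merged, human_metrics = human_metrics,
                  worm_metrics = worm_metrics,
                  modules = modules, modules_kept = modules_kept,
                  enrichment_human = enr_h, enrichment_worm = enr_w,
                  common_terms = common),
    human_kr = human_kr, worm_kr = worm_kr,
    networks = list(human = human_net, worm = worm_net)),
    class = "pipeline_result")
}

#' Write human-readable report tables from a pipeline result
#'
#' Emits the reporting artifacts of the analysis: top-10 centrality tables
#' per species, the key-regulator module-membership table, the significant
#' module summary (3-decimal scores), and the common-pathway table with both
#' species' p-values (an explicit zero-row note when no term is shared).
#'
#' @param result a `pipeline_result` from [run_pipeline()].
#' @param dir output directory (default: the pipeline outdir + `/report`).
#' @return character vector of written file paths, invisibly.
#' @export
write_report <- function(result, dir = file.path(result$outdir, "report")) {
  required <- c("manifest", "tables", "human_kr", "worm_kr")
  missing <- required[!required %in% names(result)]
  if (length(missing) == 0L) {
    tabs <- c("human_metrics", "worm_metrics", "modules_kept", "common_terms")
    missing <- paste0("tables$", tabs[!tabs %in% names(result$tables)])
    missing <- missing[missing != "tables$"]
    if (all(tabs %in% names(result$tables))) missing <- character(0)
  }
  if (length(missing))
    stop2("incomplete pipeline result; missing: ",
          paste(missing, collapse = ", "))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (sp in c("human", "worm")) {
    metrics <- result$tables[[paste0(sp, "_metrics")]]
    for (m in c("degree", "betweenness", "closeness", "bottleneck")) {
      rl <- top_n_genes(metrics, m, n = 10L)
      f <- file.path(dir, sprintf("top10_%s_%s.tsv", sp, m))
      write_tsv(data.frame(rank = seq_along(rl$genes), gene = rl$genes,
                           value = metrics[[m]][match(rl$genes,
                                                      metrics$gene)]), f)
      paths <- c(paths, f)
    }
  }
  mt <- module_table(result$tables$modules_kept)
  f <- file.path(dir, "module_summary.tsv")
  write_tsv(mt, f); paths <- c(paths, f)

  membership <- do.call(rbind, lapply(result$tables$modules_kept, function(m)
    data.frame(module_id = m$module_id,
               key_regulators = paste(intersect(result$worm_kr$genes,
                                                m$nodes), collapse = ","),
               stringsAsFactors = FALSE)))
  if (is.null(membership))
    membership <- data.frame(module_id = integer(0),
                             key_regulators = character(0))
  f <- file.path(dir, "kr_module_membership.tsv")
  write_tsv(membership, f); paths <- c(paths, f)

  common <- result$tables$common_terms
  f <- file.path(dir, "common_terms.tsv")
  if (nrow(common) == 0L) {
    writeLines(c("term_a\tterm_b\tname\tp_a\tp_b",
                 "0 common terms\t\t\t\t"), f)
  } else {
    write_tsv(common[, c("term_a", "term_b", "name", "p_a", "p_b")], f)
  }
  paths <- c(paths, f)
  invisible(paths)
}
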