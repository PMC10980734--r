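# Synthetic inputs with known ground truth: two-group log2 expression
# matrices with planted differentially expressed genes, scored interaction
# networks (preferential-attachment or planted dense modules), one-to-many
# ortholog tables, and GMT annotations with planted enriched terms. Every
# generator is a pure function of its arguments including the seed.

new_truth <- function(de_genes = character(0), de_direction = integer(0),
                      planted_modules = list(), enriched_terms = character(0),
                      seed = NA_integer_) {
  structure(list(de_genes = de_genes, de_direction = de_direction,
                 planted_modules = planted_modules,
                 enriched_terms = enriched_terms, seed = seed),
            class = "synthetic_truth")
}

#' Generate a two-group log2 expression matrix with planted DE genes
#'
#' Non-DE genes are Gaussian noise around a gene-specific baseline with equal
#' group means; planted DE genes have their case-group mean shifted by
#' `effect_size` log2 units, signs alternating so roughly half the planted
#' genes go up and half down.
#'
#' @param n_genes,n_case,n_control positive dimensions.
#' @param n_de number of planted differentially expressed genes
#'   (`n_de <= n_genes`).
#' @param effect_size case-mean shift in log2 units (default 1).
#' @param sigma Gaussian noise standard deviation on the log2 scale
#'   (default 0.5).
#' @param seed integer random seed.
#' @param dataset_id dataset label.
#' @return list with `dataset` (an `expression_dataset`) and `truth` (a
#'   `synthetic_truth` whose `de_genes` / `de_direction` record the planted
#'   genes and their signs).
#' @export
generate_expression <- function(n_genes, n_case, n_control, n_de = 0L,
                                effect_size = 1, sigma = 0.5, seed = 1L,
                                dataset_id = "synthetic") {
  n_genes <- assert_count(n_genes, "n_genes")
  n_case <- assert_count(n_case, "n_case")
  n_control <- assert_count(n_control, "n_control")
  n_de <- assert_count(n_de, "n_de", min = 0L)
  assert_positive(sigma, "sigma")
  if (n_de > n_genes) stop2("`n_de` must not exceed `n_genes`")
  set.seed(seed)
  genes <- sprintf("GENE%05d", seq_len(n_genes))
  samples <- c(sprintf("case_%02d", seq_len(n_case)),
               sprintf("ctrl_%02d", seq_len(n_control)))
  base <- stats::runif(n_genes, 6, 10)
  m <- base + matrix(stats::rnorm(n_genes * length(samples), sd = sigma),
                     n_genes, length(samples))
  dimnames(m) <- list(genes, samples)
  de_idx <- if (n_de > 0L) sort(sample.int(n_genes, n_de)) else integer(0)
  dirs <- rep(c(1L, -1L), length.out = n_de)
  if (n_de > 0L)
    m[de_idx, seq_len(n_case)] <- m[de_idx, seq_len(n_case)] +
      dirs * effect_size
  groups <- c(rep("case", n_case), rep("control", n_control))
  list(dataset = expression_dataset(m, groups, dataset_id),
       truth = new_truth(de_genes = genes[de_idx],
                         de_direction = stats::setNames(dirs, genes[de_idx]),
                         seed = seed))
}

#' Generate a scored interaction network with known structure
#'
#' `model = "scale_free"` grows a hub-dominated network by preferential
#' attachment (`params$m` edges per arriving node, default 2). `model =
#' "planted_modules"` embeds cliques of sizes `params$module_sizes` on
#' disjoint node blocks and superimposes background noise edges drawn
#' independently with probability `params$noise_p` (default 0.02); colliding
#' edges are kept once. Edge confidence scores are drawn uniformly on
#' \[0.5, 1\].
#'
#' @param n_nodes number of nodes.
#' @param model `"scale_free"` or `"planted_modules"`.
#' @param params model parameters (see above).
#' @param seed integer random seed.
#' @param node_names optional character vector of node names (default
#'   `N0001`, `N0002`, ...).
#' @return list with `edges` (data frame `gene_a`, `gene_b`, `score`, no
#'   self-pairs, no duplicate unordered pairs) and `truth` (planted module
#'   node sets, if any).
#' @export
generate_network <- function(n_nodes, model = c("scale_free",
                                                "planted_modules"),
                             params = list(), seed = 1L, node_names = NULL) {
  n_nodes <- assert_count(n_nodes, "n_nodes")
  if (length(model) != 1L || !model %in% c("scale_free", "planted_modules"))
    stop2("unknown network model '", paste(model, collapse = "/"),
          "'; use 'scale_free' or 'planted_modules'")
  if (is.null(node_names)) node_names <- sprintf("N%04d", seq_len(n_nodes))
  if (length(node_names) != n_nodes)
    stop2("`node_names` must have length `n_nodes`")
  set.seed(seed)
  planted <- list()
  if (model == "scale_free") {
    m_attach <- as.integer(params$m %||% 2L)
    if (m_attach < 1L) stop2("attachment count `params$m` must be >= 1")
    g <- igraph::sample_pa(n_nodes, power = 1, m = m_attach, directed = FALSE)
    el <- igraph::as_edgelist(g, names = FALSE)
    ea <- pmin(el[, 1], el[, 2]); eb <- pmax(el[, 1], el[, 2])
  } else {
    sizes <- as.integer(params$module_sizes %||% integer(0))
    if (any(sizes > n_nodes)) stop2("planted module sizes must be <= n_nodes")
    if (sum(sizes) > n_nodes)
      stop2("planted modules must fit on disjoint node blocks")
    noise_p <- assert_fraction(params$noise_p %||% 0.02, "params$noise_p")
    ea <- integer(0); eb <- integer(0)
    offset <- 0L
    for (s in sizes) {
      block <- offset + seq_len(s)
      if (s >= 2L) {
        pairs <- utils::combn(block, 2L)
        ea <- c(ea, pairs[1L, ]); eb <- c(eb, pairs[2L, ])
      }
      planted[[length(planted) + 1L]] <- node_names[block]
      offset <- offset + s
    }
    if (noise_p > 0 && n_nodes >= 2L) {
      up <- which(upper.tri(matrix(0L, n_nodes, n_nodes)), arr.ind = TRUE)
      hit <- stats::runif(nrow(up)) < noise_p
      ea <- c(ea, up[hit, 1L]); eb <- c(eb, up[hit, 2L])
    }
  }
  key <- paste(ea, eb)
  first <- !duplicated(key)
  ea <- ea[first]; eb <- eb[first]
  edges <- data.frame(gene_a = node_names[ea], gene_b = node_names[eb],
                      score = round(stats::runif(length(ea), 0.5, 1), 3),
                      stringsAsFactors = FALSE)
  list(edges = edges,
       truth = new_truth(planted_modules = planted, seed = seed))
}

#' Generate a one-to-many ortholog table
#'
#' Approximately `coverage * length(source_genes)` source genes receive at
#' least one target; a `one_to_many_rate` fraction of the mapped genes
#' receive two targets. Target names are fresh model-organism-style
#' identifiers; all pairs are unique.
#'
#' @param source_genes character vector of source-species genes.
#' @param coverage fraction of source genes that map (default 0.8).
#' @param one_to_many_rate fraction of mapped genes with two targets
#'   (default 0.2).
#' @param seed integer random seed.
#' @param target_prefix prefix for generated target gene names
#'   (default `"wrm"`).
#' @param evidence evidence label for the pairs.
#' @return ortholog pair data frame (`source_gene`, `target_gene`,
#'   `evidence`).
#' @export
generate_ortholog_table <- function(source_genes, coverage = 0.8,
                                    one_to_many_rate = 0.2, seed = 1L,
                                    target_prefix = "wrm",
                                    evidence = "synthetic") {
  assert_fraction(coverage, "coverage")
  assert_fraction(one_to_many_rate, "one_to_many_rate")
  set.seed(seed)
  src <- unique(as.character(source_genes))
  n_map <- round(coverage * length(src))
  if (n_map == 0L)
    return(data.frame(source_gene = character(0), target_gene = character(0),
                      evidence = character(0), stringsAsFactors = FALSE))
  mapped <- sort(sample(src, n_map))
  n_two <- round(one_to_many_rate * n_map)
  two <- if (n_two > 0L) sort(sample(mapped, n_two)) else character(0)
  n_targets <- vapply(mapped, function(g)
    if (g %in% two) 2L else 1L, integer(1))
  total <- sum(n_targets)
  targets <- sprintf("%s-%d", target_prefix, seq_len(total))
  data.frame(source_gene = rep(mapped, n_targets), target_gene = targets,
             evidence = evidence, stringsAsFactors = FALSE)
}

#' Generate GMT annotations with planted enriched terms
#'
#' Planted terms draw about 80% of their members from `target_set`, far above
#' a uniform draw, so downstream over-representation of the target set is
#' guaranteed; remaining terms sample the universe uniformly. Planted term
#' identifiers take numeric suffixes 04001, 04002, ... and background terms
#' 01001, 01002, ..., so two collections generated with the same counts and
#' different `id_prefix` crosswalk onto each other KEGG-style.
#'
#' @param gene_universe character vector of genes.
#' @param n_terms number of terms.
#' @param term_size_range integer interval for term sizes (default
#'   `c(10, 50)`).
#' @param planted_terms number of planted (over-represented) terms.
#' @param target_set gene set the planted terms are built to overlap.
#' @param seed integer random seed.
#' @param id_prefix species-style identifier prefix (default `"hsa"`).
#' @param category category label stored in the description field.
#' @param planted_overlap fraction of each planted term drawn from
#'   `target_set` (default 0.8).
#' @return list with `terms` (term list as in [read_gmt()]) and `truth`
#'   (planted term identifiers).
#' @export
generate_annotations <- function(gene_universe, n_terms,
                                 term_size_range = c(10L, 50L),
                                 planted_terms = 0L,
                                 target_set = character(0), seed = 1L,
                                 id_prefix = "hsa", category = "pathway",
                                 planted_overlap = 0.8) {
  n_terms <- assert_count(n_terms, "n_terms")
  planted_terms <- assert_count(planted_terms, "planted_terms", min = 0L)
  if (planted_terms > n_terms)
    stop2("`planted_terms` must not exceed `n_terms`")
  universe <- unique(as.character(gene_universe))
  if (max(term_size_range) > length(universe))
    stop2("term sizes must not exceed the gene universe size")
  if (planted_terms > 0L && length(target_set) == 0L)
    stop2("planted terms require a nonempty `target_set`")
  set.seed(seed)
  target_set <- intersect(unique(as.character(target_set)), universe)
  other <- setdiff(universe, target_set)
  sizes <- sample(seq(term_size_range[1L], term_size_range[2L]),
                  n_terms, replace = TRUE)
  terms <- vector("list", n_terms)
  planted_ids <- character(0)
  for (i in seq_len(n_terms)) {
    if (i <= planted_terms) {
      id <- sprintf("%s%05d", id_prefix, 4000L + i)
      k_t <- min(ceiling(planted_overlap * sizes[i]), length(target_set))
      members <- c(sample(target_set, k_t),
                   if (sizes[i] - k_t > 0L && length(other))
                     sample(other, min(sizes[i] - k_t, length(other))))
      planted_ids <- c(planted_ids, id)
    } else {
      id <- sprintf("%s%05d", id_prefix, 1000L + i)
      members <- sample(universe, sizes[i])
    }
    terms[[i]] <- list(term_id = id, name = category, category = category,
                       members = unique(members))
  }
  list(terms = terms,
       truth = new_truth(enriched_terms = planted_ids, seed = seed))
}
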