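# Two-group differential-expression screening on log2 expression matrices.

#' Construct an expression dataset
#'
#' @param matrix numeric gene x sample matrix of log2-scale values with gene
#'   identifiers as row names and sample identifiers as column names.
#' @param groups character vector (or named vector keyed by sample) of
#'   `"case"` / `"control"` labels, one per sample.
#' @param dataset_id label for provenance tracking.
#' @param log2_scale set `FALSE` for linear-scale input; values are then
#'   log2(x + 1)-transformed on construction.
#' @return an `expression_dataset` object.
#' @export
expression_dataset <- function(matrix, groups, dataset_id = "dataset",
                               log2_scale = TRUE) {
  if (!is.matrix(matrix) || !is.numeric(matrix))
    stop2("`matrix` must be a numeric matrix")
  if (is.null(rownames(matrix)) || anyDuplicated(rownames(matrix)))
    stop2("matrix must have unique gene identifiers as row names")
  groups <- as.character(groups)
  if (length(groups) != ncol(matrix))
    stop2("need one group label per sample column")
  if (!all(groups %in% c("case", "control")))
    stop2("group labels must be 'case' or 'control'")
  if (!log2_scale) matrix <- log2(matrix + 1)
  structure(list(dataset_id = dataset_id, matrix = matrix, groups = groups),
            class = "expression_dataset")
}

#' Read an expression matrix and sample-group file
#'
#' The matrix file is a TSV whose first column holds gene identifiers and
#' whose header row holds sample identifiers; the group file is a two-column
#' TSV (sample, group) with groups `case` / `control`.
#'
#' @param matrix_path path to the expression TSV.
#' @param groups_path path to the sample-group TSV.
#' @param dataset_id dataset label.
#' @param log2_scale whether values are already log2 (default `TRUE`).
#' @return an `expression_dataset`.
#' @export
read_expression <- function(matrix_path, groups_path,
                            dataset_id = basename(matrix_path),
                            log2_scale = TRUE) {
  tab <- read_tsv(matrix_path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- as.character(tab[[1]])
  g <- read_tsv(groups_path)
  grp <- stats::setNames(as.character(g[[2]]), as.character(g[[1]]))
  if (!all(colnames(m) %in% names(grp)))
    stop2("group file is missing labels for some samples")
  expression_dataset(m, grp[colnames(m)], dataset_id, log2_scale)
}

#' Per-gene differential-expression statistics
#'
#' For each gene: `log2fc` = mean(case) - mean(control); a two-sample t-test
#' p-value (Welch's unequal-variance test by default, pooled-variance
#' optionally); Benjamini-Hochberg adjusted p across genes. No filtering is
#' applied here — see [screen_degs()]. A gene constant across all samples
#' gets p = 1 by convention.
#'
#' @param dataset an `expression_dataset` (values on log2 scale).
#' @param pooled use the pooled-variance (Student) test instead of Welch.
#' @return data frame with columns `gene`, `log2fc`, `p_value`, `adj_p`,
#'   `direction` (all `"none"` at this stage), carrying the dataset id as the
#'   `dataset_id` attribute.
#' @export
compute_gene_stats <- function(dataset, pooled = FALSE) {
  stopifnot(inherits(dataset, "expression_dataset"))
  case <- dataset$matrix[, dataset$groups == "case", drop = FALSE]
  ctrl <- dataset$matrix[, dataset$groups == "control", drop = FALSE]
  for (g in c("case", "control")) {
    nc <- if (g == "case") ncol(case) else ncol(ctrl)
    if (nc < 2L)
      stop2(sprintf("group '%s' has %d sample(s); at least 2 required", g, nc))
  }
  n1 <- ncol(case); n0 <- ncol(ctrl)
  m1 <- rowMeans(case); m0 <- rowMeans(ctrl)
  v1 <- rowSums((case - m1)^2) / (n1 - 1)
  v0 <- rowSums((ctrl - m0)^2) / (n0 - 1)
  lfc <- m1 - m0
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n0)
    df <- rep(n1 + n0 - 2, length(lfc))
  } else {
    se2 <- v1 / n1 + v0 / n0
    df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v0 / n0)^2 / (n0 - 1))
  }
  p <- ifelse(se2 > 0,
              2 * stats::pt(-abs(lfc) / sqrt(se2), df),
              ifelse(lfc == 0, 1, .Machine$double.xmin))
  p[is.na(p)] <- 1  # zero-variance, zero-effect genes
  out <- data.frame(gene = rownames(dataset$matrix), log2fc = lfc,
                    p_value = p, adj_p = stats::p.adjust(p, method = "BH"),
                    direction = "none",
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "dataset_id") <- dataset$dataset_id
  out
}

#' Screen differentially expressed genes
#'
#' Retains genes with p <= `p_max` (BH-adjusted p when `use_adjusted`) and
#' `lfc_min` <= |log2fc| <= `lfc_max`, and assigns the direction (`up` /
#' `down`) from the sign of the fold change. The default band |log2fc| in
#' \[0.25, 1.5\] is a two-sided screen; set `lfc_max = Inf` for the
#' conventional one-sided threshold.
#'
#' @param stats gene-stats data frame from [compute_gene_stats()].
#' @param p_max p-value threshold (default 0.05).
#' @param lfc_min,lfc_max |log2 fold change| band (defaults 0.25 and 1.5).
#' @param use_adjusted gate on the BH-adjusted p-value instead of the raw p.
#' @return the retained rows with `direction` set, dataset id attribute
#'   preserved.
#' @export
screen_degs <- function(stats, p_max = 0.05, lfc_min = 0.25, lfc_max = 1.5,
                        use_adjusted = FALSE) {
  if (p_max <= 0 || p_max > 1) stop2("`p_max` must be in (0, 1]")
  if (lfc_min < 0) stop2("`lfc_min` must be >= 0")
  if (lfc_min > lfc_max) stop2("`lfc_min` must not exceed `lfc_max`")
  p <- if (use_adjusted) stats$adj_p else stats$p_value
  keep <- p <= p_max & abs(stats$log2fc) >= lfc_min &
    abs(stats$log2fc) <= lfc_max
  out <- stats[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  attr(out, "dataset_id") <- attr(stats, "dataset_id")
  out
}

#' Merge per-dataset DEG tables into one de-duplicated gene list
#'
#' Each gene appears once in the merged list; the `datasets` column records
#' the contributing dataset ids (comma-joined). Genes screened in opposite
#' directions in different datasets are flagged (`conflict = TRUE`,
#' `direction = "conflict"`) rather than silently resolved. Merging a merged
#' table with itself is a no-op.
#'
#' @param tables list of retained DEG data frames (from [screen_degs()] or a
#'   previous merge); dataset ids are taken from the `datasets` column when
#'   present, else the `dataset_id` attribute, else the list names.
#' @return data frame with columns `gene`, `direction`, `conflict`,
#'   `datasets`, sorted by gene.
#' @export
merge_deg_tables <- function(tables) {
  if (!is.list(tables) || length(tables) == 0L)
    stop2("need at least one DEG table to merge")
  pieces <- lapply(seq_along(tables), function(i) {
    t <- tables[[i]]
    ds <- if ("datasets" %in% names(t)) t$datasets else
      rep(attr(t, "dataset_id") %||% names(tables)[i] %||%
            paste0("table", i), nrow(t))
    data.frame(gene = t$gene, direction = t$direction, datasets = ds,
               stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, pieces)
  genes <- sort(unique(all$gene))
  dir <- character(length(genes))
  dsets <- character(length(genes))
  by_gene <- split(all, all$gene)
  for (i in seq_along(genes)) {
    g <- by_gene[[genes[i]]]
    d <- unique(g$direction)
    dir[i] <- if (length(setdiff(d, "conflict")) > 1L || "conflict" %in% d)
      "conflict" else d
    dsets[i] <- paste(sort(unique(unlist(
      strsplit(g$datasets, ",", fixed = TRUE)))), collapse = ",")
  }
  data.frame(gene = genes, direction = dir, conflict = dir == "conflict",
             datasets = dsets, stringsAsFactors = FALSE)
}
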