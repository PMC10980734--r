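`%||%` <- function(x, y) if (is.null(x)) y else x

stop2 <- function(...) stop(..., call. = FALSE)

assert_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x != round(x) || x < min)
    stop2(sprintf("`%s` must be a single integer >= %d", name, min))
  as.integer(x)
}

assert_fraction <- function(x, name) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x < 0 || x > 1)
    stop2(sprintf("`%s` must be a single number in [0, 1]", name))
  as.numeric(x)
}

assert_positive <- function(x, name) {
  if (length(x) != 1L || is.na(x) || !is.numeric(x) || x <= 0)
    stop2(sprintf("`%s` must be a single positive number", name))
  as.numeric(x)
}

#' Write a data frame as tab-separated values
#'
#' Plain TSV with a header row, no quoting and no row names; the on-disk
#' format used for every table the pipeline emits.
#'
#' @param x data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

read_tsv <- function(path, header = TRUE, ...) {
  utils::read.table(path, sep = "\t", header = header, quote = "",
                    comment.char = "", stringsAsFactors = FALSE,
                    check.names = FALSE, ...)
}
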