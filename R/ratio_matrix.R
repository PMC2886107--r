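#' Protein-by-(block, channel) ratio matrix
#'
#' The central container of the pipeline: a numeric matrix of log-scale
#' measurements with one row per protein (group) and one column per
#' (block, channel) pair, named `"<block>|<label>"`, together with the
#' `block_design` its columns refer to. A protein missing from a block has
#' `NA` in all (or, with channel dropout, some) of that block's columns.
#'
#' @param values Numeric matrix with protein row names and `block|label`
#'   column names.
#' @param design The `block_design` the columns correspond to.
#' @return An object of class `ratio_matrix`.
#' @export
new_ratio_matrix <- function(values, design) {
  stopifnot(is.matrix(values), is.numeric(values))
  blocks <- sort(unique(design$block_id))
  expected <- as.vector(outer(channel_labels(), blocks,
                              function(l, b) paste(b, l, sep = "|")))
  if (!setequal(colnames(values), expected)) {
    stop("column names must be '<block>|<label>' for every design block")
  }
  values <- values[, expected, drop = FALSE]
  structure(list(values = values, design = design), class = "ratio_matrix")
}

#' @export
print.ratio_matrix <- function(x, ...) {
  cat("ratio_matrix:", nrow(x$values), "proteins x",
      length(unique(x$design$block_id)), "blocks (3 channels each)\n")
  obs <- observed_blocks(x)
  cat("observed cells:", sum(obs), "/", length(obs), "\n")
  invisible(x)
}

#' @export
dim.ratio_matrix <- function(x) dim(x$values)

#' @export
as.matrix.ratio_matrix <- function(x, ...) x$values

#' Per-protein block observation indicator
#'
#' @param x A `ratio_matrix`.
#' @return Logical matrix proteins x blocks; `TRUE` where at least one
#'   channel of that block is quantified for the protein.
#' @export
observed_blocks <- function(x) {
  stopifnot(inherits(x, "ratio_matrix"))
  blocks <- sort(unique(x$design$block_id))
  out <- sapply(blocks, function(b) {
    cols <- paste(b, channel_labels(), sep = "|")
    rowSums(!is.na(x$values[, cols, drop = FALSE])) > 0
  })
  out <- matrix(out, nrow = nrow(x$values),
                dimnames = list(rownames(x$values), as.character(blocks)))
  out
}

#' Keep proteins observed in at least a fraction of blocks
#'
#' Retains proteins observed in at least `floor(min_fraction * n_blocks)`
#' blocks. With 58 blocks and the default fraction of 0.25 the threshold is
#' 14 blocks, so a protein quantified in 14 blocks is retained and one seen
#' in 13 is dropped.
#'
#' @param x A `ratio_matrix`.
#' @param min_fraction Minimum fraction of blocks (default 0.25).
#' @return A `ratio_matrix` restricted to the retained proteins.
#' @export
filter_by_observation <- function(x, min_fraction = 0.25) {
  stopifnot(inherits(x, "ratio_matrix"), min_fraction >= 0, min_fraction <= 1)
  obs <- observed_blocks(x)
  threshold <- floor(min_fraction * ncol(obs))
  keep <- rowSums(obs) >= threshold
  new_ratio_matrix(x$values[keep, , drop = FALSE], x$design)
}

#' Write / read a ratio matrix as TSV
#'
#' One row per protein; first column `protein_id`, remaining columns the
#' `block|label` channels. Reading requires the matching design to restore
#' the column contract.
#'
#' @param x A `ratio_matrix`.
#' @param path File path.
#' @param design A `block_design` (for `read_ratio_matrix_tsv`).
#' @return `write_ratio_matrix_tsv` returns `path` invisibly;
#'   `read_ratio_matrix_tsv` returns a `ratio_matrix`.
#' @export
write_ratio_matrix_tsv <- function(x, path) {
  stopifnot(inherits(x, "ratio_matrix"))
  df <- data.frame(protein_id = rownames(x$values), x$values,
                   check.names = FALSE)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ratio_matrix_tsv
#' @export
read_ratio_matrix_tsv <- function(path, design) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  values <- as.matrix(df[, -1, drop = FALSE])
  rownames(values) <- df$protein_id
  new_ratio_matrix(values, design)
}
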