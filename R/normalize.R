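#' Block-center a ratio matrix
#'
#' First normalization stage: for each protein independently, subtract from
#' each block's channel values the mean of that block's observed channels.
#' After centering, any fully observed protein-by-block triple sums to zero;
#' a cell with a single observed channel becomes 0.
#'
#' @param x A `ratio_matrix` of log-scale values.
#' @return A block-centered `ratio_matrix`.
#' @export
block_center <- function(x) {
  stopifnot(inherits(x, "ratio_matrix"))
  values <- x$values
  blocks <- sort(unique(x$design$block_id))
  for (b in blocks) {
    cols <- paste(b, channel_labels(), sep = "|")
    sub <- values[, cols, drop = FALSE]
    m <- rowMeans(sub, na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    values[, cols] <- sub - m
  }
  new_ratio_matrix(values, x$design)
}

#' Standardize a ratio matrix within each label
#'
#' Second normalization stage: within each label channel, values are
#' centered by their median and scaled by their median absolute deviation
#' (raw MAD, i.e. without the 1.4826 normal-consistency constant, unless
#' `constant` says otherwise), computed across all proteins. By default the
#' median/MAD pool all blocks of a label (one pair per label channel);
#' `per_block = TRUE` computes one pair per (block, label) column instead.
#'
#' @param x A block-centered `ratio_matrix`.
#' @param constant Multiplier applied to the MAD (default 1; use 1.4826 for
#'   normal consistency).
#' @param per_block Compute median/MAD per (block, label) column rather than
#'   pooled per label.
#' @return A standardized `ratio_matrix`: per label (or per column) the
#'   across-protein median is 0 and the MAD is 1.
#' @export
label_standardize <- function(x, constant = 1, per_block = FALSE) {
  stopifnot(inherits(x, "ratio_matrix"), constant > 0)
  values <- x$values
  standardize <- function(v, what) {
    med <- median(v, na.rm = TRUE)
    scale <- constant * median(abs(v - med), na.rm = TRUE)
    if (!is.finite(scale) || scale == 0) {
      stop("degenerate scale: ", what, " has zero (or undefined) MAD")
    }
    (v - med) / scale
  }
  if (per_block) {
    for (j in seq_len(ncol(values))) {
      values[, j] <- standardize(values[, j], paste("column", colnames(values)[j]))
    }
  } else {
    labels <- vapply(strsplit(colnames(values), "|", fixed = TRUE),
                     `[[`, character(1), 2)
    for (lab in channel_labels()) {
      cols <- which(labels == lab)
      values[, cols] <- standardize(values[, cols],
                                    paste("label", sQuote(lab)))
    }
  }
  new_ratio_matrix(values, x$design)
}

#' Run both normalization stages
#'
#' Convenience wrapper: [block_center()] followed by [label_standardize()].
#'
#' @inheritParams label_standardize
#' @return A normalized `ratio_matrix`.
#' @export
normalize_ratios <- function(x, constant = 1, per_block = FALSE) {
  label_standardize(block_center(x), constant = constant,
                    per_block = per_block)
}
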