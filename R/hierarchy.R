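#' Euclidean hierarchical clustering with Newick export
#'
#' Agglomerative clustering of profile rows or columns with Euclidean
#' distance; average linkage (UPGMA) by default, with single and complete
#' available. Used to order proteins (rows) and populations (columns)
#' within clusters for display.
#'
#' @param x Numeric matrix without missing values.
#' @param axis Cluster the `"rows"` (e.g. proteins) or `"columns"`
#'   (e.g. populations).
#' @param linkage `"average"`, `"single"` or `"complete"`.
#' @return An object of class `dendrogram_fit`: list with the `hclust`
#'   object (`hc`), merge `heights`, the `order` of leaves, and `newick`
#'   (the tree as a Newick string with branch lengths).
#' @export
hierarchical_cluster <- function(x, axis = c("rows", "columns"),
                                 linkage = c("average", "single",
                                             "complete")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  x <- as.matrix(x)
  if (axis == "columns") x <- t(x)
  if (nrow(x) < 2) stop("need at least 2 items on the chosen axis")
  if (anyNA(x)) stop("missing values are not supported")
  if (is.null(rownames(x))) rownames(x) <- sprintf("item%03d", seq_len(nrow(x)))
  hc <- hclust(dist(x, method = "euclidean"), method = linkage)
  newick <- ape::write.tree(ape::as.phylo(hc))
  structure(list(hc = hc, heights = hc$height, order = hc$order,
                 labels = hc$labels, newick = newick),
            class = "dendrogram_fit")
}

#' @export
print.dendrogram_fit <- function(x, ...) {
  cat("dendrogram_fit:", length(x$labels), "leaves;",
      "merge heights:", paste(signif(x$heights, 4), collapse = ", "), "\n")
  invisible(x)
}
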