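check_overlap_bounds <- function(o, n_x, n_y, N) {
  if (n_x <= 0 || n_y <= 0) stop("set sizes must be positive")
  if (o < 0 || o > min(n_x, n_y)) {
    stop("overlap must lie in [0, min(n_x, n_y)]")
  }
  if (max(n_x, n_y) > N) stop("set sizes cannot exceed the background size")
}

#' Representation factor of two protein sets
#'
#' Observed overlap divided by the overlap expected by chance:
#' `o * N / (n_x * n_y)` for sets of sizes `n_x`, `n_y` drawn from a
#' background of `N` proteins. Values above 1 indicate more overlap than
#' expected.
#'
#' @param o Observed overlap count.
#' @param n_x,n_y Set sizes.
#' @param N Background size.
#' @return The representation factor (>= 0).
#' @examples
#' representation_factor(10, 20, 30, 100)  # 1.667
#' @export
representation_factor <- function(o, n_x, n_y, N) {
  check_overlap_bounds(o, n_x, n_y, N)
  o * N / (n_x * n_y)
}

#' Exact one-tailed hypergeometric overlap test
#'
#' Upper-tail probability `P(X >= o)` for
#' `X ~ Hypergeometric(N, n_x, n_y)`: the chance of observing at least `o`
#' common proteins between random sets of sizes `n_x` and `n_y` from a
#' background of `N`. Symmetric in `n_x` and `n_y`.
#'
#' @inheritParams representation_factor
#' @return A P-value in (0, 1\].
#' @export
hypergeom_overlap_test <- function(o, n_x, n_y, N) {
  check_overlap_bounds(o, n_x, n_y, N)
  if (o == 0) return(1)
  phyper(o - 1, n_x, N - n_x, n_y, lower.tail = FALSE)
}

#' Pairwise population similarity by significant-set overlap
#'
#' For every unordered pair of populations, counts the significant proteins
#' the two share and scores the overlap by its representation factor and
#' exact one-tailed hypergeometric P-value against the quantified background.
#' By default a protein is "common" only when its effect has the same sign
#' in both populations (overlap in expression pattern, not mere membership);
#' set `direction = "blind"` to count any shared significant protein.
#'
#' @param sig A [significance_table()].
#' @param background_ids Background protein ids; defaults to the table's
#'   `background_ids` attribute (all successfully fitted proteins).
#' @param direction `"match"` (same-sign overlap, default) or `"blind"`.
#' @param alpha Significance flag threshold for `significant` (default 0.05).
#' @return A tibble with one row per pair: `pop_x`, `pop_y`, `n_x`, `n_y`,
#'   `n_overlap`, `n_background`, `representation_factor`, `p_value`,
#'   `significant`. Pairs with an empty set have `NA` representation factor.
#' @export
similarity_matrix <- function(sig, background_ids = NULL,
                              direction = c("match", "blind"),
                              alpha = 0.05) {
  direction <- match.arg(direction)
  if (is.null(background_ids)) background_ids <- attr(sig, "background_ids")
  if (is.null(background_ids)) {
    stop("background_ids is required when the table carries no background")
  }
  if (!all(sig$protein_id %in% background_ids)) {
    stop("significant sets must be subsets of the background")
  }
  N <- length(unique(background_ids))
  pops <- sort(unique(sig$population))
  sets <- lapply(pops, function(p) {
    rows <- sig[sig$population == p, , drop = FALSE]
    list(up = rows$protein_id[rows$direction == "up"],
         down = rows$protein_id[rows$direction == "down"])
  })
  names(sets) <- pops
  pairs <- utils::combn(pops, 2, simplify = FALSE)
  rows <- lapply(pairs, function(pr) {
    a <- sets[[pr[1]]]
    b <- sets[[pr[2]]]
    n_x <- length(unique(c(a$up, a$down)))
    n_y <- length(unique(c(b$up, b$down)))
    o <- if (direction == "match") {
      length(intersect(a$up, b$up)) + length(intersect(a$down, b$down))
    } else {
      length(intersect(unique(c(a$up, a$down)), unique(c(b$up, b$down))))
    }
    if (n_x == 0 || n_y == 0) {
      return(tibble::tibble(pop_x = pr[1], pop_y = pr[2], n_x = n_x,
                            n_y = n_y, n_overlap = o, n_background = N,
                            representation_factor = NA_real_,
                            p_value = NA_real_, significant = NA))
    }
    rf <- representation_factor(o, n_x, n_y, N)
    p <- hypergeom_overlap_test(o, n_x, n_y, N)
    tibble::tibble(pop_x = pr[1], pop_y = pr[2], n_x = n_x, n_y = n_y,
                   n_overlap = o, n_background = N,
                   representation_factor = rf, p_value = p,
                   significant = p < alpha)
  })
  do.call(rbind, rows)
}

#' Term enrichment by the hypergeometric test
#'
#' Tests each annotation term represented in the foreground for
#' over-representation relative to the background (upper-tail
#' hypergeometric), with Benjamini-Hochberg adjustment across the tested
#' terms. Foreground ids absent from the annotation table simply count as
#' un-annotated.
#'
#' @param foreground_ids Protein ids of interest (subset of background).
#' @param background_ids The quantified background set.
#' @param annotations A data frame with columns `protein_id`, `term_id` and
#'   optionally `term_name`, `namespace`.
#' @return A tibble sorted by adjusted P: `term_id`, `term_name`,
#'   `namespace`, `n_fg_with_term`, `n_fg`, `n_bg_with_term`, `n_bg`,
#'   `p_value`, `fdr_adjusted_p`.
#' @export
term_enrichment <- function(foreground_ids, background_ids, annotations) {
  foreground_ids <- unique(foreground_ids)
  background_ids <- unique(background_ids)
  if (!all(foreground_ids %in% background_ids)) {
    stop("foreground must be a subset of the background")
  }
  stopifnot(all(c("protein_id", "term_id") %in% names(annotations)))
  ann <- annotations[annotations$protein_id %in% background_ids, ,
                     drop = FALSE]
  unknown <- setdiff(unique(annotations$protein_id), background_ids)
  if (length(unknown) > 0) {
    message(length(unknown),
            " annotated protein(s) outside the background were ignored")
  }
  n_fg <- length(foreground_ids)
  n_bg <- length(background_ids)
  terms <- unique(ann$term_id[ann$protein_id %in% foreground_ids])
  if (length(terms) == 0) {
    return(tibble::tibble(term_id = character(), term_name = character(),
                          namespace = character(),
                          n_fg_with_term = integer(), n_fg = integer(),
                          n_bg_with_term = integer(), n_bg = integer(),
                          p_value = numeric(), fdr_adjusted_p = numeric()))
  }
  rows <- lapply(terms, function(t) {
    with_term <- unique(ann$protein_id[ann$term_id == t])
    q <- length(intersect(with_term, foreground_ids))
    m <- length(with_term)
    p <- hypergeom_overlap_test(q, m, n_fg, n_bg)
    meta <- ann[match(t, ann$term_id), , drop = FALSE]
    tibble::tibble(
      term_id = t,
      term_name = if ("term_name" %in% names(meta)) meta$term_name else NA,
      namespace = if ("namespace" %in% names(meta)) meta$namespace else NA,
      n_fg_with_term = q, n_fg = n_fg,
      n_bg_with_term = m, n_bg = n_bg,
      p_value = p
    )
  })
  out <- do.call(rbind, rows)
  out$fdr_adjusted_p <- p.adjust(out$p_value, method = "BH")
  out[order(out$fdr_adjusted_p, out$p_value, out$term_id), , drop = FALSE]
}

#' Read an annotation TSV
#'
#' Columns: `protein_id`, `term_id`, and optionally `term_name`,
#' `namespace`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_annotation_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("protein_id", "term_id"), names(df))
  if (length(missing) > 0) {
    stop("annotation file is missing columns: ",
         paste(missing, collapse = ", "))
  }
  tibble::as_tibble(df)
}
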