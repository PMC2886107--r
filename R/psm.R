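#' Filter peptide-spectrum matches by ion score
#'
#' Retains PSMs whose ion score is at least `min_score`; the boundary is
#' inclusive, so a score exactly at the cut-off is kept.
#'
#' @param psms A PSM tibble (see [simulate_psm_table()] / [read_psm_tsv()]).
#' @param min_score Minimum ion score (default 25).
#' @return The filtered PSM tibble.
#' @export
filter_psms <- function(psms, min_score = 25) {
  stopifnot(is.data.frame(psms), "ion_score" %in% names(psms))
  psms[psms$ion_score >= min_score, , drop = FALSE]
}

#' Decoy-based false discovery rate of a PSM set
#'
#' Estimates the identification FDR as `rev / (for + rev)`, where `rev` is
#' the number of hits to reversed (decoy) sequences and `for` the number of
#' hits to real sequences, at whatever score cut-off `psms` was filtered to.
#' Returns 0 for an empty table.
#'
#' @param psms A PSM tibble with logical column `is_decoy`.
#' @return The estimated FDR as a fraction in \[0, 1\].
#' @examples
#' # 5 decoys among 2000 retained PSMs -> 0.25%
#' @export
estimate_fdr <- function(psms) {
  stopifnot(is.data.frame(psms), "is_decoy" %in% names(psms))
  if (nrow(psms) == 0) return(0)
  sum(psms$is_decoy) / nrow(psms)
}

split_accessions <- function(x) strsplit(x, ";", fixed = TRUE)

#' Parsimonious protein group inference
#'
#' Builds a non-redundant protein list by a minimal-set-cover heuristic
#' (Occam's razor): proteins are ranked by their number of distinct
#' supporting peptides (ties broken by accession order); walking down the
#' ranking, a protein whose peptides are all contained in an already
#' accepted group is merged into that group as a member, otherwise it starts
#' a new group with itself as leader. Every peptide ends up explained by at
#' least one group. Decoy records must be removed (or kept apart) first.
#'
#' @param psms A filtered PSM tibble; decoy rows are dropped with a message
#'   if present.
#' @return A tibble with one row per group: `leader_accession`,
#'   `member_accessions` (list), `peptides` (list), `n_peptides`.
#' @export
infer_protein_groups <- function(psms) {
  stopifnot(is.data.frame(psms))
  if (any(psms$is_decoy)) {
    message("dropping ", sum(psms$is_decoy), " decoy PSMs before inference")
    psms <- psms[!psms$is_decoy, , drop = FALSE]
  }
  if (nrow(psms) == 0) {
    return(tibble::tibble(leader_accession = character(),
                          member_accessions = list(),
                          peptides = list(), n_peptides = integer()))
  }
  accs <- split_accessions(psms$accessions)
  pairs <- data.frame(
    peptide = rep(psms$peptide_seq, lengths(accs)),
    accession = unlist(accs),
    stringsAsFactors = FALSE
  )
  pairs <- unique(pairs)
  pep_sets <- split(pairs$peptide, pairs$accession)
  pep_sets <- lapply(pep_sets, unique)
  ord <- order(-lengths(pep_sets), names(pep_sets))
  pep_sets <- pep_sets[ord]
  groups <- list()
  group_peps <- list()
  for (acc in names(pep_sets)) {
    peps <- pep_sets[[acc]]
    merged <- FALSE
    for (g in seq_along(groups)) {
      if (all(peps %in% group_peps[[g]])) {
        groups[[g]]$members <- c(groups[[g]]$members, acc)
        merged <- TRUE
        break
      }
    }
    if (!merged) {
      groups[[length(groups) + 1L]] <- list(leader = acc,
                                            members = character(0))
      group_peps[[length(groups)]] <- peps
    }
  }
  tibble::tibble(
    leader_accession = vapply(groups, `[[`, character(1), "leader"),
    member_accessions = lapply(groups, `[[`, "members"),
    peptides = group_peps,
    n_peptides = lengths(group_peps)
  )
}

#' Aggregate peptide ratios into a protein-by-block matrix
#'
#' For each protein group and block, averages the log2 channel intensities
#' of the group's supporting peptides' PSMs; a block without any supporting
#' PSM is a missing cell. Peptides shared between non-nested groups count
#' toward every group containing them unless `unique_only = TRUE`.
#'
#' @param groups Output of [infer_protein_groups()].
#' @param psms The filtered PSM tibble the groups were inferred from.
#' @param design A `block_design`; PSMs referring to blocks absent from the
#'   design are an error.
#' @param unique_only Drop peptides supporting more than one group before
#'   averaging.
#' @return A `ratio_matrix` with one row per group leader.
#' @export
aggregate_ratios <- function(groups, psms, design, unique_only = FALSE) {
  stopifnot(is.data.frame(groups), is.data.frame(psms))
  psms <- psms[!psms$is_decoy, , drop = FALSE]
  blocks <- sort(unique(design$block_id))
  bad <- setdiff(unique(psms$block_id), blocks)
  if (length(bad) > 0) {
    stop("PSMs refer to blocks absent from the design: ",
         paste(head(bad, 5), collapse = ", "))
  }
  if (unique_only) {
    counts <- table(unlist(lapply(groups$peptides, unique)))
    shared <- names(counts)[counts > 1]
  } else {
    shared <- character(0)
  }
  cols <- as.vector(outer(channel_labels(), blocks,
                          function(l, b) paste(b, l, sep = "|")))
  values <- matrix(NA_real_, nrow = nrow(groups), ncol = length(cols),
                   dimnames = list(groups$leader_accession, cols))
  logint <- log2(as.matrix(psms[, channel_labels()]))
  for (g in seq_len(nrow(groups))) {
    peps <- setdiff(groups$peptides[[g]], shared)
    rows <- which(psms$peptide_seq %in% peps)
    if (length(rows) == 0) next
    by_block <- split(rows, psms$block_id[rows])
    for (b in names(by_block)) {
      m <- colMeans(logint[by_block[[b]], , drop = FALSE])
      values[g, paste(b, channel_labels(), sep = "|")] <- m
    }
  }
  new_ratio_matrix(values, design)
}

#' Write / read a PSM table as TSV
#'
#' Columns: `peptide_seq`, `accessions` (semicolon-separated), `is_decoy`,
#' `ion_score`, `block_id`, `light`, `medium`, `heavy`.
#'
#' @param psms A PSM tibble.
#' @param path File path.
#' @return `write_psm_tsv` returns `path` invisibly; `read_psm_tsv` a
#'   tibble.
#' @export
write_psm_tsv <- function(psms, path) {
  write.table(as.data.frame(psms), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' @rdname write_psm_tsv
#' @export
read_psm_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  required <- c("peptide_seq", "accessions", "is_decoy", "ion_score",
                "block_id", channel_labels())
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("PSM file is missing columns: ", paste(missing, collapse = ", "))
  }
  df$is_decoy <- as.logical(df$is_decoy)
  tibble::as_tibble(df)
}
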