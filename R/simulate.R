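#' Construct ground truth for a synthetic ratio matrix
#'
#' Defines the generative model the downstream mixed-effects analysis
#' assumes: on the log scale each measurement is the sum of a per-protein
#' population effect (zero-mean across populations by construction), a
#' per-block shift, a per-label shift, a per-(protein, colony) random
#' intercept, and Gaussian residual noise. Whole protein-by-block triplex
#' cells go missing independently with probability `missing_prob`.
#'
#' @param design A `block_design` the matrix will be simulated over.
#' @param n_proteins Number of proteins (>= 1).
#' @param effect_size Scale of population effects: for
#'   `effect_pattern = "spread"` the per-population SD before centering; for
#'   `"single"` the planted log-scale shift of `affected_population`.
#' @param effect_pattern `"spread"` (independent zero-centered effects,
#'   `effect_size = 0` gives a global null) or `"single"` (one population
#'   shifted by `effect_size`, the rest compensating so effects sum to zero).
#' @param affected_population Population name for `"single"`; defaults to
#'   the first population in the design.
#' @param block_sd,label_sd SDs of the per-block and per-label shifts.
#' @param colony_sd SD of the per-(protein, colony) random intercept.
#' @param residual_sd Residual measurement SD on the log scale.
#' @param missing_prob Probability a protein is unobserved in a block;
#'   a scalar or one probability per protein.
#' @param decoy_frac Fraction of decoy records used when the truth feeds
#'   [simulate_psm_table()].
#' @param seed Integer seed for the effect draws.
#' @return An object of class `ground_truth`.
#' @export
make_ground_truth <- function(design, n_proteins,
                              effect_size = 0.5,
                              effect_pattern = c("spread", "single"),
                              affected_population = NULL,
                              block_sd = 0.2, label_sd = 0.1,
                              colony_sd = 0.15, residual_sd = 0.3,
                              missing_prob = 0.2, decoy_frac = 0.01,
                              seed = 1L) {
  if (n_proteins < 1) stop("n_proteins must be >= 1")
  effect_pattern <- match.arg(effect_pattern)
  stopifnot(colony_sd >= 0, residual_sd >= 0, block_sd >= 0, label_sd >= 0,
            all(missing_prob >= 0), all(missing_prob <= 1),
            length(missing_prob) %in% c(1L, n_proteins),
            decoy_frac >= 0, decoy_frac <= 1)
  pops <- unique(design$population)
  blocks <- sort(unique(design$block_id))
  with_seed(seed, {
    if (effect_pattern == "spread") {
      eff <- matrix(rnorm(n_proteins * length(pops), 0, effect_size),
                    nrow = n_proteins)
      eff <- eff - rowMeans(eff)
    } else {
      if (is.null(affected_population)) affected_population <- pops[1]
      if (!affected_population %in% pops) {
        stop("affected_population not present in design")
      }
      eff <- matrix(-effect_size / (length(pops) - 1),
                    nrow = n_proteins, ncol = length(pops))
      eff[, match(affected_population, pops)] <- effect_size
    }
    dimnames(eff) <- list(sprintf("prot%04d", seq_len(n_proteins)), pops)
    structure(list(
      population_effect = eff,
      block_effect = setNames(rnorm(length(blocks), 0, block_sd),
                              as.character(blocks)),
      label_effect = setNames(rnorm(3, 0, label_sd), channel_labels()),
      colony_sd = colony_sd,
      residual_sd = residual_sd,
      missing_prob = missing_prob,
      decoy_frac = decoy_frac
    ), class = "ground_truth")
  })
}

#' Simulate a protein-by-(block, channel) ratio matrix
#'
#' Draws log-scale measurements for every sample of `design` under the
#' generative model in `truth` (see [make_ground_truth()]): population +
#' block + label + colony + Normal(0, residual_sd). Missingness is applied
#' per protein-by-block cell, i.e. the whole triplex cell is observed or not,
#' matching how triplex quantitation reports protein ratios per analysis.
#'
#' @param design A valid `block_design`.
#' @param truth A `ground_truth`.
#' @param seed Integer seed for colony effects, residuals and missingness.
#' @return A list with `ratio` (a `ratio_matrix`), `truth`, and
#'   `colony_effects` (proteins x colonies matrix of the drawn random
#'   intercepts).
#' @export
simulate_ratio_matrix <- function(design, truth, seed = 1L) {
  stopifnot(inherits(truth, "ground_truth"))
  report <- validate_design(design,
                            distinct_populations =
                              !anyDuplicated_within_blocks(design))
  if (!report$valid) stop("design fails validation; see validate_design()")
  n_proteins <- nrow(truth$population_effect)
  proteins <- rownames(truth$population_effect)
  blocks <- sort(unique(design$block_id))
  colonies <- unique(design$colony_id)
  design_key <- paste(design$block_id, design$label, sep = "|")
  cols <- as.vector(outer(channel_labels(), blocks,
                          function(l, b) paste(b, l, sep = "|")))
  with_seed(seed, {
    colony_eff <- matrix(rnorm(n_proteins * length(colonies),
                               0, truth$colony_sd),
                         nrow = n_proteins,
                         dimnames = list(proteins, colonies))
    observed <- matrix(runif(n_proteins * length(blocks)) >=
                         truth$missing_prob,
                       nrow = n_proteins,
                       dimnames = list(proteins, as.character(blocks)))
    values <- matrix(NA_real_, nrow = n_proteins, ncol = length(cols),
                     dimnames = list(proteins, cols))
    for (j in seq_along(cols)) {
      row <- match(cols[j], design_key)
      b <- design$block_id[row]
      lab <- design$label[row]
      pop <- design$population[row]
      colony <- design$colony_id[row]
      values[, j] <- truth$population_effect[, pop] +
        truth$block_effect[as.character(b)] +
        truth$label_effect[lab] +
        colony_eff[, colony] +
        rnorm(n_proteins, 0, truth$residual_sd)
    }
    for (b in blocks) {
      miss <- !observed[, as.character(b)]
      if (any(miss)) {
        values[miss, paste(b, channel_labels(), sep = "|")] <- NA_real_
      }
    }
    list(ratio = new_ratio_matrix(values, design),
         truth = truth,
         colony_effects = colony_eff)
  })
}

# TRUE when some block repeats a population (then validation is run in
# colony-distinct mode only).
anyDuplicated_within_blocks <- function(design) {
  any(vapply(split(design$population, design$block_id),
             anyDuplicated, integer(1)) > 0)
}

#' Simulate a peptide-spectrum-match table
#'
#' Generates a PSM table with the columns the assembly stage reads: peptide
#' sequence, mapped accessions, decoy flag, ion score, block id and the three
#' channel intensities (raw scale, log-normal). Shared-peptide structure can
#' be injected through `peptide_map`, a named list mapping peptide sequences
#' to character vectors of accessions; peptides not covered by the map are
#' each assigned to one protein drawn from `n_proteins` accessions.
#'
#' @param n_targets,n_decoys Numbers of target and decoy records (>= 0).
#' @param score_dist Function of `n` returning `n` ion scores (negative
#'   draws are truncated at 0).
#' @param seed Integer seed.
#' @param n_blocks Number of blocks PSMs are spread over.
#' @param n_proteins Size of the target accession pool.
#' @param peptide_map Optional named list: peptide sequence -> accessions.
#' @return A tibble with columns `peptide_seq`, `accessions`
#'   (semicolon-separated), `is_decoy`, `ion_score`, `block_id`, `light`,
#'   `medium`, `heavy`.
#' @export
simulate_psm_table <- function(n_targets, n_decoys,
                               score_dist = function(n) rnorm(n, 45, 12),
                               seed = 1L, n_blocks = 58L, n_proteins = 200L,
                               peptide_map = NULL) {
  if (n_targets < 0 || n_decoys < 0) stop("counts must be >= 0")
  n <- n_targets + n_decoys
  with_seed(seed, {
    target_peps <- if (n_targets > 0) {
      sprintf("PEPTIDE%05d", sample.int(max(1L, n_targets %/% 2L + 1L),
                                        n_targets, replace = TRUE))
    } else {
      character(0)
    }
    decoy_peps <- if (n_decoys > 0) {
      sprintf("REVPEP%05d", seq_len(n_decoys))
    } else {
      character(0)
    }
    prot_of_pep <- function(peps, prefix) {
      u <- unique(peps)
      acc <- setNames(sprintf("%sPROT%04d", prefix,
                              sample.int(n_proteins, length(u),
                                         replace = TRUE)), u)
      out <- acc[peps]
      if (!is.null(peptide_map)) {
        hit <- peps %in% names(peptide_map)
        out[hit] <- vapply(peptide_map[peps[hit]],
                           paste, character(1), collapse = ";")
      }
      unname(out)
    }
    tbl <- tibble::tibble(
      peptide_seq = c(target_peps, decoy_peps),
      accessions = c(prot_of_pep(target_peps, ""),
                     if (n_decoys > 0) {
                       sprintf("REV_PROT%04d",
                               sample.int(n_proteins, n_decoys,
                                          replace = TRUE))
                     } else {
                       character(0)
                     }),
      is_decoy = rep(c(FALSE, TRUE), c(n_targets, n_decoys)),
      ion_score = pmax(0, score_dist(n)),
      block_id = sample.int(n_blocks, n, replace = TRUE),
      light = rlnorm(n, 10, 1),
      medium = rlnorm(n, 10, 1),
      heavy = rlnorm(n, 10, 1)
    )
    tbl
  })
}
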