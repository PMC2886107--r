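study_design <- function(seed = 1) {
  generate_design(enumerate_samples(example_roster()), seed = seed,
                  n_restarts = 1, n_sweeps = 0)
}

protein_df <- function(x, protein) {
  design <- x$design
  key <- paste(design$block_id, design$label, sep = "|")
  v <- x$values[protein, ]
  ok <- !is.na(v)
  idx <- match(names(v)[ok], key)
  data.frame(value = unname(v[ok]),
             block_id = design$block_id[idx],
             label = design$label[idx],
             colony_id = design$colony_id[idx],
             population = design$population[idx])
}

test_that("observation filter uses the floor threshold", {
  design <- study_design()
  truth <- make_ground_truth(design, n_proteins = 3, missing_prob = 0,
                             seed = 1)
  sim <- simulate_ratio_matrix(design, truth, seed = 1)
  x <- sim$ratio
  # protein 1 observed in exactly 14 blocks, protein 2 in 13, protein 3 all
  blank <- function(i, keep_blocks) {
    drop <- setdiff(sort(unique(design$block_id)), keep_blocks)
    for (b in drop) {
      x$values[i, paste(b, c("light", "medium", "heavy"), sep = "|")] <<- NA
    }
  }
  blank(1, 1:14)
  blank(2, 1:13)
  kept <- filter_by_observation(x)
  expect_equal(rownames(kept$values),
               rownames(x$values)[c(1, 3)])
  expect_equal(nrow(filter_by_observation(x, min_fraction = 0)$values), 3)
})

test_that("one- and two-sided P-value conversions are exact", {
  expect_equal(one_sided_pvalues(0, 1), 0.5)
  expect_equal(one_sided_pvalues(1.959964, 1), 0.975, tolerance = 1e-6)
  expect_equal(one_sided_pvalues(-1.959964, 1), 0.025, tolerance = 1e-6)
  expect_error(one_sided_pvalues(1, -1), "positive")
  expect_equal(two_sided_from_one_sided(0.5), 1)
  expect_equal(two_sided_from_one_sided(0.975), 0.05)
  expect_equal(two_sided_from_one_sided(0.025), 0.05)
  grid <- seq(0, 1, length.out = 1001)
  expect_equal(two_sided_from_one_sided(grid), 1 - 2 * abs(grid - 0.5))
  expect_true(all(two_sided_from_one_sided(grid) >= 0))
  expect_true(all(two_sided_from_one_sided(grid) <= 1))
})

test_that("noise-free data is recovered exactly and effects sum to zero", {
  design <- make_design(4, 2, seed = 3)
  truth <- make_ground_truth(design, n_proteins = 5, effect_size = 0.6,
                             block_sd = 0.3, label_sd = 0.2, colony_sd = 0,
                             residual_sd = 1e-8, missing_prob = 0, seed = 4)
  sim <- simulate_ratio_matrix(design, truth, seed = 5)
  fit <- lme_population(block_center(sim$ratio), factor_test = "none")
  for (p in fit$proteins$protein_id) {
    est <- fit$effects$effect[fit$effects$protein_id == p]
    expect_equal(sum(est), 0, tolerance = 1e-9)
    expect_equal(unname(est),
                 unname(truth$population_effect[p, fit$populations]),
                 tolerance = 1e-4)
  }
})

test_that("fixed effects match a direct GLS oracle at the REML variances", {
  design <- make_design(2, 2, seed = 6, distinct_populations = FALSE)
  truth <- make_ground_truth(design, n_proteins = 1, effect_size = 0.5,
                             colony_sd = 0.3, residual_sd = 0.2,
                             missing_prob = 0, seed = 7)
  sim <- simulate_ratio_matrix(design, truth, seed = 8)
  x <- block_center(sim$ratio)
  df <- protein_df(x, 1)
  ours <- fit_protein_lme(df, factor_test = "none")
  m <- lme4::lmer(value ~ population + block + label + (1 | colony),
                  data = transform(df,
                                   population = factor(population),
                                   block = factor(block_id),
                                   label = factor(label),
                                   colony = factor(colony_id)),
                  REML = TRUE,
                  contrasts = list(population = "contr.sum"))
  vc <- as.data.frame(lme4::VarCorr(m))
  oracle <- gls_population_effects(df,
                                   sigma_colony = vc$sdcor[vc$grp == "colony"],
                                   sigma_resid = vc$sdcor[vc$grp == "Residual"])
  expect_equal(unname(ours$effects[!is.na(ours$effects)]), unname(oracle),
               tolerance = 1e-6)
})

test_that("planted effects are recovered within 3 SE on most proteins", {
  design <- study_design(seed = 2)
  truth <- make_ground_truth(design, n_proteins = 60, effect_size = 0.5,
                             effect_pattern = "single",
                             affected_population = "CA1", seed = 9)
  sim <- simulate_ratio_matrix(design, truth, seed = 10)
  fit <- lme_population(block_center(filter_by_observation(sim$ratio)),
                        factor_test = "none")
  eff <- fit$effects[fit$effects$population == "CA1" &
                       !is.na(fit$effects$effect), ]
  truthv <- truth$population_effect[eff$protein_id, "CA1"]
  coverage <- mean(abs(eff$effect - truthv) <= 3 * eff$se)
  expect_gte(coverage, 0.95)
})

test_that("the factor test agrees with a fixed-effects F oracle", {
  # enough colonies per population that the colony variance is resolved;
  # with very few colonies the mixed model is rightly more conservative
  # than the fixed-effects oracle
  design <- make_design(6, 6, seed = 11)
  truth <- make_ground_truth(design, n_proteins = 80, effect_size = 0.25,
                             colony_sd = 0, missing_prob = 0, seed = 12)
  sim <- simulate_ratio_matrix(design, truth, seed = 13)
  x <- block_center(sim$ratio)
  fit <- lme_population(x)
  oracle_p <- vapply(fit$proteins$protein_id, function(p) {
    df <- protein_df(x, p)
    df$population <- factor(df$population)
    df$block <- factor(df$block_id)
    df$label <- factor(df$label)
    full <- lm(value ~ population + block + label, data = df)
    red <- lm(value ~ block + label, data = df)
    stats::anova(red, full)[2, "Pr(>F)"]
  }, numeric(1))
  agree <- mean((fit$proteins$factor_pvalue < 0.05) == (oracle_p < 0.05))
  expect_gte(agree, 0.95)
})

test_that("significance tables apply a strict threshold and drop zeros", {
  pops <- c("A", "B")
  fit <- structure(list(
    effects = tibble::tibble(
      protein_id = rep(c("p1", "p2", "p3"), each = 2),
      population = rep(pops, 3),
      effect = c(1, -1, 0.5, -0.5, 0, -0.2),
      se = rep(0.1, 6),
      p1 = rep(0.5, 6), p2 = rep(1, 6)
    ),
    proteins = tibble::tibble(
      protein_id = c("p1", "p2", "p3"),
      factor_pvalue = c(0.01, 0.05, 0.001),
      n_blocks_observed = 10, n_obs = 30,
      singular = FALSE, ok = TRUE, message = NA_character_
    ),
    populations = pops
  ), class = "lme_pop_fit")
  tab <- significance_table(fit, alpha = 0.05)
  # p2 sits exactly at alpha -> excluded
  expect_setequal(attr(tab, "significant_ids"), c("p1", "p3"))
  # zero effect joins neither set
  expect_false(any(tab$protein_id == "p3" & tab$population == "A"))
  expect_equal(tab$direction[tab$protein_id == "p1"], c("up", "down"))
  expect_setequal(attr(tab, "background_ids"), c("p1", "p2", "p3"))
})

test_that("results TSV has the wide expression-spreadsheet layout", {
  design <- make_design(4, 2, seed = 14)
  truth <- make_ground_truth(design, n_proteins = 4, seed = 15)
  sim <- simulate_ratio_matrix(design, truth, seed = 16)
  fit <- lme_population(normalize_ratios(sim$ratio))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_lme_results_tsv(fit, path)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), 4)
  expect_true(all(c("protein_id", "factor_pvalue", "significant") %in%
                    names(back)))
  expect_equal(sum(grepl("^p1_", names(back))), 4)
  expect_equal(sum(grepl("^effect_", names(back))), 4)
})
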