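test_that("enumerate_samples yields three replicates per colony", {
  samples <- enumerate_samples(example_roster())
  expect_equal(nrow(samples), 174)
  expect_true(all(table(samples$colony_id) == 3))
  small <- enumerate_samples(simulate_roster(2, c(2, 1), seed = 1))
  expect_equal(nrow(small), 9)
  expect_error(enumerate_samples(example_roster()[0, ]), "at least one")
})

test_that("generated designs always satisfy the constraints", {
  for (seed in 1:3) {
    roster <- simulate_roster(4, c(2, 3, 2, 2), seed = seed)
    design <- generate_design(enumerate_samples(roster), seed = seed,
                              n_restarts = 1, n_sweeps = 1)
    report <- validate_design(design)
    expect_true(report$valid, info = paste("seed", seed))
  }
  design <- generate_design(enumerate_samples(example_roster()), seed = 7,
                            n_restarts = 1, n_sweeps = 0)
  expect_equal(length(unique(design$block_id)), 58)
  expect_true(validate_design(design)$valid)
})

test_that("three populations of one colony give three Latin-square blocks", {
  roster <- simulate_roster(3, 1, seed = 2)
  design <- generate_design(enumerate_samples(roster), seed = 2)
  expect_equal(length(unique(design$block_id)), 3)
  expect_true(validate_design(design)$valid)
  # every block holds all three colonies, labels form a Latin square
  for (b in unique(design$block_id)) {
    expect_setequal(design$colony_id[design$block_id == b],
                    unique(design$colony_id))
  }
})

test_that("infeasible rosters are rejected with an explicit error", {
  two_pops <- enumerate_samples(simulate_roster(2, 2, seed = 1))
  expect_error(generate_design(two_pops), "infeasible")
  # one population holding more than a third of all samples
  lopsided <- enumerate_samples(simulate_roster(3, c(10, 2, 2), seed = 1))
  expect_error(generate_design(lopsided), "infeasible")
})

test_that("validate_design flags specific violations", {
  design <- make_design(3, 2, seed = 4)
  expect_true(validate_design(design)$valid)
  # duplicate a population inside one block
  broken <- design
  b1 <- which(broken$block_id == 1)
  broken$population[b1[1]] <- broken$population[b1[2]]
  broken$colony_id[b1[1]] <- paste0(broken$colony_id[b1[2]], "_x")
  report <- validate_design(broken)
  expect_false(report$valid)
  expect_true("population_distinct" %in% report$violations$type)
  # reuse a label across one colony's replicates
  broken2 <- design
  rows <- which(broken2$colony_id == broken2$colony_id[1])
  broken2$label[rows] <- broken2$label[rows[1]]
  report2 <- validate_design(broken2)
  expect_true("label_balance" %in% report2$violations$type)
})

test_that("the Ds criterion is a pure function and punishes confounding", {
  design <- make_design(3, 2, seed = 5)
  s1 <- d_criterion(design)
  s2 <- d_criterion(design)
  expect_identical(s1$criterion_value, s2$criterion_value)
  expect_true(s1$feasible)
  # one colony per population, colony confounded with label: the population
  # contrast collapses into the label adjustment
  samples <- enumerate_samples(simulate_roster(3, 1, seed = 1))
  confounded <- samples
  confounded$block_id <- rep(1:3, 3)
  confounded$label <- rep(c("light", "medium", "heavy"), each = 3)
  sc <- d_criterion(confounded)
  balanced <- generate_design(samples, seed = 1)
  expect_lt(sc$criterion_value, d_criterion(balanced)$criterion_value)
  expect_false(sc$feasible)
})

test_that("more restarts never decrease the criterion", {
  samples <- enumerate_samples(simulate_roster(4, 2, seed = 9))
  d1 <- generate_design(samples, seed = 9, n_restarts = 1, n_sweeps = 1)
  d3 <- generate_design(samples, seed = 9, n_restarts = 3, n_sweeps = 1)
  expect_gte(d_criterion(d3)$criterion_value,
             d_criterion(d1)$criterion_value)
})

test_that("the optimizer attains the exhaustive optimum on 9 samples", {
  roster <- simulate_roster(3, 1, seed = 6)
  samples <- enumerate_samples(roster)
  all_designs <- enumerate_tiny_designs(samples)
  expect_gt(length(all_designs), 0)
  scores <- vapply(all_designs,
                   function(d) d_criterion(d)$criterion_value, numeric(1))
  generated <- generate_design(samples, seed = 6)
  expect_equal(d_criterion(generated)$criterion_value, max(scores),
               tolerance = 1e-8)
})

test_that("design CSV round-trips", {
  design <- make_design(3, 2, seed = 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_design_csv(design, path)
  back <- read_design_csv(path)
  expect_equal(as.data.frame(back), as.data.frame(design))
})
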