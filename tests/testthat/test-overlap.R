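test_that("representation factor follows the printed formula", {
  expect_equal(representation_factor(10, 20, 30, 100), 10 * 100 / (20 * 30))
  # observed equal to expected overlap gives exactly 1
  expect_equal(representation_factor(6, 20, 30, 100), 1)
  expect_equal(representation_factor(0, 20, 30, 100), 0)
  expect_error(representation_factor(25, 20, 30, 100), "overlap")
  expect_error(representation_factor(5, 0, 30, 100), "positive")
  expect_error(representation_factor(5, 20, 120, 100), "background")
})

test_that("RF > 1 exactly when overlap exceeds expectation", {
  set.seed(42)
  for (i in 1:50) {
    N <- sample(20:200, 1)
    n_x <- sample(1:N, 1)
    n_y <- sample(1:N, 1)
    o <- sample(0:min(n_x, n_y), 1)
    rf <- representation_factor(o, n_x, n_y, N)
    expect_equal(rf > 1, o > n_x * n_y / N)
  }
})

test_that("hypergeometric overlap test matches exhaustive enumeration", {
  expect_equal(hypergeom_overlap_test(5, 5, 5, 10), 1 / choose(10, 5),
               tolerance = 1e-12)
  expect_equal(hypergeom_overlap_test(0, 5, 5, 10), 1)
  set.seed(7)
  for (i in 1:100) {
    N <- sample(5:60, 1)
    n_x <- sample(1:N, 1)
    n_y <- sample(1:N, 1)
    o <- sample(0:min(n_x, n_y), 1)
    p <- hypergeom_overlap_test(o, n_x, n_y, N)
    expect_equal(p, hyper_upper_sum(o, n_x, n_y, N), tolerance = 1e-12)
    expect_equal(p, hypergeom_overlap_test(o, n_y, n_x, N),
                 tolerance = 1e-14)
  }
})

fake_sig_table <- function(sets, background) {
  rows <- do.call(rbind, lapply(names(sets), function(p) {
    tibble::tibble(protein_id = c(sets[[p]]$up, sets[[p]]$down),
                   population = p,
                   effect = c(rep(1, length(sets[[p]]$up)),
                              rep(-1, length(sets[[p]]$down))),
                   direction = c(rep("up", length(sets[[p]]$up)),
                                 rep("down", length(sets[[p]]$down))))
  }))
  attr(rows, "background_ids") <- background
  attr(rows, "alpha") <- 0.05
  class(rows) <- c("significance_table", class(rows))
  rows
}

test_that("similarity matrix scores identical and disjoint sets correctly", {
  bg <- sprintf("p%03d", 1:100)
  sets <- list(
    A = list(up = bg[1:10], down = bg[11:20]),
    B = list(up = bg[1:10], down = bg[11:20]),
    C = list(up = bg[21:30], down = bg[31:40])
  )
  sim <- similarity_matrix(fake_sig_table(sets, bg))
  ab <- sim[sim$pop_x == "A" & sim$pop_y == "B", ]
  expect_equal(ab$representation_factor, 100 / 20)  # N / n
  expect_equal(ab$p_value, min(sim$p_value))
  ac <- sim[sim$pop_x == "A" & sim$pop_y == "C", ]
  expect_equal(ac$representation_factor, 0)
  expect_equal(ac$p_value, 1)
})

test_that("direction-matched overlap ignores sign-discordant proteins", {
  bg <- sprintf("p%03d", 1:60)
  sets <- list(A = list(up = bg[1:10], down = character(0)),
               B = list(up = character(0), down = bg[1:10]))
  matched <- similarity_matrix(fake_sig_table(sets, bg))
  blind <- similarity_matrix(fake_sig_table(sets, bg), direction = "blind")
  expect_equal(matched$n_overlap, 0)
  expect_equal(blind$n_overlap, 10)
})

test_that("overlap significance calls are calibrated under random sets", {
  # under random same-size sets the overlap is hypergeometric, so the exact
  # rejection probability is available in closed form
  N <- 578; n_x <- 80; n_y <- 80
  crit <- qhyper(0.95, n_x, N - n_x, n_y)
  os <- 0:min(n_x, n_y)
  pvals <- vapply(os, function(o) hypergeom_overlap_test(o, n_x, n_y, N),
                  numeric(1))
  exact_rate <- sum(dhyper(os, n_x, N - n_x, n_y)[pvals < 0.05])
  set.seed(21)
  bg <- sprintf("p%03d", 1:N)
  hits <- replicate(2000, {
    x <- sample(bg, n_x)
    y <- sample(bg, n_y)
    o <- length(intersect(x, y))
    hypergeom_overlap_test(o, n_x, n_y, N) < 0.05
  })
  se <- sqrt(exact_rate * (1 - exact_rate) / 2000)
  expect_lt(abs(mean(hits) - exact_rate), 4 * se)
  expect_lt(exact_rate, 0.05 + 1e-9)
})

test_that("term enrichment matches brute-force enumeration on tiny sets", {
  bg <- sprintf("p%02d", 1:10)
  fg <- bg[1:4]
  ann <- tibble::tibble(protein_id = fg, term_id = "T",
                        term_name = "term T", namespace = "BP")
  res <- term_enrichment(fg, bg, ann)
  expect_equal(res$p_value, 1 / choose(10, 4), tolerance = 1e-12)
  # brute force: enumerate all C(10, 4) foregrounds
  combos <- combn(10, 4)
  count <- sum(apply(combos, 2, function(ix) sum(ix <= 4) >= 4))
  expect_equal(res$p_value, count / ncol(combos), tolerance = 1e-12)
  # a term covering everything is never enriched
  ann_all <- tibble::tibble(protein_id = bg, term_id = "ALL",
                            term_name = "everything", namespace = "BP")
  expect_equal(term_enrichment(fg, bg, ann_all)$p_value, 1)
})

test_that("BH adjustment matches arithmetic and is monotone", {
  bg <- sprintf("p%02d", 1:20)
  fg <- bg[1:6]
  ann <- rbind(
    tibble::tibble(protein_id = bg[1:6], term_id = "T1"),
    tibble::tibble(protein_id = bg[c(1:3, 7:9)], term_id = "T2"),
    tibble::tibble(protein_id = bg[c(1, 10:14)], term_id = "T3")
  )
  res <- term_enrichment(fg, bg, ann)
  expect_equal(res$fdr_adjusted_p, p.adjust(res$p_value, "BH"))
  expect_true(all(res$fdr_adjusted_p >= res$p_value - 1e-15))
  expect_true(all(diff(res$fdr_adjusted_p) >= -1e-15))
  expect_equal(unname(p.adjust(c(0.01, 0.02, 0.03), "BH")),
               c(0.03, 0.03, 0.03))
})

test_that("foreground proteins without annotation count as un-annotated", {
  bg <- sprintf("p%02d", 1:12)
  fg <- bg[1:5]
  ann <- tibble::tibble(protein_id = bg[1:3], term_id = "T")
  res <- term_enrichment(fg, bg, ann)
  expect_equal(res$n_fg_with_term, 3)
  expect_equal(res$n_fg, 5)
  expect_error(term_enrichment(c(fg, "zzz"), bg, ann), "subset")
})
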