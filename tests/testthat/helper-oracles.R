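# Independent oracles used across tests: all deliberately naive.

# Upper-tail hypergeometric probability as an explicit PMF sum.
hyper_upper_sum <- function(o, n_x, n_y, N) {
  if (o == 0) return(1)
  ks <- o:min(n_x, n_y)
  sum(dhyper(ks, n_x, N - n_x, n_y))
}

# Average-linkage agglomeration by direct recomputation of cluster-pair
# mean distances at every step; returns the sorted merge heights.
average_linkage_heights <- function(x) {
  x <- as.matrix(x)
  clusters <- lapply(seq_len(nrow(x)), identity)
  d <- as.matrix(dist(x))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- clusters[-best]
    clusters[[length(clusters) + 1]] <- merged
  }
  sort(heights)
}

# Generalized least squares at given variance components for the
# population + block + label model with a colony random intercept.
gls_population_effects <- function(df, sigma_colony, sigma_resid) {
  df$population <- droplevels(factor(df$population))
  df$block <- droplevels(factor(df$block_id))
  df$label <- droplevels(factor(df$label, levels = c("light", "medium", "heavy")))
  k <- nlevels(df$population)
  terms <- c("population",
             if (nlevels(df$block) > 1) "block",
             if (nlevels(df$label) > 1) "label")
  X <- model.matrix(as.formula(paste("~", paste(terms, collapse = "+"))),
                    data = df,
                    contrasts.arg = list(population = "contr.sum"))
  Z <- model.matrix(~ 0 + factor(colony_id), data = df)
  V <- sigma_colony^2 * Z %*% t(Z) + sigma_resid^2 * diag(nrow(df))
  Vi <- solve(V)
  beta <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% df$value)
  pop <- beta[grep("^population", rownames(beta)), 1]
  c(pop, -sum(pop))
}

# Exhaustive enumeration of all feasible designs for a roster of three
# populations with one colony each (9 samples): every assignment of the
# three replicates of each colony to the three blocks, and of labels to
# replicates, subject to the block/label constraints.
enumerate_tiny_designs <- function(samples) {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                c(3, 1, 2), c(3, 2, 1))
  labels <- c("light", "medium", "heavy")
  designs <- list()
  for (pa in perms) for (pb in perms) for (pc in perms) {
    block_of <- c(pa, pb, pc)  # one entry per sample row
    for (la in perms) for (lb in perms) for (lc in perms) {
      label_of <- labels[c(la, lb, lc)]
      df <- samples
      df$block_id <- block_of
      df$label <- label_of
      ok <- all(vapply(split(df$label, df$block_id),
                       function(l) !anyDuplicated(l), logical(1)))
      if (ok) designs[[length(designs) + 1]] <- df
    }
  }
  designs
}

# Small helper: a feasible colony-distinct design built by the package.
make_design <- function(n_pops, colonies_per_pop, seed = 1,
                        distinct_populations = TRUE) {
  roster <- simulate_roster(n_pops, colonies_per_pop, seed = seed)
  generate_design(enumerate_samples(roster), seed = seed,
                  n_restarts = 1, n_sweeps = 0,
                  distinct_populations = distinct_populations)
}
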