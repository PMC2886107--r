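#' Enumerate sample units from a roster
#'
#' Every colony is sampled in triplicate, so a roster with `n` colonies in
#' total yields `3 * n` sample units in a stable ordering (population order
#' of the roster, then colony index, then replicate).
#'
#' @param roster A roster as returned by [example_roster()] or
#'   [simulate_roster()].
#' @return A tibble with columns `colony_id`, `population`, `replicate`.
#' @examples
#' nrow(enumerate_samples(example_roster()))  # 174
#' @export
enumerate_samples <- function(roster) {
  validate_roster(roster)
  pieces <- lapply(seq_len(nrow(roster)), function(i) {
    pop <- roster$name[i]
    nc <- roster$n_colonies[i]
    tibble::tibble(
      colony_id = rep(sprintf("%s_c%02d", pop, seq_len(nc)), each = 3L),
      population = pop,
      replicate = rep(1:3, nc)
    )
  })
  do.call(rbind, pieces)
}

# ---- block construction -----------------------------------------------------

# Partition sample rows into triples with distinct values of `group`,
# largest-remaining-count first with randomized tie-breaks. Returns an
# integer block id per row or NULL if it gets stuck.
partition_blocks <- function(samples, group) {
  n <- nrow(samples)
  n_blocks <- n %/% 3L
  keys <- unique(group)
  remaining <- lapply(keys, function(k) which(group == k))
  names(remaining) <- keys
  block_of <- integer(n)
  for (b in seq_len(n_blocks)) {
    counts <- vapply(remaining, length, integer(1))
    avail <- which(counts > 0)
    if (length(avail) < 3) return(NULL)
    ord <- avail[order(-counts[avail], runif(length(avail)))]
    pick <- ord[1:3]
    for (k in pick) {
      idx <- remaining[[k]]
      take <- idx[sample.int(length(idx), 1L)]
      block_of[take] <- b
      remaining[[k]] <- setdiff(idx, take)
    }
  }
  block_of
}

# ---- label assignment via bipartite edge colouring --------------------------

# Kuhn's augmenting-path maximum bipartite matching. adj: list over left
# nodes of integer vectors of right-node neighbours. Returns match_right:
# for each right node, the matched left node (NA if unmatched).
kuhn_matching <- function(adj, n_right) {
  match_right <- rep(NA_integer_, n_right)
  augment <- function(u) {
    stack_seen <- rep(FALSE, n_right)
    dfs <- function(u) {
      for (v in adj[[u]]) {
        if (!stack_seen[v]) {
          stack_seen[v] <<- TRUE
          if (is.na(match_right[v]) || dfs(match_right[v])) {
            match_right[v] <<- u
            return(TRUE)
          }
        }
      }
      FALSE
    }
    dfs(u)
  }
  for (u in seq_along(adj)) augment(u)
  match_right
}

# Assign the three labels so that labels are distinct within every block and
# across every colony's replicates. The colony-block incidence graph of a
# valid blocking is 3-regular bipartite, so it decomposes into three perfect
# matchings (Konig); each matching receives one label.
assign_labels <- function(colony, block_of) {
  colonies <- unique(colony)
  blocks <- sort(unique(block_of))
  ci <- match(colony, colonies)
  bi <- match(block_of, blocks)
  n_rows <- length(colony)
  label <- rep(NA_character_, n_rows)
  remaining <- rep(TRUE, n_rows)
  for (lab in channel_labels()) {
    adj <- lapply(seq_along(colonies), function(c0) {
      bi[remaining & ci == c0]
    })
    match_right <- kuhn_matching(adj, length(blocks))
    if (anyNA(match_right)) return(NULL)
    for (b in seq_along(blocks)) {
      c0 <- match_right[b]
      row <- which(remaining & ci == c0 & bi == b)[1]
      label[row] <- lab
      remaining[row] <- FALSE
    }
  }
  label
}

# ---- design object ----------------------------------------------------------

new_block_design <- function(df) {
  df <- df[order(df$block_id,
                 match(df$label, channel_labels())), , drop = FALSE]
  class(df) <- c("block_design", class(tibble::tibble()))
  df
}

# Canonical form: blocks renumbered by the lexicographic order of their
# sorted colony ids, rows ordered by (block, label). Makes equal designs
# byte-identical and gives a deterministic tie-break between optima.
canonicalize_design <- function(design) {
  key <- vapply(split(design$colony_id, design$block_id),
                function(x) paste(sort(x), collapse = "|"), character(1))
  old_ids <- as.integer(names(key))
  new_of_old <- match(old_ids, old_ids[order(key)])
  design$block_id <- new_of_old[match(design$block_id, old_ids)]
  new_block_design(design)
}

#' Generate a constrained triplex block design
#'
#' Assigns every sample unit (colony replicate) to a block of three samples
#' and one of three isotopic labels, subject to the design constraints:
#' the three samples of a block come from three distinct colonies of three
#' distinct populations (or merely distinct colonies when
#' `distinct_populations = FALSE`), the three labels within a block are
#' distinct, and each colony's three replicates use each label exactly once.
#' Among feasible designs, a Ds-type information criterion for the population
#' contrasts (see [d_criterion()]) is maximized by a seeded multi-restart
#' exchange heuristic, so the returned design is never worse than the best
#' random feasible design found under the same budget.
#'
#' @param samples Sample units from [enumerate_samples()].
#' @param seed Integer seed controlling the randomized construction.
#' @param n_restarts Number of independent random starts (best kept).
#' @param n_sweeps Exchange sweeps per restart; each sweep proposes one
#'   same-label block swap per sample.
#' @param distinct_populations If `TRUE` (default) blocks must contain three
#'   distinct populations; if `FALSE`, only three distinct colonies.
#' @return A `block_design` tibble with columns `block_id`, `colony_id`,
#'   `population`, `replicate`, `label`.
#' @examples
#' d <- generate_design(enumerate_samples(simulate_roster(3, 1)), seed = 1)
#' length(unique(d$block_id))  # 3
#' @export
generate_design <- function(samples, seed = 1L, n_restarts = 3L,
                            n_sweeps = 2L, distinct_populations = TRUE) {
  stopifnot(is.data.frame(samples), nrow(samples) > 0)
  n <- nrow(samples)
  if (n %% 3L != 0L) stop("number of samples must be divisible by 3")
  n_blocks <- n %/% 3L
  group <- if (distinct_populations) samples$population else samples$colony_id
  counts <- table(group)
  if (length(counts) < 3) {
    stop("infeasible: at least 3 distinct ",
         if (distinct_populations) "populations" else "colonies",
         " are required for triplex blocks")
  }
  if (max(counts) > n_blocks) {
    stop("infeasible: ", names(counts)[which.max(counts)], " holds ",
         max(counts), " samples but only ", n_blocks,
         " blocks are available")
  }
  best <- NULL
  best_score <- -Inf
  for (r in seq_len(n_restarts)) {
    cand <- with_seed(seed + (r - 1L), {
      build_feasible_design(samples, group, distinct_populations)
    })
    cand <- with_seed(seed + 10000L + (r - 1L), {
      improve_design(cand, n_sweeps = n_sweeps,
                     distinct_populations = distinct_populations)
    })
    cand <- canonicalize_design(cand)
    score <- d_criterion(cand)$criterion_value
    if (score > best_score + 1e-9 ||
        (abs(score - best_score) <= 1e-9 && !is.null(best) &&
         design_lex_key(cand) < design_lex_key(best))) {
      best <- cand
      best_score <- score
    }
  }
  best
}

design_lex_key <- function(design) {
  paste(design$colony_id, design$label, collapse = ";")
}

build_feasible_design <- function(samples, group, distinct_populations,
                                  max_attempts = 100L) {
  for (attempt in seq_len(max_attempts)) {
    block_of <- partition_blocks(samples, group)
    if (is.null(block_of)) next
    label <- assign_labels(samples$colony_id, block_of)
    if (is.null(label)) next
    df <- tibble::tibble(
      block_id = block_of,
      colony_id = samples$colony_id,
      population = samples$population,
      replicate = samples$replicate,
      label = label
    )
    return(new_block_design(df))
  }
  stop("failed to construct a feasible design in ", max_attempts, " attempts")
}

# Exchange heuristic: propose swapping the block membership of two samples
# carrying the same label (label balance is untouched); accept when the swap
# keeps blocks feasible and strictly improves the Ds criterion.
improve_design <- function(design, n_sweeps, distinct_populations) {
  if (n_sweeps < 1) return(design)
  score <- d_criterion(design)$criterion_value
  n <- nrow(design)
  for (sweep in seq_len(n_sweeps)) {
    for (k in seq_len(n)) {
      i <- sample.int(n, 1L)
      mates <- which(design$label == design$label[i] &
                     design$block_id != design$block_id[i])
      if (length(mates) == 0) next
      j <- mates[sample.int(length(mates), 1L)]
      cand <- design
      cand$block_id[c(i, j)] <- design$block_id[c(j, i)]
      if (!blocks_feasible(cand, design$block_id[c(i, j)],
                           distinct_populations)) next
      new_score <- d_criterion(cand)$criterion_value
      if (new_score > score + 1e-12) {
        design <- cand
        score <- new_score
      }
    }
  }
  design
}

blocks_feasible <- function(design, block_ids, distinct_populations) {
  for (b in unique(block_ids)) {
    rows <- design$block_id == b
    if (anyDuplicated(design$colony_id[rows])) return(FALSE)
    if (distinct_populations && anyDuplicated(design$population[rows])) {
      return(FALSE)
    }
  }
  TRUE
}

#' Validate a triplex block design
#'
#' Checks every structural constraint of a block design and reports each
#' violation: blocks of exactly three samples, distinct labels per block,
#' distinct colonies (and populations, if required) per block, three
#' replicates per colony appearing exactly once each, and label balance
#' across each colony's replicates.
#'
#' @param design A `block_design` (or compatible data frame).
#' @param distinct_populations Whether blocks must also contain three
#'   distinct populations (default `TRUE`).
#' @return An object of class `design_report`: a list with `valid` (logical)
#'   and `violations` (tibble with columns `type`, `where`, `detail`).
#' @export
validate_design <- function(design, distinct_populations = TRUE) {
  v <- list()
  add <- function(type, where, detail) {
    v[[length(v) + 1L]] <<- tibble::tibble(type = type, where = where,
                                           detail = detail)
  }
  for (b in unique(design$block_id)) {
    rows <- design[design$block_id == b, , drop = FALSE]
    if (nrow(rows) != 3) {
      add("block_size", as.character(b),
          sprintf("block has %d samples, expected 3", nrow(rows)))
    }
    if (anyDuplicated(rows$label)) {
      add("label_distinct", as.character(b), "duplicated label within block")
    }
    if (anyDuplicated(rows$colony_id)) {
      add("colony_distinct", as.character(b), "duplicated colony within block")
    }
    if (distinct_populations && anyDuplicated(rows$population)) {
      add("population_distinct", as.character(b),
          paste("duplicated population:",
                paste(rows$population[duplicated(rows$population)],
                      collapse = ", ")))
    }
  }
  for (cid in unique(design$colony_id)) {
    rows <- design[design$colony_id == cid, , drop = FALSE]
    if (!identical(sort(rows$replicate), 1:3)) {
      add("replicate_coverage", cid,
          "colony must contribute replicates 1, 2, 3 exactly once each")
    }
    if (anyDuplicated(rows$label)) {
      add("label_balance", cid,
          "colony reuses a label across its replicates")
    }
  }
  violations <- if (length(v) > 0) {
    do.call(rbind, v)
  } else {
    tibble::tibble(type = character(), where = character(),
                   detail = character())
  }
  structure(list(valid = nrow(violations) == 0, violations = violations),
            class = "design_report")
}

#' @export
print.design_report <- function(x, ...) {
  if (x$valid) {
    cat("Design valid: all constraints satisfied\n")
  } else {
    cat("Design INVALID:", nrow(x$violations), "violation(s)\n")
    print(x$violations)
  }
  invisible(x)
}

#' Ds-type information criterion for population contrasts
#'
#' Scores a design by the log-determinant of the information matrix of the
#' population contrasts after adjusting for the nuisance block and label
#' factors (a Ds-optimality criterion). Larger is better; a design in which
#' the population contrasts are not estimable (singular adjusted information)
#' scores `-Inf` with `feasible = FALSE`. Maximizing this criterion minimizes
#' the generalized variance, hence the standard errors, of the estimated
#' population effects.
#'
#' @param design A `block_design`.
#' @return A list of class `design_score` with `criterion_value` and
#'   `feasible`.
#' @export
d_criterion <- function(design) {
  population <- factor(design$population)
  block <- factor(design$block_id)
  label <- factor(design$label, levels = channel_labels())
  terms <- c("population",
             if (nlevels(block) > 1) "block",
             if (nlevels(label) > 1) "label")
  fml <- stats::as.formula(paste("~", paste(terms, collapse = " + ")))
  X <- model.matrix(fml, data = data.frame(population, block, label),
                    contrasts.arg = c(
                      list(population = "contr.sum"),
                      if (nlevels(block) > 1) list(block = "contr.treatment"),
                      if (nlevels(label) > 1) list(label = "contr.treatment")
                    ))
  pop_cols <- grep("^population", colnames(X))
  M <- crossprod(X)
  nui <- setdiff(seq_len(ncol(X)), pop_cols)
  S <- tryCatch({
    M[pop_cols, pop_cols, drop = FALSE] -
      M[pop_cols, nui, drop = FALSE] %*%
      solve(M[nui, nui, drop = FALSE], M[nui, pop_cols, drop = FALSE])
  }, error = function(e) NULL)
  if (is.null(S)) {
    return(structure(list(criterion_value = -Inf, feasible = FALSE),
                     class = "design_score"))
  }
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev < 1e-8)) {
    return(structure(list(criterion_value = -Inf, feasible = FALSE),
                     class = "design_score"))
  }
  structure(list(criterion_value = sum(log(ev)), feasible = TRUE),
            class = "design_score")
}

#' @export
print.design_score <- function(x, ...) {
  cat("Ds criterion:", format(x$criterion_value),
      if (!x$feasible) "(singular: population contrasts not estimable)",
      "\n")
  invisible(x)
}

#' Write / read a block design as CSV
#'
#' One row per sample: `block_id`, `colony_id`, `population`, `replicate`,
#' `label`.
#'
#' @param design A `block_design`.
#' @param path File path.
#' @return `write_design_csv` returns `path` invisibly; `read_design_csv`
#'   returns a `block_design`.
#' @export
write_design_csv <- function(design, path) {
  write.csv(as.data.frame(design), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @export
read_design_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("block_id", "colony_id", "population", "replicate", "label")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("design file is missing columns: ", paste(missing, collapse = ", "))
  }
  new_block_design(tibble::as_tibble(df[required]))
}
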