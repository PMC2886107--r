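#' Self-organizing tree (SOTA) clustering
#'
#' Divisive neural-network clustering of expression profiles (here,
#' per-protein vectors of one-sided P-values across populations). The tree
#' starts as a single cell holding every profile. Each growth cycle runs
#' adaptation epochs - profiles are presented in input order, assigned to
#' the nearest leaf cell (Euclidean distance, ties to the earliest-created
#' leaf), and the winning cell, its mother and its sister (when the sister
#' is a leaf) move toward the profile by their learning rates - until the
#' relative change of the total assignment error falls below `eps`. The
#' leaf with the greatest diversity (mean member distance to the cell
#' centroid) is then split into two daughters. Growth stops when the tree
#' holds `max_cycles + 1` leaves or every leaf diversity is at most
#' `max_diversity`; leaves are reported as hard clusters. The procedure is
#' deterministic for a fixed input ordering.
#'
#' @param profiles Numeric matrix, one profile per row (row names become
#'   member ids).
#' @param max_cycles Maximum number of split cycles (default 7, giving at
#'   most 8 clusters).
#' @param max_diversity Diversity threshold below which a leaf is not split
#'   (default 0.8).
#' @param rates Learning rates `c(winner, mother, sister)` with
#'   `winner >= mother >= sister > 0`.
#' @param max_epochs Cap on adaptation epochs per cycle.
#' @param eps Relative-error convergence tolerance per cycle.
#' @return An object of class `sota_tree`: list with `cluster` (integer
#'   vector, cluster id per profile), `centroids` (cluster x dimension
#'   matrix of member means), `diversity` (per cluster), `n_leaves`,
#'   `cycles`, and `nodes` (the full binary tree as a data frame).
#' @export
sota_cluster <- function(profiles, max_cycles = 7L, max_diversity = 0.8,
                         rates = c(winner = 0.01, mother = 0.005,
                                   sister = 0.001),
                         max_epochs = 100L, eps = 1e-6) {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 1) stop("at least one profile is required")
  if (is.null(rownames(profiles))) {
    rownames(profiles) <- sprintf("row%04d", seq_len(nrow(profiles)))
  }
  stopifnot(length(rates) == 3, all(rates > 0),
            rates[1] >= rates[2], rates[2] >= rates[3])
  n <- nrow(profiles)
  # node store: centroid matrix grows as nodes are added
  centroid <- matrix(colMeans(profiles), nrow = 1)
  parent <- NA_integer_
  left <- NA_integer_
  right <- NA_integer_
  is_leaf <- TRUE
  assignment <- rep(1L, n)
  leaf_ids <- function() which(is_leaf)
  dist_to <- function(i, node) sqrt(sum((profiles[i, ] - centroid[node, ])^2))
  adapt <- function() {
    prev_err <- Inf
    for (epoch in seq_len(max_epochs)) {
      err <- 0
      leaves <- leaf_ids()
      for (i in seq_len(n)) {
        d <- vapply(leaves, function(nd) dist_to(i, nd), numeric(1))
        w <- leaves[which.min(d)]
        err <- err + min(d)
        centroid[w, ] <<- centroid[w, ] +
          rates[1] * (profiles[i, ] - centroid[w, ])
        pa <- parent[w]
        if (!is.na(pa)) {
          sib <- if (left[pa] == w) right[pa] else left[pa]
          if (is_leaf[sib]) {
            centroid[pa, ] <<- centroid[pa, ] +
              rates[2] * (profiles[i, ] - centroid[pa, ])
            centroid[sib, ] <<- centroid[sib, ] +
              rates[3] * (profiles[i, ] - centroid[sib, ])
          }
        }
      }
      if (is.finite(prev_err) && prev_err > 0 &&
          abs(prev_err - err) / prev_err < eps) break
      if (err == 0) break
      prev_err <- err
    }
  }
  harden <- function() {
    leaves <- leaf_ids()
    for (i in seq_len(n)) {
      d <- vapply(leaves, function(nd) dist_to(i, nd), numeric(1))
      assignment[i] <<- leaves[which.min(d)]
    }
    # snap leaf centroids to member means so diversity is a property of the
    # hard partition (singletons and identical members get exactly 0)
    for (nd in leaves) {
      members <- which(assignment == nd)
      if (length(members) > 0) {
        centroid[nd, ] <<- colMeans(profiles[members, , drop = FALSE])
      }
    }
  }
  leaf_diversity <- function(nd) {
    members <- which(assignment == nd)
    if (length(members) == 0) return(0)
    mean(vapply(members, function(i) dist_to(i, nd), numeric(1)))
  }
  harden()
  cycles <- 0L
  repeat {
    leaves <- leaf_ids()
    div <- vapply(leaves, leaf_diversity, numeric(1))
    if (length(leaves) >= max_cycles + 1L) break
    if (all(div <= max_diversity)) break
    sizes <- vapply(leaves, function(nd) sum(assignment == nd), numeric(1))
    splittable <- leaves[sizes >= 2]
    if (length(splittable) == 0) break
    target <- splittable[which.max(div[match(splittable, leaves)])]
    for (side in 1:2) {
      centroid <- rbind(centroid, centroid[target, ])
      parent <- c(parent, target)
      left <- c(left, NA_integer_)
      right <- c(right, NA_integer_)
      is_leaf <- c(is_leaf, TRUE)
    }
    left[target] <- nrow(centroid) - 1L
    right[target] <- nrow(centroid)
    is_leaf[target] <- FALSE
    cycles <- cycles + 1L
    adapt()
    harden()
  }
  leaves <- leaf_ids()
  div <- vapply(leaves, leaf_diversity, numeric(1))
  keep <- vapply(leaves, function(nd) sum(assignment == nd) > 0, logical(1))
  leaves <- leaves[keep]
  div <- div[keep]
  cluster <- match(assignment, leaves)
  names(cluster) <- rownames(profiles)
  centroids <- centroid[leaves, , drop = FALSE]
  rownames(centroids) <- paste0("cluster", seq_along(leaves))
  colnames(centroids) <- colnames(profiles)
  nodes <- data.frame(id = seq_len(nrow(centroid)), parent = parent,
                      left = left, right = right, is_leaf = is_leaf)
  structure(list(cluster = cluster, centroids = centroids, diversity = div,
                 n_leaves = length(leaves), cycles = cycles, nodes = nodes),
            class = "sota_tree")
}

#' @export
print.sota_tree <- function(x, ...) {
  cat("sota_tree:", x$n_leaves, "clusters after", x$cycles, "cycles\n")
  sizes <- table(x$cluster)
  for (k in seq_len(x$n_leaves)) {
    cat(sprintf("  cluster %d: %d members, diversity %.4f\n",
                k, sizes[as.character(k)], x$diversity[k]))
  }
  invisible(x)
}

#' Diversity of a cluster cell
#'
#' Mean Euclidean distance of member profiles to the cell centroid. Zero
#' for a singleton or for identical members; scales linearly with the data.
#'
#' @param members Numeric matrix of member profiles (rows).
#' @param centroid Cell centroid; defaults to the member mean.
#' @return A non-negative scalar.
#' @export
cell_diversity <- function(members, centroid = colMeans(members)) {
  members <- as.matrix(members)
  if (nrow(members) == 0) stop("cell must be nonempty")
  mean(sqrt(rowSums(sweep(members, 2, centroid)^2)))
}

#' Cluster assignment table
#'
#' @param tree A `sota_tree`.
#' @return A tibble `protein_id`, `cluster_id`.
#' @export
sota_assignments <- function(tree) {
  stopifnot(inherits(tree, "sota_tree"))
  tibble::tibble(protein_id = names(tree$cluster),
                 cluster_id = as.integer(tree$cluster))
}
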