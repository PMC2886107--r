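#' Aggregate population effects over pathway gene sets
#'
#' For each pathway, summarizes the population-effect values of its member
#' proteins per population with the median (default) or mean. Composite
#' pathways are expressed naturally by listing a protein under several
#' pathway ids in the map. Pathways with no member carrying an effect for a
#' population get `NA` there; entirely empty pathways are skipped with a
#' warning.
#'
#' @param effects Long tibble with columns `protein_id`, `population`,
#'   `effect` (e.g. the `effects` element of an `lme_pop_fit`).
#' @param pathway_map Data frame with columns `pathway_id`, `protein_id`
#'   and optionally `pathway_name`.
#' @param stat `"median"` (default) or `"mean"`.
#' @return A tibble: `pathway_id`, `pathway_name`, `population`, `value`,
#'   `n_members`.
#' @export
pathway_profile <- function(effects, pathway_map,
                            stat = c("median", "mean")) {
  stat <- match.arg(stat)
  agg <- if (stat == "median") median else mean
  stopifnot(all(c("protein_id", "population", "effect") %in% names(effects)),
            all(c("pathway_id", "protein_id") %in% names(pathway_map)))
  pops <- sort(unique(effects$population))
  ids <- unique(pathway_map$pathway_id)
  rows <- list()
  for (pw in ids) {
    members <- unique(pathway_map$protein_id[pathway_map$pathway_id == pw])
    sub <- effects[effects$protein_id %in% members &
                     !is.na(effects$effect), , drop = FALSE]
    if (nrow(sub) == 0) {
      warning("pathway ", pw, " has no member with effects; skipped")
      next
    }
    name <- if ("pathway_name" %in% names(pathway_map)) {
      pathway_map$pathway_name[match(pw, pathway_map$pathway_id)]
    } else {
      NA_character_
    }
    for (p in pops) {
      v <- sub$effect[sub$population == p]
      rows[[length(rows) + 1L]] <- tibble::tibble(
        pathway_id = pw, pathway_name = name, population = p,
        value = if (length(v) > 0) agg(v) else NA_real_,
        n_members = length(v)
      )
    }
  }
  do.call(rbind, rows)
}

#' Quadratic regression of pathway effect on absolute latitude
#'
#' Ordinary least squares of a per-population aggregate value on absolute
#' latitude: `Y = b0 + b1 * A + b2 * A^2` with `A = |latitude|` in degrees.
#' Reports the coefficients, the coefficient of determination and the
#' Pearson correlation between fitted and observed values (equal to
#' `sqrt(R^2)` by the OLS identity).
#'
#' @param values Numeric vector of per-population aggregates (e.g. one
#'   pathway's medians), aligned with `latitudes`.
#' @param latitudes Signed latitudes in degrees; their absolute value is
#'   the regressor.
#' @return A list of class `latitude_fit`: `beta0`, `beta1`, `beta2`,
#'   `r_squared`, `pearson_r`, `fitted`, `model`.
#' @export
latitude_regression <- function(values, latitudes) {
  stopifnot(length(values) == length(latitudes))
  keep <- !is.na(values) & !is.na(latitudes)
  values <- values[keep]
  A <- abs(latitudes[keep])
  if (length(unique(A)) < 3) {
    stop("need >= 3 distinct absolute latitudes for a quadratic fit")
  }
  m <- lm(values ~ A + I(A^2))
  b <- unname(coef(m))
  fitted <- unname(stats::fitted(m))
  sst <- sum((values - mean(values))^2)
  r2 <- if (sst == 0) 0 else 1 - sum(stats::residuals(m)^2) / sst
  r <- if (sst == 0 || sd(fitted) == 0) {
    NA_real_
  } else {
    cor(fitted, values)
  }
  structure(list(beta0 = b[1], beta1 = b[2], beta2 = b[3],
                 r_squared = r2, pearson_r = r, fitted = fitted, model = m),
            class = "latitude_fit")
}

#' @export
print.latitude_fit <- function(x, ...) {
  cat(sprintf("Y = %.4g %+.4g A %+.4g A^2   (A = |latitude|)\n",
              x$beta0, x$beta1, x$beta2))
  cat(sprintf("R^2 = %.4f, r = %s\n", x$r_squared,
              if (is.na(x$pearson_r)) "NA" else sprintf("%.4f", x$pearson_r)))
  invisible(x)
}

#' Read a pathway map TSV
#'
#' Columns: `pathway_id`, `protein_id`, optionally `pathway_name`.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_pathway_map_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("pathway_id", "protein_id"), names(df))
  if (length(missing) > 0) {
    stop("pathway map is missing columns: ", paste(missing, collapse = ", "))
  }
  tibble::as_tibble(df)
}

#' Write / read a roster CSV
#'
#' Columns: `name`, `n_colonies`, `latitude_deg`.
#'
#' @param roster A roster tibble.
#' @param path File path.
#' @return `write_roster_csv` returns `path` invisibly; `read_roster_csv`
#'   a validated roster tibble.
#' @export
write_roster_csv <- function(roster, path) {
  write.csv(as.data.frame(roster), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_roster_csv
#' @export
read_roster_csv <- function(path) {
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  validate_roster(df)
  df
}
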