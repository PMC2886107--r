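#' One-sided P-values from effects and standard errors
#'
#' Converts estimated population effects to upper-tail probabilities
#' `p1 = pnorm(effect / se)` so that values near 1 indicate a strong
#' positive effect and values near 0 a strong negative effect, while
#' populations with indistinguishable expression sit near 0.5.
#'
#' @param effects Numeric vector of effects (log scale).
#' @param ses Positive standard errors, same length.
#' @return Vector of one-sided P-values in (0, 1).
#' @export
one_sided_pvalues <- function(effects, ses) {
  stopifnot(length(effects) == length(ses))
  if (any(ses[!is.na(ses)] <= 0)) stop("standard errors must be positive")
  pnorm(effects / ses)
}

#' Two-sided P-values from one-sided P-values
#'
#' Applies the exact folding `p2 = 1 - 2 * |p1 - 0.5|` (an inverted V
#' centred at 0.5), recovering the conventional two-sided P-value from the
#' directional one.
#'
#' @param p1 One-sided P-values in (0, 1).
#' @return Two-sided P-values in \[0, 1\].
#' @export
two_sided_from_one_sided <- function(p1) {
  stopifnot(all(is.na(p1) | (p1 >= 0 & p1 <= 1)))
  1 - 2 * abs(p1 - 0.5)
}

lmer_ctrl <- function() {
  lme4::lmerControl(
    calc.derivs = FALSE,
    check.conv.singular = "ignore",
    check.nobs.vs.nlev = "ignore",
    check.nobs.vs.nRE = "ignore"
  )
}

# Long-format observations for one protein row of a ratio_matrix.
protein_long <- function(values_row, design_lut) {
  ok <- !is.na(values_row)
  cbind(design_lut[match(names(values_row)[ok], design_lut$key), ,
                   drop = FALSE],
        data.frame(value = unname(values_row[ok])))
}

design_lookup <- function(design) {
  data.frame(
    key = paste(design$block_id, design$label, sep = "|"),
    block_id = design$block_id,
    label = design$label,
    colony_id = design$colony_id,
    population = design$population,
    stringsAsFactors = FALSE
  )
}

#' Fit the population mixed model for one protein
#'
#' Linear mixed-effects model of the normalized log-scale measurements:
#' fixed effects for population (sum-to-zero coding, so the eight effects
#' average to zero), block and label; a random intercept per colony to
#' account for the three repeated measures of each colony. Effects and
#' standard errors come from the REML fit. The overall population factor
#' P-value defaults to a Wald F test of all population contrasts on the
#' REML fit, with numerator df = populations present minus one and
#' denominator df = residual df (observations minus fixed-effect
#' parameters); this is exact in the vanishing-colony-variance limit and
#' stays calibrated despite the large nuisance (block) parameterization.
#' A maximum-likelihood likelihood-ratio chi-squared test is available via
#' `factor_test = "lrt"` but is markedly anticonservative at triplex block
#' sizes.
#'
#' @param df Long-format data for one protein with columns `value`,
#'   `block_id`, `label`, `colony_id`, `population`.
#' @param populations Character vector fixing the population order of the
#'   returned effect vector (populations without data get `NA`).
#' @param factor_test `"wald_f"` (default) or `"lrt"`; `"none"` skips the
#'   factor test.
#' @return A list: `effects`, `ses`, `p1`, `p2` (named by population),
#'   `factor_pvalue`, `n_blocks_observed`, `n_obs`, `singular`, `ok`,
#'   and `message` when the fit failed.
#' @export
fit_protein_lme <- function(df, populations = sort(unique(df$population)),
                            factor_test = c("wald_f", "lrt", "none")) {
  factor_test <- match.arg(factor_test)
  out <- list(
    effects = setNames(rep(NA_real_, length(populations)), populations),
    ses = setNames(rep(NA_real_, length(populations)), populations),
    p1 = setNames(rep(NA_real_, length(populations)), populations),
    p2 = setNames(rep(NA_real_, length(populations)), populations),
    factor_pvalue = NA_real_,
    n_blocks_observed = length(unique(df$block_id)),
    n_obs = nrow(df),
    singular = NA,
    ok = FALSE,
    message = NULL
  )
  if (length(unique(df$block_id)) < 2 || length(unique(df$population)) < 2) {
    out$message <- "needs >= 2 blocks and >= 2 populations with data"
    return(out)
  }
  df$population <- droplevels(factor(df$population, levels = populations))
  df$block <- droplevels(factor(df$block_id))
  df$label <- droplevels(factor(df$label, levels = channel_labels()))
  df$colony <- factor(df$colony_id)
  k <- nlevels(df$population)
  rhs <- c("population",
           if (nlevels(df$block) > 1) "block",
           if (nlevels(df$label) > 1) "label")
  fml <- stats::as.formula(
    paste("value ~", paste(rhs, collapse = " + "), "+ (1 | colony)"))
  contr <- list(population = "contr.sum")
  fit <- tryCatch(
    suppressMessages(suppressWarnings(
      lme4::lmer(fml, data = df, REML = TRUE, contrasts = contr,
                 control = lmer_ctrl())
    )),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    out$message <- conditionMessage(fit)
    return(out)
  }
  fe <- lme4::fixef(fit)
  pop_names <- paste0("population", seq_len(k - 1))
  if (!all(pop_names %in% names(fe))) {
    out$message <- "population contrasts not estimable (rank deficient)"
    return(out)
  }
  beta <- fe[pop_names]
  V <- as.matrix(vcov(fit))[pop_names, pop_names, drop = FALSE]
  # sum-to-zero coding: effect of level j < k is beta_j, of level k the
  # negative sum; contrast rows give the matching standard errors
  L <- rbind(diag(k - 1), rep(-1, k - 1))
  eff <- as.vector(L %*% beta)
  se <- sqrt(diag(L %*% V %*% t(L)))
  present <- levels(df$population)
  out$effects[present] <- eff
  out$ses[present] <- se
  out$p1[present] <- one_sided_pvalues(eff, se)
  out$p2[present] <- two_sided_from_one_sided(out$p1[present])
  out$singular <- lme4::isSingular(fit)
  if (factor_test == "wald_f") {
    q <- k - 1
    p_fixed <- length(fe)
    df2 <- nrow(df) - p_fixed
    out$factor_pvalue <- if (df2 > 0) {
      Fstat <- as.numeric(crossprod(beta, solve(V, beta))) / q
      stats::pf(Fstat, q, df2, lower.tail = FALSE)
    } else {
      NA_real_
    }
  } else if (factor_test == "lrt") {
    red_rhs <- setdiff(rhs, "population")
    red_fml <- stats::as.formula(
      paste("value ~", if (length(red_rhs) > 0) {
        paste(red_rhs, collapse = " + ")
      } else {
        "1"
      }, "+ (1 | colony)"))
    lrt_p <- tryCatch({
      full_ml <- suppressMessages(suppressWarnings(lme4::refitML(fit)))
      red_ml <- suppressMessages(suppressWarnings(
        lme4::lmer(red_fml, data = df, REML = FALSE, control = lmer_ctrl())
      ))
      stat <- max(0, 2 * (as.numeric(stats::logLik(full_ml)) -
                            as.numeric(stats::logLik(red_ml))))
      pchisq(stat, df = k - 1, lower.tail = FALSE)
    }, error = function(e) NA_real_)
    out$factor_pvalue <- lrt_p
  }
  out$ok <- TRUE
  out
}

#' Per-protein population effects for a whole matrix
#'
#' Applies [fit_protein_lme()] to every protein of a normalized
#' `ratio_matrix`, mapping each observed `(block, label)` channel back to
#' its colony and population through the design.
#'
#' @param x A normalized `ratio_matrix`.
#' @param factor_test Factor test per protein: `"wald_f"` (default),
#'   `"lrt"`, or `"none"` to skip it.
#' @param min_blocks Proteins observed in fewer blocks are skipped.
#' @return An object of class `lme_pop_fit`: a list with `effects` (long
#'   tibble: `protein_id`, `population`, `effect`, `se`, `p1`, `p2`),
#'   `proteins` (per-protein tibble with `factor_pvalue`,
#'   `n_blocks_observed`, `n_obs`, `singular`, `ok`, `message`) and
#'   `populations`.
#' @export
lme_population <- function(x, factor_test = c("wald_f", "lrt", "none"),
                           min_blocks = 2L) {
  factor_test <- match.arg(factor_test)
  stopifnot(inherits(x, "ratio_matrix"))
  design <- x$design
  populations <- sort(unique(design$population))
  lut <- design_lookup(design)
  proteins <- rownames(x$values)
  fits <- vector("list", length(proteins))
  for (i in seq_along(proteins)) {
    df <- protein_long(x$values[i, ], lut)
    if (length(unique(df$block_id)) < min_blocks) {
      fits[[i]] <- NULL
      next
    }
    fits[[i]] <- fit_protein_lme(df, populations = populations,
                                 factor_test = factor_test)
  }
  keep <- !vapply(fits, is.null, logical(1))
  proteins <- proteins[keep]
  fits <- fits[keep]
  effects <- tibble::tibble(
    protein_id = rep(proteins, each = length(populations)),
    population = rep(populations, length(proteins)),
    effect = unlist(lapply(fits, `[[`, "effects"), use.names = FALSE),
    se = unlist(lapply(fits, `[[`, "ses"), use.names = FALSE),
    p1 = unlist(lapply(fits, `[[`, "p1"), use.names = FALSE),
    p2 = unlist(lapply(fits, `[[`, "p2"), use.names = FALSE)
  )
  protein_tbl <- tibble::tibble(
    protein_id = proteins,
    factor_pvalue = vapply(fits, `[[`, numeric(1), "factor_pvalue"),
    n_blocks_observed = vapply(fits, `[[`, numeric(1), "n_blocks_observed"),
    n_obs = vapply(fits, `[[`, numeric(1), "n_obs"),
    singular = vapply(fits, `[[`, logical(1), "singular"),
    ok = vapply(fits, `[[`, logical(1), "ok"),
    message = vapply(fits, function(f) {
      if (is.null(f$message)) NA_character_ else f$message
    }, character(1))
  )
  structure(list(effects = effects, proteins = protein_tbl,
                 populations = populations),
            class = "lme_pop_fit")
}

#' @export
print.lme_pop_fit <- function(x, ...) {
  cat("lme_pop_fit:", nrow(x$proteins), "proteins,",
      length(x$populations), "populations\n")
  cat("fitted ok:", sum(x$proteins$ok), " failed:", sum(!x$proteins$ok), "\n")
  invisible(x)
}

#' Per-population significant protein sets
#'
#' Selects proteins whose overall population factor is significant at
#' `alpha` (strict `<`) and assigns each, per population, to the up- or
#' down-regulated set according to the sign of its population effect; a
#' zero (or missing) effect joins neither set. Proteins whose fit failed
#' are excluded.
#'
#' @param fit An `lme_pop_fit`.
#' @param alpha Significance threshold on the factor P-value (default 0.05).
#' @return A `significance_table`: tibble with `protein_id`, `population`,
#'   `effect`, `direction` ("up"/"down"), carrying the significant protein
#'   ids, the background (all successfully fitted proteins) and `alpha` as
#'   attributes.
#' @export
significance_table <- function(fit, alpha = 0.05) {
  stopifnot(inherits(fit, "lme_pop_fit"))
  ok <- fit$proteins[fit$proteins$ok & !is.na(fit$proteins$factor_pvalue), ]
  sig_ids <- ok$protein_id[ok$factor_pvalue < alpha]
  rows <- fit$effects[fit$effects$protein_id %in% sig_ids &
                        !is.na(fit$effects$effect) &
                        fit$effects$effect != 0, , drop = FALSE]
  out <- tibble::tibble(
    protein_id = rows$protein_id,
    population = rows$population,
    effect = rows$effect,
    direction = ifelse(rows$effect > 0, "up", "down")
  )
  attr(out, "alpha") <- alpha
  attr(out, "significant_ids") <- sig_ids
  attr(out, "background_ids") <- ok$protein_id
  class(out) <- c("significance_table", class(out))
  out
}

#' One-sided P-value profile matrix
#'
#' Extracts the proteins x populations matrix of one-sided P-values, the
#' input expected by [sota_cluster()]. Defaults to the complete fitted set;
#' pass `proteins` (e.g. the significant ids of a [significance_table()])
#' to restrict.
#'
#' @param fit An `lme_pop_fit`.
#' @param proteins Optional protein ids to keep, in order.
#' @return Numeric matrix of `p1` values, rows named by protein, columns by
#'   population; rows with any missing value are dropped.
#' @export
pvalue_profiles <- function(fit, proteins = NULL) {
  stopifnot(inherits(fit, "lme_pop_fit"))
  eff <- fit$effects
  if (!is.null(proteins)) {
    eff <- eff[eff$protein_id %in% proteins, , drop = FALSE]
  }
  ids <- unique(eff$protein_id)
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(fit$populations),
              dimnames = list(ids, fit$populations))
  m[cbind(match(eff$protein_id, ids),
          match(eff$population, fit$populations))] <- eff$p1
  m[stats::complete.cases(m), , drop = FALSE]
}

#' Write per-protein results as TSV
#'
#' Wide layout mirroring the classical expression spreadsheet: protein id,
#' the one-sided P-value per population, the population (stock) effect per
#' population, the factor P-value and a significance flag at `alpha`.
#'
#' @param fit An `lme_pop_fit`.
#' @param path File path.
#' @param alpha Threshold for the significance flag.
#' @return `path`, invisibly.
#' @export
write_lme_results_tsv <- function(fit, path, alpha = 0.05) {
  stopifnot(inherits(fit, "lme_pop_fit"))
  pops <- fit$populations
  ids <- fit$proteins$protein_id
  p1 <- pvalue_matrix_of(fit, "p1")
  eff <- pvalue_matrix_of(fit, "effect")
  df <- data.frame(protein_id = ids, check.names = FALSE)
  for (p in pops) df[[paste0("p1_", p)]] <- p1[ids, p]
  for (p in pops) df[[paste0("effect_", p)]] <- eff[ids, p]
  df$factor_pvalue <- fit$proteins$factor_pvalue
  df$significant <- !is.na(df$factor_pvalue) & df$factor_pvalue < alpha
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

pvalue_matrix_of <- function(fit, column) {
  eff <- fit$effects
  ids <- unique(eff$protein_id)
  m <- matrix(NA_real_, nrow = length(ids), ncol = length(fit$populations),
              dimnames = list(ids, fit$populations))
  m[cbind(match(eff$protein_id, ids),
          match(eff$population, fit$populations))] <- eff[[column]]
  m
}
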