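# Comparing species assignments across delimitation criteria and testing
# the neighbourhood effect on congruence.

pure_labels_ <- function(v) setdiff(unique(v[!is.na(v)]), "intermediate")

#' Harmonize group naming across assignment criteria
#'
#' Group labels produced by independent delimitation methods are arbitrary
#' (one method's "S1" may be another's "S2"). For each non-reference
#' criterion, the two pure labels are mapped onto the reference criterion's
#' pure labels by maximum-agreement assignment on the 2x2 overlap of
#' individuals that are non-intermediate under both; intermediates are left
#' untouched.
#'
#' @param table data frame with an `id` column and one column per criterion,
#'   cells in `{pure label 1, pure label 2, "intermediate", NA}`.
#' @param reference name of the reference criterion column (default: the
#'   first criterion column).
#' @return the table with every criterion's pure labels renamed to the
#'   reference's.
#' @export
harmonize_labels <- function(table, reference = NULL) {
  crit <- setdiff(names(table), "id")
  if (length(crit) < 2) stop("need at least 2 criteria")
  reference <- reference %||% crit[1]
  ref <- table[[reference]]
  ref_pure <- pure_labels_(ref)
  if (length(ref_pure) != 2) stop("reference criterion must have 2 pure labels")
  for (cn in setdiff(crit, reference)) {
    v <- table[[cn]]
    pv <- pure_labels_(v)
    if (length(pv) != 2) stop("criterion ", cn, " must have 2 pure labels")
    both <- !is.na(v) & !is.na(ref) & v != "intermediate" &
      ref != "intermediate"
    if (!any(both)) stop("degenerate overlap with ", cn,
                         ": no individual pure under both criteria")
    # agreement under identity pairing vs the swap; pick the better
    agree_id <- sum(v[both] == ifelse(ref[both] == ref_pure[1],
                                      pv[1], pv[2]))
    agree_sw <- sum(v[both] == ifelse(ref[both] == ref_pure[1],
                                      pv[2], pv[1]))
    map <- if (agree_sw > agree_id) stats::setNames(ref_pure, rev(pv))
           else stats::setNames(ref_pure, pv)
    idx <- !is.na(v) & v %in% pv
    table[[cn]][idx] <- map[v[idx]]
  }
  table
}

#' Summarize congruence between delimitation criteria
#'
#' Classifies every individual by how its labels behave across criteria:
#' fully consistent (same pure label everywhere), species inversion (pure
#' under at least two criteria with conflicting pure labels), or an
#' intermediate-driven discrepancy (not fully consistent, but with no pure
#' conflict — every disagreement involves the intermediate class). Rows with
#' any missing cell are counted separately.
#'
#' @param table a [harmonize_labels()]-ed assignment table.
#' @return object of class `"congruence_report"`: counts per category,
#'   per-species fully-consistent counts, number of individuals intermediate
#'   under at least one criterion, the fraction of discrepancies caused by
#'   intermediate assignments, and the pairwise criterion agreement matrix.
#' @export
congruence_summary <- function(table) {
  crit <- setdiff(names(table), "id")
  lab <- as.matrix(table[crit])
  n <- nrow(lab)
  cat_of_row <- function(v) {
    if (anyNA(v)) return("missing")
    pure <- v[v != "intermediate"]
    if (length(pure) == length(v) && length(unique(pure)) == 1)
      return("consistent")
    if (length(unique(pure)) > 1) return("inversion")
    "intermediate_discrepancy"
  }
  rowcat <- apply(lab, 1, cat_of_row)
  cons <- rowcat == "consistent"
  tb <- table(lab[cons, 1])
  by_species <- stats::setNames(as.integer(tb), names(tb))
  n_inter_any <- sum(apply(lab, 1, function(v)
    any(!is.na(v) & v == "intermediate")))
  n_disc <- sum(rowcat %in% c("inversion", "intermediate_discrepancy"))
  agree <- matrix(NA_real_, length(crit), length(crit),
                  dimnames = list(crit, crit))
  for (i in seq_along(crit)) for (j in seq_along(crit)) {
    ok <- !is.na(lab[, i]) & !is.na(lab[, j])
    agree[i, j] <- mean(lab[ok, i] == lab[ok, j])
  }
  structure(list(
    n = n,
    n_consistent = sum(cons),
    consistent_by_species = by_species,
    n_inversions = sum(rowcat == "inversion"),
    n_intermediate_discrepancies = sum(rowcat == "intermediate_discrepancy"),
    n_missing = sum(rowcat == "missing"),
    n_intermediate_any = n_inter_any,
    frac_discrepancies_from_intermediates =
      if (n_disc > 0) sum(rowcat == "intermediate_discrepancy") / n_disc
      else NA_real_,
    agreement = agree,
    row_category = stats::setNames(rowcat, table$id)
  ), class = "congruence_report")
}

#' @export
print.congruence_report <- function(x, ...) {
  cat(sprintf("Congruence over %d individuals:\n", x$n))
  cat(sprintf("  fully consistent: %d (%s)\n", x$n_consistent,
              paste(sprintf("%s: %d", names(x$consistent_by_species),
                            x$consistent_by_species), collapse = ", ")))
  cat(sprintf("  species inversions: %d\n", x$n_inversions))
  cat(sprintf("  intermediate-driven discrepancies: %d\n",
              x$n_intermediate_discrepancies))
  if (x$n_missing > 0) cat(sprintf("  missing: %d\n", x$n_missing))
  cat(sprintf("  intermediate under >=1 criterion: %d\n",
              x$n_intermediate_any))
  if (!is.na(x$frac_discrepancies_from_intermediates))
    cat(sprintf("  %.0f%% of discrepancies caused by intermediates\n",
                100 * x$frac_discrepancies_from_intermediates))
  invisible(x)
}

#' Proportion of allospecific neighbours within a radius
#'
#' For each focal individual with a pure species label, the fraction of
#' other purely-labelled individuals within `radius` metres (Euclidean,
#' boundary inclusive) that belong to the other species. Intermediates are
#' excluded both as focals and as neighbours. Individuals with no neighbour
#' in range get `NA`.
#'
#' @param coords data frame with columns `id`, `x`, `y`.
#' @param labels named character vector (names = ids) of labels; only
#'   `"S1"`/`"S2"` (or any two pure values) are used.
#' @param radius neighbourhood radius in metres (default 69, the average
#'   within-stand pollen dispersal distance of the less-dispersing oak
#'   species).
#' @return named numeric vector over the purely-labelled ids.
#' @export
allospecific_fraction <- function(coords, labels, radius = 69) {
  if (radius <= 0) stop("radius must be positive")
  lab <- labels[match(coords$id, names(labels))]
  pure <- !is.na(lab) & lab != "intermediate"
  ids <- coords$id[pure]
  xy <- cbind(coords$x, coords$y)[pure, , drop = FALSE]
  lv <- lab[pure]
  D <- as.matrix(stats::dist(xy))
  out <- rep(NA_real_, length(ids))
  for (i in seq_along(ids)) {
    nb <- which(D[i, ] <= radius)
    nb <- nb[nb != i]
    if (length(nb) > 0) out[i] <- mean(lv[nb] != lv[i])
  }
  stats::setNames(out, ids)
}

#' Logistic regression of assignment congruence on neighbourhood composition
#'
#' Tests whether the proportion of allospecific neighbours predicts whether
#' an individual's interfertility-based assignment agrees with its
#' genotype/morphology consensus. Reports the likelihood-ratio chi-squared
#' (df = 1) against the intercept-only model (the Wald statistic is stored
#' alongside) and the mean allospecific fraction in each outcome group.
#'
#' @param congruent logical (or 0/1) outcome per individual.
#' @param fraction allospecific neighbour fraction per individual.
#' @return object of class `"neighborhood_test"`: list with `slope`,
#'   `intercept`, `chisq`, `df`, `p_value`, `wald_z`, `group_means`
#'   (congruent / incongruent), `n`, `unreliable` (complete-separation
#'   flag), and the underlying `glm` fit.
#' @export
congruence_glm <- function(congruent, fraction) {
  ok <- !is.na(congruent) & !is.na(fraction)
  y <- as.integer(congruent[ok])
  x <- fraction[ok]
  if (length(unique(y)) < 2) stop("both outcome classes must be present")
  if (length(unique(x)) < 2 && stats::var(x) == 0) {
    # constant predictor: no information, LRT is exactly zero
    return(structure(list(slope = 0, intercept = stats::qlogis(mean(y)),
                          chisq = 0, df = 1L, p_value = 1, wald_z = NA_real_,
                          group_means = c(congruent = mean(x[y == 1]),
                                          incongruent = mean(x[y == 0])),
                          n = length(y), unreliable = FALSE, glm = NULL),
                     class = "neighborhood_test"))
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ x, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  chisq <- fit$null.deviance - fit$deviance
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  unreliable <- sep_warn || (is.finite(co[2]) && abs(co[2]) > 15)
  structure(list(
    slope = unname(co[2]), intercept = unname(co[1]),
    chisq = chisq, df = 1L,
    p_value = stats::pchisq(chisq, df = 1, lower.tail = FALSE),
    wald_z = unname(co[2] / se[2]),
    group_means = c(congruent = mean(x[y == 1]),
                    incongruent = mean(x[y == 0])),
    n = length(y), unreliable = unreliable, glm = fit
  ), class = "neighborhood_test")
}

#' @export
print.neighborhood_test <- function(x, ...) {
  cat(sprintf(
    "Neighbourhood effect on congruence (logistic regression, n = %d)\n",
    x$n))
  cat(sprintf("  slope = %.3f, LRT chi-sq = %.2f, df = %d, p = %.3g%s\n",
              x$slope, x$chisq, x$df, x$p_value,
              if (x$unreliable) "  [separation: test unreliable]" else ""))
  cat(sprintf(
    "  mean allospecific fraction: %.0f%% (congruent) vs %.0f%% (incongruent)\n",
    100 * x$group_means["congruent"], 100 * x$group_means["incongruent"]))
  invisible(x)
}
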