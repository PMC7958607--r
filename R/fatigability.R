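# Pittsburgh Fatigability Scale (PFS) Physical score handling and the
# association toolkit around it: scoring with person-mean imputation,
# the >= 15 fatigability cut point, rank-based group comparisons, logistic
# odds ratios, and Cohen's d effect sizes.

#' Score the 10-item PFS Physical scale
#'
#' Items are 0 ("no fatigue") to 5 ("extreme fatigue"); the Physical score
#' is their sum (0-50). With 1 to `max_missing` missing items, each missing
#' item is imputed with the mean of the respondent's completed items
#' (person-mean imputation) and the sum is rounded to the nearest integer;
#' with more missing the score is missing.
#'
#' @param items numeric vector of 10 responses in `0:5`, `NA` allowed.
#' @param max_missing maximum imputable missing items (default 3).
#' @return list with `score` (integer or `NA`) and `imputed` (logical).
#' @export
score_pfs <- function(items, max_missing = 3L) {
  if (length(items) != 10L)
    stop_rar("PFS has exactly 10 items", "rar_data_error")
  obs <- items[!is.na(items)]
  if (length(obs) && (any(obs < 0) || any(obs > 5) || any(obs != round(obs))))
    stop_rar("PFS responses must be integers in 0..5", "rar_data_error")
  n_miss <- sum(is.na(items))
  if (n_miss == 0L)
    return(list(score = as.integer(sum(items)), imputed = FALSE))
  if (n_miss > max_missing || length(obs) == 0L)
    return(list(score = NA_integer_, imputed = FALSE))
  list(score = as.integer(round(sum(obs) + n_miss * mean(obs))),
       imputed = TRUE)
}

#' Greater perceived physical fatigability
#'
#' `TRUE` when the PFS Physical score meets the established cut point
#' (default 15, boundary inclusive).
#'
#' @param score PFS Physical score(s), 0-50; `NA` propagates.
#' @param cutpoint threshold (default 15).
#' @return logical vector.
#' @export
classify_fatigability <- function(score, cutpoint = 15L) {
  if (any(!is.na(score) & (score < 0 | score > 50)))
    stop_rar("PFS scores must lie in 0..50", "rar_data_error")
  score >= cutpoint
}

#' Rank-based comparisons of scores across groups
#'
#' Kruskal-Wallis test (tie-corrected, chi-square reference) across all
#' groups, plus all pairwise two-sample Wilcoxon rank-sum tests (normal
#' approximation with tie and continuity correction). Pairwise p-values are
#' unadjusted by default; `p_adjust = "holm"` applies a Holm correction.
#'
#' @param scores numeric outcome vector.
#' @param groups group membership vector (coerced to factor).
#' @param p_adjust `"none"` (default) or any [stats::p.adjust()] method.
#' @return list with `kruskal` (`statistic`, `df`, `p_value`) and
#'   `pairwise` data frame (`group_a`, `group_b`, `p_value`).
#' @export
group_comparison_tests <- function(scores, groups, p_adjust = "none") {
  groups <- factor(groups)
  if (nlevels(groups) < 2L)
    stop_rar("need at least two groups", "rar_usage_error")
  if (any(table(groups) == 0L))
    stop_rar("empty group", "rar_usage_error")
  kw <- stats::kruskal.test(scores, groups)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2L)
  pw <- data.frame(
    group_a = pairs[1L, ], group_b = pairs[2L, ], p_value = NA_real_,
    row.names = NULL
  )
  for (i in seq_len(ncol(pairs))) {
    wt <- suppressWarnings(stats::wilcox.test(
      scores[groups == pairs[1L, i]], scores[groups == pairs[2L, i]],
      exact = FALSE, correct = TRUE))
    pw$p_value[i] <- wt$p.value
  }
  if (p_adjust != "none") pw$p_value <- stats::p.adjust(pw$p_value, p_adjust)
  list(
    kruskal = list(statistic = unname(kw$statistic),
                   df = unname(kw$parameter),
                   p_value = kw$p.value),
    pairwise = pw
  )
}

#' Odds ratio for greater fatigability per unit of a predictor
#'
#' Maximum-likelihood logistic regression (IRLS via [stats::glm()]) of the
#' fatigability flag on a predictor plus covariates; reports `exp(coef)` per
#' unit of each predictor with Wald confidence intervals. Complete
#' separation is flagged and the affected estimates suppressed.
#'
#' @param fatigued logical (or 0/1) outcome vector.
#' @param design data frame of predictor and covariates.
#' @param ci_level confidence level (default 0.95).
#' @return data frame `term, odds_ratio, ci_lower, ci_upper, p_value` with
#'   attribute `separated`.
#' @export
logistic_fatigability_or <- function(fatigued, design, ci_level = 0.95) {
  design <- as.data.frame(design)
  cc <- stats::complete.cases(fatigued, design)
  df <- data.frame(.y = as.integer(fatigued[cc]), design[cc, , drop = FALSE])
  sep <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = df, family = stats::binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep <<- TRUE
      invokeRestart("muffleWarning")
    })
  sm <- summary(fit)$coefficients
  sep <- sep || any(abs(sm[, "Estimate"]) > 15)
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  out <- data.frame(
    term = rownames(sm),
    odds_ratio = exp(sm[, "Estimate"]),
    ci_lower = exp(sm[, "Estimate"] - z * sm[, "Std. Error"]),
    ci_upper = exp(sm[, "Estimate"] + z * sm[, "Std. Error"]),
    p_value = sm[, "Pr(>|z|)"],
    row.names = NULL
  )
  if (sep) {
    warning("possible complete separation; estimates suppressed")
    out$odds_ratio <- out$ci_lower <- out$ci_upper <- out$p_value <- NA_real_
  }
  attr(out, "separated") <- sep
  out
}

#' Cohen's d effect size
#'
#' Standardized mean difference `(mean_a - mean_b) / s_pooled`, with the
#' pooled SD weighted by `n - 1` per group.
#'
#' @param group_a,group_b numeric vectors of length >= 2.
#' @return signed effect size.
#' @export
cohens_d <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L)
    stop_rar("each group needs at least two values", "rar_usage_error")
  sp2 <- ((na - 1) * stats::var(group_a) + (nb - 1) * stats::var(group_b)) /
    (na + nb - 2)
  if (sp2 == 0)
    stop_rar("zero pooled standard deviation; effect size undefined",
             "rar_domain_error")
  (mean(group_a) - mean(group_b)) / sqrt(sp2)
}
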