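#' Per-group summary statistics
#'
#' @param data Data frame with a value and a group column.
#' @param value,group Column names (strings) of the measure and grouping.
#' @return Tibble: `group`, `n`, `mean`, `sd` (n-1 denominator).
#' @export
group_stats <- function(data, value, group) {
  data <- as_tibble(data)
  stopifnot(value %in% names(data), group %in% names(data))
  out <- data |>
    filter(!is.na(.data[[value]]), !is.na(.data[[group]])) |>
    group_by(group = .data[[group]]) |>
    summarise(n = n(), mean = mean(.data[[value]]),
              sd = sd(.data[[value]]), .groups = "drop")
  if (any(out$n < 2)) {
    abort("Every group needs at least 2 observations.",
          class = "drmwell_validation_error")
  }
  out
}

#' One-way ANOVA from raw data or group summaries
#'
#' The classical fixed-effects decomposition. Accepts either raw data (a
#' value and a group column) or a summary table with columns `group`, `n`,
#' `mean`, `sd`, via the exact sums-of-squares identities
#' `SS_between = sum n_g (m_g - m)^2` and `SS_within = sum (n_g - 1) s_g^2`
#' (both routes agree to machine precision). Cohen's f is attached:
#' `f = sqrt(df1 * F / df2) = sqrt(eta^2 / (1 - eta^2))`.
#'
#' @param data Raw data frame, or a summary tibble with `group`, `n`,
#'   `mean`, `sd` columns (then `value`/`group` are ignored).
#' @param value,group Column names for the raw-data interface.
#' @return A `drm_anova`: list with `statistic` (F), `df1` (k-1), `df2`
#'   (N-k), `p_value`, `eta_sq`, `cohens_f`, and the `groups` summary.
#' @export
#' @examples
#' one_way_anova(
#'   tibble::tibble(group = c("a", "b"), n = c(10, 12),
#'                  mean = c(1, 2), sd = c(0.5, 0.6)))
one_way_anova <- function(data, value = NULL, group = NULL) {
  data <- as_tibble(data)
  gs <- if (all(c("group", "n", "mean", "sd") %in% names(data)) &&
            is.null(value)) {
    data
  } else {
    group_stats(data, value, group)
  }
  if (nrow(gs) < 2) {
    abort("Need at least 2 groups.", class = "drmwell_validation_error")
  }
  if (any(gs$n < 2)) {
    abort("Every group needs at least 2 observations.",
          class = "drmwell_validation_error")
  }
  N <- sum(gs$n)
  k <- nrow(gs)
  gm <- sum(gs$n * gs$mean) / N
  ss_b <- sum(gs$n * (gs$mean - gm)^2)
  ss_w <- sum((gs$n - 1) * gs$sd^2)
  df1 <- k - 1
  df2 <- N - k
  Fv <- (ss_b / df1) / (ss_w / df2)
  eta <- ss_b / (ss_b + ss_w)
  structure(
    list(statistic = Fv, df1 = df1, df2 = df2,
         p_value = pf(Fv, df1, df2, lower.tail = FALSE),
         eta_sq = eta, cohens_f = sqrt(eta / (1 - eta)),
         groups = gs),
    class = "drm_anova"
  )
}

#' @export
print.drm_anova <- function(x, ...) {
  cat(sprintf("<drm_anova> F(%d, %d) = %.2f, p %s, Cohen's f = %.2f (%s)\n",
              x$df1, x$df2, x$statistic,
              format.pval(x$p_value, digits = 3), x$cohens_f,
              effect_size_label(x$cohens_f, "f")))
  invisible(x)
}

#' @export
tidy.drm_anova <- function(x, ...) x$groups

#' @export
glance.drm_anova <- function(x, ...) {
  tibble(statistic = x$statistic, df1 = x$df1, df2 = x$df2,
         p_value = x$p_value, eta_sq = x$eta_sq, cohens_f = x$cohens_f)
}

#' Cohen's f for a one-way ANOVA
#'
#' `f = sqrt(df1 * F / df2)`, equivalently `sqrt(eta^2 / (1 - eta^2))`.
#'
#' @param statistic The F statistic, or a `drm_anova`.
#' @param df1,df2 Numerator/denominator degrees of freedom (ignored when a
#'   `drm_anova` is given).
#' @return Cohen's f.
#' @export
#' @examples
#' cohens_f(806.37, 6, 45651)  # ~0.33
cohens_f <- function(statistic, df1 = NULL, df2 = NULL) {
  if (inherits(statistic, "drm_anova")) {
    return(sqrt(statistic$df1 * statistic$statistic / statistic$df2))
  }
  sqrt(df1 * statistic / df2)
}

#' Hedges' g for a two-group mean difference
#'
#' `g = |m1 - m2| / s_pooled` with the pooled n-1 standard deviation, times
#' the small-sample correction `J = 1 - 3 / (4 (n1 + n2 - 2) - 1)` when
#' `correction = TRUE` (negligible at survey sizes). Reported as a positive
#' magnitude, symmetric in its arguments and scale-invariant.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries.
#' @param correction Apply the small-sample factor? Default `TRUE`.
#' @return Hedges' g (non-negative).
#' @export
#' @examples
#' hedges_g(91.85, 13.53, 3879, 75.51, 17.13, 11205)  # ~1.00
hedges_g <- function(mean1, sd1, n1, mean2, sd2, n2, correction = TRUE) {
  if (any(c(sd1, sd2) < 0) || (sd1 == 0 && sd2 == 0)) {
    abort("Pooled standard deviation undefined.",
          class = "drmwell_validation_error")
  }
  s_pool <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / (n1 + n2 - 2))
  g <- abs(mean1 - mean2) / s_pool
  if (correction) g <- g * (1 - 3 / (4 * (n1 + n2 - 2) - 1))
  g
}

#' Student's unpaired t-test from summaries or raw vectors
#'
#' Pooled-variance Student t (consistent with the pooled-sd Hedges' g),
#' two-sided p-value.
#'
#' @param mean1,sd1,n1,mean2,sd2,n2 Group summaries; or pass raw vectors
#'   via `x`/`y`.
#' @param x,y Optional raw numeric vectors (override the summaries).
#' @return Tibble: `statistic`, `df`, `p_value`.
#' @export
students_t <- function(mean1, sd1, n1, mean2, sd2, n2, x = NULL, y = NULL) {
  if (!is.null(x)) {
    mean1 <- mean(x); sd1 <- sd(x); n1 <- length(x)
    mean2 <- mean(y); sd2 <- sd(y); n2 <- length(y)
  }
  if (n1 < 2 || n2 < 2) {
    abort("Need at least 2 observations per group.",
          class = "drmwell_validation_error")
  }
  if (sd1 == 0 && sd2 == 0 && mean1 == mean2) {
    return(tibble(statistic = 0, df = n1 + n2 - 2, p_value = 1))
  }
  if (sd1 == 0 && sd2 == 0) {
    abort("Zero variance in both groups with unequal means.",
          class = "drmwell_validation_error")
  }
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df)
  tstat <- (mean1 - mean2) / (sp * sqrt(1 / n1 + 1 / n2))
  tibble(statistic = tstat, df = df,
         p_value = 2 * pt(abs(tstat), df, lower.tail = FALSE))
}

#' Bonferroni-corrected pairwise comparisons
#'
#' All `k (k - 1) / 2` unpaired Student t comparisons between groups, with
#' `p_adj = min(1, m * p)` for `m` comparisons. Following the convention of
#' multi-country DRM reports, significance is assessed at the adjusted 99%
#' level and Hedges' g is reported alongside (display conventions suppress
#' g for non-significant pairs; both the magnitude and the `significant`
#' mask are returned).
#'
#' @param groups Summary tibble (`group`, `n`, `mean`, `sd`) or the
#'   `groups` element of a [one_way_anova()].
#' @param conf_level Confidence level for the significance mask
#'   (default 0.99).
#' @return Tibble: `group1`, `group2`, `statistic`, `df`, `p_value`,
#'   `p_adj`, `significant`, `hedges_g`.
#' @export
bonferroni_pairwise <- function(groups, conf_level = 0.99) {
  if (inherits(groups, "drm_anova")) groups <- groups$groups
  groups <- as_tibble(groups)
  k <- nrow(groups)
  if (k < 2) {
    abort("Need at least 2 groups.", class = "drmwell_validation_error")
  }
  pairs <- utils::combn(k, 2)
  m <- ncol(pairs)
  out <- purrr::map(seq_len(m), function(idx) {
    i <- pairs[1, idx]; j <- pairs[2, idx]
    tt <- students_t(groups$mean[i], groups$sd[i], groups$n[i],
                     groups$mean[j], groups$sd[j], groups$n[j])
    tibble(group1 = as.character(groups$group[i]),
           group2 = as.character(groups$group[j]),
           statistic = tt$statistic, df = tt$df, p_value = tt$p_value,
           hedges_g = hedges_g(groups$mean[i], groups$sd[i], groups$n[i],
                               groups$mean[j], groups$sd[j], groups$n[j]))
  }) |> bind_rows()
  out$p_adj <- pmin(1, m * out$p_value)
  out$significant <- out$p_adj < (1 - conf_level)
  out[, c("group1", "group2", "statistic", "df", "p_value", "p_adj",
          "significant", "hedges_g")]
}

#' Cramer's V for a two-way contingency table
#'
#' `V = sqrt(chi^2 / (N * min(r - 1, c - 1)))` with the Pearson chi-square
#' (no continuity correction).
#'
#' @param tab A 2-way contingency table/matrix with all margins positive.
#' @return List: `v`, `chi_sq`, `df`, `p_value`, `n`.
#' @export
#' @examples
#' cramers_v(matrix(c(32463, 13195, 1082, 482), 2, byrow = TRUE))
cramers_v <- function(tab) {
  tab <- as.matrix(tab)
  if (nrow(tab) < 2 || ncol(tab) < 2 ||
      any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    abort("Need a 2-way table with all margins positive.",
          class = "drmwell_validation_error")
  }
  N <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / N
  chi <- sum((tab - expd)^2 / expd)
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  list(v = sqrt(chi / (N * min(nrow(tab) - 1, ncol(tab) - 1))),
       chi_sq = chi, df = df,
       p_value = pchisq(chi, df, lower.tail = FALSE), n = N)
}

#' Rebuild a 2x2 success/failure table from printed percentages
#'
#' Convenience for recomputing association effect sizes from published
#' tables: rounds `pct * n / 100` to the nearest integer count.
#'
#' @param pct1,n1,pct2,n2 Percentage (0-100) and size of each group.
#' @return 2x2 matrix (rows = groups, cols = yes/no).
#' @export
table_from_percent <- function(pct1, n1, pct2, n2) {
  y1 <- round(pct1 / 100 * n1)
  y2 <- round(pct2 / 100 * n2)
  matrix(c(y1, n1 - y1, y2, n2 - y2), nrow = 2, byrow = TRUE,
         dimnames = list(c("group1", "group2"), c("yes", "no")))
}

#' Cross-country comparison of a scored measure
#'
#' Runs the one-way ANOVA with Cohen's f and the Bonferroni pairwise table
#' with Hedges' g on a respondent score table, mirroring the standard
#' DRM cross-country analysis. Respondents with a missing measure (e.g.
#' U-index for set D) are excluded, so the U-index comparison automatically
#' uses the A/B/C subsample.
#'
#' @param scores Output of [score_affect()].
#' @param measure Column to compare (e.g. `"net_affect_pct"`, `"u_index"`).
#' @param group Grouping column (default `"country"`).
#' @return List with `anova` (a `drm_anova`) and `pairwise` (tibble).
#' @export
compare_groups <- function(scores, measure = "net_affect_pct",
                           group = "country") {
  gs <- group_stats(scores, measure, group)
  an <- one_way_anova(gs)
  list(measure = measure, anova = an, pairwise = bonferroni_pairwise(gs))
}
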