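# item -> factor assignment for the two-factor model
cfa_pattern <- function(items = DRM_ITEMS) {
  ifelse(items %in% DRM_NEG_ITEMS, 1L, 2L)
}

# model-implied correlation matrix: unit diagonal, lam_i lam_j within
# factor, lam_i lam_j phi across factors
cfa_implied <- function(lambda, phi, pattern) {
  p <- length(lambda)
  Phi <- matrix(c(1, phi, phi, 1), 2)
  Sig <- outer(lambda, lambda) * Phi[pattern, pattern]
  diag(Sig) <- 1
  Sig
}

#' Two-factor ULS fit to a polychoric correlation matrix
#'
#' Fits the congeneric two-factor model (five negative items on one
#' factor, two positive on the other, factor variances 1, residual
#' variances `1 - lambda^2`) by minimizing the unweighted least-squares
#' discrepancy `F = sum_{i<j} (S_ij - Sigma_ij)^2` with a bounded
#' quasi-Newton search and analytic gradient, from three deterministic
#' starts. Loadings are reported positive; the factor correlation carries
#' the sign. A non-positive-definite input is smoothed by clipping its
#' eigenvalues at 1e-6 (flagged); loadings hitting the upper bound are
#' flagged as Heywood cases.
#'
#' @param S 7x7 (polychoric) correlation matrix, or a `drm_polychoric`.
#' @param n Number of pooled episodes behind `S` (taken from a
#'   `drm_polychoric` automatically); used by the fit indices.
#' @return A `drm_cfa`: standardized `loadings` tibble (`item`, `factor`,
#'   `lambda`, `se` — `NA` until bootstrapped), `phi`, `fhat`, `statistic`
#'   (`T = (n-1) * fhat`), `df` (13), `cfi`, `tli`, `rmsea`, `rmsea_ci`
#'   (90%), `reliability` (composite, per factor), `n`, `flags`.
#' @export
fit_two_factor <- function(S, n = NULL) {
  if (inherits(S, "drm_polychoric")) {
    n <- n %||% S$n
    S <- S$rho
  }
  if (is.null(n)) {
    abort("`n` (pooled episode count) is required.",
          class = "drmwell_config_error")
  }
  p <- nrow(S)
  stopifnot(p == ncol(S), isTRUE(all.equal(S, t(S), tolerance = 1e-8)))
  items <- colnames(S) %||% DRM_ITEMS
  if (!setequal(items, DRM_ITEMS)) items <- DRM_ITEMS[seq_len(p)]
  S <- (S + t(S)) / 2
  flags <- character()

  ev <- eigen(S, symmetric = TRUE)
  if (min(ev$values) < 1e-6) {
    lam <- pmax(ev$values, 1e-6)
    S <- ev$vectors %*% diag(lam) %*% t(ev$vectors)
    D <- 1 / sqrt(diag(S))
    S <- diag(D) %*% S %*% diag(D)
    dimnames(S) <- list(items, items)
    flags <- c(flags, "smoothed_npd")
  }

  pattern <- cfa_pattern(items)
  off <- upper.tri(S)

  obj <- function(theta) {
    lambda <- theta[1:p]; phi <- theta[p + 1]
    R <- (S - cfa_implied(lambda, phi, pattern))[off]
    sum(R^2)
  }
  grad <- function(theta) {
    lambda <- theta[1:p]; phi <- theta[p + 1]
    Sig <- cfa_implied(lambda, phi, pattern)
    E <- Sig - S
    diag(E) <- 0
    Phi <- matrix(c(1, phi, phi, 1), 2)
    W <- Phi[pattern, pattern]        # phi weight per pair
    g_lam <- sapply(seq_len(p), function(i) {
      2 * sum(E[i, -i] * lambda[-i] * W[i, -i])
    })
    cross <- outer(pattern, pattern, "!=")
    g_phi <- 2 * sum((E * outer(lambda, lambda))[cross & upper.tri(E)])
    c(g_lam, g_phi)
  }

  starts <- list(c(rep(0.7, p), -0.5), c(rep(0.5, p), -0.2),
                 c(rep(0.9, p), -0.8))
  best <- NULL
  for (s0 in starts) {
    o <- optim(s0, obj, grad, method = "L-BFGS-B",
               lower = c(rep(1e-4, p), -0.999),
               upper = c(rep(0.999, p), 0.999),
               control = list(maxit = 500, factr = 1e4))
    if (is.null(best) || o$value < best$value) best <- o
  }
  lambda <- best$par[1:p]
  phi <- best$par[p + 1]
  if (any(lambda > 0.9985)) flags <- c(flags, "heywood_clipped")
  fhat <- best$value / 1  # sum over i<j, i.e. (1/2)||S - Sigma||_F^2

  fi <- fit_indices(fhat, S, n, df = p * (p - 1) / 2 - (p + 1))
  rel <- c(
    negative = composite_reliability(lambda[pattern == 1]),
    positive = composite_reliability(lambda[pattern == 2])
  )
  structure(
    list(
      loadings = tibble(item = items,
                        factor = c("negative", "positive")[pattern],
                        lambda = lambda, se = NA_real_),
      phi = phi, fhat = fhat, statistic = fi$statistic, df = fi$df,
      baseline_statistic = fi$baseline_statistic, baseline_df = fi$baseline_df,
      cfi = fi$cfi, tli = fi$tli, rmsea = fi$rmsea, rmsea_ci = fi$rmsea_ci,
      reliability = rel, n = n, S = S, converged = best$convergence == 0,
      flags = flags
    ),
    class = "drm_cfa"
  )
}

#' Fit indices for a covariance-structure discrepancy
#'
#' Given the minimized ULS discrepancy on a correlation matrix,
#' computes the test statistic `T = (n - 1) * F`, the baseline
#' (independence, all off-diagonal zero) statistic, CFI, TLI, RMSEA and
#' its 90% confidence interval by inverting the noncentral chi-square
#' distribution. With a WLS-family discrepancy these are the standard
#' index formulas; with ULS they are comparable in spirit, not identical,
#' to the robust WLSMV values large survey software prints.
#'
#' @param fhat Minimized discrepancy value.
#' @param S The fitted correlation matrix (for the baseline discrepancy).
#' @param n Sample size.
#' @param df Model degrees of freedom (13 for the 7-item two-factor model).
#' @return List: `statistic`, `df`, `baseline_statistic`, `baseline_df`,
#'   `cfi`, `tli`, `rmsea`, `rmsea_ci` (named `lower`/`upper`).
#' @export
fit_indices <- function(fhat, S, n, df = 13) {
  if (df <= 0) {
    abort("Model degrees of freedom must be positive.",
          class = "drmwell_config_error")
  }
  p <- nrow(S)
  f_b <- sum(S[upper.tri(S)]^2)
  df_b <- p * (p - 1) / 2
  T_m <- (n - 1) * fhat
  T_b <- (n - 1) * f_b
  num <- max(T_m - df, 0)
  den <- max(T_b - df_b, T_m - df, 0)
  cfi <- if (den == 0) 1 else 1 - num / den
  tli_raw <- ((T_b / df_b) - (T_m / df)) / ((T_b / df_b) - 1)
  tli <- if (T_m <= df) 1 else min(tli_raw, 1)
  rmsea <- sqrt(max(T_m - df, 0) / (df * (n - 1)))
  ci <- rmsea_ci(T_m, df, n)
  list(statistic = T_m, df = df, baseline_statistic = T_b,
       baseline_df = df_b, cfi = cfi, tli = tli, rmsea = rmsea,
       rmsea_ci = ci)
}

# 90% RMSEA interval by inverting the noncentral chi-square at 0.95/0.05
rmsea_ci <- function(T_m, df, n, level = 0.90) {
  alpha <- (1 - level) / 2
  bound <- function(target_p) {
    # ncp with P(chisq_df(ncp) <= T) = target_p
    if (pchisq(T_m, df) <= target_p) return(0)
    hi <- max(T_m * 2, df * 4)
    while (pchisq(T_m, df, ncp = hi) > target_p) hi <- hi * 2
    uniroot(function(nc) pchisq(T_m, df, ncp = nc) - target_p,
            c(0, hi), tol = 1e-8)$root
  }
  lo <- bound(1 - alpha)
  hi <- bound(alpha)
  c(lower = sqrt(lo / (df * (n - 1))), upper = sqrt(hi / (df * (n - 1))))
}

#' Composite reliability of a congeneric factor
#'
#' The linear composite (congeneric) reliability on standardized loadings:
#' `rho = (sum lambda)^2 / ((sum lambda)^2 + sum(1 - lambda^2))`. Survey
#' software offers a categorical-scale variant for ordinal items whose
#' printed values can differ from this linear formula; the categorical
#' variant is declared but not implemented here.
#'
#' @param lambda Standardized loadings of one factor, each in (0, 1);
#'   at least two.
#' @param method `"linear"` (implemented) or `"categorical"` (stub).
#' @return Reliability in `[0, 1]`.
#' @export
#' @examples
#' composite_reliability(c(0.8, 0.8))  # 0.7805
composite_reliability <- function(lambda, method = c("linear",
                                                     "categorical")) {
  method <- match.arg(method)
  if (method == "categorical") {
    abort(paste("Categorical-scale composite reliability (threshold-aware)",
                "is not implemented; use method = 'linear'."),
          class = "drmwell_not_implemented")
  }
  if (length(lambda) < 2) {
    abort("A factor needs at least two indicators.",
          class = "drmwell_validation_error")
  }
  if (any(lambda <= 0 | lambda > 1)) {
    abort("Loadings must lie in (0, 1].",
          class = "drmwell_range_error")
  }
  s <- sum(lambda)
  s^2 / (s^2 + sum(1 - lambda^2))
}

#' Ordinal two-factor CFA of the seven affect items
#'
#' Pools episodes (sets A/B/C event-level episodes, or set D day-part
#' blocks), estimates the polychoric correlation matrix and fits the
#' two-factor model by ULS ([fit_two_factor()]). Standard errors of the
#' loadings are obtained by a nonparametric bootstrap over episodes.
#'
#' @param survey A [drm_survey()] or an episode tibble.
#' @param pool `"abc"` (default) pools set A/B/C episodes; `"d"` pools the
#'   set D day-part blocks.
#' @param n_boot_se Bootstrap replicates for loading standard errors
#'   (default 200; 0 skips the bootstrap and leaves `se` as `NA`).
#' @param seed Seed for the bootstrap.
#' @return A `drm_cfa` (see [fit_two_factor()]).
#' @export
fit_affect_cfa <- function(survey, pool = c("abc", "d"), n_boot_se = 200,
                           seed = 1) {
  pool <- match.arg(pool)
  ep <- if (inherits(survey, "drm_survey")) survey$episodes else
    as_tibble(survey)
  ep <- if (pool == "abc") ep[ep$set_id %in% c("A", "B", "C"), ] else
    ep[ep$set_id == "D", ]
  ep <- ep[stats::complete.cases(ep[DRM_ITEMS]), ]
  if (nrow(ep) < 50) {
    abort("Too few complete episodes for a CFA.",
          class = "drmwell_validation_error")
  }
  poly <- polychoric_matrix(ep)
  fit <- fit_two_factor(poly)
  fit$pool <- pool

  if (n_boot_se > 0) {
    lam_boot <- withr::with_seed(as.integer(seed), {
      replicate(n_boot_se, {
        idx <- sample.int(nrow(ep), replace = TRUE)
        pb <- polychoric_matrix(ep[idx, ])
        fb <- fit_two_factor(pb)
        fb$loadings$lambda[match(fit$loadings$item, fb$loadings$item)]
      })
    })
    fit$loadings$se <- apply(lam_boot, 1, sd)
    fit$n_boot_se <- n_boot_se
  }
  fit
}

#' @export
print.drm_cfa <- function(x, ...) {
  cat(sprintf("<drm_cfa> two-factor ULS on polychorics, n = %d episodes\n",
              x$n))
  print(as.data.frame(x$loadings), digits = 3)
  cat(sprintf("  factor correlation: %.3f\n", x$phi))
  cat(sprintf("  T = %.2f on df = %d | CFI %.3f TLI %.3f RMSEA %.3f (%.3f, %.3f)\n",
              x$statistic, x$df, x$cfi, x$tli, x$rmsea,
              x$rmsea_ci[["lower"]], x$rmsea_ci[["upper"]]))
  cat(sprintf("  composite reliability: negative %.3f, positive %.3f\n",
              x$reliability[["negative"]], x$reliability[["positive"]]))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.drm_cfa <- function(x, ...) {
  out <- x$loadings
  out$reliability <- x$reliability[out$factor]
  out
}

#' @export
glance.drm_cfa <- function(x, ...) {
  tibble(n = x$n, statistic = x$statistic, df = x$df,
         cfi = x$cfi, tli = x$tli, rmsea = x$rmsea,
         rmsea_ci_lower = x$rmsea_ci[["lower"]],
         rmsea_ci_upper = x$rmsea_ci[["upper"]],
         phi = x$phi,
         reliability_negative = x$reliability[["negative"]],
         reliability_positive = x$reliability[["positive"]],
         converged = x$converged)
}

#' @export
autoplot.drm_cfa <- function(object, ...) {
  df <- tidy(object)
  df$item <- factor(df$item, levels = rev(DRM_ITEMS))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lambda, y = .data$item,
                                   fill = .data$factor)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_errorbarh(
      data = df[!is.na(df$se), ],
      ggplot2::aes(xmin = .data$lambda - 1.96 * .data$se,
                   xmax = .data$lambda + 1.96 * .data$se),
      height = 0.25) +
    ggplot2::xlim(0, 1) +
    ggplot2::labs(x = "standardized loading", y = NULL,
                  title = "Two-factor CFA of the affect items",
                  subtitle = sprintf("factor correlation = %.2f", object$phi)) +
    ggplot2::theme_minimal()
}

#' @export
plot.drm_cfa <- function(x, ...) print(autoplot(x, ...))

#' Serialize a CFA result to JSON
#'
#' @param fit A `drm_cfa`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_cfa_json <- function(fit, path) {
  stopifnot(inherits(fit, "drm_cfa"))
  jsonlite::write_json(
    list(n = fit$n, pool = fit$pool %||% "abc",
         loadings = fit$loadings,
         factor_correlation = fit$phi,
         statistic = fit$statistic, df = fit$df,
         cfi = fit$cfi, tli = fit$tli,
         rmsea = fit$rmsea, rmsea_ci = as.list(fit$rmsea_ci),
         composite_reliability = as.list(fit$reliability),
         flags = fit$flags),
    path, auto_unbox = TRUE, digits = 10, pretty = TRUE)
  invisible(path)
}
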