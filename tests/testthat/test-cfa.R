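test_that("thresholds are normal quantiles of cumulative proportions", {
  th <- estimate_thresholds(rep(1:3, c(50, 30, 20)))
  expect_equal(as.vector(th), c(0, qnorm(0.8)), tolerance = 1e-12)

  th_u <- estimate_thresholds(rep(1:3, c(100, 100, 100)))
  expect_equal(as.vector(th_u), c(qnorm(1 / 3), qnorm(2 / 3)))
  expect_equal(th_u[1], -th_u[2], ignore_attr = TRUE)

  # empty extreme category is merged with a warning
  expect_warning(th_m <- estimate_thresholds(
    factor(rep(2:3, c(10, 10)), levels = 1:3)), "merged")
  expect_length(th_m, 1)

  # recovery from a known cut of the standard normal
  set.seed(77)
  y <- rnorm(1e5)
  truth <- c(-0.4, 0.9)
  x <- findInterval(y, truth) + 1
  expect_equal(as.vector(estimate_thresholds(x)), truth, tolerance = 0.02)
})

test_that("bivariate-normal cell probabilities match the closed form", {
  # Phi2(0, 0, rho) = 1/4 + asin(rho) / (2 pi)
  for (rho in c(-0.8, -0.3, 0, 0.45, 0.9)) {
    got <- drmwell:::pbvnorm(0, 0, rho)
    expect_equal(got, 0.25 + asin(rho) / (2 * pi), tolerance = 1e-7,
                 info = paste("rho =", rho))
  }
  # independence factorizes
  expect_equal(drmwell:::pbvnorm(0.7, -0.2, 0),
               pnorm(0.7) * pnorm(-0.2), tolerance = 1e-7)
  # cell probabilities sum to one
  P <- drmwell:::bvn_cell_probs(c(-0.5, 0.5), c(0, 1), 0.6)
  expect_equal(sum(P), 1, tolerance = 1e-7)
})

test_that("polychoric correlation recovers the latent correlation", {
  set.seed(101)
  n <- 1e5
  z1 <- rnorm(n)
  z2 <- 0.5 * z1 + sqrt(1 - 0.25) * rnorm(n)
  cut2 <- function(z) findInterval(z, c(-0.5, 0.5)) + 1
  est <- polychoric_correlation(cut2(z1), cut2(z2))
  expect_equal(as.numeric(est), 0.5, tolerance = 0.02)

  # independent items
  z3 <- rnorm(n)
  est0 <- polychoric_correlation(cut2(z1), cut2(z3))
  expect_lt(abs(as.numeric(est0)), 0.02)

  # perfectly concordant table saturates at the bound
  diag_tab <- diag(c(40, 30, 30))
  estd <- polychoric_correlation(as.table(diag_tab))
  expect_equal(as.numeric(estd), 0.999)
  expect_true(attr(estd, "saturated"))

  expect_error(polychoric_correlation(table(rep(1, 10), rep(1:2, 5))),
               class = "drmwell_validation_error")
})

test_that("the ULS fit is exact on model-implied matrices", {
  lam <- rep(0.8, 7)
  phi <- -0.6
  S <- drmwell:::cfa_implied(lam, phi, drmwell:::cfa_pattern())
  dimnames(S) <- list(drm_items, drm_items)
  fit <- fit_two_factor(S, n = 1000)
  expect_equal(fit$loadings$lambda, lam, tolerance = 1e-6)
  expect_equal(fit$phi, phi, tolerance = 1e-6)
  expect_lt(fit$fhat, 1e-10)
  expect_equal(fit$cfi, 1)
  expect_equal(fit$tli, 1)
  expect_equal(fit$rmsea, 0)

  # fixed point with heterogeneous loadings
  lam2 <- c(0.92, 0.71, 0.85, 0.9, 0.77, 0.95, 0.66)
  S2 <- drmwell:::cfa_implied(lam2, -0.45, drmwell:::cfa_pattern())
  dimnames(S2) <- list(drm_items, drm_items)
  fit2 <- fit_two_factor(S2, n = 1000)
  expect_equal(fit2$loadings$lambda, lam2, tolerance = 1e-6)
  expect_equal(fit2$phi, -0.45, tolerance = 1e-6)

  # sign convention: loadings positive, correlation carries the sign
  expect_true(all(fit2$loadings$lambda > 0))
  expect_lt(fit2$phi, 0)
})

test_that("CFA recovers generator structure from ordinal data", {
  cfg <- null_sim_config(n = 500)
  s <- simulate_drm_survey(cfg, seed = 61)
  fit <- fit_affect_cfa(s, pool = "abc", n_boot_se = 0)
  gt <- drm_ground_truth(s)
  err <- fit$loadings$lambda - gt$loadings[fit$loadings$item]
  expect_lt(max(abs(err)), 0.05)
  expect_lt(abs(fit$phi - gt$factor_correlation), 0.08)
  expect_equal(fit$df, 13)
  expect_gt(fit$cfi, 0.95)
  expect_lt(fit$rmsea, 0.08)
})

test_that("set D day-part blocks support their own pooled CFA", {
  s <- simulate_drm_survey(drm_sim_config(
    n_respondents = c(Norland = 250, Sudland = 250),
    set_probabilities = c(A = 0.2, B = 0.2, C = 0.2, D = 0.4)), seed = 62)
  fit <- fit_affect_cfa(s, pool = "d", n_boot_se = 0)
  expect_equal(fit$pool, "d")
  expect_true(all(fit$loadings$lambda > 0.5))
  expect_lt(fit$phi, 0)
})

test_that("bootstrap standard errors are positive and shrink with n", {
  cfg <- null_sim_config(n = 80)
  s <- simulate_drm_survey(cfg, seed = 63)
  fit <- fit_affect_cfa(s, pool = "abc", n_boot_se = 15, seed = 64)
  expect_true(all(is.finite(fit$loadings$se)))
  expect_true(all(fit$loadings$se > 0))
  expect_true(all(fit$loadings$se < 0.2))
})

test_that("fit indices obey their limit identities", {
  S <- diag(7)
  dimnames(S) <- list(drm_items, drm_items)
  S[1, 2] <- S[2, 1] <- 0.5

  # perfect fit
  fi0 <- fit_indices(0, S, n = 500)
  expect_equal(fi0$cfi, 1)
  expect_equal(fi0$tli, 1)
  expect_equal(fi0$rmsea, 0)
  expect_equal(unname(fi0$rmsea_ci["lower"]), 0)

  # T exactly df: RMSEA at the max(., 0) boundary
  fi1 <- fit_indices(13 / 499, S, n = 500)
  expect_equal(fi1$statistic, 13)
  expect_equal(fi1$rmsea, 0)
  expect_equal(fi1$cfi, 1)

  # RMSEA monotone in T at fixed df, n
  Ts <- c(20, 50, 120, 400)
  rms <- sapply(Ts, function(T) fit_indices(T / 499, S, n = 500)$rmsea)
  expect_true(all(diff(rms) > 0))

  expect_error(fit_indices(1, S, n = 500, df = 0),
               class = "drmwell_config_error")
})

test_that("the RMSEA interval matches an independent noncentrality
           inversion", {
  T_m <- 100; df <- 13; n <- 10000
  ci <- drmwell:::rmsea_ci(T_m, df, n)

  # oracle: plain bisection on the noncentral chi-square CDF
  invert <- function(p) {
    lo <- 0; hi <- 1000
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (pchisq(T_m, df, ncp = mid) > p) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  expect_equal(unname(ci["lower"]),
               sqrt(invert(0.95) / (df * (n - 1))), tolerance = 1e-6)
  expect_equal(unname(ci["upper"]),
               sqrt(invert(0.05) / (df * (n - 1))), tolerance = 1e-6)
})

test_that("composite reliability follows the congeneric formula", {
  expect_equal(composite_reliability(c(0.8, 0.8)),
               2.56 / (2.56 + 0.72), tolerance = 1e-12)
  expect_equal(composite_reliability(c(1, 1)), 1)
  expect_lt(composite_reliability(rep(0.01, 5)), 0.01)
  expect_error(composite_reliability(c(0.8, 1.2)),
               class = "drmwell_range_error")
  expect_error(composite_reliability(0.9),
               class = "drmwell_validation_error")
  expect_error(composite_reliability(c(0.8, 0.8), method = "categorical"),
               class = "drmwell_not_implemented")
})

test_that("tidy and glance summarise a CFA compactly", {
  lam <- rep(0.8, 7)
  S <- drmwell:::cfa_implied(lam, -0.5, drmwell:::cfa_pattern())
  dimnames(S) <- list(drm_items, drm_items)
  fit <- fit_two_factor(S, n = 2000)
  td <- tidy(fit)
  expect_equal(nrow(td), 7)
  expect_true(all(c("item", "factor", "lambda", "se", "reliability") %in%
                    names(td)))
  gl <- glance(fit)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$df, 13)
})
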