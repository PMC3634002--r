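test_that("ANOVA from raw data and from summaries agree exactly", {
  set.seed(5)
  df <- data.frame(g = rep(c("a", "b", "c"), c(8, 11, 9)),
                   y = rnorm(28, rep(c(0, 0.4, 1), c(8, 11, 9))))
  a_raw <- one_way_anova(df, "y", "g")
  a_sum <- one_way_anova(group_stats(df, "y", "g"))
  expect_equal(a_raw$statistic, a_sum$statistic, tolerance = 1e-10)
  expect_equal(a_raw$p_value, a_sum$p_value, tolerance = 1e-10)

  # oracle: base R linear-model ANOVA
  oracle <- anova(lm(y ~ g, df))
  expect_equal(a_raw$statistic, oracle$`F value`[1], tolerance = 1e-10)
  expect_equal(a_raw$p_value, oracle$`Pr(>F)`[1], tolerance = 1e-10)
  expect_equal(a_raw$df1, oracle$Df[1])
  expect_equal(a_raw$df2, oracle$Df[2])

  # equal means give F = 0
  eq <- one_way_anova(tibble::tibble(group = c("a", "b"), n = c(10, 10),
                                     mean = c(2, 2), sd = c(1, 1)))
  expect_equal(eq$statistic, 0)

  # degrees of freedom follow the group structure: 7 groups, N = 45658
  ns <- c(14244, 4909, 11205, 2629, 4209, 3879, 4583)
  big <- one_way_anova(tibble::tibble(group = letters[1:7], n = ns,
                                      mean = 1:7, sd = 1))
  expect_equal(c(big$df1, big$df2), c(6, 45651))

  expect_error(one_way_anova(tibble::tibble(group = "a", n = 5, mean = 1,
                                            sd = 1)),
               class = "drmwell_validation_error")
})

test_that("Cohen's f satisfies its algebraic identities", {
  expect_equal(round(cohens_f(806.37, 6, 45651), 2), 0.33)
  expect_equal(round(cohens_f(572.27, 6, 35779), 2), 0.31)
  expect_equal(cohens_f(0, 6, 100), 0)

  set.seed(6)
  df <- data.frame(g = rep(c("a", "b"), each = 15), y = rnorm(30))
  a <- one_way_anova(df, "y", "g")
  expect_equal(a$cohens_f^2, a$eta_sq / (1 - a$eta_sq), tolerance = 1e-12)
  expect_equal(cohens_f(a), a$cohens_f, tolerance = 1e-12)
})

test_that("Hedges' g is a corrected pooled-sd magnitude", {
  expect_equal(hedges_g(5, 1, 50, 5, 1, 50), 0)
  # symmetric and scale invariant
  g1 <- hedges_g(10, 2, 30, 12, 3, 40)
  expect_equal(hedges_g(12, 3, 40, 10, 2, 30), g1)
  expect_equal(hedges_g(30, 6, 30, 36, 9, 40), g1)
  # the small-sample factor shrinks g and vanishes asymptotically
  expect_lt(g1, hedges_g(10, 2, 30, 12, 3, 40, correction = FALSE))
  expect_equal(hedges_g(1, 1, 1e6, 2, 1, 1e6),
               hedges_g(1, 1, 1e6, 2, 1, 1e6, correction = FALSE),
               tolerance = 1e-5)
  expect_error(hedges_g(1, 0, 10, 2, 0, 10),
               class = "drmwell_validation_error")
})

test_that("Student's t from summaries matches base R on raw data", {
  set.seed(7)
  x <- rnorm(12, 1); y <- rnorm(17, 0.3)
  got <- students_t(mean(x), sd(x), 12, mean(y), sd(y), 17)
  oracle <- t.test(x, y, var.equal = TRUE)
  expect_equal(got$statistic, unname(oracle$statistic), tolerance = 1e-10)
  expect_equal(got$p_value, oracle$p.value, tolerance = 1e-10)
  expect_equal(got$df, unname(oracle$parameter))

  same <- students_t(3, 1, 10, 3, 1, 10)
  expect_equal(c(same$statistic, same$p_value), c(0, 1))

  # |t| increases with the mean difference at fixed sd and n
  ts <- sapply(c(0.5, 1, 2), function(d)
    abs(students_t(0, 1, 20, d, 1, 20)$statistic))
  expect_true(all(diff(ts) > 0))
})

test_that("Bonferroni pairwise comparisons enumerate and cap correctly", {
  gs <- tibble::tibble(group = letters[1:7], n = rep(40, 7),
                       mean = c(0, 0, 0, 0, 0, 0, 3), sd = 1)
  pw <- bonferroni_pairwise(gs)
  expect_equal(nrow(pw), 21)  # 7 choose 2
  # null pairs cap at 1 after multiplication
  null_pairs <- pw[pw$group1 != "g" & pw$group2 != "g", ]
  expect_true(all(null_pairs$p_adj <= 1))
  expect_true(any(null_pairs$p_adj == 1))
  # the planted group is significant against everyone at the 99% level
  planted <- pw[pw$group1 == "g" | pw$group2 == "g", ]
  expect_true(all(planted$significant))

  # oracle: explicit t-tests times m on raw 3-group data
  set.seed(8)
  df <- data.frame(g = rep(c("a", "b", "c"), each = 20),
                   y = rnorm(60, rep(c(0, 1, 3), each = 20)))
  pw3 <- bonferroni_pairwise(group_stats(df, "y", "g"))
  for (i in seq_len(nrow(pw3))) {
    xi <- df$y[df$g == pw3$group1[i]]
    yi <- df$y[df$g == pw3$group2[i]]
    tt <- t.test(xi, yi, var.equal = TRUE)
    expect_equal(pw3$p_adj[i], min(1, 3 * tt$p.value), tolerance = 1e-10)
  }
})

test_that("Cramer's V spans independence to perfect association", {
  ind <- matrix(c(40, 60, 20, 30), 2)  # proportional rows
  expect_lt(cramers_v(ind)$v, 1e-8)
  perfect <- matrix(c(50, 0, 0, 50), 2)
  expect_equal(cramers_v(perfect)$v, 1)
  expect_error(cramers_v(matrix(c(5, 5, 0, 0), 2, byrow = TRUE)),
               class = "drmwell_validation_error")

  tab <- table_from_percent(71.1, 45658, 69.2, 1564)
  expect_equal(unname(tab[1, 1]), round(0.711 * 45658))
  expect_equal(unname(rowSums(tab)), c(45658, 1564))
})

test_that("compare_groups runs the full cross-country comparison", {
  s <- simulate_drm_survey(drm_sim_config(
    n_respondents = c(Lowland = 150, Highland = 150),
    country_shift = c(Lowland = 0, Highland = 0.8)), seed = 71)
  sc <- score_affect(s)
  cg <- compare_groups(sc, "net_affect_pct")
  expect_s3_class(cg$anova, "drm_anova")
  expect_equal(nrow(cg$pairwise), 1)
  expect_gt(cg$anova$statistic, 1)
  # U-index comparison uses only respondents with a defined U-index
  cu <- compare_groups(sc, "u_index")
  expect_equal(sum(cu$anova$groups$n), sum(!is.na(sc$u_index)))
  expect_true(sum(cu$anova$groups$n) < nrow(sc))
})

test_that("effect-size labels follow the conventional bands", {
  expect_equal(effect_size_label(c(0.1, 0.3, 0.6, 1), "g"),
               c("negligible", "small", "medium", "large"))
  expect_equal(effect_size_label(0.26, "f"), "medium")
  expect_equal(effect_size_label(0.05, "v"), "negligible")
})
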