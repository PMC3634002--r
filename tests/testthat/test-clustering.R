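test_that("activity profiles are episode means and honour exclusions", {
  eps <- dplyr::bind_rows(
    make_episode("r1", start_minute = 480, activity_code = "working",
                 worried = 3L),
    make_episode("r1", activity_code = "working", worried = 1L),
    make_episode("r1", activity_code = "relaxing", enjoying = 3L),
    make_episode("r1", activity_code = "sleep"),
    make_episode("r2", set_id = "D", part_of_day = "morning",
                 activity_code = "reading", start_minute = NA,
                 duration_min = NA))
  s <- drm_survey(eps, make_respondents(c("r1", "r2")),
                  one_country_scales())
  pr <- activity_profiles(s)
  expect_setequal(pr$activity_code, c("working", "relaxing"))
  expect_equal(pr$worried[pr$activity_code == "working"], 2)  # mean(3, 1)
  expect_equal(pr$n_episodes[pr$activity_code == "working"], 2)
  # set-D-only activities never enter; sleep excluded by default
  expect_false("reading" %in% pr$activity_code)
  expect_false("sleep" %in% pr$activity_code)
})

test_that("standardization gives zero-mean unit-sd columns and flags
           constants", {
  m <- matrix(c(1, 3, 5, 7), 2, dimnames = list(c("a", "b"), NULL))
  z <- standardize_profiles(m)
  expect_equal(z[, 1], c(a = -sqrt(0.5), b = sqrt(0.5)))
  mc <- cbind(m, c(4, 4))  # constant third column
  expect_warning(z2 <- standardize_profiles(mc), "Zero-variance")
  expect_true(all(z2[, 3] == 0))

  set.seed(1)
  r <- matrix(rnorm(35), 5)
  zr <- standardize_profiles(r)
  expect_equal(colMeans(zr), rep(0, 7), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(apply(zr, 2, sd), rep(1, 7), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("average-linkage merges match hand computation on the line", {
  z <- matrix(c(0, 1, 10), ncol = 1,
              dimnames = list(c("p0", "p1", "p10"), NULL))
  cl <- cluster_activities(z)
  expect_equal(cl$hclust$height, c(1, 9.5))

  two <- cluster_activities(z[1:2, , drop = FALSE])
  expect_equal(two$hclust$height, 1)

  rownames(z) <- c("a", "a", "b")
  expect_error(cluster_activities(z), class = "drmwell_validation_error")
})

test_that("UPGMA heights and members match a brute-force oracle", {
  for (seed in c(2, 5, 8)) {
    set.seed(seed)
    z <- matrix(rnorm(6 * 7), nrow = 6,
                dimnames = list(letters[1:6], NULL))
    cl <- cluster_activities(z)
    oracle <- upgma_oracle(dist(z))
    expect_equal(cl$hclust$height, oracle$heights, tolerance = 1e-10)
    got <- lapply(dendro_nodes(cl)$leaves, sort)
    want <- lapply(oracle$members, function(ix) sort(letters[ix]))
    expect_equal(got, want)
  }
})

test_that("cophenetic distances and correlation match enumeration", {
  set.seed(11)
  z <- matrix(rnorm(4 * 7), nrow = 4, dimnames = list(letters[1:4], NULL))
  cl <- cluster_activities(z)
  oracle <- upgma_oracle(dist(z))
  cd <- cophenetic_oracle(oracle)
  expect_equal(as.matrix(cophenetic(cl$hclust))[letters[1:4], letters[1:4]],
               matrix(cd, 4, dimnames = list(letters[1:4], letters[1:4])),
               tolerance = 1e-10)
  expect_equal(cophenetic_correlation(cl),
               cor(as.vector(dist(z)), cd[lower.tri(cd)]),
               tolerance = 1e-10)
})

test_that("ultrametric inputs give a cophenetic correlation of 1", {
  # three points with d(a,b) = 1 and d(a,c) = d(b,c) = 10
  z <- rbind(a = c(0, 0), b = c(1, 0), c = c(0.5, sqrt(100 - 0.25)))
  cl <- cluster_activities(z)
  expect_equal(cophenetic_correlation(cl), 1, tolerance = 1e-12)
  expect_error(
    cophenetic_correlation(cluster_activities(z[1:2, , drop = FALSE])),
    class = "drmwell_validation_error")
})

test_that("multiscale bootstrap support is deterministic and filterable", {
  s <- simulate_drm_survey(
    drm_sim_config(n_respondents = c(Norland = 120, Sudland = 120)),
    seed = 51)
  f1 <- cluster_support(s, nboot = 60, seed = 99)
  f2 <- cluster_support(s, nboot = 60, seed = 99)
  expect_identical(f1$nodes$au, f2$nodes$au)
  expect_identical(f1$nodes$bp, f2$nodes$bp)

  expect_true(all(f1$nodes$bp >= 0 & f1$nodes$bp <= 1))
  expect_true(all(f1$nodes$au >= 0 & f1$nodes$au <= 1))
  # the root is trivially supported and excluded from the highlight set
  sup <- supported_clusters(f1, threshold = 0.95)
  manual <- f1$nodes[f1$nodes$au > 0.95 & f1$nodes$flag != "root", ]
  expect_equal(sup$node, manual$node)
  expect_false(nrow(f1$nodes) %in% sup$node && TRUE)
  # threshold 0 keeps every non-root internal node; threshold 1 none
  expect_equal(nrow(supported_clusters(f1, threshold = -1e-9)),
               nrow(f1$nodes) - 1)
  expect_equal(nrow(supported_clusters(f1, threshold = 1)), 0)

  expect_error(cluster_support(s, scales = c(-0.5, 1)),
               class = "drmwell_config_error")
})

test_that("AU approximates BP when the fitted curvature is negligible", {
  f <- cluster_support(simulate_drm_survey(
    drm_sim_config(n_respondents = c(Norland = 150, Sudland = 150)),
    seed = 52), nboot = 200, seed = 53)
  ok <- f$nodes$flag == "ok" & !is.na(f$nodes$c) & abs(f$nodes$c) < 0.05
  if (any(ok)) {
    expect_equal(f$nodes$au[ok], f$nodes$bp[ok], tolerance = 0.12)
  }
  succeed()
})

test_that("cluster JSON and Newick exports reflect the fitted tree", {
  s <- simulate_drm_survey(
    drm_sim_config(n_respondents = c(Norland = 100, Sudland = 100)),
    seed = 54)
  f <- cluster_support(s, nboot = 40, seed = 55)
  jf <- withr::local_tempfile(fileext = ".json")
  write_cluster_json(f, jf)
  parsed <- jsonlite::read_json(jf)
  expect_equal(parsed$nboot, 40)
  expect_equal(parsed$tree$au, 1)  # root
  if (requireNamespace("ape", quietly = TRUE)) {
    nf <- withr::local_tempfile(fileext = ".nwk")
    export_newick(f, nf)
    phy <- ape::read.tree(nf)
    expect_setequal(phy$tip.label, f$dendro$labels)
  }
})
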