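# Shared fixtures and independent oracles, built in code.

drm_items <- c("worried", "rushed", "irritated_angry", "depressed",
               "tense_stressed", "calm_relaxed", "enjoying")

# one episode row with overridable fields
make_episode <- function(respondent_id = "r1", country = "X", set_id = "A",
                         part_of_day = "morning", activity_code = "working",
                         start_minute = NA, duration_min = 60,
                         companions = "alone",
                         worried = 1L, rushed = 1L, irritated_angry = 1L,
                         depressed = 1L, tense_stressed = 1L,
                         calm_relaxed = 1L, enjoying = 1L) {
  tibble::tibble(respondent_id = respondent_id, country = country,
                 set_id = set_id, part_of_day = part_of_day,
                 activity_code = activity_code,
                 start_minute = start_minute, duration_min = duration_min,
                 companions = companions, worried = worried,
                 rushed = rushed, irritated_angry = irritated_angry,
                 depressed = depressed, tense_stressed = tense_stressed,
                 calm_relaxed = calm_relaxed, enjoying = enjoying)
}

make_respondents <- function(ids, country = "X") {
  tibble::tibble(respondent_id = ids, country = country, sex = "female",
                 age = 50, education = "primary",
                 marital_status = "married_partner", working = "yes",
                 residence = "urban")
}

one_country_scales <- function(country = "X", minimum = 1, maximum = 3) {
  tibble::tibble(country = country, minimum = minimum, maximum = maximum)
}

tiny_survey <- function() {
  eps <- dplyr::bind_rows(
    make_episode("r1", start_minute = 480, duration_min = 60,
                 worried = 3L),
    make_episode("r1", duration_min = 30, enjoying = 3L),
    make_episode("r2", set_id = "D", part_of_day = "evening",
                 activity_code = NA, start_minute = NA, duration_min = NA)
  )
  drm_survey(eps, make_respondents(c("r1", "r2")), one_country_scales())
}

# a generator configuration with all structural effects switched off
null_sim_config <- function(n = 300, ...) {
  ap <- default_activity_profiles()
  ap$shift <- 0
  drm_sim_config(n_respondents = c(X = n), country_shift = c(X = 0),
                 activity_profiles = ap, diurnal_amplitude = 0,
                 respondent_sd = 0, ...)
}

# ---- independent clustering oracles ---------------------------------------

# brute-force UPGMA: recompute every inter-cluster average distance from the
# raw distance matrix at each merge
upgma_oracle <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  heights <- numeric(n - 1)
  members <- vector("list", n - 1)
  for (step in seq_len(n - 1)) {
    k <- length(clusters)
    best <- c(Inf, NA, NA)
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dd <- mean(d[clusters[[i]], clusters[[j]]])
        if (dd < best[1] - 1e-12) best <- c(dd, i, j)
      }
    }
    heights[step] <- best[1]
    members[[step]] <- sort(c(clusters[[best[2]]], clusters[[best[3]]]))
    clusters[[best[2]]] <- members[[step]]
    clusters[[best[3]]] <- NULL
  }
  list(heights = heights, members = members)
}

# cophenetic distances by locating each pair's lowest common merge
cophenetic_oracle <- function(oracle) {
  n <- length(oracle$heights) + 1
  cd <- matrix(0, n, n)
  for (step in seq_along(oracle$heights)) {
    mem <- oracle$members[[step]]
    for (i in mem) {
      for (j in mem) {
        if (i != j && cd[i, j] == 0) cd[i, j] <- oracle$heights[step]
      }
    }
  }
  cd
}

expect_no_error <- function(expr) expect_error(expr, NA)
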