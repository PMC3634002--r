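#' Default ordinal thresholds for a simulated affect item
#'
#' Thresholds on the standard-normal latent-response scale. Negative
#' adjectives are skewed toward "not at all" (most episodes are not
#' distressing), positive adjectives mirror them toward "very much"; the
#' category mass ratio is geometric with ratio 1/2.
#'
#' @param k Number of ordinal categories (3 for the standard dialect, 7
#'   for the 0-6 dialect).
#' @param polarity `"negative"` or `"positive"`.
#' @return Numeric vector of `k - 1` strictly increasing thresholds.
#' @export
#' @examples
#' default_item_thresholds(3, "negative")
default_item_thresholds <- function(k, polarity = c("negative", "positive")) {
  polarity <- match.arg(polarity)
  stopifnot(k >= 2)
  pmf <- 0.5 ^ (0:(k - 1))
  pmf <- pmf / sum(pmf)
  if (polarity == "positive") pmf <- rev(pmf)
  qnorm(cumsum(pmf)[-k])
}

#' Configuration for the synthetic diary generator
#'
#' Defines the data-generating process the analysis pipeline assumes: each
#' episode carries a latent (negative, positive) affect factor pair drawn
#' from a bivariate normal with correlation `factor_correlation`; a latent
#' shift composed of a country effect, an activity effect (two designed
#' groups: work/household low, leisure high), a sinusoidal diurnal cycle
#' and a respondent random intercept moves the positive factor up and the
#' negative factor down. Each ordinal item is a thresholded congeneric
#' indicator of its factor with loading `loadings[item]`. Durations are
#' log-normal; respondents are randomly assigned to instrument sets A-D
#' (set D records three day-part blocks without durations).
#'
#' Shifts are centred and the factors rescaled internally so that the
#' POOLED episode-level factors are standard with correlation exactly
#' `factor_correlation`; `loadings` are therefore the pooled standardized
#' loadings a confirmatory factor analysis estimates.
#'
#' @param n_respondents Named integer vector: respondents per country.
#' @param country_shift Named numeric vector (same names): additive latent
#'   mean shift per country, in latent affect units.
#' @param factor_correlation True correlation between the negative and
#'   positive factors, in `(-1, 0]`.
#' @param loadings Named numeric vector of 7 loadings in (0, 1), one per
#'   affect item.
#' @param thresholds Optional named list of per-item threshold vectors;
#'   defaults to [default_item_thresholds()] for `n_categories`.
#' @param activity_profiles Tibble with `activity_code`, `group`
#'   (`"work_household"` / `"leisure"`), `shift` (latent units).
#' @param respondent_sd SD of the respondent random intercept.
#' @param diurnal_amplitude,diurnal_phase Amplitude (latent units) and peak
#'   hour of the diurnal cosine in the latent shift.
#' @param duration_meanlog,duration_sdlog Log-normal parameters of episode
#'   duration in minutes (defaults give mean ~85 min, sd ~68 min).
#' @param episodes_per_part Mean episodes reported for the covered day-part.
#' @param set_probabilities Probabilities of assignment to sets A-D.
#' @param n_categories Ordinal categories per item (3 => ratings 1..3;
#'   7 => ratings 0..6, the Spain dialect).
#' @return A `drm_sim_config` list.
#' @export
drm_sim_config <- function(
    n_respondents = c(Norland = 150, Sudland = 150),
    country_shift = c(Norland = 0, Sudland = 0.5),
    factor_correlation = -0.6,
    loadings = c(worried = 0.90, rushed = 0.80, irritated_angry = 0.88,
                 depressed = 0.90, tense_stressed = 0.86,
                 calm_relaxed = 0.92, enjoying = 0.85),
    thresholds = NULL,
    activity_profiles = default_activity_profiles(),
    respondent_sd = 0.4,
    diurnal_amplitude = 0.4,
    diurnal_phase = 17,
    duration_meanlog = 4.2,
    duration_sdlog = 0.7,
    episodes_per_part = 4.7,
    set_probabilities = c(A = 0.25, B = 0.25, C = 0.25, D = 0.25),
    n_categories = 3) {

  if (!setequal(names(n_respondents), names(country_shift))) {
    abort("`n_respondents` and `country_shift` must share country names.",
          class = "drmwell_config_error")
  }
  if (sum(n_respondents) < 1) {
    abort("Need at least one respondent.", class = "drmwell_config_error")
  }
  if (factor_correlation > 0 || factor_correlation <= -1) {
    abort("`factor_correlation` must lie in (-1, 0].",
          class = "drmwell_config_error")
  }
  if (!setequal(names(loadings), DRM_ITEMS) ||
      any(loadings <= 0 | loadings >= 1)) {
    abort("`loadings` must name the 7 affect items with values in (0, 1).",
          class = "drmwell_config_error")
  }
  if (abs(sum(set_probabilities) - 1) > 1e-8 || any(set_probabilities < 0)) {
    abort("`set_probabilities` must be a probability vector over A-D.",
          class = "drmwell_config_error")
  }
  if (is.null(thresholds)) {
    thresholds <- c(
      setNames(rep(list(default_item_thresholds(n_categories, "negative")),
                   5), DRM_NEG_ITEMS),
      setNames(rep(list(default_item_thresholds(n_categories, "positive")),
                   2), DRM_POS_ITEMS)
    )
  }
  if (!setequal(names(thresholds), DRM_ITEMS) ||
      any(!purrr::map_lgl(thresholds, function(t) all(diff(t) > 0)))) {
    abort("`thresholds` must be strictly increasing, one vector per item.",
          class = "drmwell_config_error")
  }
  if (episodes_per_part < 1) {
    abort("`episodes_per_part` must be at least 1.",
          class = "drmwell_config_error")
  }

  structure(
    list(n_respondents = n_respondents, country_shift = country_shift,
         factor_correlation = factor_correlation,
         loadings = loadings[DRM_ITEMS], thresholds = thresholds[DRM_ITEMS],
         activity_profiles = as_tibble(activity_profiles),
         respondent_sd = respondent_sd,
         diurnal_amplitude = diurnal_amplitude,
         diurnal_phase = diurnal_phase,
         duration_meanlog = duration_meanlog,
         duration_sdlog = duration_sdlog,
         episodes_per_part = episodes_per_part,
         set_probabilities = set_probabilities[DRM_SETS],
         n_categories = as.integer(n_categories),
         scale_min = if (n_categories == 7) 0L else 1L),
    class = "drm_sim_config"
  )
}

#' Designed activity-affect profiles for the generator
#'
#' Two planted groups: work/household activities with a lower latent net
#' affect, leisure activities with a higher one, mirroring the two activity
#' clusters DRM studies typically recover.
#'
#' @return Tibble with `activity_code`, `group`, `shift`.
#' @export
default_activity_profiles <- function() {
  tibble(
    activity_code = c("working", "household_chores", "cooking", "commuting",
                      "socializing", "eating", "relaxing", "exercise"),
    group = rep(c("work_household", "leisure"), each = 4),
    shift = c(-0.35, -0.30, -0.25, -0.30, 0.30, 0.25, 0.35, 0.25)
  )
}

part_window <- function(part) {
  # minutes since midnight: morning 06-12, afternoon 12-18, evening 18-24
  switch(part, morning = 360, afternoon = 720, evening = 1080)
}

#' Simulate a DRM survey with known ground truth
#'
#' Draws a complete synthetic survey from a [drm_sim_config()]. The
#' generating parameters (loadings, factor correlation, thresholds, country
#' and activity shifts, diurnal cycle) are attached as the `ground_truth`
#' attribute for recovery testing; see [drm_ground_truth()].
#'
#' @param config A [drm_sim_config()].
#' @param seed Integer seed; the same seed reproduces the survey exactly.
#' @return A [drm_survey()] with attribute `ground_truth`.
#' @export
#' @examples
#' s <- simulate_drm_survey(drm_sim_config(
#'   n_respondents = c(X = 20), country_shift = c(X = 0)), seed = 1)
#' s
simulate_drm_survey <- function(config = drm_sim_config(), seed = 1) {
  stopifnot(inherits(config, "drm_sim_config"))
  withr::with_seed(as.integer(seed), simulate_drm_survey_impl(config))
}

simulate_drm_survey_impl <- function(cfg) {
  countries <- names(cfg$n_respondents)
  n_resp <- sum(cfg$n_respondents)
  resp <- tibble(
    respondent_id = sprintf("r%05d", seq_len(n_resp)),
    country = rep(countries, cfg$n_respondents),
    sex = sample(c("female", "male"), n_resp, replace = TRUE,
                 prob = c(0.55, 0.45)),
    age = pmax(18, round(rnorm(n_resp, 58, 15))),
    education = sample(c("less_than_primary", "primary", "secondary",
                         "high_school", "university"), n_resp,
                       replace = TRUE, prob = c(0.4, 0.2, 0.18, 0.15, 0.07)),
    marital_status = sample(c("married_partner", "single", "widowed"),
                            n_resp, replace = TRUE,
                            prob = c(0.7, 0.15, 0.15)),
    working = sample(c("yes", "no"), n_resp, replace = TRUE,
                     prob = c(0.42, 0.58)),
    residence = sample(c("rural", "urban"), n_resp, replace = TRUE,
                       prob = c(0.5, 0.5)),
    set_id = sample(DRM_SETS, n_resp, replace = TRUE,
                    prob = cfg$set_probabilities),
    intercept = rnorm(n_resp, 0, cfg$respondent_sd)
  )

  # --- episode skeleton -------------------------------------------------
  abc <- resp[resp$set_id != "D", ]
  ep_abc <- NULL
  if (nrow(abc)) {
    n_ep <- 1L + rpois(nrow(abc), max(cfg$episodes_per_part - 1, 0))
    part <- c(A = "morning", B = "afternoon", C = "evening")[abc$set_id]
    ep_abc <- abc[rep(seq_len(nrow(abc)), n_ep),
                  c("respondent_id", "country", "set_id", "intercept")]
    ep_abc$part_of_day <- rep(part, n_ep)
    ep_abc$duration_min <- round(pmax(
      5, rlnorm(nrow(ep_abc), cfg$duration_meanlog, cfg$duration_sdlog)))
    starts0 <- purrr::map_dbl(part, part_window) +
      sample(0:30, nrow(abc), replace = TRUE)
    ep_abc <- ep_abc |>
      mutate(.first_start = rep(starts0, n_ep)) |>
      group_by(.data$respondent_id) |>
      mutate(
        end_minute = .data$.first_start[1] + cumsum(.data$duration_min),
        start_clock = .data$end_minute - .data$duration_min,
        start_minute = ifelse(row_number() == 1, .data$start_clock, NA_real_)
      ) |>
      ungroup()
    # keep the diary inside the day after midnight wrap allowance
    ep_abc <- ep_abc[ep_abc$start_clock < 1440, ]
    ep_abc$activity_code <- sample(cfg$activity_profiles$activity_code,
                                   nrow(ep_abc), replace = TRUE)
    ep_abc$mid_hour <- ((ep_abc$start_clock + ep_abc$duration_min / 2) / 60) %% 24
  }

  d <- resp[resp$set_id == "D", ]
  ep_d <- NULL
  if (nrow(d)) {
    ep_d <- d[rep(seq_len(nrow(d)), each = 3),
              c("respondent_id", "country", "set_id", "intercept")]
    ep_d$part_of_day <- rep(DRM_PARTS, nrow(d))
    ep_d$duration_min <- NA_real_
    ep_d$start_minute <- NA_real_
    ep_d$activity_code <- NA_character_
    ep_d$mid_hour <- rep(c(9, 15, 21), nrow(d))  # block midpoints
  }
  ep <- bind_rows(ep_abc, ep_d)
  if (!nrow(ep)) {
    abort("Configuration generated zero episodes.",
          class = "drmwell_config_error")
  }

  # --- latent structure -------------------------------------------------
  act_shift <- setNames(cfg$activity_profiles$shift,
                        cfg$activity_profiles$activity_code)
  shift <- cfg$country_shift[ep$country] +
    ifelse(is.na(ep$activity_code), 0, act_shift[ep$activity_code]) +
    cfg$diurnal_amplitude *
      cos(2 * pi * (ep$mid_hour - cfg$diurnal_phase) / 24) +
    ep$intercept
  delta <- shift - mean(shift)
  s2 <- mean(delta^2)
  rho <- cfg$factor_correlation
  rho0 <- rho * (1 + s2) + s2   # unique-part correlation
  if (abs(rho0) >= 1) {
    abort("Shift variance too large for the requested factor correlation.",
          class = "drmwell_config_error")
  }
  k <- 1 / sqrt(1 + s2)
  z1 <- rnorm(nrow(ep))
  z2 <- rnorm(nrow(ep))
  zn <- z1
  zp <- rho0 * z1 + sqrt(1 - rho0^2) * z2
  f_neg <- k * (-delta + zn)
  f_pos <- k * (delta + zp)

  for (item in DRM_ITEMS) {
    lam <- cfg$loadings[[item]]
    f <- if (item %in% DRM_NEG_ITEMS) f_neg else f_pos
    ystar <- lam * f + sqrt(1 - lam^2) * rnorm(nrow(ep))
    cat_idx <- findInterval(ystar, cfg$thresholds[[item]]) # 0..K-1
    ep[[item]] <- as.integer(cat_idx + cfg$scale_min)
  }

  episodes <- ep |>
    mutate(companions = sample(c("alone", "spouse", "family", "friends"),
                               nrow(ep), replace = TRUE)) |>
    select(all_of(episode_cols))

  scales <- tibble(country = countries,
                   minimum = cfg$scale_min,
                   maximum = cfg$scale_min + cfg$n_categories - 1L)
  survey <- drm_survey(episodes,
                       resp[, respondent_cols],
                       scales)
  attr(survey, "ground_truth") <- structure(
    list(loadings = cfg$loadings,
         factor_correlation = cfg$factor_correlation,
         thresholds = cfg$thresholds,
         country_shift = cfg$country_shift,
         activity_profiles = cfg$activity_profiles,
         respondent_sd = cfg$respondent_sd,
         diurnal_amplitude = cfg$diurnal_amplitude,
         diurnal_phase = cfg$diurnal_phase,
         scale = c(minimum = cfg$scale_min,
                   maximum = cfg$scale_min + cfg$n_categories - 1L)),
    class = "drm_ground_truth"
  )
  survey
}

#' Ground truth of a simulated survey
#'
#' Returns the generating parameters attached by [simulate_drm_survey()]:
#' the 7 true loadings, the factor correlation, per-item thresholds, country
#' and activity shifts (with the planted two-group labels) and the diurnal
#' cycle parameters.
#'
#' @param survey A simulated [drm_survey()], or a `drm_ground_truth`.
#' @return A `drm_ground_truth` list.
#' @export
drm_ground_truth <- function(survey) {
  if (inherits(survey, "drm_ground_truth")) return(survey)
  gt <- attr(survey, "ground_truth")
  if (is.null(gt)) {
    abort("Survey carries no ground truth (not simulated?).",
          class = "drmwell_config_error")
  }
  gt
}

#' @export
print.drm_ground_truth <- function(x, ...) {
  cat("<drm_ground_truth>\n")
  cat("  loadings:", paste(sprintf("%s=%.2f", names(x$loadings),
                                   x$loadings), collapse = " "), "\n")
  cat(sprintf("  factor correlation: %.2f\n", x$factor_correlation))
  cat(sprintf("  diurnal: amplitude %.2f, peak hour %g\n",
              x$diurnal_amplitude, x$diurnal_phase))
  cat(sprintf("  activity groups: %s\n",
              paste(unique(x$activity_profiles$group), collapse = " vs ")))
  invisible(x)
}

#' Serialize / restore ground truth as JSON
#'
#' @param gt A `drm_ground_truth` (or simulated survey).
#' @param path Output (input) JSON path.
#' @return `write_ground_truth()` the path invisibly;
#'   `read_ground_truth()` a `drm_ground_truth`.
#' @export
write_ground_truth <- function(gt, path) {
  gt <- drm_ground_truth(gt)
  out <- unclass(gt)
  # named vectors as JSON objects so names survive the round trip
  out$loadings <- as.list(out$loadings)
  out$country_shift <- as.list(out$country_shift)
  out$scale <- as.list(out$scale)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$activity_profiles <- as_tibble(raw$activity_profiles)
  raw$loadings <- unlist(raw$loadings)[DRM_ITEMS]
  raw$country_shift <- unlist(raw$country_shift)
  raw$thresholds <- purrr::map(raw$thresholds, unlist)[DRM_ITEMS]
  raw$scale <- unlist(raw$scale)
  structure(raw, class = "drm_ground_truth")
}
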