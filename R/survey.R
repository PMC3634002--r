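episode_cols <- c("respondent_id", "country", "set_id", "part_of_day",
                  "activity_code", "start_minute", "duration_min",
                  "companions", DRM_ITEMS)
respondent_cols <- c("respondent_id", "country", "sex", "age", "education",
                     "marital_status", "working", "residence")

#' Assemble a DRM survey object
#'
#' Bundles an episode table, a respondent table and the per-country response
#' scales into a validated `drm_survey`. Episodes from sets A/B/C carry
#' positive durations and (for the first episode of a respondent) a start
#' clock time; set D records whole day-parts and must carry neither.
#'
#' @param episodes Data frame of diary episodes; see [read_drm_survey()] for
#'   the column contract.
#' @param respondents Data frame of respondents (one row per person).
#' @param scales Per-country scale table (`country`, `minimum`, `maximum`),
#'   e.g. from [drm_scale_table()] or [read_scale_config()].
#' @param on_invalid `"error"` (default) aborts with row-indexed diagnostics;
#'   `"drop"` removes offending rows and reports how many were dropped.
#' @return A `drm_survey`: list with tibbles `episodes`, `respondents`,
#'   `scales`.
#' @export
drm_survey <- function(episodes, respondents, scales,
                       on_invalid = c("error", "drop")) {
  on_invalid <- match.arg(on_invalid)
  episodes <- as_tibble(episodes)
  respondents <- as_tibble(respondents)
  scales <- as_tibble(scales)

  miss_e <- setdiff(episode_cols, names(episodes))
  miss_r <- setdiff(respondent_cols, names(respondents))
  if (length(miss_e) || length(miss_r)) {
    abort(paste0("Missing required columns: ",
                 paste(c(miss_e, miss_r), collapse = ", ")),
          class = "drmwell_schema_error")
  }
  lookup <- scale_lookup(scales)
  missing_scale <- setdiff(unique(episodes$country), names(lookup))
  if (length(missing_scale)) {
    abort(paste0("No scale configured for country: ",
                 paste(missing_scale, collapse = ", ")),
          class = "drmwell_schema_error")
  }

  problems <- validate_episode_rows(episodes, respondents, lookup)
  bad_resp <- which(!is.na(respondents$age) & respondents$age < 18)
  if (length(bad_resp)) {
    problems <- bind_rows(problems, tibble(
      table = "respondents", row = bad_resp,
      problem = "age below 18"
    ))
  }
  if (nrow(problems)) {
    msg <- paste0(
      nrow(problems), " invalid row(s): ",
      paste(sprintf("%s row %d (%s)", problems$table, problems$row,
                    problems$problem)[seq_len(min(10, nrow(problems)))],
            collapse = "; "),
      if (nrow(problems) > 10) " ..." else ""
    )
    if (on_invalid == "error") {
      abort(msg, class = "drmwell_validation_error")
    }
    inform(paste0("Dropped ", msg))
    drop_e <- problems$row[problems$table == "episodes"]
    drop_r <- problems$row[problems$table == "respondents"]
    if (length(drop_e)) episodes <- episodes[-unique(drop_e), ]
    if (length(drop_r)) respondents <- respondents[-unique(drop_r), ]
    # respondents removed for age take their episodes with them
    episodes <- episodes[episodes$respondent_id %in%
                           respondents$respondent_id, ]
  }

  structure(
    list(episodes = episodes, respondents = respondents, scales = scales),
    class = "drm_survey"
  )
}

# Row-indexed invariant checks; returns tibble(table, row, problem).
validate_episode_rows <- function(episodes, respondents, lookup) {
  n <- nrow(episodes)
  probs <- list()
  add <- function(rows, what) {
    if (length(rows)) {
      probs[[length(probs) + 1]] <<-
        tibble(table = "episodes", row = rows, problem = what)
    }
  }

  add(which(!episodes$set_id %in% DRM_SETS), "set_id not in A-D")
  is_d <- episodes$set_id == "D"
  add(which(is_d & !is.na(episodes$duration_min)),
      "set D row carries a duration")
  add(which(is_d & !is.na(episodes$start_minute)),
      "set D row carries a start time")
  add(which(is_d & !(episodes$part_of_day %in% DRM_PARTS)),
      "set D row lacks a valid part_of_day")
  abc <- !is_d & episodes$set_id %in% DRM_SETS
  add(which(abc & (is.na(episodes$duration_min) |
                     episodes$duration_min <= 0)),
      "set A/B/C row needs duration_min > 0")
  add(which(!episodes$respondent_id %in% respondents$respondent_id),
      "unknown respondent_id")

  for (ctry in intersect(unique(episodes$country), names(lookup))) {
    sc <- lookup[[ctry]]
    in_ctry <- episodes$country == ctry
    for (item in DRM_ITEMS) {
      v <- episodes[[item]]
      bad <- which(in_ctry & !is.na(v) &
                     (v < sc$minimum | v > sc$maximum | v != round(v)))
      add(bad, sprintf("%s = %s outside %d..%d scale", item,
                       episodes[[item]][bad[1]] %||% NA,
                       sc$minimum, sc$maximum))
    }
  }

  # first A/B/C episode of a respondent must report its start time
  firsts <- episodes |>
    mutate(.row = row_number()) |>
    filter(.data$set_id %in% c("A", "B", "C")) |>
    group_by(.data$respondent_id) |>
    slice(1) |>
    ungroup()
  add(firsts$.row[is.na(firsts$start_minute)],
      "first episode of respondent lacks start_minute")

  if (length(probs)) bind_rows(probs) else
    tibble(table = character(), row = integer(), problem = character())
}

#' @export
print.drm_survey <- function(x, ...) {
  cat(sprintf(
    "<drm_survey> %d episodes, %d respondents, %d countr%s\n",
    nrow(x$episodes), nrow(x$respondents), nrow(x$scales),
    if (nrow(x$scales) == 1) "y" else "ies"))
  invisible(x)
}

#' Read a DRM survey from CSV files
#'
#' Expects UTF-8, comma-separated files with a header row and empty fields
#' for missing values. `episodes_path` must provide columns
#' `respondent_id, country, set_id, part_of_day, activity_code,
#' start_minute, duration_min, companions` plus the seven affect items
#' (`worried, rushed, irritated_angry, depressed, tense_stressed,
#' calm_relaxed, enjoying`); `respondents_path` provides
#' `respondent_id, country, sex, age, education, marital_status, working,
#' residence`.
#'
#' @param episodes_path,respondents_path CSV paths.
#' @param scales A scale table, or the path to a YAML scale config
#'   (see [read_scale_config()]).
#' @inheritParams drm_survey
#' @return A validated [drm_survey()].
#' @export
read_drm_survey <- function(episodes_path, respondents_path, scales,
                            on_invalid = c("error", "drop")) {
  for (p in c(episodes_path, respondents_path)) {
    if (!file.exists(p)) {
      abort(sprintf("File '%s' not found.", p), class = "drmwell_io_error")
    }
  }
  if (is.character(scales) && length(scales) == 1) {
    scales <- read_scale_config(scales)
  }
  episodes <- readr::read_csv(
    episodes_path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      respondent_id = readr::col_character(),
      country = readr::col_character(),
      set_id = readr::col_character(),
      part_of_day = readr::col_character(),
      activity_code = readr::col_character(),
      start_minute = readr::col_double(),
      duration_min = readr::col_double(),
      companions = readr::col_character(),
      .default = readr::col_integer()
    ))
  respondents <- readr::read_csv(
    respondents_path, show_col_types = FALSE, progress = FALSE,
    col_types = readr::cols(
      respondent_id = readr::col_character(),
      age = readr::col_double(),
      .default = readr::col_character()
    ))
  drm_survey(episodes, respondents, scales, on_invalid = on_invalid)
}

#' Write a DRM survey to a directory
#'
#' Writes `episodes.csv`, `respondents.csv` and `scales.yaml` such that
#' [read_drm_survey()] round-trips the survey field-for-field. Missing
#' values are serialized as empty fields.
#'
#' @param survey A [drm_survey()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_drm_survey <- function(survey, dir) {
  stopifnot(inherits(survey, "drm_survey"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) {
    abort(sprintf("Cannot create directory '%s'.", dir),
          class = "drmwell_io_error")
  }
  paths <- c(
    episodes = file.path(dir, "episodes.csv"),
    respondents = file.path(dir, "respondents.csv"),
    scales = file.path(dir, "scales.yaml")
  )
  readr::write_csv(survey$episodes[episode_cols], paths[["episodes"]],
                   na = "")
  readr::write_csv(survey$respondents[respondent_cols],
                   paths[["respondents"]], na = "")
  cfg <- setNames(
    purrr::map2(survey$scales$minimum, survey$scales$maximum,
                function(lo, hi) list(min = as.integer(lo),
                                      max = as.integer(hi))),
    survey$scales$country
  )
  yaml::write_yaml(cfg, paths[["scales"]])
  invisible(paths)
}

#' Reconstruct the clock timeline of set A/B/C episodes
#'
#' Episodes are recorded event-by-event: the respondent reports the start
#' time of the first activity and the duration of each, so episode k starts
#' where episode k-1 ends. Intervals are half-open `[start, end)` in minutes
#' since midnight. Episodes running past midnight are split at 1440 and the
#' spill-over flagged `next_day = TRUE` (its clock minutes restart at 0).
#'
#' @param episodes Episode tibble (set A/B/C rows only), in diary order
#'   within each respondent.
#' @return Tibble with `respondent_id`, `episode_id` (row index in the
#'   input), `activity_code`, `start_minute`, `end_minute`, `next_day`.
#'   Split episodes occupy two rows sharing one `episode_id`.
#' @export
#' @examples
#' eps <- tibble::tibble(
#'   respondent_id = "r1", set_id = "A", activity_code = c("work", "eating"),
#'   start_minute = c(480, NA), duration_min = c(60, 30)
#' )
#' episode_timeline(eps)
episode_timeline <- function(episodes) {
  episodes <- as_tibble(episodes)
  if (any(episodes$set_id == "D")) {
    abort("Set D records day-parts without durations; no timeline exists.",
          class = "drmwell_unsupported_set_error")
  }
  episodes$episode_id <- seq_len(nrow(episodes))
  out <- episodes |>
    group_by(.data$respondent_id) |>
    group_modify(function(df, key) {
      if (is.na(df$start_minute[1])) {
        abort(sprintf(
          "Respondent '%s': first episode has no start_minute.",
          key$respondent_id[[1]]), class = "drmwell_validation_error")
      }
      ends <- df$start_minute[1] + cumsum(df$duration_min)
      starts <- c(df$start_minute[1], head(ends, -1))
      tibble(episode_id = df$episode_id,
             activity_code = df$activity_code,
             start_minute = starts, end_minute = ends)
    }) |>
    ungroup()

  if (any(out$start_minute >= 2 * 1440 | out$end_minute > 2 * 1440)) {
    abort("Timeline extends beyond the following day; check durations.",
          class = "drmwell_validation_error")
  }
  wraps <- out$start_minute < 1440 & out$end_minute > 1440
  tails <- out[wraps, ]
  if (nrow(tails)) {
    tails$start_minute <- 0
    tails$end_minute <- tails$end_minute[] - 1440
    out$end_minute[wraps] <- 1440
  }
  past <- out$start_minute >= 1440  # episode fully after midnight
  out$next_day <- past
  out$start_minute[past] <- out$start_minute[past] - 1440
  out$end_minute[past] <- out$end_minute[past] - 1440
  if (nrow(tails)) {
    tails$next_day <- TRUE
    out <- bind_rows(out, tails) |>
      arrange(.data$respondent_id, .data$episode_id, .data$next_day)
  }
  out
}
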