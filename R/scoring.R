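#' Episode-level affect scores
#'
#' Adds, per episode: `positive_affect` (mean of calm/relaxed and enjoying),
#' `negative_affect` (mean of the five negative adjectives), `net_affect`
#' (positive minus negative, in scale units), `unpleasant` (the U-index
#' indicator: the highest-rated feeling is a negative one) and `scorable`
#' (no affect item missing; episodes with any missing item are excluded
#' from scoring downstream).
#'
#' @param episodes Episode tibble with the seven affect item columns.
#' @param ties How to classify episodes whose maximum negative rating
#'   equals the maximum positive rating: `"pleasant"` (default; the maximum
#'   is then not *a negative* feeling) or `"unpleasant"`.
#' @return The input with score columns appended.
#' @export
#' @examples
#' episode_affect(tibble::tibble(
#'   worried = 3L, rushed = 1L, irritated_angry = 1L, depressed = 1L,
#'   tense_stressed = 1L, calm_relaxed = 1L, enjoying = 1L))
episode_affect <- function(episodes, ties = c("pleasant", "unpleasant")) {
  ties <- match.arg(ties)
  episodes <- as_tibble(episodes)
  neg <- as.matrix(episodes[DRM_NEG_ITEMS])
  pos <- as.matrix(episodes[DRM_POS_ITEMS])
  episodes$positive_affect <- rowMeans(pos)
  episodes$negative_affect <- rowMeans(neg)
  episodes$net_affect <- episodes$positive_affect - episodes$negative_affect
  max_neg <- apply(neg, 1, max)
  max_pos <- apply(pos, 1, max)
  episodes$unpleasant <- if (ties == "pleasant") {
    max_neg > max_pos
  } else {
    max_neg >= max_pos
  }
  episodes$scorable <- stats::complete.cases(episodes[DRM_ITEMS])
  episodes
}

#' Respondent-level affect summaries
#'
#' Aggregates scorable episodes to one row per respondent. For sets A/B/C
#' the positive, negative and net scores are duration-weighted means of the
#' episode scores; for set D (day-part blocks without durations) they are
#' unweighted means of the up-to-three blocks. Raw scores are mapped to the
#' 0-100 percentile scale (100 = best affective state) per the country's
#' response scale, and the U-index — the proportion of scored time in which
#' the highest-rated feeling was a negative one — is computed for sets
#' A/B/C only (`NA` for set D).
#'
#' Episodes with any missing affect item, and A/B/C episodes without a
#' positive duration, are excluded; respondents left with no scorable
#' episode are dropped and listed in the `dropped` attribute with a reason.
#'
#' @param survey A [drm_survey()].
#' @param ties Tie rule passed to [episode_affect()].
#' @return Tibble with one row per scored respondent: `respondent_id`,
#'   `country`, `set_id`, `n_episodes`, `total_minutes`,
#'   `positive_raw`, `negative_raw`, `net_affect_raw`, `positive_pct`,
#'   `negative_pct`, `net_affect_pct`, `u_index`.
#' @export
score_affect <- function(survey, ties = c("pleasant", "unpleasant")) {
  stopifnot(inherits(survey, "drm_survey"))
  ties <- match.arg(ties)
  lookup <- scale_lookup(survey$scales)
  ep <- episode_affect(survey$episodes, ties = ties)

  usable <- ep$scorable &
    (ep$set_id == "D" | (!is.na(ep$duration_min) & ep$duration_min > 0))
  scored <- ep[usable, ]
  dropped_ids <- setdiff(unique(ep$respondent_id),
                         unique(scored$respondent_id))
  if (nrow(scored) == 0) {
    inform(sprintf("%d respondent(s) had no scorable episode and were dropped.",
                   length(dropped_ids)))
    out <- tibble(respondent_id = character(), country = character(),
                  set_id = character(), n_episodes = integer(),
                  total_minutes = double(), positive_raw = double(),
                  negative_raw = double(), net_affect_raw = double(),
                  positive_pct = double(), negative_pct = double(),
                  net_affect_pct = double(), u_index = double())
    attr(out, "dropped") <- tibble(
      respondent_id = dropped_ids,
      reason = "no scorable episode (missing affect items or no valid duration)")
    return(out)
  }

  out <- scored |>
    mutate(.w = ifelse(.data$set_id == "D", 1, .data$duration_min)) |>
    group_by(.data$respondent_id, .data$country, .data$set_id) |>
    summarise(
      n_episodes = n(),
      total_minutes = if (first(.data$set_id) == "D") NA_real_ else
        sum(.data$.w),
      positive_raw = sum(.data$.w * .data$positive_affect) / sum(.data$.w),
      negative_raw = sum(.data$.w * .data$negative_affect) / sum(.data$.w),
      net_affect_raw = sum(.data$.w * .data$net_affect) / sum(.data$.w),
      u_index = if (first(.data$set_id) == "D") NA_real_ else
        sum(.data$.w * .data$unpleasant) / sum(.data$.w),
      .groups = "drop"
    )

  pct <- purrr::pmap(
    list(out$country, out$positive_raw, out$negative_raw,
         out$net_affect_raw),
    function(ctry, p, ng, nt) {
      sc <- lookup[[ctry]]
      c(positive_pct = affect_percentile(p, sc, "positive"),
        negative_pct = affect_percentile(ng, sc, "negative"),
        net_affect_pct = affect_percentile(nt, sc, "net"))
    })
  pct <- do.call(rbind, pct)
  out$positive_pct <- unname(pct[, "positive_pct"])
  out$negative_pct <- unname(pct[, "negative_pct"])
  out$net_affect_pct <- unname(pct[, "net_affect_pct"])
  out <- out[, c("respondent_id", "country", "set_id", "n_episodes",
                 "total_minutes", "positive_raw", "negative_raw",
                 "net_affect_raw", "positive_pct", "negative_pct",
                 "net_affect_pct", "u_index")]

  if (length(dropped_ids)) {
    inform(sprintf("%d respondent(s) had no scorable episode and were dropped.",
                   length(dropped_ids)))
    attr(out, "dropped") <- tibble(
      respondent_id = dropped_ids,
      reason = "no scorable episode (missing affect items or no valid duration)"
    )
  }
  out
}

#' U-index from set A/B/C episodes
#'
#' The proportion of scored time spent in episodes whose highest-rated
#' feeling is a negative one (strict comparison by default: when the
#' maximum negative rating ties the maximum positive rating the episode
#' counts as pleasant). Invariant under rescaling all durations.
#'
#' @param episodes Episode tibble (set A/B/C) with durations and the seven
#'   affect items.
#' @inheritParams episode_affect
#' @return Tibble with `respondent_id` and `u_index`.
#' @export
u_index <- function(episodes, ties = c("pleasant", "unpleasant")) {
  episodes <- as_tibble(episodes)
  if ("set_id" %in% names(episodes) && any(episodes$set_id == "D")) {
    abort("The U-index is undefined for set D (no durations).",
          class = "drmwell_unsupported_set_error")
  }
  ep <- episode_affect(episodes, ties = ties)
  ep <- ep[ep$scorable & !is.na(ep$duration_min) & ep$duration_min > 0, ]
  ep |>
    group_by(.data$respondent_id) |>
    summarise(u_index = sum(.data$duration_min * .data$unpleasant) /
                sum(.data$duration_min),
              .groups = "drop")
}
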