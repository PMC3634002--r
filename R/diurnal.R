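#' Hour-by-hour affect of each respondent
#'
#' Distributes every set A/B/C episode over the clock hours it overlaps
#' (half-open hour bins `[h, h+1)`); the value of a respondent-hour is the
#' overlap-minute-weighted mean of the overlapping episodes' net, positive
#' and negative affect, expressed on the percentile scale. Spill-over past
#' midnight is attributed to the corresponding early clock hours. The
#' overlap minutes of a respondent sum exactly to that respondent's total
#' episode minutes.
#'
#' @param survey A [drm_survey()] (set D respondents are skipped; an error
#'   is raised only if no A/B/C episodes exist).
#' @param ties Tie rule passed to [episode_affect()].
#' @return Tibble: `respondent_id`, `country`, `hour` (0-23), `minutes`,
#'   `net_pct`, `positive_pct`, `negative_pct`.
#' @export
hourly_affect <- function(survey, ties = c("pleasant", "unpleasant")) {
  stopifnot(inherits(survey, "drm_survey"))
  ties <- match.arg(ties)
  lookup <- scale_lookup(survey$scales)
  ep <- episode_affect(survey$episodes, ties = ties)
  ep <- ep[ep$set_id %in% c("A", "B", "C") & ep$scorable &
             !is.na(ep$duration_min) & ep$duration_min > 0, ]
  if (!nrow(ep)) {
    warn("No scorable set A/B/C episodes; empty diurnal result.")
    return(tibble(respondent_id = character(), country = character(),
                  hour = integer(), minutes = double(), net_pct = double(),
                  positive_pct = double(), negative_pct = double()))
  }
  tl <- episode_timeline(ep)
  idx <- match(tl$episode_id, seq_len(nrow(ep)))
  tl$country <- ep$country[idx]
  tl$net <- ep$net_affect[idx]
  tl$pos <- ep$positive_affect[idx]
  tl$neg <- ep$negative_affect[idx]

  # expand each interval over the hour bins it touches
  h0 <- floor(tl$start_minute / 60)
  h1 <- ceiling(tl$end_minute / 60) - 1
  reps <- pmax(h1 - h0 + 1, 1)
  long <- tl[rep(seq_len(nrow(tl)), reps), ]
  long$hour <- unlist(purrr::map2(h0, h1, seq))
  long$overlap <- pmin(long$end_minute, (long$hour + 1) * 60) -
    pmax(long$start_minute, long$hour * 60)
  long <- long[long$overlap > 0, ]
  long$hour <- long$hour %% 24

  out <- long |>
    group_by(.data$respondent_id, .data$country, .data$hour) |>
    summarise(
      minutes = sum(.data$overlap),
      net = sum(.data$overlap * .data$net) / sum(.data$overlap),
      pos = sum(.data$overlap * .data$pos) / sum(.data$overlap),
      neg = sum(.data$overlap * .data$neg) / sum(.data$overlap),
      .groups = "drop"
    )
  out$net_pct <- purrr::map2_dbl(out$net, out$country, function(v, c) {
    affect_percentile(v, lookup[[c]], "net")
  })
  out$positive_pct <- purrr::map2_dbl(out$pos, out$country, function(v, c) {
    affect_percentile(v, lookup[[c]], "positive")
  })
  out$negative_pct <- purrr::map2_dbl(out$neg, out$country, function(v, c) {
    affect_percentile(v, lookup[[c]], "negative")
  })
  out[, c("respondent_id", "country", "hour", "minutes", "net_pct",
          "positive_pct", "negative_pct")]
}

#' Country-level diurnal affect curves
#'
#' Averages [hourly_affect()] across respondents within country and hour
#' (respondent-first averaging: each respondent contributes one value per
#' hour regardless of how many episodes fall in it). Hours covered by no
#' respondent are absent from the result, not zero.
#'
#' @inheritParams hourly_affect
#' @return A `drm_diurnal` tibble: `country`, `hour`, `mean_net_pct`,
#'   `mean_positive_pct`, `mean_negative_pct`, `n` (contributing
#'   respondents).
#' @export
diurnal_curves <- function(survey, ties = c("pleasant", "unpleasant")) {
  hr <- hourly_affect(survey, ties = ties)
  out <- hr |>
    group_by(.data$country, .data$hour) |>
    summarise(mean_net_pct = mean(.data$net_pct),
              mean_positive_pct = mean(.data$positive_pct),
              mean_negative_pct = mean(.data$negative_pct),
              n = n(), .groups = "drop")
  class(out) <- c("drm_diurnal", class(out))
  out
}

#' Peak hour of a diurnal curve by cosinor (harmonic) regression
#'
#' Fits `mean ~ cos(2*pi*hour/24) + sin(2*pi*hour/24)` by least squares per
#' country and returns the acrophase (hour of the fitted maximum) and the
#' fitted amplitude. More stable than the argmax of the hourly means when
#' the cycle is shallow relative to sampling noise.
#'
#' @param curves A `drm_diurnal` from [diurnal_curves()].
#' @param measure Column to analyse, default `"mean_net_pct"`.
#' @return Tibble: `country`, `peak_hour` (in `[0, 24)`), `amplitude`
#'   (percentile units), `mesor` (curve mean level).
#' @export
diurnal_peak <- function(curves, measure = "mean_net_pct") {
  stopifnot(measure %in% names(curves))
  curves |>
    group_by(.data$country) |>
    group_modify(function(df, key) {
      if (nrow(df) < 4) {
        return(tibble(peak_hour = NA_real_, amplitude = NA_real_,
                      mesor = mean(df[[measure]])))
      }
      # hour bin [h, h+1) is centred at h + 0.5; hours backed by more
      # respondents carry proportionally more weight
      ang <- 2 * pi * (df$hour + 0.5) / 24
      w <- if ("n" %in% names(df)) df$n else rep(1, nrow(df))
      fit <- stats::lm.wfit(cbind(1, cos(ang), sin(ang)),
                            df[[measure]], w)
      b <- fit$coefficients
      amp <- sqrt(b[2]^2 + b[3]^2)
      peak <- (atan2(b[3], b[2]) * 24 / (2 * pi)) %% 24
      tibble(peak_hour = peak, amplitude = amp, mesor = b[1])
    }) |>
    ungroup()
}

#' @export
autoplot.drm_diurnal <- function(object, measure = "mean_net_pct", ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$hour + 0.5,
                               y = .data[[measure]],
                               colour = .data$country)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_continuous(breaks = seq(0, 24, 4), limits = c(0, 24)) +
    ggplot2::labs(x = "hour of day", y = "affect (percentile, 100 = best)",
                  colour = "country",
                  title = "Diurnal variation of affect") +
    ggplot2::theme_minimal()
}

#' @export
plot.drm_diurnal <- function(x, ...) print(autoplot(x, ...))
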