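#' Response-scale specification
#'
#' The abbreviated DRM rates each of the seven affect adjectives on a small
#' ordinal scale. Most survey samples use a 3-point scale (1 = not at all,
#' 2 = a little, 3 = very much); the Spanish sample uses 0 (not at all)
#' to 6 (very much). A `drm_scale` records the integer endpoints and
#' optional anchor labels, and fixes the theoretical net-affect range
#' `[-(max - min), +(max - min)]` used by the percentile transform.
#'
#' @param minimum,maximum Integer scale endpoints, `minimum < maximum`.
#' @param labels Optional character labels for the anchors.
#' @return An object of class `drm_scale` with fields `minimum`, `maximum`,
#'   `range` (`maximum - minimum`) and `labels`.
#' @export
#' @examples
#' drm_scale(1, 3)
#' drm_scale(0, 6)
drm_scale <- function(minimum, maximum, labels = NULL) {
  if (length(minimum) != 1 || length(maximum) != 1 ||
      !is.finite(minimum) || !is.finite(maximum) ||
      minimum != round(minimum) || maximum != round(maximum)) {
    abort("`minimum` and `maximum` must be single integers.",
          class = "drmwell_scale_error")
  }
  if (minimum >= maximum) {
    abort("`minimum` must be strictly less than `maximum`.",
          class = "drmwell_scale_error")
  }
  structure(
    list(minimum = as.integer(minimum), maximum = as.integer(maximum),
         range = as.integer(maximum - minimum), labels = labels),
    class = "drm_scale"
  )
}

#' @export
print.drm_scale <- function(x, ...) {
  cat(sprintf("<drm_scale> %d..%d (net-affect range +/-%d)\n",
              x$minimum, x$maximum, x$range))
  invisible(x)
}

#' Per-country response-scale table
#'
#' Builds the country -> scale lookup used when reading or simulating
#' surveys. The default mirrors the study design: every country on the
#' 3-point scale except Spain on 0-6.
#'
#' @param countries Character vector of country codes.
#' @param spain Name(s) in `countries` that use the 0-6 dialect.
#' @return A tibble with columns `country`, `minimum`, `maximum`.
#' @export
#' @examples
#' drm_scale_table(c("China", "Ghana", "Spain"))
drm_scale_table <- function(countries, spain = "Spain") {
  tibble(
    country = as.character(countries),
    minimum = ifelse(countries %in% spain, 0L, 1L),
    maximum = ifelse(countries %in% spain, 6L, 3L)
  )
}

#' Read a per-country scale configuration from YAML
#'
#' The file maps country codes to `{min, max}` entries, e.g.
#' `Spain: {min: 0, max: 6}`.
#'
#' @param path Path to a YAML file.
#' @return A tibble with columns `country`, `minimum`, `maximum`.
#' @export
read_scale_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Scale config '%s' not found.", path),
          class = "drmwell_io_error")
  }
  cfg <- yaml::read_yaml(path)
  out <- purrr::imap(cfg, function(entry, country) {
    if (is.null(entry$min) || is.null(entry$max)) {
      abort(sprintf("Scale entry for '%s' needs `min` and `max`.", country),
            class = "drmwell_schema_error")
    }
    tibble(country = country, minimum = as.integer(entry$min),
           maximum = as.integer(entry$max))
  })
  bind_rows(out)
}

# Internal: scale table -> named list of drm_scale, validated.
scale_lookup <- function(scales) {
  scales <- as_tibble(scales)
  need <- c("country", "minimum", "maximum")
  if (!all(need %in% names(scales))) {
    abort("`scales` must have columns country, minimum, maximum.",
          class = "drmwell_schema_error")
  }
  if (anyDuplicated(scales$country)) {
    abort("Duplicate country in scale table.", class = "drmwell_schema_error")
  }
  setNames(
    purrr::map2(scales$minimum, scales$maximum, drm_scale),
    scales$country
  )
}

#' Percentile transform of affect scores
#'
#' Maps raw affect scores linearly onto 0-100, where 100 is the best
#' affective state. For net affect the theoretical range
#' `[-(max - min), +(max - min)]` maps onto `[0, 100]`:
#' `pct = 100 * (raw + R) / (2 R)` with `R = max - min`. Positive affect
#' maps `[min, max]` onto `[0, 100]`; negative affect is reverse-coded
#' (`100` = no negative affect) so that higher is always better.
#'
#' @param raw Numeric vector of raw scores.
#' @param scale A [drm_scale()].
#' @param measure `"net"`, `"positive"` or `"negative"`.
#' @return Numeric vector of percentiles in `[0, 100]`; `NA` passes through.
#' @export
#' @examples
#' s <- drm_scale(1, 3)
#' affect_percentile(c(-2, 0, 2), s)          # 0, 50, 100
#' affect_percentile(3, s, "positive")        # 100
#' affect_percentile(1, s, "negative")        # 100 (no negative affect)
affect_percentile <- function(raw, scale,
                              measure = c("net", "positive", "negative")) {
  measure <- match.arg(measure)
  stopifnot(inherits(scale, "drm_scale"))
  r <- scale$range
  ok <- is.na(raw) | switch(measure,
    net = raw >= -r - 1e-9 & raw <= r + 1e-9,
    positive = ,
    negative = raw >= scale$minimum - 1e-9 & raw <= scale$maximum + 1e-9
  )
  if (!all(ok)) {
    abort(sprintf("Raw %s affect outside the theoretical range: %s",
                  measure, paste(format(raw[!ok]), collapse = ", ")),
          class = "drmwell_range_error")
  }
  switch(measure,
    net = 100 * (raw + r) / (2 * r),
    positive = 100 * (raw - scale$minimum) / r,
    negative = 100 * (scale$maximum - raw) / r
  )
}
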