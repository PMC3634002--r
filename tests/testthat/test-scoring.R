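test_that("episode net affect is positive mean minus negative mean", {
  # all negatives at 1, both positives at 3 on the 1-3 scale: the extreme
  e1 <- episode_affect(make_episode(worried = 1L, calm_relaxed = 3L,
                                    enjoying = 3L))
  expect_equal(e1$net_affect, 2)

  # complete indifference
  e2 <- episode_affect(make_episode())
  expect_equal(e2$net_affect, 0)

  # mixed ratings: (2+3)/2 - (1+2+1+1+2)/5 = 2.5 - 1.4
  e3 <- episode_affect(make_episode(
    calm_relaxed = 2L, enjoying = 3L,
    worried = 1L, rushed = 2L, irritated_angry = 1L, depressed = 1L,
    tense_stressed = 2L))
  expect_equal(e3$net_affect, 1.1)

  # missing item marks the episode unscorable
  e4 <- episode_affect(make_episode(worried = NA))
  expect_false(e4$scorable)
})

test_that("respondent scores are duration-weighted for A/B/C, raw for D", {
  eps <- dplyr::bind_rows(
    make_episode("r1", start_minute = 480, duration_min = 30,
                 calm_relaxed = 3L, enjoying = 3L),           # net +2
    make_episode("r1", duration_min = 60, worried = 2L, rushed = 2L,
                 irritated_angry = 2L, depressed = 2L,
                 tense_stressed = 2L))                        # net -1
  s <- drm_survey(eps, make_respondents("r1"), one_country_scales())
  sc <- score_affect(s)
  expect_equal(sc$net_affect_raw, (30 * 2 + 60 * -1) / 90)  # = 0
  expect_equal(sc$net_affect_pct, 50)
  expect_equal(sc$total_minutes, 90)

  # set D: unweighted mean over the three day-part blocks
  d <- dplyr::bind_rows(lapply(c("morning", "afternoon", "evening"),
    function(p) make_episode("r2", set_id = "D", part_of_day = p,
                             activity_code = NA, start_minute = NA,
                             duration_min = NA, calm_relaxed = 3L,
                             enjoying = 3L, worried = 2L, rushed = 2L,
                             irritated_angry = 2L, depressed = 2L,
                             tense_stressed = 2L)))            # net +1 each
  s2 <- drm_survey(d, make_respondents("r2"), one_country_scales())
  sc2 <- score_affect(s2)
  expect_equal(sc2$net_affect_raw, 1)
  expect_true(is.na(sc2$u_index))
  expect_true(is.na(sc2$total_minutes))

  # single episode: duration cancels
  one <- make_episode("r3", start_minute = 600, duration_min = 7,
                      enjoying = 3L)
  sc3 <- score_affect(drm_survey(one, make_respondents("r3"),
                                 one_country_scales()))
  expect_equal(sc3$net_affect_raw, episode_affect(one)$net_affect)
})

test_that("duration-weighted net affect is invariant to splitting an
           episode into identical halves", {
  whole <- dplyr::bind_rows(
    make_episode("r1", start_minute = 480, duration_min = 120,
                 enjoying = 3L, worried = 2L),
    make_episode("r1", duration_min = 60, calm_relaxed = 2L))
  halves <- dplyr::bind_rows(
    make_episode("r1", start_minute = 480, duration_min = 60,
                 enjoying = 3L, worried = 2L),
    make_episode("r1", duration_min = 60, enjoying = 3L, worried = 2L),
    make_episode("r1", duration_min = 60, calm_relaxed = 2L))
  r <- make_respondents("r1")
  expect_equal(
    score_affect(drm_survey(whole, r, one_country_scales()))$net_affect_raw,
    score_affect(drm_survey(halves, r, one_country_scales()))$net_affect_raw)
})

test_that("the percentile transform maps endpoints exactly and is strictly
           increasing", {
  sc <- drm_scale(1, 3)
  expect_equal(affect_percentile(c(-2, 0, 2), sc), c(0, 50, 100))
  expect_equal(affect_percentile(1.02, sc), 75.5)
  expect_equal(affect_percentile(6, drm_scale(0, 6)), 100)
  # positive / negative affect mappings (negative reverse-coded)
  expect_equal(affect_percentile(3, sc, "positive"), 100)
  expect_equal(affect_percentile(1, sc, "negative"), 100)
  expect_equal(affect_percentile(3, sc, "negative"), 0)

  x <- seq(-2, 2, by = 0.25)
  expect_true(all(diff(affect_percentile(x, sc)) > 0))
  expect_error(affect_percentile(2.5, sc), class = "drmwell_range_error")
})

test_that("U-index counts time whose top-rated feeling is negative,
           with ties pleasant", {
  eps <- dplyr::bind_rows(
    make_episode("r1", start_minute = 480, duration_min = 60,
                 worried = 3L),                          # unpleasant
    make_episode("r1", duration_min = 120, enjoying = 3L))
  expect_equal(u_index(eps)$u_index, 1 / 3)

  # max negative = max positive = 2: the maximum is not *a negative*
  tie <- make_episode("r1", start_minute = 480, duration_min = 60,
                      worried = 2L, enjoying = 2L)
  expect_equal(u_index(tie)$u_index, 0)
  expect_equal(u_index(tie, ties = "unpleasant")$u_index, 1)

  # bounds
  allp <- make_episode("r1", start_minute = 480, enjoying = 3L)
  expect_equal(u_index(allp)$u_index, 0)
  alln <- make_episode("r1", start_minute = 480, depressed = 3L)
  expect_equal(u_index(alln)$u_index, 1)

  # invariant under rescaling all durations
  eps10 <- eps
  eps10$duration_min <- eps10$duration_min * 10
  expect_equal(u_index(eps10)$u_index, u_index(eps)$u_index)

  d <- make_episode(set_id = "D", start_minute = NA, duration_min = NA)
  expect_error(u_index(d), class = "drmwell_unsupported_set_error")
})

test_that("respondents without scorable episodes are reported, not scored", {
  eps <- make_episode("r1", start_minute = 480, worried = NA)
  s <- drm_survey(eps, make_respondents("r1"), one_country_scales())
  expect_message(sc <- score_affect(s), "no scorable")
  expect_equal(nrow(sc), 0)
  expect_equal(attr(sc, "dropped")$respondent_id, "r1")
})
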