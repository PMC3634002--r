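# drmwell

Experienced well-being from abbreviated Day Reconstruction Method (DRM)
diaries.

Large multi-country surveys measure *experienced* well-being — how people
actually felt while living their day, rather than how they evaluate their
life — with an abbreviated DRM interview: each respondent reconstructs one
day-part of the previous day as a sequence of episodes (activity, timing,
company) and rates seven affect adjectives per episode, five negative
(worried, rushed, irritated/angry, depressed, tense/stressed) and two
positive (calm/relaxed, enjoying). `drmwell` implements the full analysis
pipeline for such diaries, for survey methodologists and well-being
researchers:

* **Data model** — episode/respondent tables with per-country response
  scales (3-point, or the 0–6 dialect), validation, CSV/YAML round-trip
  (`drm_survey()`, `read_drm_survey()`, `write_drm_survey()`,
  `episode_timeline()`).
* **Affect scoring** — episode net affect (mean positive minus mean
  negative), duration-weighted respondent scores on a 0–100 percentile
  scale (`pct = 100 (x + R)/(2R)` for net affect with scale range `R`),
  and the U-index, the proportion of time whose highest-rated feeling is
  negative (`score_affect()`, `u_index()`).
* **Diurnal curves** — hour-by-hour affect from episode timelines with
  exact overlap-minute weighting, plus cosinor peak estimation
  (`diurnal_curves()`, `diurnal_peak()`).
* **Activity clustering** — mean affect profiles per activity, z-scored,
  clustered with Euclidean distance and average linkage; cophenetic
  correlation; multiscale-bootstrap cluster support with approximately
  unbiased (AU) p-values fitted from `qnorm(1 - BP_r) = v√r + c/√r`,
  `AU = 1 − Φ(v − c)` (`cluster_support()`, `supported_clusters()`).
* **Ordinal CFA** — polychoric correlations (two-step estimator), a
  two-factor unweighted-least-squares fit (negative vs positive items),
  CFI/TLI/RMSEA with a 90% noncentral-χ² RMSEA interval, congeneric
  composite reliability, bootstrap loading standard errors
  (`fit_affect_cfa()`, `polychoric_matrix()`, `composite_reliability()`).
* **Effect sizes** — one-way ANOVA from raw data *or* published
  `(n, mean, sd)` summaries, Cohen's f, Hedges' g, Bonferroni pairwise
  tables, Cramér's V (`one_way_anova()`, `hedges_g()`, `cohens_f()`,
  `cramers_v()`, `bonferroni_pairwise()`).
* **Synthetic diaries** — a seeded generator with known latent structure
  (two correlated affect factors, thresholded ordinal items, country and
  activity shifts, a diurnal cycle) so every stage has a ground-truth
  recovery test (`simulate_drm_survey()`, `drm_ground_truth()`).

Everything is data-frame in, tibble out, with `tidy()`/`glance()` methods
and `autoplot()` for curves, dendrograms and loadings, plus
`run_drm_pipeline()` to chain the stages with a reproducibility manifest.

## Worked example

```r
library(drmwell)

survey <- simulate_drm_survey(drm_sim_config(
  n_respondents = c(Norland = 400, Sudland = 400)), seed = 2026)
#> <drm_survey> 3250 episodes, 800 respondents, 2 countries

scores <- score_affect(survey)
aggregate(cbind(net_affect_pct, u_index) ~ country, scores,
          function(x) round(mean(x, na.rm = TRUE), 1))
#>   country net_affect_pct u_index
#> 1 Norland           66.2     0.2
#> 2 Sudland           76.0     0.1
```

Sudland was simulated with a latent affect shift of +0.5, visible as ~10
percentile points of net affect and half the U-index. The cross-country
comparison quantifies it:

```r
compare_groups(scores, "net_affect_pct")$anova
#> <drm_anova> F(1, 798) = 86.62, p <2e-16, Cohen's f = 0.33 (medium)
```

The two-factor structure of the seven items, fitted on polychoric
correlations of the pooled set A/B/C episodes:

```r
fit_affect_cfa(survey, n_boot_se = 0)
#> <drm_cfa> two-factor ULS on polychorics, n = 2677 episodes
#>              item   factor lambda se
#> 1         worried negative  0.897 NA
#> ...
#>   factor correlation: -0.616
#>   T = 1.81 on df = 13 | CFI 1.000 TLI 1.000 RMSEA 0.000 (0.000, 0.000)
#>   composite reliability: negative 0.940, positive 0.873
```

The loadings and factor correlation recover the generator's truth
(loadings 0.80–0.92, correlation −0.6). Activity clustering flags exactly
the two planted activity groups (work/household vs leisure) with AU
support 1.00:

```r
sup <- cluster_support(survey, nboot = 1000, seed = 1)
supported_clusters(sup)[, c("leaves", "height", "bp", "au")]
#> # A tibble: 2 × 4
#>   leaves    height    bp    au
#> 1 <chr [4]>  0.863 0.998  1.00
#> 2 <chr [4]>  1.19  0.999  1.00
cophenetic_correlation(sup$dendro)
#> [1] 0.98

diurnal_peak(diurnal_curves(survey))
#> # A tibble: 2 × 4
#>   country peak_hour amplitude mesor
#> 1 Norland      17.6      8.36  64.3
#> 2 Sudland      16.6      9.66  73.1
```

Net affect peaks near 17:00 in both simulated countries — the hour the
generator's diurnal cycle was configured to peak at.

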