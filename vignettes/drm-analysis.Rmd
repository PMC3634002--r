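---
title: "Scoring and validating abbreviated day-reconstruction diaries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring and validating abbreviated day-reconstruction diaries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(drmwell)
```

## The instrument and its data model

The Day Reconstruction Method (DRM) asks a respondent to re-live the
previous day as a sequence of episodes — what they did, for how long, with
whom — and to rate, for each episode, seven affect adjectives: five
negative (worried, rushed, irritated/angry, depressed, tense/stressed) and
two positive (calm/relaxed, enjoying). The abbreviated interview variant
used in large multi-country ageing surveys randomizes each respondent to
one of four instrument sets. Sets A, B and C reconstruct a single day-part
(morning, afternoon or evening respectively) event by event, recording the
clock time at which the first activity started and the duration of every
activity; set D records the three day-parts as whole blocks, without
durations. Ratings sit on a 3-point scale (1 = not at all … 3 = very much)
in most samples and on 0–6 in the Spanish sample; `drmwell` carries the
scale per country (`drm_scale_table()`).

`drmwell` represents a survey as three tibbles — episodes, respondents,
per-country scales — bundled by `drm_survey()`, which enforces the data
model: set D rows carry neither duration nor start time, set A/B/C rows
carry positive durations, ratings lie on the country's scale, every episode
belongs to a known respondent. Timelines are half-open minute intervals
`[start, end)`; episode *k* starts where *k − 1* ends. Episodes running
past midnight are split at minute 1440 and the spill-over flagged — the
source instrument never addresses this case, so the package makes the
convention explicit rather than silently mis-binning early-morning time.

An episode with **any** missing affect item is excluded from scoring and
from the factor analysis (listwise by episode). Both the positive and the
negative mean enter every derived score, and no imputation rule is part of
the instrument; partial scoring would silently change the estimand.

## Affect scores

For an episode, positive affect is the mean of the two positive items,
negative affect the mean of the five negative ones, and net affect their
difference. Respondent-level scores are duration-weighted means over
episodes for sets A/B/C and unweighted means over the (up to three)
day-part blocks for set D — the blocks have no durations, so a raw average
is the only defensible aggregate.

Scores are reported on a percentile scale with 100 the best affective
state. Net affect on a scale with range $R = \max - \min$ lives in
$[-R, R]$ and maps linearly:

$$\mathrm{pct} = 100\,(x + R)/(2R).$$

Positive affect maps $[\min,\max]$ onto $[0,100]$; negative affect is
reverse-coded so that 100 always means "best". The map is linear, so
weighting episodes first and transforming afterwards (or vice versa) give
identical results.

The **U-index** is the proportion of scored time spent in episodes whose
*highest-rated* feeling is a negative one. When the maximum negative
rating ties the maximum positive rating, the maximum is not *a negative
feeling*, so ties count as pleasant; the rule is configurable
(`ties = "unpleasant"`) for sensitivity analysis. The U-index is undefined
for set D.

## Diurnal curves

`hourly_affect()` distributes each episode over the clock hours it
overlaps and takes overlap-minute-weighted means per respondent-hour;
overlap weighting (rather than midpoint assignment) conserves time exactly
and is robust to long episodes. Country curves average across respondents
within each hour — respondent-first averaging, so a respondent with many
short episodes in an hour counts once. Hours no respondent covers are
absent, not zero.

`diurnal_peak()` estimates the acrophase by first-order cosinor
(harmonic) regression of the hourly means on $\cos(2\pi h/24)$ and
$\sin(2\pi h/24)$, weighted by the number of contributing respondents per
hour. A diurnal cycle of a few percentile points is shallow relative to
hourly sampling noise, so the argmax of the raw curve is unstable; the
cosinor uses every covered hour and is the standard estimator for diurnal
rhythms. Note the instrument only covers roughly 06:00–24:00, so phases
placed in the small hours are not identifiable.

## Activity clustering with bootstrap support

Activities are summarized by their mean rating on each of the seven
adjectives over all set A/B/C episodes (sleep-type activities are excluded
— affect is not coded while asleep; activities seen only in set D carry no
activity-coded affect). Columns are z-scored across activities (n − 1
denominator; zero-variance columns are left at 0 and flagged), and the
activities are clustered agglomeratively with Euclidean distance and
average linkage (UPGMA) — the combination chosen because it tends to
maximize the cophenetic correlation coefficient, the Pearson correlation
between input distances and dendrogram merge heights. Some descriptions
of this analysis say "divisive" while simultaneously specifying average
linkage and AU/BP support software, which are agglomerative; the package
implements the agglomerative reading. Merge ties break deterministically
by input order.

Cluster support follows the multiscale bootstrap. The resampling unit is
the *episode* (the rows behind the profile means): at each scale
$r \in \{0.5, 0.6, \dots, 1.4\}$ the episodes are resampled with
replacement to size $\lceil rn\rceil$, profiles are recomputed,
re-standardized and re-clustered, and a cluster's bootstrap probability
$BP_r$ is the fraction of replicate trees containing exactly the same leaf
set. The probit-scale curve

$$\Phi^{-1}(1 - BP_r) = v\sqrt{r} + c/\sqrt{r}$$

is fitted by weighted least squares (binomial delta-method weights), and
the approximately unbiased value is $AU = 1 - \Phi(v - c)$; $BP$ is
reported at $r = 1$. Defaults are 10 scales × 1000 replicates — the
classical "10,000 runs" read as a total — and clusters with AU above 0.95
are highlighted (`supported_clusters()`).

Numerical edge handling: $BP$ is clamped to $[1/2B,\,1 - 1/2B]$ before the
probit transform. Scales where the count saturates at 0 or $B$ carry no
curve information, so they are dropped from the fit; when fewer than three
informative scales remain, or when fewer than ~5 expected misses (hits)
per scale exist overall, the clamp would flatten the curve toward
AU ≈ 0.5, so such clusters are reported at the appropriate boundary (AU 1
if recovered essentially always, 0 if essentially never) with an explicit
flag. The root contains every leaf by construction and is excluded from
the highlight set.

## Ordinal two-factor CFA

The construct validity analysis asks whether the seven items form two
correlated factors (negative, positive). Because the items are short
ordinal scales, Pearson correlations are attenuated and distorted; the
package estimates the **polychoric** correlation matrix instead, by the
two-step estimator: thresholds fixed at $\Phi^{-1}$ of the cumulative
margin proportions, then the latent bivariate-normal correlation maximized
over $(-0.999, 0.999)$ by bounded 1-D search. Bivariate-normal cell
probabilities are evaluated by 48-node Gauss–Legendre quadrature of
$\phi(x)\,\Phi\!\big((b-\rho x)/\sqrt{1-\rho^2}\big)$ (checked in the
tests against the closed form $\Phi_2(0,0,\rho) = 1/4 + \arcsin(\rho)/2\pi$).
Empty cells contribute nothing to the multinomial likelihood (model
probabilities floored at $10^{-12}$); a perfectly concordant table
therefore saturates at the bound and is flagged. Categories empty at an
extreme are merged into their neighbour with a warning.

The structured model — items load only on their assigned factor, factor
variances 1, residual variances $1-\lambda^2$ — is fitted by unweighted
least squares, minimizing $F = \sum_{i<j}(S_{ij}-\Sigma_{ij})^2$ with an
analytic gradient under box constraints (`L-BFGS-B`), from three
deterministic starts to guard against local minima. Loadings are reported
positive; the factor correlation carries the sign. Non-positive-definite
inputs are smoothed by eigenvalue clipping at $10^{-6}$ and flagged;
loadings pinned at the upper bound are flagged as Heywood cases. This is
deliberately *not* a re-implementation of the mean-and-variance-adjusted
weighted least squares (WLSMV) estimator of commercial SEM software: the
weight matrix and robust corrections are out of scope, so the test
statistic and derived indices are comparable in spirit, not digit-for-digit.

Fit indices use $T = (n-1)\hat F$ against the independence baseline
($\Sigma = I$, $df_b = 21$; the model has $df = 13$):
CFI $= 1 - \max(T-df,0)/\max(T_b-df_b,\,T-df,\,0)$, the Tucker–Lewis
index by its usual ratio form (capped at 1 so that $T \le df$ yields
exactly 1), and RMSEA $= \sqrt{\max(T-df,0)/(df\,(n-1))}$ with a 90%
interval from inverting the noncentral $\chi^2$ CDF at 0.95/0.05 via
`uniroot`.

Composite reliability per factor uses the congeneric formula on
standardized loadings,
$\rho = (\sum\lambda)^2 / \big((\sum\lambda)^2 + \sum(1-\lambda^2)\big)$,
labelled *linear* composite reliability. Published categorical-data
reliability values computed with threshold-aware maximum-likelihood
machinery are generally **not** reproducible from printed loadings with
this formula (it typically gives larger values); the categorical variant
is declared (`method = "categorical"`) but intentionally unimplemented,
and linear values should not be compared against threshold-aware ones.
Loading standard errors come from a nonparametric bootstrap over episodes
(200 replicates by default) rather than asymptotic WLSMV formulas.

## Cross-group comparison

Country differences in net affect and U-index use the one-way fixed-effects
ANOVA; `one_way_anova()` accepts raw data or `(n, mean, sd)` summaries
through the exact sums-of-squares identities, which makes published
summary tables first-class inputs. Effect sizes: Cohen's
$f = \sqrt{df_1 F/df_2}$, Hedges' $g$ as the pooled-sd magnitude with the
small-sample factor $1 - 3/(4(n_1+n_2-2)-1)$ (reported as a magnitude,
matching how pairwise tables are printed), and Cramér's
$V = \sqrt{\chi^2/(N\min(r-1,c-1))}$ without continuity correction.
Pairwise comparisons are pooled-variance Student t tests (consistent with
pooled-sd $g$) with Bonferroni adjustment over all $k(k-1)/2$ pairs and a
significance mask at the adjusted 99% level. The U-index comparison
automatically drops set D respondents, whose U-index is undefined, so its
denominator degrees of freedom differ from the net-affect comparison.

## The synthetic diary generator

Real multi-country DRM microdata are not redistributable, so validation
rests on a generator (`simulate_drm_survey()`) that draws diaries with the
exact latent structure the analyses assume, exposing the truth for
recovery tests (`drm_ground_truth()`):

* **Measurement model.** Each episode has a latent (negative, positive)
  factor pair; item $i$'s latent response is
  $\lambda_i f + \sqrt{1-\lambda_i^2}\,\varepsilon$ cut at fixed
  thresholds. Default loadings sit in 0.80–0.92, the magnitude band
  typical of these instruments; default thresholds skew negative items
  toward "not at all" and positive items toward "very much" (geometric
  category masses, ratio ½), giving realistic marginal distributions and
  a positive average net affect. A 7-category flag produces the 0–6
  dialect.
* **Structure.** A latent shift — country effect + activity effect +
  sinusoidal diurnal cycle (default amplitude 0.4 latent units ≈ 5
  percentile points, peak 17:00) + respondent random intercept (sd 0.4) —
  moves the positive factor up and the negative factor down. Activities
  come in two planted groups (work/household low, leisure high), the
  structure the clustering stage should recover.
* **Standardization.** Shifts are centred and the factors rescaled so the
  *pooled* episode-level factors are exactly standard with correlation
  `factor_correlation` (default −0.6); the unique-part correlation is
  back-solved. The configured loadings and correlation are therefore the
  pooled standardized quantities the episode-pooled CFA estimates, which
  is what makes sharp recovery tolerances meaningful.
* **Diaries.** Set A/B/C respondents cover their day-part event by event
  (first start jittered within the part; ~4.7 episodes; log-normal
  durations, meanlog 4.2, sdlog 0.7 ≈ mean 85 min, sd 68 min); set D
  respondents contribute three day-part blocks without durations.

What the generator does **not** emulate: survey weights and nonresponse,
translation or cultural response styles (e.g. extreme-category use),
activity-dependent duration distributions, within-day autocorrelation of
affect beyond the smooth cycle, and real country demographic composition.
Passing recovery tests therefore demonstrates the estimators are correct
under the assumed model, not that real data meet the model.

## Problem sizes and reproducibility

The test-suite and acceptance computations use sizes chosen to keep Monte
Carlo error comfortably below the tolerance being asserted: ~20,000 pooled
episodes for CFA recovery (tolerances 0.03 on loadings, 0.05 on the factor
correlation), $10^5$ observations for polychoric accuracy (0.02), ~5,000
episodes and 10 × 1000 bootstrap replicates for planted-cluster AU, five
null surveys × 10 × 500 replicates for the false-positive calibration
(asserted against a one-sided 99.9% binomial bound around the nominal 5%
level), and 2,000 respondents for diurnal peak recovery within ±1 h.
Every stochastic routine takes an explicit seed; `run_drm_pipeline()`
writes a manifest with the seed and MD5 digests of its inputs, and a
fixed seed reproduces every output byte for byte.

## Known limitations

* ULS fit statistics are not WLSMV statistics; treat CFI/TLI/RMSEA from
  this package as comparable in spirit only.
* The linear composite reliability is not the threshold-aware categorical
  variant (see above).
* AU values for clusters recovered in essentially all replicates are
  reported as 1 with a flag rather than extrapolated from a saturated
  curve.
* Set D blocks have no durations, so no U-index and no diurnal placement
  beyond the day-part label.
* The percentile transform presumes the theoretical scale range; scores
  outside it (data errors) are rejected, not clipped.
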