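---
title: "Methods: a daily-updated model of bird occurrence and vocal activity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a daily-updated model of bird occurrence and vocal activity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`birdtwin` maintains a per-species probability that a bird is detected in
an audio recording submitted from the field. That probability factors
into three components,

$$P[Y_{ij} = 1] = m_j(\mathrm{lat}_i, t_i)\; s_j(c_i)\; d_j(t_i, r_i, x_i),$$

where for species $j$ and recording $i$:

* **Migration** $m_j$ is the probability the species has arrived from
  spring migration and not yet left on autumn migration. It is the
  pointwise minimum of a rising and a falling normal CDF in day-of-year,
  whose means are linear in latitude:
  $m = \min\{\Phi[(t - \mu_S(\mathrm{lat}))/\sigma_S],\,
  1 - \Phi[(t - \mu_A(\mathrm{lat}))/\sigma_A]\}$,
  with $m \equiv 1$ for residents. Six parameters per species.
* **Occurrence** $s_j$ is the probability the one-hectare cell is part of
  the species' distribution during residency, stored as a raster
  (`raster_layer`) with a mean and an uncertainty (sd) layer.
* **Detection** $d_j$ is the probability that, given presence, the bird
  vocalises such that the classifier flags it at high confidence. Its
  seasonal and diurnal shape comes from a periodic logistic regression
  fitted to fixed-station acoustic monitoring (first and second
  harmonics of the day and time-of-day fractions); a probit
  *translation* maps that per-minute probability onto app recordings of
  any type and length:
  $d^{app} = \Phi(\alpha + \beta_{r} x + \gamma\,\Phi^{-1}(d^{pam}))$,
  with $x$ the log-duration in minutes and $r$ the recording type
  (direct, interval or point count).

The twin updates the migration and occurrence components from the
accumulating stream every night and refits the translation once per
year; the factorisation keeps each update a low-dimensional, per-species
problem.

## Prior model fitting

* `fit_prior_detection()` is a plain binomial GLM on the 8 periodic
  features. Before fitting, `filter_presence_window()` restricts each
  site-year to the span between the 5% and 95% accumulation points of
  that year's detections (integer-rank rule $k = \lceil qn\rceil$), so
  non-detections reflect silence of a present bird rather than absence.
  Single-class responses and complete separation are explicit errors,
  not silent fallbacks.
* `fit_prior_migration()` regresses the per-year, per-latitude-zone 5%
  ("first") and 95% ("last") observation quantiles on zone latitude by
  OLS. The spread parameters are one quarter of the 95% prediction
  interval width, averaged over zones and floored at 0.5 days — without
  the floor a noiseless fit collapses the curve into a step function and
  later likelihoods degenerate. Groups below 50 observations are
  dropped.
* Occurrence priors are inputs (in production they come from a joint
  species distribution model); the package reads and writes them as
  plain-text ASCII-grid rasters because no binary geospatial raster
  library is a dependency.

## Posterior updaters

**Detection translation** (`fit_translation`). MAP under independent
$N(0, 5^2)$ priors on the five coefficients, with the migration and
occurrence components frozen at their prior values. The objective is
smooth and 5-dimensional; BFGS with the analytic gradient is polished by
a few damped Newton steps because BFGS alone stalls near the
objective's rounding floor on large streams; convergence is declared at
gradient sup-norm $<10^{-6}$. Interval-mode recordings are always one
minute long, so their log-duration is 0 and $\beta_{interval}$ is
informed only by its prior — the MAP correctly returns it to 0.

**Migration** (`fit_posterior_migration`). Year-specific MAP with a
*functional* prior: the penalty is the integrated squared distance
between the posterior and prior migration curves over a latitude × day
domain (`functional_penalty`, a Riemann mean times the domain area in
degree-days), so large parameter moves that barely change the curve are
cheap while shape changes are not. Spread parameters are optimised on
the log scale (floored at 0.5 days); the search is Nelder–Mead started
at the prior, so the fitted objective never exceeds the prior's.
The default precision is $\lambda = 0.01$. On a desk-scale stream
($\sim 10^4$ records) that penalty is orders of magnitude smaller than
the likelihood; for species that complete arrival before the
observation season starts, the in-season data carry no migration signal
and the unpenalised curve degenerates into a free seasonal dial. The
packaged evaluation pipeline therefore runs with $\lambda = 1$,
chosen so the prior-to-likelihood information ratio is comparable to a
national-scale stream (three orders of magnitude more records); all
functions accept any $\lambda$.

**Occurrence** (`update_cell`, `update_raster`). Per-cell local
likelihood: every record's Bernoulli term (success probability
$m\,s\,d$, with $m$ and $d$ plugged in) is weighted by a Gaussian kernel
$\exp(-\tau\,\mathrm{dist}^2/2)$ of the distance between the record's
1-km cell and the focal cell. Defaults $\tau = 1/2.5^2$ per km² with a
hard truncation at 7.5 km (three kernel sd); at $\tau = 0$ the kernel is
identically one and the update reduces to a single pooled MLE shared by
all cells. The prior is a normal truncated to $[0,1]$ with moments from
the prior raster; the posterior sd is the Laplace curvature at the mode,
falling back to the prior sd if the curvature is not negative (cannot
occur with a proper prior, kept as a guard). The log posterior is
strictly concave in $s$, so the raster-level C++ path uses safeguarded
Newton on the analytic derivative (detection terms collapse to a single
$\sum w_i y_i / s$ term); the single-cell R path uses Brent search, and
the two agree with an exhaustive grid search to $2\times10^{-5}$.

Coarse/fine reconciliation: fine priors are block-averaged (means and
variances separately, nodata excluded) to the 1-km grid where the update
runs; `upsample_posterior()` then shifts each fine prior on the probit
scale by a common block offset chosen by monotone root finding so the
block mean equals the coarse posterior. This preserves within-block
ranks exactly. A literal least-squares variant that shifts the coarse
value instead (and is therefore constant within a block) is available
via `method = "literal"` for comparison; it cannot preserve local
geometry, which is why it is not the default.
`probit_prior_moments()` converts probit-scale prior summaries to the
probability scale by 64-node Gauss–Hermite quadrature, with a stratified
Monte Carlo route as an independent cross-check.

## Evaluation and site selection

`walk_forward()` sweeps a fitting day $T$ over the season: migration and
occurrence posteriors are refitted from scratch on all records up to
$T$, and both the prior and posterior model score the records in
$(T, T + \text{window}]$. Predictions are pooled over all test periods
before one AUC (Mann–Whitney, ties counted half) per species is
computed; species below a detection-count threshold are dropped. The
translation is pre-fitted on a burn-in year and held fixed. A guard
asserts no record later than $T$ ever enters a fit.

`select_day_sites()` implements the validation-survey utility: the gain
for visiting a cell is the absolute prior–posterior disagreement
$f_j = |s^{post} - s^{prior}|$, discounted by
$\prod_i (1 - g_j)$ over previously chosen sites, where $g_j$ is a
Gaussian kernel in (prior, posterior) probability space
($\tau = 400$, i.e. sd 0.05, ceiling $\gamma = 0.95$) gated by a
migration indicator ($m \ge 0.75$) so that visits made before a species
had arrived do not penalise. The exponent is negative — the kernel must
*decay* with scenario distance to mean "this scenario was already
sampled"; the bounded form is the only one consistent with that role.
Selection is greedy: best cell within 50 km of the volunteer's home,
then nine more within 10 km of the first, all at least 1 km from every
previously selected site, ties broken to the lower (row, col).
Same-day picks enter the penalty immediately (the state updates after
each pick). `point_count_layout()` places the five survey points at the
centre and corners of a 100-m square.

## The synthetic world

`make_world()` draws a community over a 200 × 200 one-hectare grid
(a 20 × 20 km landscape spanning latitudes 60–62):

* True occurrence surfaces are probit-transformed band-limited noise
  (bilinear interpolation of a 4 × 4 normal lattice), clipped to
  $[0.02, 0.98]$. The 4-knot default gives ~7-km features: the
  kernel-weighted estimator has a ~2.5-km resolution, and a field
  varying below that scale is unlearnable *by construction* for any
  local smoother, which would make simulation checks uninformative
  about correctness.
* Migration: 80% of species migratory; spring arrival days 90–160 at
  latitude 60 with 0.5–3 days/degree delay northward; spreads 3–10 days;
  autumn departures day 240–290.
* Vocal activity: periodic-logistic coefficients with intercepts
  $U(-3, -1.5)$ (a few detections per hundred acoustic minutes).
* Translation truths use intercepts $U(0.5, 1.5)$: app recordings are
  typically *initiated because a bird is vocalising*, so per-recording
  detection runs far above a random acoustic minute; negative intercepts
  produce detection rates an order of magnitude below real streams.

`perturb_prior()` creates the prior-versus-truth gap the twin must
learn away: a smooth probit-scale shift of the occurrence surface
(sd 1.0 in the packaged signal scenario — strong enough that the prior
genuinely misranks areas, the regime the method is for; sd 0 is the null
scenario), a constant prior sd layer of 0.15, and normal shifts
(sd 7 days) of the migration mean-day parameters.

`observer_population()` and `simulate_mk_stream()` emulate the stream:
200 users at fixed homes, active 30% of days; direct recordings
(Poisson mean 1.2 per active day) with log-normal durations
(median 33 s) whose start minutes are sampled proportionally to
$1 + b \times$ expected community vocal activity ($b = 1$; $b = 0$
gives uniform times); interval sessions of six 1-minute segments every
10 minutes; 5-minute point counts at the nearest of 20 fixed stations.
Detections are Bernoulli draws from the true product model. Everything
is a pure function of its seed.

What the generator does *not* emulate: classifier errors (detections are
post-threshold), per-user skill or preference heterogeneity, road
networks and travel, weather, within-day vocal bouts, and real
geography. Passing the simulation checks therefore demonstrates
correctness of the estimators under the stated model, not performance on
real Finnish data.

## Problem sizes and numerical choices

The packaged evaluation (`run_evaluation()`) simulates one ~100-day
season (days 105–203) twice — a burn-in year for the translation fit and
an evaluation year — over the default world (10 species, 200 users,
~10,000 recordings/season), then walk-forwards with a 7-day window
(13 fitting days). These sizes were chosen so a full
simulate–update–evaluate cycle runs in about a minute on one core while
leaving hundreds of detections per species in the test pool.

* Logistic/probit fits: IRLS (`glm`) and BFGS+Newton to gradient
  sup-norm $10^{-6}$.
* Migration MAP: Nelder–Mead, restart polish in standalone fits,
  300-iteration cap inside the walk-forward loop.
* Per-cell MAP: Newton/Brent to $10^{-11}$ in $s$, search domain
  $[10^{-6}, 1 - 10^{-6}]$.
* Probabilities are clamped at $10^{-12}$ (likelihoods) or $10^{-9}$
  (probit transforms) before logs; clamps that fire on genuinely
  out-of-range inputs warn.
* Ties in site selection break on (utility, row, col); all stochastic
  code paths take explicit integer seeds.

## Known limitations

* Only the product $m\,s\,d$ is identified by detection data. The
  translation fit absorbs part of any systematic level error in the
  prior occurrence surface, so the *absolute* calibration of the updated
  surface can drift even while its spatial structure (and predictive
  ranking) improves. Comparisons against truth in the tests are
  therefore made on discrimination (AUC) and correlation, not absolute
  error.
* The local-likelihood update trades bias for variance: it cannot
  recover structure finer than the kernel scale, and under a perfect
  prior it adds a small amount of smoothing noise (the null-scenario
  AUC cost is bounded in the acceptance checks).
* Trigger-biased initiation times are simulated but not modelled; the
  translation intercept absorbs the average effect only.
* The upsampling default intentionally implements the stated goals of
  the procedure (rank preservation, block-mean consistency) rather than
  the literal printed objective, which contradicts them; the literal
  form is available behind an option.
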