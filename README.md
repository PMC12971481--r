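# birdtwin

A continuously updatable ("digital twin") model of bird spatiotemporal
distributions driven by streaming, audio-based citizen-science
detections, for quantitative ecologists who want daily occurrence and
activity forecasts that blend long-term knowledge with a live data
stream.

The probability that species *j* is detected in recording *i* factors
into three components,

```
P[Y_ij = 1] = m_j(lat_i, t_i) * s_j(c_i) * d_j(t_i, r_i, x_i)
```

* `m` — migration: `min{ Φ[(t − μ_S(lat))/σ_S], 1 − Φ[(t − μ_A(lat))/σ_A] }`,
  the probability the species has arrived and not yet departed
  (≡ 1 for residents);
* `s` — occurrence: the probability the one-hectare cell belongs to the
  species' distribution, held as mean + sd rasters;
* `d` — detection: a periodic logistic model of vocal activity in
  day-of-year and time-of-day, translated to app recordings through a
  probit model `Φ(α + β_r·log duration + γ·Φ⁻¹(d_pam))`.

Priors for each component are fitted from long-term data
(`fit_prior_detection()`, `fit_prior_migration()`; occurrence priors are
raster inputs). The stream then updates the model nightly:

* `fit_translation()` — MAP probit translation of acoustic detection
  probabilities to app recordings (Gaussian priors, refit yearly);
* `fit_posterior_migration()` — year-specific migration curve under a
  functional prior that penalises the integrated squared distance
  between posterior and prior curves;
* `update_raster()` / `update_cell()` — per-cell MAP of the occurrence
  surface under a kernel-weighted local likelihood (Gaussian kernel,
  sd 2.5 km, truncated at 7.5 km) with a truncated-normal prior and
  Laplace posterior sd, plus coarse↔fine raster reconciliation
  (`downsample_prior()`, `upsample_posterior()`).

`walk_forward()` scores prior vs updated models on next-period data by
pooled Mann–Whitney AUC; `select_day_sites()` chooses validation survey
sites by a utility that targets prior–posterior disagreement while
penalising repeated scenarios; `make_world()` / `simulate_mk_stream()`
generate fully synthetic worlds with known ground truth so every stage
is testable offline.

## Worked example

Simulate a season over a 20 × 20 km landscape (10 species, 200 app
users), deliberately hand the twin a *wrong* prior, and compare
next-week predictions of the prior and the updated model:

```r
library(birdtwin)
res <- run_evaluation(seed = 1)   # ~1.5 min on one core
res
#> # A tibble: 10 × 5
#>    species_id n_detections auc_prior auc_posterior  delta
#>    <chr>             <int>     <dbl>         <dbl>  <dbl>
#>  1 sp01                478     0.863         0.878 0.0152
#>  2 sp02                850     0.705         0.750 0.0455
#>  3 sp03               3124     0.648         0.731 0.0836
#>  4 sp04                453     0.722         0.757 0.0348
#>  5 sp05                612     0.767         0.812 0.0456
#>  6 sp06               2165     0.636         0.691 0.0556
#>  7 sp07               1717     0.735         0.768 0.0333
#>  8 sp08                412     0.825         0.867 0.0420
#>  9 sp09               2018     0.681         0.730 0.0490
#> 10 sp10               1212     0.859         0.878 0.0189
mean(res$delta)
#> [1] 0.04234485
```

Each row is one species: `n_detections` counts its detections in the
pooled test periods, `auc_prior` and `auc_posterior` are the
probabilities that a randomly chosen detection outranks a randomly
chosen non-detection under each model, and `delta` is the improvement
the nightly updates bought. `autoplot(res)` draws the prior-vs-posterior
AUC scatter. Re-running with `spatial_shift_sd = 0,
migration_shift_days = 0` (a prior that already equals the truth) shows
the updates are honest: `mean(res$delta)` stays near zero.

A thin command-line wrapper over the same functions lives at
`inst/cli/birdtwin.R` (`simulate` and `evaluate` subcommands).

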