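test_that("worlds are pure functions of their seed", {
  w1 <- tiny_world(seed = 101L)
  w2 <- tiny_world(seed = 101L)
  expect_identical(w1, w2)
  w3 <- tiny_world(seed = 102L)
  expect_false(identical(w1$species$sp01$s_true$values,
                         w3$species$sp01$s_true$values))
  w_one <- make_world(n_species = 1L, n_rows = 40L, n_cols = 40L, seed = 5L)
  expect_equal(length(w_one$species), 1L)
  expect_named(w_one$species, "sp01")
  # field summary matches an independent regeneration with the same seed
  s1 <- c(mean(w1$species$sp02$s_true$values),
          stats::sd(w1$species$sp02$s_true$values))
  s2 <- c(mean(tiny_world(seed = 101L)$species$sp02$s_true$values),
          stats::sd(tiny_world(seed = 101L)$species$sp02$s_true$values))
  expect_identical(s1, s2)
  expect_true(all(w1$species$sp01$s_true$values >= 0.02 &
                    w1$species$sp01$s_true$values <= 0.98))
})

test_that("prior perturbation creates a controlled, reproducible gap", {
  w <- tiny_world()
  # zero shifts reproduce the truth exactly
  pr0 <- perturb_prior(w, spatial_shift_sd = 0, migration_shift_days = 0,
                       seed = 7L)
  expect_equal(pr0$sp01$prior_mean_fine$values, w$species$sp01$s_true$values,
               tolerance = 1e-12)
  expect_identical(pr0$sp01$migration, w$species$sp01$migration)
  # positive shift: a reproducible nonzero gap
  prA <- perturb_prior(w, spatial_shift_sd = 0.5, seed = 7L)
  prB <- perturb_prior(w, spatial_shift_sd = 0.5, seed = 7L)
  expect_identical(prA$sp01$prior_mean_fine$values,
                   prB$sp01$prior_mean_fine$values)
  gap <- mean(abs(prA$sp01$prior_mean_fine$values -
                    w$species$sp01$s_true$values))
  expect_gt(gap, 0)
  # the prior sd layer is the stated constant everywhere
  expect_true(all(prA$sp01$prior_sd_fine$values == 0.15))
})

test_that("acoustic streams follow the product model", {
  w <- tiny_world()
  stations <- tibble::tibble(row = c(5L, 30L), col = c(8L, 25L))
  # a silent species is never detected
  w_mute <- w
  w_mute$species$sp01$pam_coefs["intercept"] <- -50
  pam <- simulate_pam(w_mute, stations, days = 120:150, seed = 8L)
  expect_equal(sum(pam$sp01), 0L)
  # empirical detection rate within 3 Monte-Carlo sd of the analytic mean
  pam2 <- simulate_pam(w, stations, days = 120:150,
                       minutes_of_day = seq(0, 1430, by = 10), seed = 9L)
  one <- dplyr::filter(pam2, site_id == "st01")
  p_true <- migration_probability(w$species$sp02$migration,
                                  birdtwin:::row_latitude(5, 40, c(60, 62)),
                                  one$day_of_year) *
    raster_value_at(w$species$sp02$s_true, 5, 8) *
    predict_d_pam(w$species$sp02$pam_coefs, day_fraction(one$day_of_year),
                  minute_fraction(one$minute_of_day))
  mu <- mean(p_true)
  mc_sd <- sqrt(sum(p_true * (1 - p_true))) / nrow(one)
  expect_lt(abs(mean(one$sp02) - mu), 3 * mc_sd)
})

test_that("app streams are reproducible with isolated seed lanes", {
  w <- tiny_world()
  obs <- observer_population(w, n_users = 30L, n_stations = 4L, seed = 21L)
  s1 <- simulate_mk_stream(w, obs, days = 130:150, seed = 22L)
  # interleaving an unrelated acoustic simulation cannot perturb the stream
  invisible(simulate_pam(w, tibble::tibble(row = 1L, col = 1L),
                         days = 130:135, seed = 8L))
  s2 <- simulate_mk_stream(w, obs, days = 130:150, seed = 22L)
  expect_identical(as.data.frame(s1), as.data.frame(s2))
  expect_silent(validate_recordings(s1))
  # streams round-trip losslessly through the CSV writers
  path <- withr::local_tempfile(fileext = ".csv")
  write_recordings(s1, path)
  expect_equal(as.data.frame(read_recordings(path)[, names(s1)]),
               as.data.frame(s1), tolerance = 1e-12)
})

test_that("a species absent all season is never detected in the app stream", {
  w <- tiny_world()
  # push spring arrival far past the simulated window
  w$species$sp01$migration <- migration_params(400, 0, 5, 500, 0, 5)
  obs <- observer_population(w, n_users = 30L, n_stations = 4L, seed = 23L)
  st <- simulate_mk_stream(w, obs, days = 120:150, seed = 24L)
  expect_equal(sum(st$sp01), 0L)
})

test_that("unbiased observers initiate direct recordings uniformly in time", {
  w <- tiny_world()
  minutes <- integer(0)
  for (s in 1:20) {
    obs <- observer_population(w, n_users = 40L, trigger_bias = 0,
                               interval_prob = 0, point_prob = 0,
                               n_stations = 2L, seed = 300L + s)
    st <- simulate_mk_stream(w, obs, days = 140:144, seed = 400L + s)
    minutes <- c(minutes, st$minute_of_day)
  }
  # chi-square goodness of fit against uniform occupancy of the window
  # (recordings start in 240..1199; 15 bins of 64 minutes each)
  bins <- cut(minutes, breaks = seq(240, 1200, by = 64), include.lowest = TRUE)
  p <- suppressWarnings(stats::chisq.test(table(bins))$p.value)
  expect_gt(p, 0.01)
})

test_that("app detection rates match the analytic expectation", {
  w <- tiny_world()
  obs <- observer_population(w, n_users = 60L, n_stations = 4L, seed = 25L)
  st <- simulate_mk_stream(w, obs, days = 120:170, seed = 26L)
  sp <- "sp03"
  p_true <- migration_probability(w$species[[sp]]$migration, st$latitude_deg,
                                  st$day_of_year) *
    raster_value_at(w$species[[sp]]$s_true, st$row, st$col) *
    d_mk(w$species[[sp]]$translation, st$rec_type, st$log_duration,
         predict_d_pam(w$species[[sp]]$pam_coefs,
                       day_fraction(st$day_of_year),
                       minute_fraction(st$minute_of_day)))
  mu <- mean(p_true)
  mc_sd <- sqrt(sum(p_true * (1 - p_true))) / nrow(st)
  expect_lt(abs(mean(st[[sp]]) - mu), 3 * mc_sd)
})
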