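test_that("kernel weights follow the truncated Gaussian form", {
  tau <- 1 / 2.5^2
  expect_equal(kernel_weight(0, tau), 1)
  expect_equal(kernel_weight(2.5, tau), exp(-0.5), tolerance = 1e-12)
  expect_equal(kernel_weight(7.5, tau), exp(-4.5), tolerance = 1e-12)
  expect_equal(kernel_weight(7.6, tau), 0)
  expect_equal(kernel_weight(c(0, 3, 100), 0), rep(1, 3))
})

test_that("the local likelihood matches a brute-force oracle", {
  g <- grid_spec(4, 4, cell_size_km = 1.0)
  rec <- toy_spatial_records()
  cfg <- spatial_update_config()
  for (s in c(0.1, 0.5, 0.9)) {
    expect_equal(local_log_likelihood(s, 1, 2, rec, g, cfg),
                 brute_local_loglik(s, 1, 2, rec, g, cfg$tau_spatial,
                                    cfg$truncation_radius_km),
                 tolerance = 1e-10)
  }
  # tau = 0 reduces to the pooled, unweighted likelihood
  cfg0 <- spatial_update_config(tau_spatial = 0)
  pooled <- sum(rec$y * log(rec$m * 0.4 * rec$d) +
                  (1 - rec$y) * log(1 - rec$m * 0.4 * rec$d))
  expect_equal(local_log_likelihood(0.4, 0, 0, rec, g, cfg0), pooled,
               tolerance = 1e-10)
  # only focal-cell data: equals the single-cell likelihood for any tau
  focal_only <- dplyr::filter(rec, row == 2, col == 2)
  expect_equal(local_log_likelihood(0.3, 2, 2, focal_only, g, cfg),
               sum(focal_only$y * log(focal_only$m * 0.3 * focal_only$d) +
                     (1 - focal_only$y) *
                     log(1 - focal_only$m * 0.3 * focal_only$d)),
               tolerance = 1e-12)
})

test_that("the per-cell MAP matches grid search and known limits", {
  g <- grid_spec(4, 4, cell_size_km = 1.0)
  rec <- toy_spatial_records()
  cfg <- spatial_update_config()

  # no records in reach: the mode is the (interior) prior mean
  out0 <- update_cell(1, 1, rec[0, ], 0.35, 0.1, g, cfg)
  expect_equal(out0$s_hat, 0.35, tolerance = 1e-6)
  expect_equal(out0$posterior_sd, 0.1, tolerance = 1e-4)

  # grid-search oracle over 1e5 equally spaced values
  sgrid <- seq(1e-6, 1 - 1e-6, length.out = 1e5)
  for (case in list(list(r = 1, c = 2, pm = 0.3, psd = 0.15),
                    list(r = 0, c = 0, pm = 0.8, psd = 0.05),
                    list(r = 3, c = 3, pm = 0.5, psd = 0.5))) {
    obj <- vapply(sgrid, function(s)
      local_log_likelihood(s, case$r, case$c, rec, g, cfg) +
        birdtwin:::log_trunc_normal(s, case$pm, case$psd), 0)
    out <- update_cell(case$r, case$c, rec, case$pm, case$psd, g, cfg)
    expect_lt(abs(out$s_hat - sgrid[which.max(obj)]), 2e-5)
    expect_gt(out$posterior_sd, 0)
  }

  # many weighted detections with m = d = 1 and a diffuse prior: the MAP
  # approaches the weighted empirical detection rate
  withr::with_seed(61, {
    big <- tibble::tibble(row = sample(0:3, 3000, TRUE),
                          col = sample(0:3, 3000, TRUE),
                          y = rbinom(3000, 1, 0.35), m = 1, d = 1)
    w <- kernel_weight(cell_distance_km(big$row, big$col, 1, 1, g),
                       cfg$tau_spatial, cfg$truncation_radius_km)
    rate <- sum(w * big$y) / sum(w)
    out <- update_cell(1, 1, big, 0.5, 10, g, cfg)
    expect_lt(abs(out$s_hat - rate), 0.01)
  })
  expect_error(update_cell(1, 1, rec, 1.5, 0.1, g, cfg), "prior")
})

test_that("raster updates agree with the single-cell path and its limits", {
  g <- grid_spec(4, 4, cell_size_km = 1.0)
  rec <- toy_spatial_records(n = 120L)
  cfg <- spatial_update_config()
  pm <- raster_layer(matrix(0.4, 4, 4), g)
  psd <- raster_layer(matrix(0.15, 4, 4), g)
  post <- update_raster(rec, pm, psd, cfg)
  for (r in 0:3) for (c in 0:3) {
    cell <- update_cell(r, c, rec, 0.4, 0.15, g, cfg)
    expect_lt(abs(raster_value_at(post$mean, r, c) - cell$s_hat), 1e-7)
    expect_lt(abs(raster_value_at(post$sd, r, c) - cell$posterior_sd), 1e-5)
  }
  # nodata prior cells stay nodata
  pm2 <- pm; pm2$values[2, 2] <- NA
  post2 <- update_raster(rec, pm2, psd, cfg)
  expect_true(is.na(post2$mean$values[2, 2]))

  # very large tau: only focal-cell data matter
  cfg_big <- spatial_update_config(tau_spatial = 100)
  post_big <- update_raster(rec, pm, psd, cfg_big)
  focal <- dplyr::filter(rec, row == 2, col == 1)
  cell_big <- update_cell(2, 1, focal, 0.4, 0.15, g,
                          spatial_update_config(tau_spatial = 100))
  expect_lt(abs(raster_value_at(post_big$mean, 2, 1) - cell_big$s_hat), 1e-4)

  # tau = 0: every cell shares the pooled MAP
  cfg0 <- spatial_update_config(tau_spatial = 0)
  post0 <- update_raster(rec, pm, psd, cfg0)
  expect_lt(diff(range(post0$mean$values)), 1e-9)
  expect_gt(min(post0$sd$values), 0)
})

test_that("block averaging of prior moments masks nodata correctly", {
  fg <- grid_spec(20, 20, cell_size_km = 0.1)
  v <- matrix(0.6, 20, 20)
  out <- downsample_prior(raster_layer(v, fg), raster_layer(v * 0 + 0.02, fg))
  expect_true(all(out$mean$values == 0.6))
  expect_true(all(abs(out$var$values - 0.02) < 1e-15))

  withr::with_seed(67, {
    m <- matrix(runif(400), 20, 20)
    blk <- m[1:10, 1:10]
    out2 <- downsample_prior(raster_layer(m, fg),
                             raster_layer(matrix(0.01, 20, 20), fg))
    expect_equal(out2$mean$values[1, 1], sum(blk) / 100, tolerance = 1e-12)
    m3 <- m; m3[1:10, 1:5] <- NA
    out3 <- downsample_prior(raster_layer(m3, fg),
                             raster_layer(matrix(0.01, 20, 20), fg))
    expect_equal(out3$mean$values[1, 1], mean(m[1:10, 6:10]), tolerance = 1e-12)
    m4 <- m; m4[1:10, 1:10] <- NA
    out4 <- downsample_prior(raster_layer(m4, fg),
                             raster_layer(matrix(0.01, 20, 20), fg))
    expect_true(is.na(out4$mean$values[1, 1]))
  })
})

test_that("probit-normal priors convert to probability-scale moments", {
  expect_equal(probit_prior_moments(0.7, 0),
               c(prob_mean = pnorm(0.7), prob_sd = 0))
  expect_equal(probit_prior_moments(0, 1)[["prob_mean"]], 0.5,
               tolerance = 1e-10)
  # large-sample Monte Carlo oracle
  withr::with_seed(71, {
    z <- rnorm(1e7, 1, 0.5)
    oracle <- c(mean(pnorm(z)), stats::sd(pnorm(z)))
  })
  gh <- probit_prior_moments(1, 0.25)
  expect_lt(abs(gh[["prob_mean"]] - oracle[1]), 2e-3)
  expect_lt(abs(gh[["prob_sd"]] - oracle[2]), 2e-3)
  # the quadrature and Monte Carlo routes agree
  mc <- probit_prior_moments(1, 0.25, method = "monte_carlo", seed = 5)
  expect_lt(max(abs(gh - mc)), 1e-3)
})

test_that("upsampling preserves prior geometry and block means", {
  withr::with_seed(73, {
    block <- runif(100, 0.1, 0.9)
    # uniform block equal to the coarse value: unchanged
    expect_equal(upsample_posterior(0.4, rep(0.4, 100)), rep(0.4, 100),
                 tolerance = 1e-9)
    for (target in c(0.15, 0.5, 0.85)) {
      up <- upsample_posterior(target, block)
      expect_lt(abs(mean(up) - target), 1e-6)
      expect_identical(rank(up), rank(block))
      # brute-force 1-D scan oracle for the shift
      deltas <- seq(-8, 8, by = 1e-4)
      err <- abs(vapply(deltas, function(d) mean(pnorm(qnorm(block) + d)), 0) -
                   target)
      delta_scan <- deltas[which.min(err)]
      delta_hat <- qnorm(up[1]) - qnorm(block[1])
      expect_lt(abs(delta_hat - delta_scan), 2e-4)
    }
    # raising the block: every fine value moves up
    up_hi <- upsample_posterior(mean(block) + 0.2, block)
    expect_true(all(up_hi >= block))
    # the literal printed objective yields a constant block
    lit <- upsample_posterior(0.5, block, method = "literal")
    expect_equal(length(unique(lit)), 1L)
    expect_warning(upsample_posterior(1, block), "clamped")
  })
})
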