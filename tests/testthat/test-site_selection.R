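test_that("the disagreement term is the absolute prior-posterior gap", {
  expect_equal(disagreement_term(0.3, 0.8), 0.5)
  expect_equal(disagreement_term(0.8, 0.3), 0.5)
  expect_equal(disagreement_term(0.1, 0.6), 0.5)
  x <- runif(10)
  expect_equal(disagreement_term(x, x), rep(0, 10))
  expect_error(disagreement_term(-0.1, 0.5))
})

test_that("the scenario penalty is a gated Gaussian kernel in probability space", {
  cfg <- selection_config()
  expect_equal(scenario_penalty(0.3, 0.8, 0.3, 0.8, 1), 0.95)
  expect_equal(scenario_penalty(0.3, 0.8, 0.3, 0.8, 0.5), 0)  # not arrived
  # direct evaluation oracle: both gaps 0.05 with tau = 400 gives e^-1
  expect_equal(scenario_penalty(0.35, 0.65, 0.3, 0.6, 1), 0.95 * exp(-1),
               tolerance = 1e-9)
  expect_true(all(scenario_penalty(runif(20), runif(20), runif(20),
                                   runif(20), 1) <= 0.95))
})

test_that("species utilities multiply the survival of past penalties", {
  cfg <- selection_config()
  none <- tibble::tibble(prior = numeric(), posterior = numeric(),
                         migration = numeric())
  expect_equal(species_utility(0.3, 0.8, none), 0.5)
  once <- tibble::tibble(prior = 0.3, posterior = 0.8, migration = 1)
  expect_equal(species_utility(0.3, 0.8, once), 0.5 * 0.05, tolerance = 1e-12)
  withr::with_seed(91, {
    hist3 <- tibble::tibble(prior = runif(3), posterior = runif(3),
                            migration = runif(3))
    cand <- runif(2)
    got <- species_utility(cand[1], cand[2], hist3)
    # brute-force product oracle
    f <- abs(cand[2] - cand[1])
    for (i in 1:3) {
      g <- 0.95 * (hist3$migration[i] >= 0.75) *
        exp(-200 * ((cand[1] - hist3$prior[i])^2 +
                      (cand[2] - hist3$posterior[i])^2))
      f <- f * (1 - g)
    }
    expect_equal(got, unname(f), tolerance = 1e-12)
    # utility is invariant to history order
    expect_equal(species_utility(cand[1], cand[2], hist3[3:1, ]), got,
                 tolerance = 1e-15)
    expect_lte(got, abs(cand[2] - cand[1]))
  })
})

test_that("total utility sums migration-gated species utilities", {
  state <- selection_state()
  cand <- tibble::tibble(species_id = c("a", "b"),
                         prior = c(0.2, 0.6), posterior = c(0.7, 0.1),
                         migration = c(0.9, 0.5))
  # species b has not arrived at the candidate: only a contributes
  expect_equal(total_utility(cand, state), 0.5)
  cand$migration <- c(0.5, 0.6)
  expect_equal(total_utility(cand, state), 0)
})

test_that("daily site selection is greedy, separated and deterministic", {
  g <- grid_spec(30, 30, cell_size_km = 1.0)
  cfg <- selection_config(satellite_radius_km = 10, sites_per_volunteer = 3L)
  withr::with_seed(97, {
    cells <- tidyr::expand_grid(row = seq(0L, 28L, by = 2L),
                                col = seq(0L, 28L, by = 2L)) |>
      dplyr::slice_sample(n = 20)
    cands <- tidyr::expand_grid(dplyr::mutate(cells, cell = dplyr::row_number()),
                                species_id = c("s1", "s2")) |>
      dplyr::mutate(prior = runif(dplyr::n()), posterior = runif(dplyr::n()),
                    migration = runif(dplyr::n(), 0.7, 1)) |>
      dplyr::select(-cell)
  })
  out <- select_day_sites(15, 15, cands, selection_state(), g, day = 140,
                          config = cfg)
  expect_equal(nrow(out$sites), 3L)
  # exhaustive-search oracle re-evaluating utilities after each pick
  st <- selection_state()
  chosen <- list()
  pool0 <- dplyr::distinct(cands, row, col)
  for (k in 1:3) {
    pool <- pool0
    if (k > 1) {
      first <- chosen[[1]]
      keep <- cell_distance_km(pool$row, pool$col, first$row, first$col, g) <= 10
      pool <- pool[keep, ]
    } else {
      pool <- pool[cell_distance_km(pool$row, pool$col, 15, 15, g) <= 50, ]
    }
    if (length(chosen)) {
      prev <- dplyr::bind_rows(chosen)
      ok <- vapply(seq_len(nrow(pool)), function(i)
        all(cell_distance_km(pool$row[i], pool$col[i], prev$row, prev$col,
                             g) >= 1), TRUE)
      pool <- pool[ok, ]
    }
    util <- vapply(seq_len(nrow(pool)), function(i) {
      cand <- dplyr::filter(cands, row == pool$row[i], col == pool$col[i])
      total_utility(cand, st, cfg)
    }, 0)
    best <- order(-util, pool$row, pool$col)[1]
    pick <- list(row = pool$row[best], col = pool$col[best])
    sv <- dplyr::filter(cands, row == pick$row, col == pick$col) |>
      dplyr::select(species_id, prior, posterior, migration)
    st <- birdtwin:::record_choice(st, pick$row, pick$col, 140L, sv)
    chosen[[k]] <- tibble::as_tibble(pick)
  }
  oracle <- dplyr::bind_rows(chosen)
  expect_equal(out$sites$row, oracle$row)
  expect_equal(out$sites$col, oracle$col)

  # identical rerun: identical sequence
  out2 <- select_day_sites(15, 15, cands, selection_state(), g, day = 140,
                           config = cfg)
  expect_identical(out$sites, out2$sites)

  # every pair of selected sites at least 1 km apart
  d <- as.matrix(dist(cbind(out$sites$row, out$sites$col)))
  expect_true(all(d[upper.tri(d)] >= 1))

  # a single admissible candidate is chosen
  one <- dplyr::filter(cands, row == cands$row[1], col == cands$col[1])
  expect_warning(
    out3 <- select_day_sites(15, 15, one, selection_state(), g, day = 1,
                             config = selection_config(sites_per_volunteer = 2L)),
    "exhausted")
  expect_equal(nrow(out3$sites), 1L)

  # equal utilities break ties toward the lower (row, col)
  tie <- tibble::tibble(row = c(5L, 3L), col = c(2L, 4L), species_id = "s1",
                        prior = 0.2, posterior = 0.7, migration = 1)
  out4 <- select_day_sites(4, 3, tie, selection_state(), g, day = 1,
                           config = selection_config(sites_per_volunteer = 1L))
  expect_equal(out4$sites$row, 3L)
})

test_that("point-count layouts form a 100 m square plus centre", {
  lay <- point_count_layout(0, 0)
  expect_equal(nrow(lay), 5L)
  expect_equal(lay$easting_km[1], 0)
  expect_equal(colMeans(lay[, c("easting_km", "northing_km")]),
               c(easting_km = 0, northing_km = 0))
  corners <- as.matrix(lay[2:5, c("easting_km", "northing_km")])
  d <- as.matrix(dist(corners))
  expect_true(all(abs(d[upper.tri(d)] - 0.1) < 1e-12 |
                    abs(d[upper.tri(d)] - 0.1 * sqrt(2)) < 1e-12))
})
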