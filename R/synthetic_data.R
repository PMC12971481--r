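#' @name synthetic_world
#' @title Synthetic worlds with known ground truth
#'
#' @description The generator builds desk-scale worlds that emulate the
#' structure of the real system: a fine one-hectare grid over a
#' two-degree latitude band, a community of species each with a true
#' migration curve, a true smooth occurrence surface, true periodic vocal
#' activity coefficients and true detection-translation parameters; a
#' population of observers producing direct, interval and point-count
#' recordings; and Bernoulli detections drawn from the product model
#' `m * s * d`. Every stochastic generator is a pure function of its
#' inputs and seed.
NULL

# latitude of a fine-grid row centre (row 0 = northern edge)
row_latitude <- function(row, n_rows, lat_range) {
  lat_range[2] - (row + 0.5) / n_rows * (lat_range[2] - lat_range[1])
}

# Smooth unit-variance random surface: bilinear interpolation of a coarse
# lattice of iid normals (band-limited noise).
smooth_field <- function(n_rows, n_cols, knots = 8L) {
  z <- matrix(rnorm(knots^2), knots, knots)
  rows_at <- seq(1, knots, length.out = n_rows)
  cols_at <- seq(1, knots, length.out = n_cols)
  # interpolate rows, then columns
  tmp <- apply(z, 2, function(col) stats::approx(seq_len(knots), col,
                                                 xout = rows_at)$y)
  out <- t(apply(tmp, 1, function(row) stats::approx(seq_len(knots), row,
                                                     xout = cols_at)$y))
  out / stats::sd(out)
}

#' Generate a synthetic world
#'
#' @param n_species Number of species, default 10.
#' @param n_rows,n_cols Fine-grid dimensions, default 200 x 200 cells of
#'   0.1 km (a 20 x 20 km landscape).
#' @param lat_range Latitude band mapped affinely onto grid rows
#'   (northern edge first row), default 60-62 degrees.
#' @param p_migratory Probability a species is migratory, default 0.8.
#' @param field_knots Lattice size of the band-limited noise behind the
#'   true occurrence surfaces. The default 4 gives landscape-scale
#'   features (roughly 7 km across on the default 20-km domain),
#'   comparable to the resolution of the kernel-weighted spatial
#'   estimator; finer lattices produce fields varying below the kernel
#'   scale that no local-likelihood smoother could recover.
#' @param seed Integer seed; identical seeds give identical worlds.
#' @return An object of class `synthetic_world`: fine and coarse
#'   `grid_spec`s, the latitude mapping and a named species list, each
#'   entry holding `migration` (true [migration_params()]), `pam_coefs`
#'   (true periodic logistic coefficients), `translation` (true
#'   [translation_params()]) and `s_true` (true fine occurrence
#'   `raster_layer`, values in `[0.02, 0.98]`).
#' @export
make_world <- function(n_species = 10L, n_rows = 200L, n_cols = 200L,
                       lat_range = c(60, 62), p_migratory = 0.8,
                       field_knots = 4L, seed = 1L) {
  stopifnot(n_species >= 1L)
  fine <- grid_spec(n_rows, n_cols, cell_size_km = 0.1)
  withr::with_seed(seed, {
    species <- lapply(seq_len(n_species), function(j) {
      migratory <- runif(1) < p_migratory
      # spring arrival day 90-160 at the band's reference latitude,
      # a few days per degree later northwards; autumn departure well after
      s_lat <- runif(1, 0.5, 3)
      a_lat <- runif(1, -3, -0.5)
      migration <- migration_params(
        s_mean = runif(1, 90, 160) - s_lat * 60, s_lat = s_lat,
        s_sd = runif(1, 3, 10),
        a_mean = runif(1, 240, 290) - a_lat * 60, a_lat = a_lat,
        a_sd = runif(1, 5, 15),
        is_migratory = migratory)
      pam_coefs <- c(intercept = runif(1, -3, -1.5),
                     d_sin1 = runif(1, -0.8, 0.8), d_cos1 = runif(1, -0.8, 0.8),
                     d_sin2 = runif(1, -0.4, 0.4), d_cos2 = runif(1, -0.4, 0.4),
                     t_sin1 = runif(1, -1.2, 1.2), t_cos1 = runif(1, -1.2, 1.2),
                     t_sin2 = runif(1, -0.6, 0.6), t_cos2 = runif(1, -0.6, 0.6))
      # positive alpha: app recordings are typically initiated because a
      # bird is vocalising, so per-recording detection runs well above a
      # random acoustic-monitoring minute
      translation <- translation_params(
        alpha = runif(1, 0.5, 1.5), beta_direct = runif(1, 0.3, 0.8),
        beta_interval = runif(1, 0.1, 0.5), beta_point = runif(1, 0.2, 0.6),
        gamma = runif(1, 0.6, 1))
      z <- smooth_field(n_rows, n_cols, field_knots) + runif(1, -1.5, 0.5)
      s_true <- raster_layer(pmin(pmax(pnorm(z), 0.02), 0.98), fine)
      list(migration = migration, pam_coefs = pam_coefs,
           translation = translation, s_true = s_true)
    })
    names(species) <- sprintf("sp%02d", seq_len(n_species))
    structure(list(fine_grid = fine, coarse_grid = coarsen_grid(fine, 10L),
                   coarse_factor = 10L, lat_range = lat_range,
                   species = species, seed = seed),
              class = "synthetic_world")
  })
}

#' @export
print.synthetic_world <- function(x, ...) {
  cat(sprintf("<synthetic_world> %d species on a %d x %d fine grid (seed %d)\n",
              length(x$species), x$fine_grid$n_rows, x$fine_grid$n_cols,
              x$seed))
  invisible(x)
}

#' Derive perturbed prior models from a synthetic world
#'
#' Creates the prior-versus-truth gap the updaters must learn away. The
#' prior spatial mean is the truth shifted on the probit scale by a
#' smooth noise field (`spatial_shift_sd = 0` reproduces the truth
#' exactly); the prior sd layer is a stated constant; the prior migration
#' means are shifted by independent normal draws.
#'
#' @param world A [make_world()] result.
#' @param spatial_shift_sd Probit-scale sd of the smooth spatial shift.
#' @param migration_shift_days Sd (days) of the shift applied to the
#'   spring and autumn mean-day parameters.
#' @param prior_sd_value Constant prior sd layer, default 0.15.
#' @param field_knots Lattice size of the smooth shift field (see
#'   [make_world()]).
#' @param seed Integer seed.
#' @return A named list per species: `migration` (prior
#'   [migration_params()]), `prior_mean_fine`, `prior_sd_fine`
#'   (fine `raster_layer`s), and the block-averaged `prior_mean_coarse`,
#'   `prior_sd_coarse` used by the spatial updater.
#' @export
perturb_prior <- function(world, spatial_shift_sd = 0.5,
                          migration_shift_days = 7,
                          prior_sd_value = 0.15, field_knots = 4L,
                          seed = 2L) {
  stopifnot(inherits(world, "synthetic_world"),
            spatial_shift_sd >= 0, migration_shift_days >= 0)
  g <- world$fine_grid
  withr::with_seed(seed, {
    out <- lapply(world$species, function(sp) {
      shift <- if (spatial_shift_sd > 0) {
        smooth_field(g$n_rows, g$n_cols, field_knots) * spatial_shift_sd
      } else matrix(0, g$n_rows, g$n_cols)
      prior_mean <- pnorm(qnorm(sp$s_true$values) + shift)
      prior_mean <- pmin(pmax(prior_mean, 1e-4), 1 - 1e-4)
      mprior <- sp$migration
      if (mprior$is_migratory && migration_shift_days > 0) {
        mprior <- migration_params(
          mprior$s_mean + rnorm(1, 0, migration_shift_days), mprior$s_lat,
          mprior$s_sd,
          mprior$a_mean + rnorm(1, 0, migration_shift_days), mprior$a_lat,
          mprior$a_sd, is_migratory = TRUE)
      }
      fine_mean <- raster_layer(prior_mean, g)
      fine_sd <- raster_layer(matrix(prior_sd_value, g$n_rows, g$n_cols), g)
      coarse <- downsample_prior(fine_mean,
                                 raster_layer(fine_sd$values^2, g),
                                 world$coarse_factor)
      list(migration = mprior,
           prior_mean_fine = fine_mean, prior_sd_fine = fine_sd,
           prior_mean_coarse = coarse$mean,
           prior_sd_coarse = raster_layer(sqrt(coarse$var$values),
                                          coarse$var$grid))
    })
    names(out) <- names(world$species)
    out
  })
}

#' Simulate a passive acoustic monitoring stream
#'
#' Fixed stations produce 1-minute segments at the requested minutes of
#' day; detections are Bernoulli draws from the product of the true
#' migration, true occurrence and true per-minute vocal detection
#' probabilities.
#'
#' @param world A [make_world()] result.
#' @param stations Tibble with 0-based fine-grid `row`, `col` (one row
#'   per station).
#' @param days Integer vector of days of year.
#' @param minutes_of_day Sampled minutes, default every 30 minutes.
#' @param year Calendar year stamped on the records.
#' @param seed Integer seed (independent of the app-stream seed).
#' @return Tibble `site_id, year, day_of_year, minute_of_day` plus one
#'   0/1 column per species.
#' @export
simulate_pam <- function(world, stations, days,
                         minutes_of_day = seq(0, 1430, by = 30),
                         year = 2023L, seed = 3L) {
  stopifnot(inherits(world, "synthetic_world"))
  g <- world$fine_grid
  if (any(stations$row < 0 | stations$row >= g$n_rows |
          stations$col < 0 | stations$col >= g$n_cols)) {
    rlang::abort("Stations outside the grid.")
  }
  base <- tidyr::expand_grid(
    site_id = sprintf("st%02d", seq_len(nrow(stations))),
    day_of_year = as.integer(days),
    minute_of_day = as.integer(minutes_of_day)
  ) |>
    dplyr::left_join(
      dplyr::mutate(stations, site_id = sprintf("st%02d", dplyr::row_number())),
      by = "site_id") |>
    dplyr::mutate(year = as.integer(year),
                  latitude_deg = row_latitude(.data$row, g$n_rows,
                                              world$lat_range))
  dayf <- day_fraction(base$day_of_year)
  timef <- minute_fraction(base$minute_of_day)
  withr::with_seed(seed, {
    for (sp in names(world$species)) {
      w <- world$species[[sp]]
      p <- migration_probability(w$migration, base$latitude_deg,
                                 base$day_of_year) *
        raster_value_at(w$s_true, base$row, base$col) *
        predict_d_pam(w$pam_coefs, dayf, timef)
      base[[sp]] <- rbinom(nrow(base), 1, p)
    }
  })
  dplyr::select(base, "site_id", "year", "day_of_year", "minute_of_day",
                "row", "col", dplyr::all_of(names(world$species)))
}

#' Define a synthetic observer population
#'
#' @param world A [make_world()] result.
#' @param n_users Number of app users, default 200.
#' @param activity_rate Probability a user is active on a given day.
#' @param trigger_bias Non-negative direct-recording trigger bias `b`:
#'   initiation probability at minute `t` is proportional to
#'   `1 + b * expected vocal activity summed over species`; `b = 0`
#'   gives uniform initiation times.
#' @param direct_rate Mean direct recordings per active user-day.
#' @param interval_prob,point_prob Per active user-day probabilities of
#'   starting an interval session / a point count.
#' @param interval_segments 1-minute segments per interval session
#'   (10 minutes apart).
#' @param n_stations Number of fixed point-count stations.
#' @param seed Seed for homes and stations.
#' @return An object of class `observer_population`.
#' @export
observer_population <- function(world, n_users = 200L, activity_rate = 0.3,
                                trigger_bias = 1, direct_rate = 1.2,
                                interval_prob = 0.08, point_prob = 0.05,
                                interval_segments = 6L, n_stations = 20L,
                                seed = 4L) {
  stopifnot(inherits(world, "synthetic_world"), trigger_bias >= 0)
  g <- world$fine_grid
  withr::with_seed(seed, {
    homes <- tibble::tibble(
      user_id = sprintf("u%03d", seq_len(n_users)),
      row = sample.int(g$n_rows, n_users, replace = TRUE) - 1L,
      col = sample.int(g$n_cols, n_users, replace = TRUE) - 1L)
    stations <- tibble::tibble(
      row = sample.int(g$n_rows, n_stations, replace = TRUE) - 1L,
      col = sample.int(g$n_cols, n_stations, replace = TRUE) - 1L)
  })
  # nearest station per user (ties to the first)
  homes$station <- purrr::map_int(seq_len(nrow(homes)), function(i) {
    which.min((stations$row - homes$row[i])^2 + (stations$col - homes$col[i])^2)
  })
  structure(list(homes = homes, stations = stations,
                 activity_rate = activity_rate, trigger_bias = trigger_bias,
                 direct_rate = direct_rate, interval_prob = interval_prob,
                 point_prob = point_prob,
                 interval_segments = as.integer(interval_segments)),
            class = "observer_population")
}

#' Simulate an app recording stream
#'
#' Users emit recordings at their home cells: short direct recordings
#' (log-normal duration, median about half a minute) whose initiation
#' times are biased toward minutes of high expected vocal activity;
#' interval sessions of 1-minute segments every 10 minutes; and 5-minute
#' point counts at the user's nearest fixed station. Detections are
#' Bernoulli draws from `m * s_true * d_MK`, with `d_MK` derived from
#' the true translation parameters.
#'
#' @param world A [make_world()] result.
#' @param observers An [observer_population()].
#' @param days Integer vector of days of year to simulate.
#' @param year Calendar year stamped on the records.
#' @param active_window Minutes of day within which recordings start.
#' @param seed Integer seed.
#' @return A validated recording tibble (see [validate_recordings()]).
#' @export
simulate_mk_stream <- function(world, observers, days, year = 2024L,
                               active_window = c(240L, 1200L), seed = 5L) {
  stopifnot(inherits(world, "synthetic_world"),
            inherits(observers, "observer_population"))
  g <- world$fine_grid
  homes <- observers$homes
  n_users <- nrow(homes)
  lat_home <- row_latitude(homes$row, g$n_rows, world$lat_range)
  sp_ids <- names(world$species)
  tgrid <- seq(active_window[1], active_window[2] - 15L, by = 15L)
  s_home <- sapply(sp_ids, function(sp)
    raster_value_at(world$species[[sp]]$s_true, homes$row, homes$col))

  withr::with_seed(seed, {
    recs <- vector("list", length(days))
    for (di in seq_along(days)) {
      day <- days[di]
      dayf <- day_fraction(day)
      # per-species vocal activity profile over the minute grid
      dpam <- sapply(sp_ids, function(sp)
        predict_d_pam(world$species[[sp]]$pam_coefs, dayf,
                      minute_fraction(tgrid)))           # |tgrid| x n_sp
      m_day <- sapply(sp_ids, function(sp)
        migration_probability(world$species[[sp]]$migration, lat_home, day))
      active <- which(runif(n_users) < observers$activity_rate)
      if (length(active) == 0L) next
      # direct recordings: trigger-biased initiation minutes
      n_dir <- rpois(length(active), observers$direct_rate)
      du <- rep(active, n_dir)
      dir_rows <- NULL
      if (length(du)) {
        W <- 1 + observers$trigger_bias *
          dpam %*% t(m_day[active, , drop = FALSE] *
                       s_home[active, , drop = FALSE])   # |tgrid| x n_active
        C <- apply(sweep(W, 2, colSums(W), "/"), 2, cumsum)
        pr <- runif(length(du))
        gi <- colSums(C[, match(du, active), drop = FALSE] <
                        rep(pr, each = nrow(C))) + 1L
        dir_rows <- tibble::tibble(
          minute_of_day = as.integer(tgrid[gi] +
                                       sample.int(15L, length(du), TRUE) - 1L),
          rec_type = "direct",
          duration_min = pmax(rlnorm(length(du), log(0.55), 0.5), 0.1),
          row = homes$row[du], col = homes$col[du])
      }
      # interval sessions: 1-min segments every 10 min
      iu <- active[runif(length(active)) < observers$interval_prob]
      int_rows <- NULL
      if (length(iu)) {
        starts <- sample(seq(active_window[1], 900L), length(iu), TRUE)
        nseg <- observers$interval_segments
        int_rows <- tibble::tibble(
          minute_of_day = as.integer(rep(starts, each = nseg) +
                                       10L * (seq_len(nseg) - 1L)),
          rec_type = "interval", duration_min = 1,
          row = rep(homes$row[iu], each = nseg),
          col = rep(homes$col[iu], each = nseg))
      }
      # point counts at the user's nearest fixed station
      pu <- active[runif(length(active)) < observers$point_prob]
      pt_rows <- NULL
      if (length(pu)) {
        st <- homes$station[pu]
        pt_rows <- tibble::tibble(
          minute_of_day = as.integer(sample(seq(300L, 900L), length(pu), TRUE)),
          rec_type = "point", duration_min = 5,
          row = observers$stations$row[st], col = observers$stations$col[st])
      }
      day_rows <- dplyr::bind_rows(dir_rows, int_rows, pt_rows)
      if (nrow(day_rows)) {
        day_rows$day_of_year <- as.integer(day)
        recs[[di]] <- day_rows
      }
    }
    out <- dplyr::bind_rows(recs)
    out <- out |>
      dplyr::mutate(
        recording_id = sprintf("r%06d", dplyr::row_number()),
        year = as.integer(year),
        latitude_deg = row_latitude(.data$row, g$n_rows, world$lat_range),
        log_duration = log(.data$duration_min))
    dayf <- day_fraction(out$day_of_year)
    timef <- minute_fraction(out$minute_of_day)
    for (sp in sp_ids) {
      w <- world$species[[sp]]
      p <- migration_probability(w$migration, out$latitude_deg,
                                 out$day_of_year) *
        raster_value_at(w$s_true, out$row, out$col) *
        d_mk(w$translation, out$rec_type, out$log_duration,
             predict_d_pam(w$pam_coefs, dayf, timef))
      out[[sp]] <- rbinom(nrow(out), 1, p)
    }
    out <- dplyr::select(out, "recording_id", "year", "day_of_year",
                         "minute_of_day", "row", "col", "latitude_deg",
                         "rec_type", "duration_min", "log_duration",
                         dplyr::all_of(sp_ids))
    validate_recordings(out)
    out
  })
}
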