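#' Per-recording detection probability
#'
#' The model's headline quantity: the probability a species is observed
#' in a recording is the product of the migration, spatial and detection
#' components.
#'
#' @param m,s,d Component probabilities in `[0, 1]` (vectorised).
#' @return `m * s * d`.
#' @export
predict_recording <- function(m, s, d) {
  if (any(m < 0 | m > 1 | s < 0 | s > 1 | d < 0 | d > 1, na.rm = TRUE)) {
    rlang::abort("Component probabilities must lie in [0, 1].")
  }
  m * s * d
}

#' Area under the ROC curve
#'
#' Mann-Whitney formulation with ties counted half: the probability that
#' a randomly chosen positive outranks a randomly chosen negative.
#' Invariant under strictly increasing transforms of the scores.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 outcome labels.
#' @return AUC in `[0, 1]`, or `NA` when only one class is present.
#' @export
auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Relative AUC gain over a chance baseline
#'
#' Expresses an AUC improvement as a percentage of the prior model's
#' excess over chance: `100 * (auc_posterior - auc_prior) /
#' (auc_prior - baseline)`, rounded to the nearest integer percent.
#'
#' @param auc_prior,auc_posterior AUC values.
#' @param baseline Chance level, default 0.5.
#' @return Integer percent, or `NA` when `auc_prior <= baseline`.
#' @export
relative_auc_gain <- function(auc_prior, auc_posterior, baseline = 0.5) {
  ifelse(auc_prior > baseline,
         round(100 * (auc_posterior - auc_prior) / (auc_prior - baseline)),
         NA_real_)
}

#' Bundle the model components the updaters and evaluator need
#'
#' @param species Named list, one entry per species id, each a list with
#'   `migration` (prior [migration_params()]), `pam_coefs` (length-9
#'   periodic logistic coefficients), `translation`
#'   (a [translation_params()], typically pre-fitted on a burn-in
#'   period), `prior_mean` and `prior_sd` (coarse `raster_layer`s of the
#'   prior occurrence surface).
#' @param fine_grid `grid_spec` of the recording stream's cell indices.
#' @param coarse_factor Fine-to-coarse nesting factor, default 10.
#' @return An object of class `twin_components`.
#' @export
twin_components <- function(species, fine_grid, coarse_factor = 10L) {
  stopifnot(is.list(species), length(species) >= 1L,
            !is.null(names(species)), inherits(fine_grid, "grid_spec"))
  structure(list(species = species, fine_grid = fine_grid,
                 coarse_factor = as.integer(coarse_factor)),
            class = "twin_components")
}

#' Walk-forward evaluation schedule and thresholds
#'
#' @param start_day,end_day First and last day of year of the evaluation
#'   season.
#' @param forecast_window_days Length of each test period; fitting uses
#'   data up to `T` and predictions cover `(T, T + window]`. Default 1
#'   (next-day); 7 mirrors a weekly realtime variant.
#' @param min_detections Species with fewer pooled test-period detections
#'   are excluded from the AUC table (scaled-down default for synthetic
#'   runs).
#' @param spatial A [spatial_update_config()].
#' @param migration A [migration_update_config()].
#' @param migration_maxit Iteration cap for the per-period migration fit.
#' @return An object of class `walk_forward_config`.
#' @export
walk_forward_config <- function(start_day, end_day, forecast_window_days = 1L,
                                min_detections = 25L,
                                spatial = spatial_update_config(),
                                migration = migration_update_config(),
                                migration_maxit = 300L) {
  stopifnot(forecast_window_days >= 1L, start_day <= end_day)
  structure(list(start_day = as.integer(start_day),
                 end_day = as.integer(end_day),
                 forecast_window_days = as.integer(forecast_window_days),
                 min_detections = as.integer(min_detections),
                 spatial = spatial, migration = migration,
                 migration_maxit = as.integer(migration_maxit)),
            class = "walk_forward_config")
}

# Per-species fixed quantities reused across test periods.
precompute_species <- function(records, comp, sp) {
  cs <- comp$species[[sp]]
  dayf <- day_fraction(records$day_of_year)
  timef <- minute_fraction(records$minute_of_day)
  d_pam <- predict_d_pam(cs$pam_coefs, dayf, timef)
  d <- d_mk(cs$translation, records$rec_type, records$log_duration, d_pam)
  cc <- coarse_cell_of(records$row, records$col, comp$coarse_factor)
  list(
    y = records[[sp]],
    d = d,
    m_prior = migration_probability(cs$migration, records$latitude_deg,
                                    records$day_of_year),
    s_prior = raster_value_at(cs$prior_mean, cc$row, cc$col),
    crow = cc$row, ccol = cc$col
  )
}

#' Walk-forward next-period predictive evaluation
#'
#' For each fitting day `T` of the schedule, the year-specific migration
#' parameters and the local-likelihood spatial posterior are refitted
#' from scratch on all records with `day_of_year <= T`, and both the
#' prior and the posterior model score the records falling in
#' `(T, T + window]`. Predictions are pooled across all test periods
#' before one AUC per species is computed (not averaged per-period).
#' The detection translation inside `components` is fixed throughout and
#' should have been fitted on a preceding burn-in period.
#'
#' @param records Validated recording tibble for one evaluation year.
#' @param components A [twin_components()].
#' @param config A [walk_forward_config()].
#' @return A tibble of class `twin_eval` with `species_id, n_detections,
#'   auc_prior, auc_posterior, delta`, and attributes `predictions`
#'   (the pooled per-recording prediction table) and `final_posterior`
#'   (per-species posterior mean rasters at the last fitting day).
#' @export
walk_forward <- function(records, components, config) {
  stopifnot(inherits(components, "twin_components"),
            inherits(config, "walk_forward_config"))
  validate_recordings(records)
  if (length(unique(records$year)) > 1L) {
    rlang::abort("Walk-forward evaluation expects a single-year stream.")
  }
  sp_ids <- names(components$species)
  pre <- lapply(sp_ids, function(sp) precompute_species(records, components, sp))
  names(pre) <- sp_ids
  day <- records$day_of_year

  schedule <- seq(config$start_day - 1L, config$end_day - 1L,
                  by = config$forecast_window_days)
  acc <- vector("list", length(schedule) * length(sp_ids))
  k <- 0L
  final_posterior <- list()

  for (T in schedule) {
    train_idx <- which(day <= T)
    test_idx <- which(day > T & day <= min(T + config$forecast_window_days,
                                           config$end_day))
    if (length(test_idx) == 0L) {
      rlang::inform(sprintf("Empty test period after day %d; skipped.", T))
      next
    }
    # leakage guard: no future record may enter a fit
    stopifnot(all(day[train_idx] <= T))
    train <- records[train_idx, ]

    for (sp in sp_ids) {
      cs <- components$species[[sp]]
      ps <- pre[[sp]]

      # migration update (spatial and detection fixed)
      theta_tilde <- fit_posterior_migration(
        train, sp, cs$migration, config$migration,
        sd_fixed = ps$s_prior[train_idx] * ps$d[train_idx],
        maxit = config$migration_maxit, polish = FALSE)
      m_post_train <- migration_probability(
        theta_tilde, records$latitude_deg[train_idx], day[train_idx])

      # spatial update with the updated migration component
      rec_sp <- tibble::tibble(row = ps$crow[train_idx],
                               col = ps$ccol[train_idx],
                               y = ps$y[train_idx],
                               m = m_post_train,
                               d = ps$d[train_idx])
      post <- update_raster(rec_sp, cs$prior_mean, cs$prior_sd, config$spatial)

      m_post_test <- migration_probability(
        theta_tilde, records$latitude_deg[test_idx], day[test_idx])
      s_post_test <- raster_value_at(post$mean, ps$crow[test_idx],
                                     ps$ccol[test_idx])
      k <- k + 1L
      acc[[k]] <- tibble::tibble(
        species_id = sp,
        recording_id = records$recording_id[test_idx],
        y = ps$y[test_idx],
        p_prior = predict_recording(ps$m_prior[test_idx],
                                    ps$s_prior[test_idx], ps$d[test_idx]),
        p_posterior = predict_recording(m_post_test, s_post_test,
                                        ps$d[test_idx])
      )
      if (T == schedule[length(schedule)]) final_posterior[[sp]] <- post$mean
    }
  }

  predictions <- dplyr::bind_rows(acc[seq_len(k)])
  out <- predictions |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(
      n_detections = sum(.data$y),
      auc_prior = auc(.data$p_prior, .data$y),
      auc_posterior = auc(.data$p_posterior, .data$y),
      .groups = "drop"
    ) |>
    dplyr::mutate(delta = .data$auc_posterior - .data$auc_prior) |>
    dplyr::filter(.data$n_detections >= config$min_detections)
  attr(out, "predictions") <- predictions
  attr(out, "final_posterior") <- final_posterior
  class(out) <- c("twin_eval", class(out))
  out
}

#' Prior-versus-posterior AUC scatter for a walk-forward result
#'
#' @param object A `twin_eval` tibble from [walk_forward()].
#' @param ... Unused.
#' @return A ggplot: each point one species; points above the diagonal
#'   are species the updated model predicts better.
#' @export
autoplot.twin_eval <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$auc_prior, .data$auc_posterior)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_detections), alpha = 0.7) +
    ggplot2::coord_equal(xlim = c(0.4, 1), ylim = c(0.4, 1)) +
    ggplot2::labs(x = "Prior AUC", y = "Posterior AUC", size = "Detections")
}

#' Write a walk-forward result with its JSON sidecar
#'
#' @param result A `twin_eval` tibble.
#' @param path Output CSV path; a `.json` sidecar with run metadata is
#'   written alongside.
#' @param meta Named list of run metadata (seeds, config echo, ...).
#' @return `path`, invisibly.
#' @export
write_eval_results <- function(result, path, meta = list()) {
  readr::write_csv(tibble::as_tibble(result), path)
  side <- sub("\\.csv$", ".json", path)
  meta$written_utc <- format(Sys.time(), tz = "UTC")
  meta$n_species <- nrow(result)
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
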