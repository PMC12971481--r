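#' Periodic seasonal and diurnal basis features
#'
#' The vocal detection model is a logistic regression on first- and
#' second-harmonic sine/cosine terms of the day-of-year fraction and the
#' time-of-day fraction, both scaled to `[0, 1)`.
#'
#' @param day_fraction,time_fraction Numeric vectors in `[0, 1)` (recycled
#'   to a common length).
#' @return A numeric matrix with columns `d_sin1, d_cos1, d_sin2, d_cos2,
#'   t_sin1, t_cos1, t_sin2, t_cos2`.
#' @export
periodic_features <- function(day_fraction, time_fraction) {
  n <- max(length(day_fraction), length(time_fraction))
  d <- rep_len(day_fraction, n); t <- rep_len(time_fraction, n)
  if (any(!is.finite(d)) || any(!is.finite(t))) {
    rlang::abort("Fractions must be finite.")
  }
  out <- cbind(
    d_sin1 = sin(2 * pi * d), d_cos1 = cos(2 * pi * d),
    d_sin2 = sin(4 * pi * d), d_cos2 = cos(4 * pi * d),
    t_sin1 = sin(2 * pi * t), t_cos1 = cos(2 * pi * t),
    t_sin2 = sin(4 * pi * t), t_cos2 = cos(4 * pi * t)
  )
  out
}

#' Seasonal presence window of a detection series
#'
#' Detection data are filtered, per site and year, to the period between
#' the accumulation of 5% and 95% of that year's detections, so that the
#' detection model is conditioned on the species actually being present.
#' The k-th chronological detection with `k = ceiling(q * n)` defines each
#' endpoint (integer-rank rule, no interpolation).
#'
#' @param detection_days Integer vector of day-of-year values, one per
#'   detection (any order; duplicates allowed).
#' @return Named numeric vector `c(start_day, end_day)`.
#' @export
presence_window <- function(detection_days) {
  if (length(detection_days) == 0L) {
    rlang::abort("`detection_days` must be non-empty.")
  }
  d <- sort(detection_days)
  n <- length(d)
  c(start_day = d[ceiling(0.05 * n)], end_day = d[ceiling(0.95 * n)])
}

#' Restrict acoustic-monitoring records to per-site presence windows
#'
#' @param records Tibble with `site_id`, `year`, `day_of_year` and a 0/1
#'   column per species.
#' @param species Name of the species column to window on.
#' @return The rows of `records` whose day falls inside the presence
#'   window of their site-year (site-years with no detections dropped).
#' @export
filter_presence_window <- function(records, species) {
  windows <- records |>
    dplyr::filter(.data[[species]] == 1) |>
    dplyr::group_by(.data$site_id, .data$year) |>
    dplyr::summarise(
      start_day = presence_window(.data$day_of_year)[["start_day"]],
      end_day = presence_window(.data$day_of_year)[["end_day"]],
      .groups = "drop"
    )
  records |>
    dplyr::inner_join(windows, by = c("site_id", "year")) |>
    dplyr::filter(.data$day_of_year >= .data$start_day,
                  .data$day_of_year <= .data$end_day) |>
    dplyr::select(-"start_day", -"end_day")
}

#' Fit the prior vocal detection model from acoustic-monitoring data
#'
#' Maximum-likelihood logistic regression (via [stats::glm()], binomial
#' family) of per-minute detection on the eight periodic features of day
#' and time, pooled across sites. Callers are expected to have applied
#' [filter_presence_window()] so that non-detections reflect silence of a
#' present bird rather than absence.
#'
#' @param records Tibble with `day_of_year`, `minute_of_day` and a 0/1
#'   detection column named by `species`.
#' @param species Species column name.
#' @return A `pam_detection_fit` with elements `species_id`,
#'   `coefficients` (length 9, intercept first) and the underlying `glm`.
#' @export
fit_prior_detection <- function(records, species) {
  y <- records[[species]]
  if (is.null(y)) rlang::abort(sprintf("No column `%s`.", species))
  if (length(unique(y)) < 2L) {
    rlang::abort("Single-class response: detection model cannot be fitted.")
  }
  X <- periodic_features(day_fraction(records$day_of_year),
                         minute_fraction(records$minute_of_day))
  dat <- data.frame(y = y, X)
  fit <- withCallingHandlers(
    glm(y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        rlang::abort("Complete separation: detection model cannot be fitted.")
      }
      invokeRestart("muffleWarning")
    }
  )
  if (!fit$converged || any(!is.finite(coef(fit)))) {
    rlang::abort("Detection model fit did not converge.")
  }
  cf <- coef(fit)
  names(cf) <- c("intercept", colnames(X))
  structure(list(species_id = species, coefficients = cf, glm = fit),
            class = "pam_detection_fit")
}

#' @export
print.pam_detection_fit <- function(x, ...) {
  cat(sprintf("<pam_detection_fit> %s; intercept %.3f (n = %d)\n",
              x$species_id, x$coefficients[[1]], length(x$glm$y)))
  invisible(x)
}

#' @export
tidy.pam_detection_fit <- function(x, ...) {
  s <- summary(x$glm)$coefficients
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients),
                 std.error = unname(s[, "Std. Error"]),
                 statistic = unname(s[, "z value"]),
                 p.value = unname(s[, "Pr(>|z|)"]))
}

#' @export
glance.pam_detection_fit <- function(x, ...) {
  tibble::tibble(nobs = length(x$glm$y),
                 deviance = x$glm$deviance,
                 null.deviance = x$glm$null.deviance,
                 AIC = stats::AIC(x$glm))
}

#' Predict the per-minute acoustic detection probability
#'
#' Evaluates the periodic logistic model: `plogis(intercept + beta %*%
#' features)`. Periodic in both arguments with period 1.
#'
#' @param object A `pam_detection_fit`, or a length-9 numeric coefficient
#'   vector (intercept first, then the eight periodic terms).
#' @param day_fraction,time_fraction Fractions in `[0, 1)`; values outside
#'   are wrapped.
#' @return Detection probabilities in `(0, 1)`.
#' @export
predict_d_pam <- function(object, day_fraction, time_fraction) {
  cf <- if (inherits(object, "pam_detection_fit")) object$coefficients else object
  if (length(cf) != 9L || any(!is.finite(cf))) {
    rlang::abort("Need 9 finite coefficients (intercept + 8 periodic terms).")
  }
  X <- periodic_features(day_fraction %% 1, time_fraction %% 1)
  plogis(cf[1] + drop(X %*% cf[-1]))
}

#' Read / write a detection coefficient table
#'
#' CSV schema: `species_id, intercept, d_sin1, d_cos1, d_sin2, d_cos2,
#' t_sin1, t_cos1, t_sin2, t_cos2`.
#'
#' @param path File path.
#' @return `read_detection_coefficients()` returns a tibble in the schema
#'   above.
#' @export
read_detection_coefficients <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(species_id = readr::col_character()))
}

#' @rdname read_detection_coefficients
#' @param coefs Tibble in the schema above.
#' @export
write_detection_coefficients <- function(coefs, path) {
  readr::write_csv(coefs, path)
  invisible(path)
}
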