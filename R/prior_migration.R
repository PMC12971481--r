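#' Construct migration phenology parameters
#'
#' The migration component models the probability that a species has
#' arrived from spring migration and not yet departed on autumn
#' migration, as a function of day-of-year and latitude. Spring arrival
#' day is normally distributed with mean `s_mean + s_lat * latitude` and
#' sd `s_sd`; autumn departure analogously with the `a_*` parameters.
#'
#' @param s_mean,s_lat,s_sd Spring arrival: day intercept, days-per-degree
#'   latitude slope, and spread (days, `>= 0.5`).
#' @param a_mean,a_lat,a_sd Autumn departure counterparts.
#' @param is_migratory If `FALSE` the species is resident and the
#'   migration probability is identically 1; the other fields are ignored.
#' @return An object of class `migration_params`.
#' @export
migration_params <- function(s_mean = 0, s_lat = 0, s_sd = 1,
                             a_mean = 0, a_lat = 0, a_sd = 1,
                             is_migratory = TRUE) {
  if (is_migratory && (s_sd <= 0 || a_sd <= 0)) {
    rlang::abort("Migration sd parameters must be positive.")
  }
  structure(list(s_mean = s_mean, s_lat = s_lat, s_sd = s_sd,
                 a_mean = a_mean, a_lat = a_lat, a_sd = a_sd,
                 is_migratory = isTRUE(is_migratory)),
            class = "migration_params")
}

#' @export
print.migration_params <- function(x, ...) {
  if (!x$is_migratory) cat("<migration_params> resident (m = 1)\n")
  else cat(sprintf(
    "<migration_params> spring %.1f + %.2f*lat (sd %.1f); autumn %.1f + %.2f*lat (sd %.1f)\n",
    x$s_mean, x$s_lat, x$s_sd, x$a_mean, x$a_lat, x$a_sd))
  invisible(x)
}

#' Migration presence probability
#'
#' `m(lat, day) = min{ Phi[(day - mu_S(lat)) / sd_S],
#' 1 - Phi[(day - mu_A(lat)) / sd_A] }` for migratory species, 1 for
#' residents. Non-decreasing in day through spring, non-increasing through
#' autumn, and bounded in `[0, 1]`.
#'
#' @param params A `migration_params`.
#' @param latitude_deg,day_of_year Numeric vectors (recycled).
#' @return Presence probabilities.
#' @export
migration_probability <- function(params, latitude_deg, day_of_year) {
  n <- max(length(latitude_deg), length(day_of_year))
  if (!params$is_migratory) return(rep(1, n))
  if (params$s_sd <= 0 || params$a_sd <= 0) {
    rlang::abort("Migration sd parameters must be positive.")
  }
  lat <- rep_len(latitude_deg, n); day <- rep_len(day_of_year, n)
  spring <- pnorm((day - (params$s_mean + params$s_lat * lat)) / params$s_sd)
  autumn <- 1 - pnorm((day - (params$a_mean + params$a_lat * lat)) / params$a_sd)
  pmin(spring, autumn)
}

#' First/last phenological quantiles per year and latitude zone
#'
#' For each year x latitude-zone group with at least `min_n` observations,
#' the "first" and "last" observation days are the 5% and 95%
#' chronological quantiles (integer-rank rule `k = ceiling(q * n)`).
#' Undersized groups are dropped with a message.
#'
#' @param observations Tibble with columns `year`, `zone_latitude_deg`,
#'   `day_of_year` (one row per occurrence record).
#' @param min_n Minimum group size, default 50.
#' @return Tibble `year, zone_latitude_deg, first_day, last_day,
#'   n_observations`.
#' @export
quantile_first_last <- function(observations, min_n = 50L) {
  grouped <- observations |>
    dplyr::group_by(.data$year, .data$zone_latitude_deg) |>
    dplyr::summarise(
      first_day = sort(.data$day_of_year)[ceiling(0.05 * dplyr::n())],
      last_day = sort(.data$day_of_year)[ceiling(0.95 * dplyr::n())],
      n_observations = dplyr::n(),
      .groups = "drop"
    )
  dropped <- sum(grouped$n_observations < min_n)
  if (dropped > 0) {
    rlang::inform(sprintf("Dropped %d year-zone group(s) with < %d observations.",
                          dropped, min_n))
  }
  dplyr::filter(grouped, .data$n_observations >= min_n)
}

#' Fit the prior migration model from phenology summaries
#'
#' Ordinary least squares of `first_day` (and `last_day`) on zone latitude
#' gives the spring (autumn) mean and latitude slope. The spread
#' parameters are one quarter of the 95% prediction-interval width of the
#' respective regression, evaluated at each distinct zone latitude and
#' averaged over zones, floored at 0.5 days so that noiseless fits do not
#' degenerate to step functions.
#'
#' @param summaries Tibble as returned by [quantile_first_last()]; at
#'   least two distinct latitude zones are required.
#' @return A `migration_fit` holding `params` (a [migration_params()]) and
#'   the two `lm` fits.
#' @export
fit_prior_migration <- function(summaries) {
  zones <- unique(summaries$zone_latitude_deg)
  if (length(zones) < 2L) {
    rlang::abort("At least two distinct latitude zones are required.")
  }
  fit_one <- function(response) {
    f <- stats::as.formula(paste(response, "~ zone_latitude_deg"))
    m <- lm(f, data = summaries)
    if (any(is.na(coef(m)))) rlang::abort("Rank-deficient design.")
    newd <- data.frame(zone_latitude_deg = zones)
    pi_ <- suppressWarnings(
      predict(m, newdata = newd, interval = "prediction", level = 0.95))
    sd_hat <- max(mean((pi_[, "upr"] - pi_[, "lwr"]) / 4), 0.5)
    list(mean = unname(coef(m)[1]), slope = unname(coef(m)[2]),
         sd = sd_hat, lm = m)
  }
  spring <- fit_one("first_day")
  autumn <- fit_one("last_day")
  structure(
    list(params = migration_params(spring$mean, spring$slope, spring$sd,
                                   autumn$mean, autumn$slope, autumn$sd,
                                   is_migratory = TRUE),
         lm_spring = spring$lm, lm_autumn = autumn$lm,
         n_zones = length(zones), nobs = nrow(summaries)),
    class = "migration_fit")
}

#' @export
print.migration_fit <- function(x, ...) {
  print(x$params); invisible(x)
}

#' @export
tidy.migration_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("s_mean", "s_lat", "s_sd", "a_mean", "a_lat", "a_sd"),
    estimate = c(p$s_mean, p$s_lat, p$s_sd, p$a_mean, p$a_lat, p$a_sd)
  )
}

#' @export
glance.migration_fit <- function(x, ...) {
  tibble::tibble(nobs = x$nobs, n_zones = x$n_zones,
                 r.squared.spring = summary(x$lm_spring)$r.squared,
                 r.squared.autumn = summary(x$lm_autumn)$r.squared)
}

#' Migration curve plot over a season
#'
#' @param params A `migration_params` (or `migration_fit`).
#' @param latitude_deg Latitudes at which to draw the curve.
#' @param days Day range, default the full year.
#' @return A ggplot.
#' @export
plot_migration_curve <- function(params, latitude_deg = 60, days = 1:365) {
  if (inherits(params, "migration_fit")) params <- params$params
  df <- tidyr::expand_grid(latitude_deg = latitude_deg, day = days) |>
    dplyr::mutate(m = migration_probability(params, .data$latitude_deg, .data$day))
  ggplot2::ggplot(df, ggplot2::aes(.data$day, .data$m,
                                   colour = factor(.data$latitude_deg))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Day of year", y = "Presence probability",
                  colour = "Latitude") +
    ggplot2::ylim(0, 1)
}

#' Read / write a migration parameter table
#'
#' CSV schema: `species_id, is_migratory, s_mean, s_lat, s_sd, a_mean,
#' a_lat, a_sd` (plus an optional `year` column for posterior tables).
#'
#' @param path File path.
#' @return A tibble in the schema above.
#' @export
read_migration_params <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(species_id = readr::col_character()))
}

#' @rdname read_migration_params
#' @param params Tibble in the schema above.
#' @export
write_migration_params <- function(params, path) {
  readr::write_csv(params, path)
  invisible(path)
}

# One row of a migration parameter table -> migration_params object.
params_from_row <- function(row) {
  migration_params(row$s_mean, row$s_lat, row$s_sd,
                   row$a_mean, row$a_lat, row$a_sd,
                   is_migratory = as.logical(row$is_migratory))
}

# migration_params -> one-row tibble.
params_to_row <- function(params, species_id = NA_character_) {
  tibble::tibble(species_id = species_id,
                 is_migratory = params$is_migratory,
                 s_mean = params$s_mean, s_lat = params$s_lat, s_sd = params$s_sd,
                 a_mean = params$a_mean, a_lat = params$a_lat, a_sd = params$a_sd)
}
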