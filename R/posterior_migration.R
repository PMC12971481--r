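#' Integration grid for the functional migration penalty
#'
#' The functional prior penalises the squared distance between the
#' posterior and prior migration curves, integrated over a latitude x day
#' domain approximated by a uniform grid. The default covers Finland
#' (latitudes 59.5-70 in 0.5-degree steps) over the 365-day year.
#'
#' @param latitudes_deg Ascending, uniformly spaced latitudes.
#' @param days Ascending, uniformly spaced days of year.
#' @return An object of class `penalty_grid`.
#' @export
penalty_grid <- function(latitudes_deg = seq(59.5, 70, by = 0.5),
                         days = 1:365) {
  if (length(latitudes_deg) == 0L || length(days) == 0L) {
    rlang::abort("Penalty grid axes must be non-empty.")
  }
  uniform <- function(x) length(x) < 3L || isTRUE(all.equal(diff(x), rep(diff(x)[1], length(x) - 1)))
  if (!uniform(latitudes_deg) || !uniform(days) ||
      is.unsorted(latitudes_deg) || is.unsorted(days)) {
    rlang::abort("Penalty grid axes must be ascending and uniformly spaced.")
  }
  structure(list(latitudes_deg = latitudes_deg, days = as.numeric(days)),
            class = "penalty_grid")
}

# Curve values of a migration_params on a penalty grid, as a vector.
curve_on_grid <- function(params, grid) {
  lat <- rep(grid$latitudes_deg, times = length(grid$days))
  day <- rep(grid$days, each = length(grid$latitudes_deg))
  migration_probability(params, lat, day)
}

#' Functional distance between two migration curves
#'
#' Riemann approximation of the integral of the squared difference
#' between the curves induced by two parameter sets, over the grid's
#' latitude x day domain (in degree-days): the grid mean of the squared
#' difference times the domain area. A degenerate axis (a single latitude
#' or day) contributes a unit factor, so the penalty reduces to the
#' integral over the remaining axis.
#'
#' @param theta_tilde,theta_prior `migration_params` objects.
#' @param grid A [penalty_grid()].
#' @return Non-negative scalar; 0 iff the curves agree on the grid.
#' @export
functional_penalty <- function(theta_tilde, theta_prior, grid) {
  stopifnot(inherits(grid, "penalty_grid"))
  sq <- (curve_on_grid(theta_tilde, grid) - curve_on_grid(theta_prior, grid))^2
  span <- function(x) if (length(x) > 1L) diff(range(x)) else 1
  mean(sq) * span(grid$latitudes_deg) * span(grid$days)
}

#' Configuration for the posterior migration update
#'
#' @param lambda_precision Penalty precision `lambda > 0`; the default
#'   0.01 applies light shrinkage of the year-specific curve toward the
#'   prior curve on the degree-day scale of [functional_penalty()].
#' @param grid A [penalty_grid()].
#' @return An object of class `migration_update_config`.
#' @export
migration_update_config <- function(lambda_precision = 0.01,
                                    grid = penalty_grid()) {
  stopifnot(lambda_precision > 0, inherits(grid, "penalty_grid"))
  structure(list(lambda_precision = lambda_precision, grid = grid),
            class = "migration_update_config")
}

#' Year-specific MAP update of the migration parameters
#'
#' Minimises the Bernoulli negative log likelihood of the current year's
#' detections, with success probability `m_theta(lat_i, day_i) * s_i *
#' d_i` (spatial and detection components fixed), plus
#' `lambda * functional_penalty(theta, theta_prior)`. The spread
#' parameters are optimised on the log scale to stay positive; the search
#' (Nelder-Mead, deterministic) starts at the prior so the fitted
#' objective can never exceed the prior's. Residents are returned
#' unchanged, as is the prior when no records are supplied.
#'
#' @param records Tibble with per-record `latitude_deg`, `day_of_year`,
#'   detection column named by `species`, all from one calendar year.
#' @param species Species column name.
#' @param theta_prior Prior `migration_params`.
#' @param config A [migration_update_config()].
#' @param sd_fixed Per-record fixed product `s_i * d_i` of the spatial and
#'   detection components.
#' @param maxit Optimiser iteration cap.
#' @param polish Restart the simplex once from its own solution (tighter
#'   optimum; the default). Disabled in the daily walk-forward loop where
#'   speed matters more than the last digits.
#' @return The posterior `migration_params` with attributes `objective`
#'   and `objective_prior`.
#' @export
fit_posterior_migration <- function(records, species, theta_prior, config,
                                    sd_fixed, maxit = 1500L, polish = TRUE) {
  stopifnot(inherits(theta_prior, "migration_params"),
            inherits(config, "migration_update_config"))
  if (!theta_prior$is_migratory || nrow(records) == 0L) return(theta_prior)
  if (length(unique(records$year)) > 1L) {
    rlang::abort("Records must come from a single calendar year.")
  }
  y <- records[[species]]
  sd_fixed <- rep_len(sd_fixed, length(y))
  # recordings share (latitude, day) heavily (users record repeatedly at
  # home); evaluating the curve on the unique pairs only saves most of
  # the normal-CDF work
  key <- paste(records$latitude_deg, records$day_of_year)
  uidx <- !duplicated(key)
  lat <- records$latitude_deg[uidx]
  day <- records$day_of_year[uidx]
  rec_of <- match(key, key[uidx])
  lambda <- config$lambda_precision
  prior_curve <- curve_on_grid(theta_prior, config$grid)
  grid_lat <- rep(config$grid$latitudes_deg, times = length(config$grid$days))
  grid_day <- rep(config$grid$days, each = length(config$grid$latitudes_deg))
  span <- function(x) if (length(x) > 1L) diff(range(x)) else 1
  area <- span(config$grid$latitudes_deg) * span(config$grid$days)

  unpack <- function(par) {
    # log-scale spreads keep positivity; the 0.5-day floor stops noiseless
    # or one-sided seasons collapsing the curve into a step function
    migration_params(par[1], par[2], max(exp(par[3]), 0.5),
                     par[4], par[5], max(exp(par[6]), 0.5),
                     is_migratory = TRUE)
  }
  objective <- function(par) {
    th <- unpack(par)
    m <- migration_probability(th, lat, day)[rec_of]
    p <- pmin(pmax(m * sd_fixed, 1e-12), 1 - 1e-12)
    nll <- -sum(y * log(p) + (1 - y) * log(1 - p))
    pen <- mean((migration_probability(th, grid_lat, grid_day) - prior_curve)^2) * area
    nll + lambda * pen
  }
  par0 <- c(theta_prior$s_mean, theta_prior$s_lat, log(theta_prior$s_sd),
            theta_prior$a_mean, theta_prior$a_lat, log(theta_prior$a_sd))
  opt <- optim(par0, objective, method = "Nelder-Mead",
               control = list(maxit = maxit, reltol = 1e-10))
  best <- opt
  if (polish) {
    opt2 <- optim(opt$par, objective, method = "Nelder-Mead",
                  control = list(maxit = maxit, reltol = 1e-12))
    if (opt2$value <= opt$value) best <- opt2
  }
  # the simplex starts at the prior, so the fit can only improve on it
  if (best$value > objective(par0)) best <- list(par = par0, value = objective(par0))
  out <- unpack(best$par)
  attr(out, "objective") <- best$value
  attr(out, "objective_prior") <- objective(par0)
  out
}
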