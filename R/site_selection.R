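#' Site-selection configuration
#'
#' Tuning constants of the sequential validation-site selection: the
#' utility targets prior-posterior disagreement, a Gaussian kernel in
#' probability space (`tau_scenario = 400`, i.e. sd 0.05) penalises
#' revisiting similar prior/posterior scenarios, `gamma < 1` keeps the
#' penalty from zeroing utilities exactly, and a migration indicator at
#' threshold 0.75 gates both the utility and the penalty.
#'
#' @param gamma Penalty ceiling in `(0, 1)`, default 0.95.
#' @param tau_scenario Scenario-kernel precision, default 400.
#' @param migration_threshold Arrival indicator threshold, default 0.75.
#' @param central_radius_km Radius around a volunteer's home for the
#'   first site, default 50.
#' @param satellite_radius_km Radius around the first site for the
#'   remaining sites, default 10.
#' @param min_separation_km Minimum distance from every previously
#'   selected site, default 1.
#' @param sites_per_volunteer Sites per volunteer-day, default 10.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(gamma = 0.95, tau_scenario = 400,
                             migration_threshold = 0.75,
                             central_radius_km = 50,
                             satellite_radius_km = 10,
                             min_separation_km = 1,
                             sites_per_volunteer = 10L) {
  stopifnot(gamma > 0, gamma < 1, tau_scenario > 0)
  structure(list(gamma = gamma, tau_scenario = tau_scenario,
                 migration_threshold = migration_threshold,
                 central_radius_km = central_radius_km,
                 satellite_radius_km = satellite_radius_km,
                 min_separation_km = min_separation_km,
                 sites_per_volunteer = as.integer(sites_per_volunteer)),
            class = "selection_config")
}

#' Prior-posterior disagreement term
#'
#' The absolute difference between a cell's prior and posterior
#' occurrence probabilities: direction-agnostic, so (0.3, 0.8),
#' (0.8, 0.3) and (0.1, 0.6) all score 0.5.
#'
#' @param prior_prob,posterior_prob Probabilities in `[0, 1]`
#'   (vectorised).
#' @return `abs(posterior_prob - prior_prob)`.
#' @export
disagreement_term <- function(prior_prob, posterior_prob) {
  if (any(prior_prob < 0 | prior_prob > 1 | posterior_prob < 0 |
          posterior_prob > 1)) {
    rlang::abort("Probabilities must lie in [0, 1].")
  }
  abs(posterior_prob - prior_prob)
}

#' Repeat-scenario penalty against one previously chosen site
#'
#' A Gaussian kernel in (prior, posterior) probability space:
#' `gamma * 1(migration_at_chosen >= threshold) *
#' exp(-(tau/2) * ((d_prior)^2 + (d_posterior)^2))`. Close scenarios are
#' penalised nearly fully (up to `gamma`); sites where the species had
#' not yet arrived when chosen do not penalise at all.
#'
#' @param cand_prior,cand_posterior Candidate cell probabilities.
#' @param chosen_prior,chosen_posterior Probabilities cached for the
#'   previously chosen site.
#' @param migration_at_chosen Migration probability at the chosen site on
#'   its selection day.
#' @param config A [selection_config()].
#' @return Values in `[0, gamma]` (vectorised over chosen sites).
#' @export
scenario_penalty <- function(cand_prior, cand_posterior, chosen_prior,
                             chosen_posterior, migration_at_chosen,
                             config = selection_config()) {
  ind <- as.numeric(migration_at_chosen >= config$migration_threshold)
  config$gamma * ind *
    exp(-(config$tau_scenario / 2) *
          ((cand_prior - chosen_prior)^2 +
             (cand_posterior - chosen_posterior)^2))
}

#' Per-species site utility
#'
#' `U_j = f_j(candidate) * prod over chosen sites of (1 - g_j)`; with an
#' empty history the utility is the disagreement term itself.
#'
#' @param cand_prior,cand_posterior Candidate probabilities for the
#'   species.
#' @param history Tibble of previously chosen sites for this species with
#'   columns `prior`, `posterior`, `migration` (may have zero rows).
#' @param config A [selection_config()].
#' @return Non-negative scalar `<= f_j <= 1`.
#' @export
species_utility <- function(cand_prior, cand_posterior, history,
                            config = selection_config()) {
  f <- disagreement_term(cand_prior, cand_posterior)
  if (is.null(history) || nrow(history) == 0L) return(f)
  g <- scenario_penalty(cand_prior, cand_posterior, history$prior,
                        history$posterior, history$migration, config)
  f * prod(1 - g)
}

#' Total migration-modulated utility of a candidate cell
#'
#' `U = sum_j 1(m_j(candidate, day) >= threshold) * U_j(candidate)`:
#' species that have not arrived at the candidate contribute nothing.
#'
#' @param candidate Tibble with one row per species: `species_id`,
#'   `prior`, `posterior`, `migration` (migration probability at the
#'   candidate cell on the selection day).
#' @param state A [selection_state()].
#' @param config A [selection_config()].
#' @return Non-negative scalar.
#' @export
total_utility <- function(candidate, state, config = selection_config()) {
  u <- purrr::map_dbl(seq_len(nrow(candidate)), function(i) {
    sp <- candidate$species_id[i]
    m_ind <- as.numeric(candidate$migration[i] >= config$migration_threshold)
    if (m_ind == 0) return(0)
    hist_sp <- dplyr::filter(state$history, .data$species_id == sp)
    m_ind * species_utility(candidate$prior[i], candidate$posterior[i],
                            hist_sp, config)
  })
  sum(u)
}

#' Initialise an empty site-selection state
#'
#' The state carries the chronologically ordered chosen sites and, per
#' chosen site and species, the cached prior/posterior/migration
#' probabilities the penalty needs.
#'
#' @return An object of class `selection_state`.
#' @export
selection_state <- function() {
  structure(
    list(
      chosen = tibble::tibble(row = integer(), col = integer(),
                              day = integer()),
      history = tibble::tibble(row = integer(), col = integer(),
                               day = integer(), species_id = character(),
                               prior = numeric(), posterior = numeric(),
                               migration = numeric())
    ),
    class = "selection_state")
}

record_choice <- function(state, row, col, day, species_values) {
  state$chosen <- dplyr::bind_rows(
    state$chosen, tibble::tibble(row = row, col = col, day = day))
  state$history <- dplyr::bind_rows(
    state$history,
    dplyr::mutate(species_values, row = row, col = col, day = day))
  state
}

#' Select one volunteer-day's validation sites
#'
#' Greedy sequential selection: the first site maximises the total
#' utility within `central_radius_km` of the volunteer's home; the
#' remaining sites maximise it within `satellite_radius_km` of the first
#' site. Every pick must lie at least `min_separation_km` from all
#' previously selected sites (including earlier days and same-day picks),
#' and the state is updated after each pick so later picks feel the
#' penalty of earlier ones. Ties break on (utility, row, col)
#' lexicographic order (lower indices win).
#'
#' @param home_row,home_col Volunteer home cell (0-based, coarse grid).
#' @param candidates Long tibble, one row per candidate cell x species:
#'   `row`, `col`, `species_id`, `prior`, `posterior`, `migration`.
#' @param state A [selection_state()] (carried across days).
#' @param grid Coarse `grid_spec` used for distances.
#' @param day Integer selection day.
#' @param config A [selection_config()].
#' @return List with `sites` (tibble `day, site_rank, row, col, utility`)
#'   and the updated `state`. Fewer than `sites_per_volunteer` rows are
#'   returned, with a warning, when the pool is exhausted.
#' @export
select_day_sites <- function(home_row, home_col, candidates, state, grid, day,
                             config = selection_config()) {
  stopifnot(inherits(state, "selection_state"), inherits(grid, "grid_spec"))
  cells <- dplyr::distinct(candidates, .data$row, .data$col)
  if (nrow(cells) == 0L) rlang::abort("Empty candidate pool.")
  cells$dist_home <- cell_distance_km(cells$row, cells$col,
                                      home_row, home_col, grid)

  pick <- function(pool, st) {
    if (nrow(pool) == 0L) return(NULL)
    util <- purrr::map_dbl(seq_len(nrow(pool)), function(i) {
      cand <- dplyr::filter(candidates, .data$row == pool$row[i],
                            .data$col == pool$col[i])
      total_utility(cand, st, config)
    })
    ord <- order(-util, pool$row, pool$col)
    i <- ord[1]
    list(row = pool$row[i], col = pool$col[i], utility = util[i])
  }
  separated <- function(pool, st) {
    if (nrow(st$chosen) == 0L) return(pool)
    keep <- purrr::map_lgl(seq_len(nrow(pool)), function(i) {
      all(cell_distance_km(pool$row[i], pool$col[i],
                           st$chosen$row, st$chosen$col, grid) >=
            config$min_separation_km)
    })
    pool[keep, ]
  }

  sites <- tibble::tibble(day = integer(), site_rank = integer(),
                          row = integer(), col = integer(),
                          utility = numeric())
  first_pool <- separated(
    dplyr::filter(cells, .data$dist_home <= config$central_radius_km), state)
  if (nrow(first_pool) == 0L) {
    rlang::warn("No admissible candidate for the central site.")
    return(list(sites = sites, state = state))
  }
  p <- pick(first_pool, state)
  sv <- dplyr::filter(candidates, .data$row == p$row, .data$col == p$col) |>
    dplyr::select("species_id", "prior", "posterior", "migration")
  state <- record_choice(state, p$row, p$col, day, sv)
  sites <- dplyr::bind_rows(sites, tibble::tibble(
    day = as.integer(day), site_rank = 1L, row = p$row, col = p$col,
    utility = p$utility))

  near_first <- dplyr::filter(
    cells, cell_distance_km(.data$row, .data$col, p$row, p$col, grid) <=
      config$satellite_radius_km)
  for (k in seq_len(config$sites_per_volunteer - 1L) + 1L) {
    pool <- separated(near_first, state)
    q <- pick(pool, state)
    if (is.null(q)) {
      rlang::warn(sprintf("Candidate pool exhausted after %d site(s).", k - 1L))
      break
    }
    sv <- dplyr::filter(candidates, .data$row == q$row, .data$col == q$col) |>
      dplyr::select("species_id", "prior", "posterior", "migration")
    state <- record_choice(state, q$row, q$col, day, sv)
    sites <- dplyr::bind_rows(sites, tibble::tibble(
      day = as.integer(day), site_rank = as.integer(k), row = q$row,
      col = q$col, utility = q$utility))
  }
  list(sites = sites, state = state)
}

#' Point-count layout around a site centre
#'
#' Five point-count locations: the centre and the four corners of an
#' axis-aligned 100 m x 100 m square centred at the site.
#'
#' @param easting_km,northing_km Site centre coordinates in km.
#' @return Tibble with `point_rank` (0 = centre, 1..4 = corners),
#'   `easting_km`, `northing_km`.
#' @export
point_count_layout <- function(easting_km, northing_km) {
  stopifnot(is.finite(easting_km), is.finite(northing_km))
  tibble::tibble(
    point_rank = 0:4,
    easting_km = easting_km + c(0, -0.05, 0.05, -0.05, 0.05),
    northing_km = northing_km + c(0, -0.05, -0.05, 0.05, 0.05)
  )
}
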