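#' Configuration of the local-likelihood spatial update
#'
#' @param tau_spatial Gaussian kernel precision per km^2. The default
#'   `1 / 2.5^2` corresponds to a kernel sd of 2.5 km, letting cells
#'   within roughly 7.5 km influence a focal cell.
#' @param truncation_radius_km Hard kernel cutoff; weights beyond are
#'   exactly zero. Default 7.5 km (three kernel sd). Ignored when
#'   `tau_spatial = 0`, where the kernel is identically 1 and the local
#'   likelihood reduces to the ordinary pooled likelihood.
#' @param coarse_cell_km Edge length of the coarse update grid.
#' @return An object of class `spatial_update_config`.
#' @export
spatial_update_config <- function(tau_spatial = 1 / 2.5^2,
                                  truncation_radius_km = 7.5,
                                  coarse_cell_km = 1.0) {
  stopifnot(tau_spatial >= 0, truncation_radius_km > 0, coarse_cell_km > 0)
  structure(list(tau_spatial = tau_spatial,
                 truncation_radius_km = truncation_radius_km,
                 coarse_cell_km = coarse_cell_km),
            class = "spatial_update_config")
}

#' Gaussian kernel weight of a neighbouring cell
#'
#' `exp(-tau * d^2 / 2)` with hard truncation to zero beyond
#' `truncation_radius_km`; identically 1 when `tau = 0`.
#'
#' @param distance_km Non-negative distances.
#' @param tau Kernel precision (per km^2).
#' @param truncation_radius_km Cutoff radius.
#' @return Weights in `[0, 1]`.
#' @export
kernel_weight <- function(distance_km, tau, truncation_radius_km = 7.5) {
  stopifnot(all(distance_km >= 0), tau >= 0)
  if (tau == 0) return(rep(1, length(distance_km)))
  ifelse(distance_km <= truncation_radius_km,
         exp(-tau * distance_km^2 / 2), 0)
}

#' Kernel-weighted local log likelihood of a spatial probability
#'
#' For a focal coarse cell, every record's Bernoulli log-likelihood term
#' (success probability `p_i = m_i * s * d_i`) is weighted by the
#' Gaussian kernel distance between the record's cell and the focal cell.
#'
#' @param s Candidate occurrence probability in `(0, 1)`.
#' @param focal_row,focal_col 0-based focal cell on the coarse grid.
#' @param records Tibble with 0-based coarse `row`, `col`, 0/1 `y`, and
#'   fixed per-record components `m` and `d`.
#' @param grid Coarse `grid_spec`.
#' @param config A [spatial_update_config()].
#' @return Scalar weighted log likelihood; probabilities hitting 0/1 are
#'   clamped at 1e-12 with a warning.
#' @export
local_log_likelihood <- function(s, focal_row, focal_col, records, grid,
                                 config = spatial_update_config()) {
  stopifnot(s > 0, s < 1)
  if (nrow(records) == 0L) return(0)
  d_km <- cell_distance_km(records$row, records$col, focal_row, focal_col, grid)
  w <- kernel_weight(d_km, config$tau_spatial, config$truncation_radius_km)
  p <- records$m * s * records$d
  if (any(p <= 1e-12 & records$y == 1)) {
    rlang::warn("Success probabilities at 0 clamped to 1e-12.")
  }
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(w * (records$y * log(p) + (1 - records$y) * log1p(-p)))
}

# log density (up to the truncation constant) of N(mean, sd) truncated to [0,1]
log_trunc_normal <- function(s, mean, sd) {
  -0.5 * ((s - mean) / sd)^2
}

#' MAP update of the occurrence probability in one coarse cell
#'
#' Maximises the kernel-weighted local log likelihood plus the log
#' density of a `N(prior_mean, prior_sd)` prior truncated to `[0, 1]`,
#' over `s` in `[1e-6, 1 - 1e-6]`. The posterior sd is the Laplace
#' approximation `(-d^2/ds^2 log posterior)^{-1/2}` at the mode, falling
#' back to `prior_sd` when the curvature is non-negative.
#'
#' @inheritParams local_log_likelihood
#' @param prior_mean Prior occurrence probability in `[0, 1]`.
#' @param prior_sd Positive prior sd on the probability scale.
#' @return A tibble with `s_hat` and `posterior_sd`.
#' @export
update_cell <- function(focal_row, focal_col, records, prior_mean, prior_sd,
                        grid, config = spatial_update_config()) {
  if (!is.finite(prior_mean) || prior_mean < 0 || prior_mean > 1 ||
      !is.finite(prior_sd) || prior_sd <= 0) {
    rlang::abort("Invalid prior moments.")
  }
  lower <- 1e-6; upper <- 1 - 1e-6
  if (nrow(records) > 0L) {
    d_km <- cell_distance_km(records$row, records$col, focal_row, focal_col, grid)
    w <- kernel_weight(d_km, config$tau_spatial, config$truncation_radius_km)
    keep <- w > 0
    w <- w[keep]
    a <- (records$m * records$d)[keep]
    y <- as.integer(records$y[keep])
  } else {
    w <- numeric(0); a <- numeric(0); y <- integer(0)
  }
  obj <- function(s) cpp_log_post(s, w, a, y, prior_mean, prior_sd)
  opt <- optimize(obj, interval = c(lower, upper), maximum = TRUE,
                  tol = 1e-9)
  s_hat <- opt$maximum
  h <- min(1e-5, (s_hat - lower) / 2, (upper - s_hat) / 2)
  posterior_sd <- prior_sd
  if (h > 1e-12) {
    curv <- (obj(s_hat + h) - 2 * obj(s_hat) + obj(s_hat - h)) / h^2
    if (curv < 0) posterior_sd <- 1 / sqrt(-curv)
  }
  tibble::tibble(s_hat = s_hat, posterior_sd = posterior_sd)
}

#' MAP update of a whole coarse occurrence raster
#'
#' Runs [update_cell()]'s computation independently for every coarse cell
#' (compiled loop). Cells are conditionally independent given the data,
#' so the result does not depend on update order.
#'
#' @param records Tibble with 0-based coarse `row`, `col`, 0/1 `y`, fixed
#'   per-record `m` and `d`.
#' @param prior_mean,prior_sd `raster_layer`s on the coarse grid (`NA` =
#'   nodata; such cells stay nodata).
#' @param config A [spatial_update_config()].
#' @return A list with `mean` and `sd` `raster_layer`s.
#' @export
update_raster <- function(records, prior_mean, prior_sd,
                          config = spatial_update_config()) {
  stopifnot(inherits(prior_mean, "raster_layer"),
            inherits(prior_sd, "raster_layer"))
  g <- prior_mean$grid
  res <- cpp_update_map(as.integer(records$row), as.integer(records$col),
                        as.integer(records$y), records$m * records$d,
                        prior_mean$values, prior_sd$values,
                        config$tau_spatial, config$truncation_radius_km,
                        g$cell_size_km, 1e-6, 1 - 1e-6)
  list(mean = raster_layer(res$mean, g), sd = raster_layer(res$sd, g))
}

#' Block-average fine prior moments onto the coarse grid
#'
#' Each coarse cell receives the arithmetic mean of the means and of the
#' variances of its nested fine cells; nodata fine cells are excluded,
#' and a fully-nodata block yields a nodata coarse cell.
#'
#' @param fine_mean,fine_var `raster_layer`s on the fine grid.
#' @param factor Nesting factor, default 10.
#' @return A list with coarse `mean` and `var` `raster_layer`s.
#' @export
downsample_prior <- function(fine_mean, fine_var, factor = 10L) {
  stopifnot(inherits(fine_mean, "raster_layer"), inherits(fine_var, "raster_layer"))
  cg <- coarsen_grid(fine_mean$grid, factor)
  block_mean <- function(m) {
    out <- matrix(NA_real_, cg$n_rows, cg$n_cols)
    for (r in seq_len(cg$n_rows)) {
      rows <- ((r - 1L) * factor + 1L):(r * factor)
      for (c in seq_len(cg$n_cols)) {
        cols <- ((c - 1L) * factor + 1L):(c * factor)
        v <- m[rows, cols]
        if (any(is.finite(v))) out[r, c] <- mean(v[is.finite(v)])
      }
    }
    out
  }
  list(mean = raster_layer(block_mean(fine_mean$values), cg),
       var = raster_layer(block_mean(fine_var$values), cg))
}

#' Probability-scale moments of a probit-normal prior
#'
#' Given a probit-scale linear predictor `Z ~ N(probit_mean, probit_var)`,
#' returns the mean and sd of `Phi(Z)` on the probability scale, by
#' Gauss-Hermite quadrature (default, 64 nodes) or Monte Carlo.
#'
#' @param probit_mean,probit_var Scalars, `probit_var >= 0`.
#' @param method `"quadrature"` or `"monte_carlo"`.
#' @param nodes Number of Gauss-Hermite nodes.
#' @param n_mc Monte Carlo sample size.
#' @param seed Seed for the Monte Carlo route.
#' @return Named numeric vector `c(prob_mean, prob_sd)`.
#' @export
probit_prior_moments <- function(probit_mean, probit_var,
                                 method = c("quadrature", "monte_carlo"),
                                 nodes = 64L, n_mc = 1e5, seed = 1L) {
  method <- match.arg(method)
  stopifnot(probit_var >= 0)
  if (probit_var == 0) {
    return(c(prob_mean = pnorm(probit_mean), prob_sd = 0))
  }
  if (method == "quadrature") {
    gh <- pracma::gaussHermite(nodes)
    # E[f(Z)] = sum w_i f(mu + sqrt(2 v) x_i) / sqrt(pi)
    z <- probit_mean + sqrt(2 * probit_var) * gh$x
    p <- pnorm(z)
    m1 <- sum(gh$w * p) / sqrt(pi)
    m2 <- sum(gh$w * p^2) / sqrt(pi)
  } else {
    # randomized stratified sampling: one uniform draw per stratum keeps
    # the estimator unbiased while shrinking the error to O(1/n), so the
    # two routes agree reliably at the default sample size
    u <- withr::with_seed(seed, runif(n_mc))
    z <- probit_mean + sqrt(probit_var) * qnorm((seq_len(n_mc) - u) / n_mc)
    p <- pnorm(z)
    m1 <- mean(p)
    m2 <- mean(p^2)
  }
  c(prob_mean = m1, prob_sd = sqrt(max(m2 - m1^2, 0)))
}

#' Upsample a coarse posterior probability into its fine block
#'
#' The default method preserves the local geometry of the fine prior: the
#' fine posterior is `Phi(Phi^{-1}(fine_prior_i) + delta)` with the
#' common shift `delta` chosen (by monotone root finding) so that the
#' block mean equals the coarse posterior. Outputs therefore keep exactly
#' the prior's within-block ranks. `method = "literal"` instead shifts
#' the coarse posterior itself, minimising the printed squared-error
#' objective; it returns a constant within the block and is provided for
#' comparison only.
#'
#' @param coarse_posterior Scalar in `(0, 1)` (0/1 clamped with warning).
#' @param fine_prior_block Numeric vector of fine prior probabilities in
#'   `(0, 1)`.
#' @param method `"shift"` (default) or `"literal"`.
#' @return Numeric vector of fine posterior probabilities, one per input
#'   prior.
#' @export
upsample_posterior <- function(coarse_posterior, fine_prior_block,
                               method = c("shift", "literal")) {
  method <- match.arg(method)
  coarse_posterior <- clamp_prob(coarse_posterior)
  if (any(fine_prior_block <= 0 | fine_prior_block >= 1)) {
    rlang::abort("Fine prior probabilities must lie strictly inside (0, 1).")
  }
  z <- qnorm(fine_prior_block)
  if (method == "shift") {
    f <- function(delta) mean(pnorm(z + delta)) - coarse_posterior
    delta_hat <- uniroot(f, lower = -12, upper = 12, tol = 1e-12)$root
    pnorm(z + delta_hat)
  } else {
    z0 <- qnorm(coarse_posterior)
    g <- function(delta) sum((pnorm(z0 + delta) - fine_prior_block)^2)
    delta_hat <- optimize(g, interval = c(-12, 12), tol = 1e-10)$minimum
    rep(pnorm(z0 + delta_hat), length(fine_prior_block))
  }
}

#' Heat-map plot of a raster layer
#'
#' @param object A `raster_layer`.
#' @param ... Unused.
#' @return A ggplot tile map (row 0 drawn at the top, matching the
#'   north-west-origin convention).
#' @export
autoplot.raster_layer <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Column", y = "Row", fill = "Value")
}
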