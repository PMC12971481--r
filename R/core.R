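#' Standard normal cumulative distribution function
#'
#' Thin validated wrapper around [stats::pnorm()]. The migration phenology
#' curve, the probit detection translation and the probit-scale raster
#' conversions all use the standard normal CDF, so the package exposes it
#' under a single name with strict input checking.
#'
#' @param z Numeric vector of finite quantiles.
#' @return `P(Z <= z)` for `Z ~ N(0, 1)`, in `(0, 1)` elementwise.
#' @examples
#' std_normal_cdf(0)    # 0.5
#' std_normal_cdf(2)    # 0.9772499
#' @export
std_normal_cdf <- function(z) {
  if (!is.numeric(z) || length(z) == 0L || any(!is.finite(z))) {
    rlang::abort("`z` must be a finite numeric vector.")
  }
  stats::pnorm(z)
}

#' Standard normal quantile function
#'
#' Inverse of [std_normal_cdf()]; the probit link used throughout the
#' detection-translation and raster-rescaling machinery.
#'
#' @param p Numeric vector of probabilities strictly inside `(0, 1)`.
#' @return Quantiles `z` with `std_normal_cdf(z) = p`.
#' @export
std_normal_quantile <- function(p) {
  if (!is.numeric(p) || length(p) == 0L || any(!is.finite(p)) ||
      any(p <= 0) || any(p >= 1)) {
    rlang::abort("`p` must lie strictly inside (0, 1).")
  }
  stats::qnorm(p)
}

#' Define a regular planar grid
#'
#' The package works on planar projected grids in kilometre units: a fine
#' grid of 0.1 km (one hectare) cells and a coarse grid of 1 km cells into
#' which the fine grid nests exactly 10 x 10. Indices are 0-based and
#' row-major with the origin at the north-west corner (row 0 is the
#' northernmost row), matching common raster conventions.
#'
#' @param n_rows,n_cols Positive integer grid dimensions.
#' @param cell_size_km Cell edge length in km (0.1 fine, 1.0 coarse).
#' @param origin_easting_km,origin_northing_km Planar coordinates of the
#'   north-west corner of the grid.
#' @return An object of class `grid_spec`.
#' @export
grid_spec <- function(n_rows, n_cols, cell_size_km = 0.1,
                      origin_easting_km = 0, origin_northing_km = 0) {
  stopifnot(n_rows >= 1, n_cols >= 1, cell_size_km > 0)
  structure(
    list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
         cell_size_km = cell_size_km,
         origin_easting_km = origin_easting_km,
         origin_northing_km = origin_northing_km),
    class = "grid_spec"
  )
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d x %d cells of %g km\n",
              x$n_rows, x$n_cols, x$cell_size_km))
  invisible(x)
}

#' Coarsen a grid specification
#'
#' @param grid A `grid_spec`.
#' @param factor Integer block size; the default 10 turns the 0.1 km fine
#'   grid into the 1 km coarse grid.
#' @return A `grid_spec` whose cells are `factor` x `factor` blocks of the
#'   input cells. Dimensions must divide evenly.
#' @export
coarsen_grid <- function(grid, factor = 10L) {
  stopifnot(inherits(grid, "grid_spec"))
  factor <- as.integer(factor)
  if (grid$n_rows %% factor != 0L || grid$n_cols %% factor != 0L) {
    rlang::abort("Grid dimensions must be divisible by `factor`.")
  }
  grid_spec(grid$n_rows %/% factor, grid$n_cols %/% factor,
            cell_size_km = grid$cell_size_km * factor,
            origin_easting_km = grid$origin_easting_km,
            origin_northing_km = grid$origin_northing_km)
}

#' Map fine-grid cells to their enclosing coarse cell
#'
#' @param row,col 0-based fine-grid indices (vectorised).
#' @param factor Nesting factor, default 10.
#' @return A tibble with 0-based `row`, `col` on the coarse grid.
#' @export
coarse_cell_of <- function(row, col, factor = 10L) {
  tibble::tibble(row = as.integer(row) %/% as.integer(factor),
                 col = as.integer(col) %/% as.integer(factor))
}

#' Euclidean distance between cell centres
#'
#' Distances are planar Euclidean in kilometres on the projected grid;
#' geodesy is deliberately decoupled from kernel geometry (latitude enters
#' the migration model separately, as a per-recording covariate).
#'
#' @param row_a,col_a,row_b,col_b 0-based cell indices (vectorised,
#'   recycled).
#' @param grid The shared `grid_spec`; cells must lie within its bounds.
#' @return Distance(s) in km.
#' @export
cell_distance_km <- function(row_a, col_a, row_b, col_b, grid) {
  stopifnot(inherits(grid, "grid_spec"))
  ok <- function(r, c) all(r >= 0 & r < grid$n_rows & c >= 0 & c < grid$n_cols)
  if (!ok(row_a, col_a) || !ok(row_b, col_b)) {
    rlang::abort("Cell indices outside the grid bounds.")
  }
  grid$cell_size_km * sqrt((row_a - row_b)^2 + (col_a - col_b)^2)
}

#' Scale a day-of-year or minute-of-day onto the unit interval
#'
#' Periodic covariates enter the detection model scaled to `[0, 1)`.
#' Days use a 365-day cycle with day 1 mapping to 0 and the leap day 366
#' wrapping back to 0, keeping the periodic basis continuous across year
#' boundaries. Minutes map as `minute / 1440`.
#'
#' @param value Integer vector: days in `1..period_length + 1` when
#'   `period_length = 365`, minutes in `0..period_length - 1` when
#'   `period_length = 1440`.
#' @param period_length 365 for days (default) or 1440 for minutes.
#' @return Fractions in `[0, 1)`.
#' @export
scale_to_unit <- function(value, period_length = 365L) {
  if (period_length == 1440L) {
    if (any(value < 0 | value > 1439)) {
      rlang::abort("Minute-of-day must lie in 0..1439.")
    }
    value / 1440
  } else {
    if (any(value < 1 | value > period_length + 1)) {
      rlang::abort(sprintf("Day must lie in 1..%d.", period_length + 1))
    }
    ((value - 1) %% period_length) / period_length
  }
}

#' @rdname scale_to_unit
#' @export
day_fraction <- function(value) scale_to_unit(value, 365L)

#' @rdname scale_to_unit
#' @export
minute_fraction <- function(value) scale_to_unit(value, 1440L)

# Clamp probabilities away from 0/1 before a probit transform.
clamp_prob <- function(p, eps = 1e-9, warn = TRUE) {
  out_of_range <- p < eps | p > 1 - eps
  if (warn && any(out_of_range, na.rm = TRUE)) {
    rlang::warn("Probabilities at 0 or 1 clamped before probit transform.")
  }
  pmin(pmax(p, eps), 1 - eps)
}

#' Construct a raster layer
#'
#' A raster layer is a numeric matrix bound to a `grid_spec`; `NA` entries
#' are nodata. Row 1 of the matrix is grid row 0 (the northern edge).
#'
#' @param values Numeric matrix `n_rows x n_cols`.
#' @param grid The owning `grid_spec`.
#' @return An object of class `raster_layer`.
#' @export
raster_layer <- function(values, grid) {
  stopifnot(inherits(grid, "grid_spec"), is.matrix(values))
  if (nrow(values) != grid$n_rows || ncol(values) != grid$n_cols) {
    rlang::abort("Matrix dimensions do not match the grid.")
  }
  structure(list(values = values, grid = grid), class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  v <- x$values[is.finite(x$values)]
  cat(sprintf("<raster_layer> %d x %d @ %g km; range [%.4g, %.4g]\n",
              x$grid$n_rows, x$grid$n_cols, x$grid$cell_size_km,
              if (length(v)) min(v) else NA, if (length(v)) max(v) else NA))
  invisible(x)
}

#' Tidy a raster layer into a long tibble
#'
#' @param x A `raster_layer`.
#' @param ... Unused.
#' @return A tibble with 0-based `row`, `col` and `value` (nodata rows
#'   dropped).
#' @export
tidy.raster_layer <- function(x, ...) {
  g <- x$grid
  out <- tibble::tibble(
    row = rep(seq_len(g$n_rows) - 1L, times = g$n_cols),
    col = rep(seq_len(g$n_cols) - 1L, each = g$n_rows),
    value = as.vector(x$values)
  )
  dplyr::filter(out, is.finite(.data$value))
}

#' Raster value at 0-based cell indices (vectorised)
#' @param layer A `raster_layer`.
#' @param row,col 0-based indices.
#' @return Numeric vector of cell values.
#' @export
raster_value_at <- function(layer, row, col) {
  stopifnot(inherits(layer, "raster_layer"))
  layer$values[cbind(row + 1L, col + 1L)]
}

#' Validate a recording stream
#'
#' Checks the schema of a recording tibble: one row per recording with
#' timestamp fields, fine-grid cell, latitude, recording type, duration,
#' log-duration and one 0/1 column per species.
#'
#' @param records A tibble.
#' @param species Character vector of species column names (defaults to
#'   every column after the metadata block).
#' @return `records`, invisibly, with `log_duration` recomputed if absent.
#' @export
validate_recordings <- function(records, species = species_columns(records)) {
  meta <- c("recording_id", "year", "day_of_year", "minute_of_day",
            "row", "col", "latitude_deg", "rec_type", "duration_min")
  missing <- setdiff(meta, names(records))
  if (length(missing)) {
    rlang::abort(paste0("Missing columns: ", paste(missing, collapse = ", ")))
  }
  if (any(records$duration_min <= 0)) {
    rlang::abort("`duration_min` must be positive.")
  }
  if (!all(records$rec_type %in% c("direct", "interval", "point"))) {
    rlang::abort("`rec_type` must be direct, interval or point.")
  }
  if (any(records$day_of_year < 1 | records$day_of_year > 366) ||
      any(records$minute_of_day < 0 | records$minute_of_day > 1439)) {
    rlang::abort("Timestamp fields out of range.")
  }
  if (!"log_duration" %in% names(records)) {
    records$log_duration <- log(records$duration_min)
  }
  for (sp in species) {
    v <- records[[sp]]
    if (!all(v %in% c(0, 1))) rlang::abort(sprintf("Column %s is not 0/1.", sp))
  }
  invisible(records)
}

#' Species columns of a recording stream
#' @param records A recording tibble.
#' @return Character vector: every column after the standard metadata block.
#' @export
species_columns <- function(records) {
  meta <- c("recording_id", "year", "day_of_year", "minute_of_day",
            "row", "col", "latitude_deg", "rec_type", "duration_min",
            "log_duration", "site_id")
  setdiff(names(records), meta)
}
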