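#' Read and write recording streams
#'
#' CSV schema: `recording_id, year, day_of_year, minute_of_day, row, col,
#' latitude_deg, rec_type, duration_min` followed by one 0/1 column per
#' species. UTF-8, header required. `log_duration` is recomputed on read.
#'
#' @param path File path.
#' @return `read_recordings()` returns a validated recording tibble.
#' @export
read_recordings <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           recording_id = readr::col_character(),
                           rec_type = readr::col_character()))
  out$log_duration <- log(out$duration_min)
  validate_recordings(out)
  out
}

#' @rdname read_recordings
#' @param records A validated recording tibble.
#' @export
write_recordings <- function(records, path) {
  validate_recordings(records)
  readr::write_csv(dplyr::select(records, -dplyr::any_of("log_duration")), path)
  invisible(path)
}

#' Read and write raster layers as plain text
#'
#' ASCII-grid format: six header lines (`ncols`, `nrows`,
#' `xllcorner`, `yllcorner`, `cellsize`, `NODATA_value`, all in km) then
#' the matrix rows north to south. Nodata cells are written as -1 and
#' read back as `NA`. This plain-text representation keeps raster
#' artefacts portable and diffable.
#'
#' @param path File path.
#' @return `read_ascii_raster()` returns a `raster_layer`.
#' @export
read_ascii_raster <- function(path) {
  lines <- readLines(path)
  hdr <- strsplit(trimws(lines[1:6]), "\\s+")
  key <- vapply(hdr, `[`, "", 1)
  val <- as.numeric(vapply(hdr, `[`, "", 2))
  names(val) <- tolower(key)
  n_rows <- as.integer(val[["nrows"]]); n_cols <- as.integer(val[["ncols"]])
  body <- scan(text = paste(lines[-(1:6)], collapse = "\n"), quiet = TRUE)
  m <- matrix(body, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  m[m == val[["nodata_value"]]] <- NA_real_
  grid <- grid_spec(n_rows, n_cols, cell_size_km = val[["cellsize"]],
                    origin_easting_km = val[["xllcorner"]],
                    origin_northing_km = val[["yllcorner"]] +
                      n_rows * val[["cellsize"]])
  raster_layer(m, grid)
}

#' @rdname read_ascii_raster
#' @param layer A `raster_layer`.
#' @param digits Significant digits written, default 8.
#' @export
write_ascii_raster <- function(layer, path, digits = 8) {
  stopifnot(inherits(layer, "raster_layer"))
  g <- layer$grid
  m <- layer$values
  m[!is.finite(m)] <- -1
  hdr <- c(sprintf("ncols %d", g$n_cols),
           sprintf("nrows %d", g$n_rows),
           sprintf("xllcorner %g", g$origin_easting_km),
           sprintf("yllcorner %g", g$origin_northing_km -
                     g$n_rows * g$cell_size_km),
           sprintf("cellsize %g", g$cell_size_km),
           "NODATA_value -1")
  body <- apply(m, 1, function(r) paste(signif(r, digits), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}
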