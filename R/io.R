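#' Read and write long-format area grids
#'
#' Area grids travel as long-format CSV with columns `row`, `col`, `epoch`,
#' `year`, `crop`, `water_regime`, `area_ha` (0-based row-major cell
#' indexing). This is the package's interchange format for harvested-area
#' maps.
#'
#' @param grids Tibble as produced by [generate_area_grids()].
#' @param path File path.
#' @return `write_area_grid()` returns `path` invisibly;
#'   `read_area_grid()` returns the tibble.
#' @export
write_area_grid <- function(grids, path) {
  assert_columns(grids, c("row", "col", "epoch", "year", "area_ha"), "grids")
  readr::write_csv(grids, path)
  invisible(path)
}

#' @rdname write_area_grid
#' @export
read_area_grid <- function(path) {
  readr::read_csv(
    path,
    col_types = readr::cols(
      row = readr::col_integer(), col = readr::col_integer(),
      epoch = readr::col_integer(), year = readr::col_integer(),
      crop = readr::col_character(), water_regime = readr::col_character(),
      area_ha = readr::col_double()
    )
  )
}

#' Read and write station weather series
#'
#' Daily weather travels as CSV with `year`, `doy`, `month`, `tmin_c`,
#' `tmax_c`, `srad_mj_m2`, `rain_mm`; the station's grid cell and latitude
#' are stored in leading comment lines so a round trip preserves them.
#'
#' @param weather Tibble from [generate_weather()].
#' @param path File path.
#' @return `write_weather()` returns `path` invisibly; `read_weather()`
#'   returns the tibble with `row`, `col`, `lat` attributes restored.
#' @export
write_weather <- function(weather, path) {
  assert_columns(weather, c("year", "doy", "tmin_c", "tmax_c", "srad_mj_m2", "rain_mm"), "weather")
  header <- sprintf(
    "# station_row=%s station_col=%s lat=%s",
    attr(weather, "row") %||% NA, attr(weather, "col") %||% NA,
    attr(weather, "lat") %||% NA
  )
  writeLines(header, path)
  readr::write_csv(weather, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_weather
#' @export
read_weather <- function(path) {
  header <- readLines(path, n = 1)
  out <- readr::read_csv(path, comment = "#", col_types = readr::cols())
  kv <- regmatches(header, gregexpr("[a-z_]+=[-0-9.e+NA]+", header))[[1]]
  vals <- setNames(
    as.numeric(sub(".*=", "", kv)),
    sub("=.*", "", kv)
  )
  attr(out, "row") <- unname(vals["station_row"])
  attr(out, "col") <- unname(vals["station_col"])
  attr(out, "lat") <- unname(vals["lat"])
  out
}

#' Write buffer membership and selection trace
#'
#' @param buffers List of `buffer_zone`s.
#' @param path File path for the membership CSV (`station_id`, `row`, `col`,
#'   `cz_id`, `area_ha`).
#' @return `path`, invisibly.
#' @export
write_buffer_membership <- function(buffers, path) {
  rows <- purrr::map_dfr(buffers, function(b) {
    dplyr::mutate(b$cells, station_id = b$station_id, cz_id = b$cz_id)
  }) |>
    dplyr::select("station_id", "row", "col", "cz_id", "area_ha")
  readr::write_csv(rows, path)
  invisible(path)
}

#' Save and load a pipeline configuration as YAML
#'
#' Serialises the scalar/vector parts of a [pipeline_config()] (functions
#' such as the sequence rule and cultivar overrides are reconstructed from
#' defaults on load, so round trips are exact only for default rules).
#'
#' @param config A [pipeline_config()].
#' @param path File path.
#' @return `write_pipeline_config()` returns `path` invisibly;
#'   `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  x <- list(
    landscape = unclass(config$landscape),
    climate = unclass(config$climate),
    selection = unclass(config$selection),
    cultivar = unclass(config$cultivar),
    weather_years = config$weather_years, n_stations = config$n_stations,
    water_regime = config$water_regime, n_soils = config$n_soils,
    bin_edges = config$bin_edges,
    ensure_region_stations = config$ensure_region_stations,
    include_flagged = config$include_flagged,
    init_fraction = config$init_fraction, seed = config$seed
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- yaml::read_yaml(path)
  ls_args <- x$landscape
  ls_args$grid_shape <- unlist(ls_args$grid_shape)
  if (!is.null(ls_args$expansion_region)) {
    ls_args$expansion_region <- lapply(ls_args$expansion_region, unlist)
  }
  ls_args$urban_centers <- lapply(ls_args$urban_centers, function(uc) {
    list(cell = unlist(uc$cell), strength = uc$strength)
  })
  pipeline_config(
    landscape = do.call(landscape_config, ls_args),
    climate = do.call(climate_params, x$climate),
    selection = do.call(selection_config, x$selection),
    weather_years = x$weather_years, n_stations = x$n_stations,
    water_regime = x$water_regime,
    cultivar = do.call(cultivar, x$cultivar),
    n_soils = unlist(x$n_soils),
    bin_edges = lapply(x$bin_edges, unlist),
    ensure_region_stations = x$ensure_region_stations,
    include_flagged = x$include_flagged,
    init_fraction = x$init_fraction, seed = x$seed
  )
}

#' Write the yield-ratio report as CSV
#'
#' @param report A `yield_ratio_report`.
#' @param path File path; the side table is written with the ratio appended
#'   as attribute columns.
#' @return `path`, invisibly.
#' @export
write_report_csv <- function(report, path) {
  stopifnot(inherits(report, "yield_ratio_report"))
  out <- dplyr::mutate(
    report$sides,
    yield_ratio = report$ratio, yield_ratio_1dp = report$ratio_1dp,
    ratio_defined = report$ratio_defined, crop = report$crop
  )
  readr::write_csv(out, path)
  invisible(path)
}
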