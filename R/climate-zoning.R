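#' Growing degree days
#'
#' Accumulated thermal time: `sum(max(0, min(T, cap) - base))` over the daily
#' mean temperature series. The optional cap limits the daily contribution of
#' very hot days, as in standard agro-climatic GDD definitions.
#'
#' @param daily_mean_temp Numeric vector of daily mean temperatures (C).
#' @param base_temp Base temperature (C).
#' @param cap Optional upper temperature cap (C); must be `>= base_temp`.
#' @return Accumulated degree days (C-days), non-negative.
#' @examples
#' growing_degree_days(rep(25, 100), base_temp = 10) # 1500
#' @export
growing_degree_days <- function(daily_mean_temp, base_temp, cap = NULL) {
  if (length(daily_mean_temp) == 0) abort("temperature series is empty.")
  if (!is.null(cap) && cap < base_temp) abort("`cap` must be >= `base_temp`.")
  t <- daily_mean_temp
  if (!is.null(cap)) t <- pmin(t, cap)
  sum(pmax(0, t - base_temp))
}

#' Temperature seasonality
#'
#' Population standard deviation of the 12 climatological monthly mean
#' temperatures. Daily input must cover whole calendar months (365-day years;
#' each month of each year must be complete).
#'
#' @param weather Tibble with `year`, `month`, `doy` and either `tmean_c` or
#'   `tmin_c`/`tmax_c` (averaged).
#' @return Seasonality in degrees C (>= 0).
#' @export
temperature_seasonality <- function(weather) {
  assert_columns(weather, c("year", "month"), "weather")
  tmean <- weather_tmean(weather)
  days_per_month <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  counts <- dplyr::count(weather, .data$year, .data$month)
  if (!all(counts$n == days_per_month[counts$month])) {
    abort("incomplete months in weather series; seasonality needs whole months.")
  }
  if (length(unique(weather$month)) < 12) {
    abort("seasonality needs at least 12 months of data.")
  }
  monthly <- tibble::tibble(month = weather$month, tmean = tmean) |>
    dplyr::group_by(.data$month) |>
    dplyr::summarise(m = mean(.data$tmean), .groups = "drop")
  m <- monthly$m
  sqrt(mean((m - mean(m))^2)) # population SD over the 12 climatological means
}

weather_tmean <- function(weather) {
  if ("tmean_c" %in% names(weather)) {
    weather$tmean_c
  } else {
    assert_columns(weather, c("tmin_c", "tmax_c"), "weather")
    (weather$tmin_c + weather$tmax_c) / 2
  }
}

#' Daily extraterrestrial radiation
#'
#' Top-of-atmosphere solar radiation for a latitude and day of year, by the
#' standard solar-geometry formula (solar constant 0.0820 MJ m-2 min-1,
#' inverse relative Earth--Sun distance, solar declination, sunset hour
#' angle). Polar day/night is handled by clamping the sunset-angle cosine.
#'
#' @param lat Latitude in decimal degrees.
#' @param doy Day(s) of year (1--365).
#' @return Radiation in MJ m-2 d-1.
#' @export
extraterrestrial_radiation <- function(lat, doy) {
  phi <- lat * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  delta <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  ws <- acos(pmin(1, pmax(-1, -tan(phi) * tan(delta))))
  (24 * 60 / pi) * 0.0820 * dr *
    (ws * sin(phi) * sin(delta) + cos(phi) * cos(delta) * sin(ws))
}

#' Potential evapotranspiration (Hargreaves)
#'
#' Daily reference evapotranspiration by the Hargreaves--Samani equation,
#' `0.0023 * Ra * (Tmean + 17.8) * sqrt(Tmax - Tmin)` with Ra converted from
#' MJ m-2 d-1 to mm d-1 (x 0.408). Chosen because it needs only temperature
#' and solar geometry, which the station records always carry.
#'
#' @param weather Tibble with `doy`, `tmin_c`, `tmax_c` and a `lat` attribute
#'   (as produced by [generate_weather()]), or pass `lat` explicitly.
#' @param lat Latitude in degrees; defaults to `attr(weather, "lat")`.
#' @return Non-negative numeric vector of daily PET (mm).
#' @export
potential_evapotranspiration <- function(weather, lat = attr(weather, "lat")) {
  assert_columns(weather, c("doy", "tmin_c", "tmax_c"), "weather")
  if (is.null(lat)) abort("latitude missing: supply `lat` or a weather `lat` attribute.")
  if (any(weather$tmax_c < weather$tmin_c)) abort("tmax < tmin in weather series.")
  ra <- extraterrestrial_radiation(lat, weather$doy)
  tmean <- (weather$tmin_c + weather$tmax_c) / 2
  pmax(0, 0.0023 * 0.408 * ra * (tmean + 17.8) * sqrt(weather$tmax_c - weather$tmin_c))
}

#' Aridity index
#'
#' Annual precipitation divided by annual potential evapotranspiration.
#'
#' @param annual_precip Annual precipitation (mm).
#' @param annual_pet Annual PET (mm), must be > 0.
#' @return Dimensionless ratio, >= 0.
#' @examples
#' aridity_index(600, 1500) # 0.4
#' @export
aridity_index <- function(annual_precip, annual_pet) {
  if (any(annual_pet <= 0)) abort("`annual_pet` must be > 0.")
  if (any(annual_precip < 0)) abort("`annual_precip` must be >= 0.")
  annual_precip / annual_pet
}

#' Default climate-zone bin edges
#'
#' Interior bin edges for the three zonation variables: growing degree days in
#' 1000 C-day bins, seasonality in 5 C bins, and aridity edges at 0.2, 0.5,
#' 0.65 and 1.0. These are configurable placeholders with the right
#' granularity, not a published codebook.
#'
#' @return Named list `gdd`, `seasonality`, `aridity` of increasing edges.
#' @export
zone_bin_defaults <- function() {
  list(
    gdd = seq(1000, 14000, by = 1000),
    seasonality = seq(5, 25, by = 5),
    aridity = c(0.2, 0.5, 0.65, 1.0)
  )
}

#' Delimit climate zones by binning the three metrics
#'
#' Each cell's `(gdd, seasonality, aridity)` triple is binned against the
#' given edges; cells sharing a bin triple share a zone. Zone ids are stable
#' integers assigned in lexicographic order of the occupied bin triples, so
#' the labelling depends only on the metric values, never on cell order.
#'
#' @param metrics Tibble with `row`, `col`, `gdd`, `seasonality`, `aridity`.
#' @param bin_edges Named list of increasing interior edges per metric; see
#'   [zone_bin_defaults()].
#' @return Tibble `row`, `col`, `gdd_bin`, `seasonality_bin`, `aridity_bin`,
#'   `zone_id`, with `bin_edges` attached as an attribute.
#' @export
delimit_zones <- function(metrics, bin_edges = zone_bin_defaults()) {
  assert_columns(metrics, c("row", "col", "gdd", "seasonality", "aridity"), "metrics")
  for (nm in c("gdd", "seasonality", "aridity")) {
    e <- bin_edges[[nm]]
    if (is.null(e) || is.unsorted(e, strictly = TRUE)) {
      abort(sprintf("bin edges for `%s` must be strictly increasing.", nm))
    }
    if (!all(is.finite(metrics[[nm]]))) abort(sprintf("non-finite `%s` values.", nm))
  }
  out <- dplyr::mutate(
    metrics,
    gdd_bin = findInterval(.data$gdd, bin_edges$gdd),
    seasonality_bin = findInterval(.data$seasonality, bin_edges$seasonality),
    aridity_bin = findInterval(.data$aridity, bin_edges$aridity)
  )
  triples <- dplyr::distinct(out, .data$gdd_bin, .data$seasonality_bin, .data$aridity_bin) |>
    dplyr::arrange(.data$gdd_bin, .data$seasonality_bin, .data$aridity_bin) |>
    dplyr::mutate(zone_id = dplyr::row_number())
  out <- dplyr::left_join(
    out, triples,
    by = c("gdd_bin", "seasonality_bin", "aridity_bin")
  )
  attr(out, "bin_edges") <- bin_edges
  out
}

#' Per-cell climate metrics from the synthetic climate model
#'
#' Computes the three zonation metrics for every grid row from the noise-free
#' climatology underlying [generate_weather()] (climate varies only with row
#' in the synthetic landscape) and replicates them across columns. GDD uses
#' base 0 C capped at 30 C, the usual agro-climatic convention for zonation.
#'
#' @param grid_shape Integer `c(rows, cols)`.
#' @param params A [climate_params()].
#' @param gdd_base,gdd_cap GDD base and cap temperatures (C).
#' @return Tibble `row`, `col`, `gdd`, `seasonality`, `aridity`.
#' @export
climate_metrics_grid <- function(grid_shape, params, gdd_base = 0, gdd_cap = 30) {
  doy <- 1:365
  month_of_doy <- rep(1:12, times = c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))
  per_row <- purrr::map_dfr(0:(grid_shape[1] - 1), function(r) {
    clim <- row_climatology(r, params, doy)
    lat <- params$lat_top + params$lat_per_row * r
    w <- tibble::tibble(
      year = 1L, doy = doy, month = month_of_doy,
      tmean_c = clim$tmean,
      tmin_c = clim$tmean - params$diurnal_range / 2,
      tmax_c = clim$tmean + params$diurnal_range / 2
    )
    pet <- potential_evapotranspiration(w, lat = lat)
    tibble::tibble(
      row = r,
      gdd = growing_degree_days(clim$tmean, gdd_base, gdd_cap),
      seasonality = temperature_seasonality(w),
      aridity = aridity_index(clim$annual_rain, sum(pet))
    )
  })
  tidyr::expand_grid(row = 0:(grid_shape[1] - 1), col = 0:(grid_shape[2] - 1)) |>
    dplyr::left_join(per_row, by = "row")
}
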