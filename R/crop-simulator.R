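#' Define a cultivar for the simplified crop model
#'
#' The simulator is deliberately simple: phenology is driven by growing degree
#' days to maturity (the single genotype parameter that matters most for
#' yield-potential simulation), light capture by a logistic canopy intercepted
#' via Beer's law, growth by radiation-use efficiency (RUE) on intercepted
#' photosynthetically active radiation, modulated by a trapezoidal
#' temperature response and (rainfed only) a soil-water supply/demand stress
#' factor. Grain yield is biomass times harvest index, converted to the
#' crop's commercial moisture standard.
#'
#' @param gdd_to_maturity Thermal time from emergence to physiological
#'   maturity (C-days above `base_temp`).
#' @param base_temp Base temperature (C).
#' @param rue Radiation-use efficiency (g dry matter per MJ intercepted PAR).
#' @param max_lai Maximum leaf area index.
#' @param harvest_index Grain fraction of final biomass, in (0, 1).
#' @param standard_moisture Commercial moisture fraction at which yield is
#'   reported (0.155 for maize, 0.14 for rice).
#' @param t_opt_lo,t_opt_hi,t_lethal Vertices of the trapezoidal temperature
#'   response: 0 at `base_temp`, rising to 1 at `t_opt_lo`, flat to
#'   `t_opt_hi`, falling to 0 at `t_lethal`.
#' @return A `cultivar` list.
#' @export
cultivar <- function(gdd_to_maturity, base_temp, rue, max_lai, harvest_index,
                     standard_moisture, t_opt_lo = base_temp + 8,
                     t_opt_hi = 30, t_lethal = 42) {
  assert_scalar_number(gdd_to_maturity, "gdd_to_maturity", lower = 1e-9)
  assert_scalar_number(rue, "rue", lower = 1e-9)
  assert_scalar_number(max_lai, "max_lai", lower = 1e-9)
  assert_scalar_number(harvest_index, "harvest_index", 1e-9, 1 - 1e-9)
  assert_scalar_number(standard_moisture, "standard_moisture", 0, 0.2)
  stopifnot(base_temp < t_opt_lo, t_opt_lo <= t_opt_hi, t_opt_hi < t_lethal)
  structure(
    list(
      gdd_to_maturity = gdd_to_maturity, base_temp = base_temp, rue = rue,
      max_lai = max_lai, harvest_index = harvest_index,
      standard_moisture = standard_moisture,
      t_opt_lo = t_opt_lo, t_opt_hi = t_opt_hi, t_lethal = t_lethal
    ),
    class = "cultivar"
  )
}

#' @rdname cultivar
#' @param ... Overrides passed to [cultivar()].
#' @export
cultivar_rice <- function(...) {
  defaults <- list(
    gdd_to_maturity = 1600, base_temp = 8, rue = 2.2, max_lai = 6,
    harvest_index = 0.45, standard_moisture = 0.14
  )
  do.call(cultivar, utils::modifyList(defaults, list(...)))
}

#' @rdname cultivar
#' @export
cultivar_maize <- function(...) {
  defaults <- list(
    gdd_to_maturity = 1500, base_temp = 10, rue = 3.2, max_lai = 5,
    harvest_index = 0.5, standard_moisture = 0.155
  )
  do.call(cultivar, utils::modifyList(defaults, list(...)))
}

#' Soil profile: a single-layer water bucket
#'
#' @param paw_capacity_mm Plant-available water capacity (mm), > 0.
#' @param area_share Share of buffer harvested area on this soil.
#' @return A `soil_profile` list.
#' @export
soil_profile <- function(paw_capacity_mm, area_share = 1) {
  assert_scalar_number(paw_capacity_mm, "paw_capacity_mm", lower = 1e-9)
  assert_scalar_number(area_share, "area_share", 1e-12, 1)
  structure(
    list(paw_capacity_mm = paw_capacity_mm, area_share = area_share),
    class = "soil_profile"
  )
}

#' Crop sequence: one or more crops per year on the same land
#'
#' @param sowing_days Strictly increasing day-of-year vector, one per crop
#'   slot (1--3 slots).
#' @param cultivars A single [cultivar()] (recycled) or a list, one per slot.
#' @param area_share Share of buffer harvested area under this sequence.
#' @return A `crop_sequence` list; `crops_per_year` equals the slot count.
#' @export
crop_sequence <- function(sowing_days, cultivars, area_share = 1) {
  n <- length(sowing_days)
  if (n < 1 || n > 3) abort("a sequence has 1-3 crop slots.")
  if (is.unsorted(sowing_days, strictly = TRUE)) {
    abort("`sowing_days` must be strictly increasing.")
  }
  if (inherits(cultivars, "cultivar")) cultivars <- rep(list(cultivars), n)
  if (length(cultivars) != n) abort("one cultivar per sowing day required.")
  assert_scalar_number(area_share, "area_share", 1e-12, 1)
  structure(
    list(
      crops_per_year = n, sowing_days = as.integer(sowing_days),
      cultivars = cultivars, area_share = area_share
    ),
    class = "crop_sequence"
  )
}

# Trapezoidal temperature response in [0, 1].
temperature_factor <- function(tmean, cv) {
  piecewise_linear(
    tmean,
    c(cv$base_temp, cv$t_opt_lo, cv$t_opt_hi, cv$t_lethal),
    c(0, 1, 1, 0)
  )
}

# Beer's-law extinction coefficient and bucket extraction/evaporation
# constants; package-level numerical choices, documented in the vignette.
.sim_const <- list(k_ext = 0.5, par_frac = 0.5, extract_frac = 0.1, evap_frac = 0.5)

ensure_pet <- function(weather, lat = attr(weather, "lat")) {
  if ("pet_mm" %in% names(weather)) {
    return(weather)
  }
  weather$pet_mm <- potential_evapotranspiration(weather, lat = lat)
  weather
}

#' Simulate one growing season
#'
#' Runs the daily model from sowing to physiological maturity within one
#' weather year. Under irrigation the water-stress factor is 1; rainfed
#' growth is scaled by the supply/demand ratio of a single-layer soil water
#' bucket (inflow rain, overflow beyond capacity, outflows crop transpiration
#' and soil evaporation). If thermal time does not reach maturity before the
#' weather ends, the season is flagged incomplete and the yield-to-date is
#' returned with a warning.
#'
#' @param weather One year of daily weather (`doy`, `tmin_c`, `tmax_c`,
#'   `srad_mj_m2`, `rain_mm`; `pet_mm` is computed from the `lat` attribute
#'   if absent).
#' @param cultivar A [cultivar()].
#' @param soil A [soil_profile()] (used only when `water_regime = "rainfed"`).
#' @param water_regime `"irrigated"` or `"rainfed"`.
#' @param initial_soil_water Plant-available water at sowing (mm); see
#'   [initialize_soil_water()].
#' @param sowing_doy Sowing day of year.
#' @param daily If `TRUE` (rainfed only), attach a per-day tibble of bucket
#'   storage and stress as attribute `"daily"`.
#' @return One-row tibble: `yield_t_ha` (at the cultivar's standard
#'   moisture), `biomass_t_ha` (dry), `water_stress_days`, `season_length`,
#'   `maturity_doy`, `final_soil_water_mm`, `incomplete`, and the season
#'   water budget (`rain_mm`, `overflow_mm`, `transpiration_mm`,
#'   `evaporation_mm`, `delta_storage_mm`; zero under irrigation).
#' @export
simulate_season <- function(weather, cultivar, soil, water_regime = c("irrigated", "rainfed"),
                            initial_soil_water = soil$paw_capacity_mm, sowing_doy = 1,
                            daily = FALSE) {
  water_regime <- match.arg(water_regime)
  assert_columns(weather, c("doy", "tmin_c", "tmax_c", "srad_mj_m2", "rain_mm"), "weather")
  w <- weather[weather$doy >= sowing_doy, , drop = FALSE]
  if (nrow(w) == 0) abort("weather does not cover the sowing date.")

  tmean <- (w$tmin_c + w$tmax_c) / 2
  gdd_d <- pmax(0, tmean - cultivar$base_temp)
  tt <- cumsum(gdd_d)
  mat <- match(TRUE, tt >= cultivar$gdd_to_maturity)
  incomplete <- is.na(mat)
  if (incomplete) {
    warn("season incomplete: maturity not reached before weather ends; reporting yield to date.")
    mat <- nrow(w)
  }
  idx <- seq_len(mat)
  frac <- pmin(1, tt[idx] / cultivar$gdd_to_maturity)
  lai <- cultivar$max_lai / (1 + exp(-12 * (frac - 0.3)))
  fpar <- 1 - exp(-.sim_const$k_ext * lai)
  tf <- temperature_factor(tmean[idx], cultivar)
  par <- .sim_const$par_frac * w$srad_mj_m2[idx]
  pot_growth <- cultivar$rue * fpar * par * tf # g m-2 d-1

  if (water_regime == "irrigated") {
    biomass_g <- sum(pot_growth)
    stress_days <- 0L
    final_w <- min(initial_soil_water, soil$paw_capacity_mm)
    budget <- c(rain = 0, overflow = 0, transp = 0, evap = 0, dstore = 0)
  } else {
    w2 <- ensure_pet(w)
    pet <- w2$pet_mm[idx]
    rain <- w2$rain_mm[idx]
    paw <- soil$paw_capacity_mm
    store <- min(max(initial_soil_water, 0), paw)
    store0 <- store
    stress <- numeric(mat)
    storage_trace <- numeric(mat)
    tot <- c(rain = 0, overflow = 0, transp = 0, evap = 0)
    for (i in idx) {
      store <- store + rain[i]
      ov <- max(0, store - paw)
      store <- store - ov
      demand <- fpar[i] * pet[i]
      supply <- .sim_const$extract_frac * store
      transp <- min(demand, supply)
      stress[i] <- if (demand > 0) transp / demand else 1
      evap <- min(.sim_const$evap_frac * (1 - fpar[i]) * pet[i], store - transp)
      store <- store - transp - evap
      storage_trace[i] <- store
      tot <- tot + c(rain[i], ov, transp, evap)
    }
    biomass_g <- sum(pot_growth * stress)
    stress_days <- sum(stress < 1 - 1e-9)
    final_w <- store
    budget <- c(tot, dstore = store - store0)
  }

  biomass_t_ha <- biomass_g * 0.01
  yield <- biomass_t_ha * cultivar$harvest_index / (1 - cultivar$standard_moisture)
  out <- tibble::tibble(
    yield_t_ha = yield, biomass_t_ha = biomass_t_ha,
    water_stress_days = as.integer(stress_days), season_length = as.integer(mat),
    maturity_doy = as.integer(w$doy[mat]), final_soil_water_mm = final_w,
    incomplete = incomplete,
    rain_mm = unname(budget["rain"]), overflow_mm = unname(budget["overflow"]),
    transpiration_mm = unname(budget["transp"]),
    evaporation_mm = unname(budget["evap"]),
    delta_storage_mm = unname(budget["dstore"])
  )
  if (daily && water_regime == "rainfed") {
    attr(out, "daily") <- tibble::tibble(
      day = seq_along(storage_trace), doy = w$doy[idx],
      storage_mm = storage_trace, stress = stress
    )
  }
  out
}

#' Soil water at sowing
#'
#' Either a fixed fraction of the soil's plant-available water capacity, or a
#' fallow spin-up: the bucket is run without a crop (rain in, overflow out,
#' bare-soil evaporation only) from the end of the previous season to sowing.
#'
#' @param mode `"fallow_spinup"` or `"fixed_fraction"`.
#' @param weather Daily weather for the fallow period's year (needs `doy`,
#'   `rain_mm`, and temperature columns for PET).
#' @param soil A [soil_profile()].
#' @param sowing_doy Sowing day of year; the spin-up runs over days
#'   `[start_doy, sowing_doy)`.
#' @param fraction Fraction of capacity for `"fixed_fraction"`, in `[0, 1]`.
#' @param start_doy First day of the fallow period (previous harvest).
#' @param initial_store_mm Bucket content at `start_doy` (default half
#'   capacity).
#' @return Plant-available soil water at sowing (mm).
#' @export
initialize_soil_water <- function(mode = c("fallow_spinup", "fixed_fraction"),
                                  weather = NULL, soil, sowing_doy = NULL,
                                  fraction = 0.5, start_doy = 1,
                                  initial_store_mm = 0.5 * soil$paw_capacity_mm) {
  mode <- match.arg(mode)
  if (mode == "fixed_fraction") {
    if (fraction < 0 || fraction > 1) abort("`fraction` must be in [0, 1].")
    return(fraction * soil$paw_capacity_mm)
  }
  assert_columns(weather, c("doy", "rain_mm"), "weather")
  w <- ensure_pet(weather)
  days <- w[w$doy >= start_doy & w$doy < sowing_doy, , drop = FALSE]
  paw <- soil$paw_capacity_mm
  store <- min(max(initial_store_mm, 0), paw)
  for (i in seq_len(nrow(days))) {
    store <- min(paw, store + days$rain_mm[i])
    evap <- min(.sim_const$evap_frac * days$pet_mm[i], store)
    store <- store - evap
  }
  store
}

#' Annual yield potential of a crop sequence
#'
#' Sums simulated grain yield over the sequence's crop slots within one
#' weather year, carrying soil water between seasons through a fallow
#' spin-up from each harvest to the next sowing.
#'
#' @param weather_year One year of daily weather.
#' @param sequence A [crop_sequence()].
#' @param soil A [soil_profile()].
#' @param water_regime `"irrigated"` or `"rainfed"`.
#' @param init_fraction Soil water fraction at the start of the year.
#' @return Annual yield (t ha-1 yr-1) with the per-slot results attached as
#'   attribute `"seasons"`. Errors if a slot would sow before the previous
#'   slot matures.
#' @export
annual_yield_potential <- function(weather_year, sequence, soil,
                                   water_regime = c("irrigated", "rainfed"),
                                   init_fraction = 0.5) {
  water_regime <- match.arg(water_regime)
  stopifnot(inherits(sequence, "crop_sequence"))
  w <- if (water_regime == "rainfed") ensure_pet(weather_year) else weather_year
  prev_end <- 1L
  store <- init_fraction * soil$paw_capacity_mm
  seasons <- vector("list", sequence$crops_per_year)
  for (s in seq_len(sequence$crops_per_year)) {
    sow <- sequence$sowing_days[s]
    if (s > 1 && sow <= prev_end) {
      abort(sprintf(
        "overlapping seasons: slot %d sows on day %d but slot %d matures on day %d.",
        s, sow, s - 1, prev_end
      ))
    }
    if (water_regime == "rainfed") {
      store <- initialize_soil_water(
        "fallow_spinup",
        weather = w, soil = soil, sowing_doy = sow,
        start_doy = prev_end, initial_store_mm = store
      )
    }
    res <- simulate_season(
      w, sequence$cultivars[[s]], soil, water_regime,
      initial_soil_water = store, sowing_doy = sow
    )
    prev_end <- res$maturity_doy
    store <- res$final_soil_water_mm
    res$slot <- s
    seasons[[s]] <- res
  }
  seasons <- dplyr::bind_rows(seasons)
  out <- sum(seasons$yield_t_ha)
  attr(out, "seasons") <- seasons
  out
}

#' Multi-year site yield potential, weighted over soils and sequences
#'
#' For each weather year, annual yield potential is computed for every
#' combination of soil type and crop sequence and averaged with weights
#' `soil share x sequence share` (each set of shares must sum to 1). The
#' result carries the yearly series, its mean, inter-annual CV, and the
#' share-weighted crop intensity.
#'
#' @param buffer A `buffer_zone` (or `NULL`; then `buffer_id`/`cz_id` are NA).
#' @param soils List of [soil_profile()]s with shares summing to 1.
#' @param sequences List of [crop_sequence()]s with shares summing to 1.
#' @param weather Multi-year daily weather (column `year`).
#' @param water_regime `"irrigated"` or `"rainfed"`.
#' @param init_fraction Soil water fraction at the start of each year.
#' @return One-row tibble (`site_yield`): `buffer_id`, `cz_id`,
#'   `yearly_yield` (list column), `mean_annual_yield`, `cv_pct`,
#'   `crop_intensity`, `irrigated_share`, `n_years`.
#' @export
site_yield_potential <- function(buffer, soils, sequences, weather,
                                 water_regime = c("irrigated", "rainfed"),
                                 init_fraction = 0.5) {
  water_regime <- match.arg(water_regime)
  soil_shares <- vapply(soils, `[[`, numeric(1), "area_share")
  seq_shares <- vapply(sequences, `[[`, numeric(1), "area_share")
  if (abs(sum(soil_shares) - 1) > 1e-6) abort("soil area shares must sum to 1.")
  if (abs(sum(seq_shares) - 1) > 1e-6) abort("sequence area shares must sum to 1.")
  w <- if (water_regime == "rainfed") ensure_pet(weather) else weather
  years <- sort(unique(w$year))
  yearly <- vapply(years, function(y) {
    wy <- w[w$year == y, , drop = FALSE]
    total <- 0
    for (i in seq_along(soils)) {
      for (j in seq_along(sequences)) {
        total <- total + soil_shares[i] * seq_shares[j] *
          as.numeric(annual_yield_potential(
            wy, sequences[[j]], soils[[i]], water_regime, init_fraction
          ))
      }
    }
    total
  }, numeric(1))

  irr_share <- NA_real_
  if (!is.null(buffer) && !is.null(buffer$area_by_regime) && buffer$harvested_area > 0 &&
    any(names(buffer$area_by_regime) %in% c("irrigated", "rainfed"))) {
    irr <- buffer$area_by_regime["irrigated"]
    irr_share <- unname(ifelse(is.na(irr), 0, irr)) / buffer$harvested_area
  }
  tibble::tibble(
    buffer_id = if (is.null(buffer)) NA_integer_ else buffer$station_id,
    cz_id = if (is.null(buffer)) NA_integer_ else buffer$cz_id,
    yearly_yield = list(setNames(yearly, years)),
    mean_annual_yield = mean(yearly),
    cv_pct = if (length(yearly) >= 2 && mean(yearly) > 0) {
      yield_stability_cv(yearly)
    } else {
      NA_real_
    },
    crop_intensity = sum(seq_shares * vapply(sequences, `[[`, numeric(1), "crops_per_year")),
    irrigated_share = irr_share,
    n_years = length(years)
  )
}
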