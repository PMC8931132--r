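# Independent oracles and fixture builders, written deliberately naively and
# kept free of the package's own code paths wherever they re-check one.

# Constant daily weather for closed-form checks.
const_weather <- function(days = 365, tmean = 25, diurnal = 10, srad = 16,
                          rain = 0, year = 1L, lat = 30) {
  w <- tibble::tibble(
    year = year, doy = seq_len(days),
    month = rep(1:12, times = c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))[seq_len(days)],
    tmin_c = tmean - diurnal / 2, tmax_c = tmean + diurnal / 2,
    srad_mj_m2 = srad, rain_mm = rain
  )
  attr(w, "lat") <- lat
  w
}

# Minimal buffer object for selection tests: cells given as integer ids with
# unit area unless stated.
toy_buffer <- function(station_id, cells, cz_id = 1L, area_per_cell = 1) {
  structure(
    list(
      station_id = station_id, row = 0L, col = 0L, cz_id = as.integer(cz_id),
      cells = tibble::tibble(
        row = 0L, col = as.integer(cells), cell = as.integer(cells),
        area_ha = area_per_cell
      ),
      harvested_area = length(cells) * area_per_cell,
      area_by_regime = c(total = length(cells) * area_per_cell),
      national_share = NA_real_
    ),
    class = "buffer_zone"
  )
}

# Brute-force greedy selection, recoded from the rules without reusing any
# package internals: explicit loops, explicit union bookkeeping.
oracle_select <- function(buffers, national_area, min_share = 0.01,
                          max_overlap = 0.20, coverage_target = 0.50) {
  areas <- sapply(buffers, function(b) b$harvested_area)
  ids <- sapply(buffers, function(b) b$station_id)
  ord <- order(-areas, ids)
  chosen <- integer(0)
  union_cells <- tibble::tibble(cell = integer(), area_ha = numeric())
  coverage <- 0
  for (i in ord) {
    if (coverage >= coverage_target) break
    b <- buffers[[i]]
    if (!(b$harvested_area / national_area > min_share)) next
    ok <- TRUE
    for (j in chosen) {
      shared <- sum(b$cells$cell %in% buffers[[j]]$cells$cell)
      if (shared / nrow(b$cells) >= max_overlap) {
        ok <- FALSE
        break
      }
    }
    if (!ok) next
    chosen <- c(chosen, i)
    new_cells <- b$cells[!(b$cells$cell %in% union_cells$cell), c("cell", "area_ha")]
    union_cells <- rbind(union_cells, new_cells)
    coverage <- sum(union_cells$area_ha) / national_area
  }
  list(ids = ids[chosen], coverage = coverage)
}

# Random candidate set on a 1-D cell line with controlled overlap structure.
random_candidates <- function(n = 6, n_cells = 60, area_per_cell = 1) {
  buffers <- lapply(seq_len(n), function(i) {
    start <- sample.int(n_cells - 12, 1)
    len <- sample(4:12, 1)
    toy_buffer(i, start:(start + len - 1), area_per_cell = area_per_cell)
  })
  list(buffers = buffers, national_area = n_cells * area_per_cell)
}

ensure_pet_for_test <- function(w) {
  w$pet_mm <- potential_evapotranspiration(w)
  w
}

# Random simulator scenario for the property suites.
random_scenario <- function() {
  params <- climate_params(
    mean_temp = runif(1, 14, 26), mean_temp_gradient = 0,
    seasonal_amplitude = runif(1, 0, 8), annual_rain = runif(1, 300, 2000),
    rain_days_fraction = runif(1, 0.2, 0.6), radiation_mean = runif(1, 12, 22),
    interannual_sd = runif(1, 0, 0.1), lat_top = runif(1, 5, 45)
  )
  w <- generate_weather(list(row = 0, col = 0), 1, params, sample.int(1e6, 1))
  cv <- cultivar(
    gdd_to_maturity = runif(1, 900, 1800), base_temp = runif(1, 5, 12),
    rue = runif(1, 1.5, 4), max_lai = runif(1, 3, 7),
    harvest_index = runif(1, 0.3, 0.55), standard_moisture = runif(1, 0, 0.2)
  )
  list(
    weather = w, cultivar = cv,
    soil = soil_profile(runif(1, 50, 250)),
    sowing = sample(30:150, 1),
    init_water = runif(1, 0, 250)
  )
}

# Engineered landscape where both change regions are guaranteed stations and
# the climate is spatially uniform; used by the parameter-recovery and
# crop-intensity experiments.
uniform_recovery_config <- function(seed, climate, ...) {
  ls_cfg <- landscape_config(
    grid_shape = c(24, 24), base_area_ha = 2500,
    urban_centers = list(list(cell = c(17, 12), strength = 60000)),
    contraction_radius = 2,
    expansion_region = list(rows = c(0, 4), cols = c(0, 23)),
    expansion_gain_ha = 60000, expansion_base_frac = 0.5,
    crop = "rice", water_regimes = "irrigated"
  )
  pipeline_config(
    landscape = ls_cfg, climate = climate,
    weather_years = 10, n_stations = 6, water_regime = "irrigated",
    seed = seed, ...
  )
}
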