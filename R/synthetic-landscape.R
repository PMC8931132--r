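#' Configure a synthetic cropland landscape
#'
#' Describes an equal-area lattice of grid cells (nominally 10 x 10 km, i.e.
#' 10 000 ha per cell) carrying harvested area of one staple crop, together
#' with the two spatial change processes the analysis targets: contraction of
#' harvested area around growing urban centers, and expansion into a frontier
#' region. Cell indexing is 0-based and row-major; row 0 is the northern edge.
#'
#' Harvested area is counted once per crop cycle, so a double-cropped cell can
#' legitimately carry more harvested hectares than its physical area; cell
#' values are therefore only constrained to be non-negative.
#'
#' @param grid_shape Integer vector `c(rows, cols)`.
#' @param cell_area_ha Physical cell area in hectares (default 10 000,
#'   matching a 10 x 10 km cell).
#' @param base_area_ha Mean baseline harvested area per cell (ha).
#' @param base_area_cv Lognormal coefficient of variation of the baseline
#'   across cells (spatial heterogeneity).
#' @param urban_centers List of urban centers, each `list(cell = c(row, col),
#'   strength = <total ha lost over the decade>)`.
#' @param contraction_radius Decay radius of the loss kernel, in cells (see
#'   [contraction_kernel()]).
#' @param expansion_region `list(rows = c(r0, r1), cols = c(c0, c1))`,
#'   inclusive cell ranges of the frontier region, or `NULL` for none.
#' @param expansion_gain_ha Total harvested-area gain (ha) spread uniformly
#'   over the expansion region between the two epochs.
#' @param expansion_base_frac Baseline harvested area in the expansion region
#'   as a fraction of `base_area_ha` (frontiers start with less cropland).
#' @param crop Crop name, `"rice"` or `"maize"`.
#' @param water_regimes Character subset of `c("irrigated", "rainfed")`.
#' @param irrigated_fraction Fraction of each cell's harvested area under
#'   irrigation when both regimes are present.
#' @param year_noise_sd Relative SD of the small year-to-year noise within an
#'   epoch (3-year windows are averaged downstream to damp exactly this).
#' @param epoch_years Years per epoch window (default 3).
#' @param seed Integer master seed; fixed seed implies byte-identical output.
#' @return A `landscape_config` list.
#' @export
landscape_config <- function(grid_shape = c(30, 30),
                             cell_area_ha = 10000,
                             base_area_ha = 2000,
                             base_area_cv = 0.3,
                             urban_centers = list(),
                             contraction_radius = 3,
                             expansion_region = NULL,
                             expansion_gain_ha = 0,
                             expansion_base_frac = 0.25,
                             crop = "rice",
                             water_regimes = "irrigated",
                             irrigated_fraction = 1,
                             year_noise_sd = 0.02,
                             epoch_years = 3,
                             seed = 1) {
  stopifnot(length(grid_shape) == 2, all(grid_shape >= 1))
  assert_scalar_number(cell_area_ha, "cell_area_ha", lower = 1e-9)
  assert_scalar_number(contraction_radius, "contraction_radius", lower = 0)
  assert_scalar_number(expansion_gain_ha, "expansion_gain_ha", lower = 0)
  assert_scalar_number(irrigated_fraction, "irrigated_fraction", 0, 1)
  assert_scalar_number(year_noise_sd, "year_noise_sd", lower = 0)
  if (!all(water_regimes %in% c("irrigated", "rainfed")) || length(water_regimes) < 1) {
    abort("`water_regimes` must be a non-empty subset of {irrigated, rainfed}.")
  }
  crop <- match.arg(crop, c("rice", "maize"))
  for (uc in urban_centers) {
    if (is.null(uc$cell) || length(uc$cell) != 2 || is.null(uc$strength)) {
      abort("each urban center must be list(cell = c(row, col), strength = <ha>)")
    }
  }
  structure(
    list(
      grid_shape = as.integer(grid_shape), cell_area_ha = cell_area_ha,
      base_area_ha = base_area_ha, base_area_cv = base_area_cv,
      urban_centers = urban_centers, contraction_radius = contraction_radius,
      expansion_region = expansion_region, expansion_gain_ha = expansion_gain_ha,
      expansion_base_frac = expansion_base_frac, crop = crop,
      water_regimes = water_regimes, irrigated_fraction = irrigated_fraction,
      year_noise_sd = year_noise_sd, epoch_years = as.integer(epoch_years),
      seed = as.integer(seed)
    ),
    class = "landscape_config"
  )
}

#' Per-cell harvested-area loss kernel around an urban center
#'
#' Loss decays exponentially with Euclidean distance from the center:
#' `w(d) = exp(-d / r)` on cells with `d <= 3 r` (support truncated at three
#' decay radii), normalised so the kernel sums exactly to the center's
#' `strength`. This closed form is part of the generator's contract: the total
#' loss applied between epochs equals `strength` unless capped by the
#' available baseline area in a cell.
#'
#' @param center `list(cell = c(row, col), strength = <ha>)`.
#' @param grid_shape Integer `c(rows, cols)`.
#' @param radius Decay radius in cells.
#' @return Tibble with `row`, `col`, `loss_ha`; `sum(loss_ha) == strength`
#'   (up to floating point) when the support fits in the grid.
#' @export
contraction_kernel <- function(center, grid_shape, radius) {
  if (radius <= 0) {
    return(tibble::tibble(row = integer(), col = integer(), loss_ha = numeric()))
  }
  r0 <- center$cell[1]
  c0 <- center$cell[2]
  support <- 3 * radius
  rows <- max(0, floor(r0 - support)):min(grid_shape[1] - 1, ceiling(r0 + support))
  cols <- max(0, floor(c0 - support)):min(grid_shape[2] - 1, ceiling(c0 + support))
  grid <- tidyr::expand_grid(row = rows, col = cols)
  d <- sqrt((grid$row - r0)^2 + (grid$col - c0)^2)
  keep <- d <= support
  w <- exp(-d[keep] / radius)
  tibble::tibble(
    row = as.integer(grid$row[keep]), col = as.integer(grid$col[keep]),
    loss_ha = center$strength * w / sum(w)
  )
}

expansion_cells <- function(region, grid_shape) {
  if (is.null(region)) {
    return(tibble::tibble(row = integer(), col = integer()))
  }
  rows <- max(0, region$rows[1]):min(grid_shape[1] - 1, region$rows[2])
  cols <- max(0, region$cols[1]):min(grid_shape[2] - 1, region$cols[2])
  tidyr::expand_grid(row = as.integer(rows), col = as.integer(cols))
}

#' Generate harvested-area grids for two epochs
#'
#' Produces yearly per-cell harvested-area grids for two epochs (default three
#' years each, emulating the 3-year windows around two census epochs a decade
#' apart). Epoch 2 differs from epoch 1 by loss concentrated around the
#' configured urban centers (exponential kernel, see [contraction_kernel()])
#' and a uniform gain over the expansion region; within an epoch, years differ
#' only by small multiplicative noise.
#'
#' @param config A [landscape_config()].
#' @return Tibble with columns `row`, `col`, `epoch` (1 or 2), `year` (index
#'   within epoch), `crop`, `water_regime`, `area_ha`, with the config
#'   attached as attribute `"config"`. All areas are non-negative.
#' @export
generate_area_grids <- function(config) {
  stopifnot(inherits(config, "landscape_config"))
  gs <- config$grid_shape
  exp_cells <- expansion_cells(config$expansion_region, gs)
  # reject overlapping change descriptors: contraction support may not
  # intersect the expansion region
  if (nrow(exp_cells) > 0 && length(config$urban_centers) > 0) {
    exp_ids <- cell_index(exp_cells$row, exp_cells$col, gs[2])
    for (uc in config$urban_centers) {
      k <- contraction_kernel(uc, gs, config$contraction_radius)
      if (any(cell_index(k$row, k$col, gs[2]) %in% exp_ids)) {
        abort("contraction kernel support overlaps the expansion region; adjust centers or region.")
      }
    }
  }

  cells <- tidyr::expand_grid(row = 0:(gs[1] - 1), col = 0:(gs[2] - 1))
  n <- nrow(cells)

  baseline <- withr::with_seed(child_seed(config$seed, "baseline"), {
    sdlog <- sqrt(log(1 + config$base_area_cv^2))
    config$base_area_ha * exp(rnorm(n, -sdlog^2 / 2, sdlog))
  })
  if (nrow(exp_cells) > 0) {
    in_exp <- cell_index(cells$row, cells$col, gs[2]) %in%
      cell_index(exp_cells$row, exp_cells$col, gs[2])
    baseline[in_exp] <- baseline[in_exp] * config$expansion_base_frac
  }

  # epoch-2 deterministic change field
  delta <- numeric(n)
  for (uc in config$urban_centers) {
    k <- contraction_kernel(uc, gs, config$contraction_radius)
    idx <- match(cell_index(k$row, k$col, gs[2]), cell_index(cells$row, cells$col, gs[2]))
    delta[idx] <- delta[idx] - k$loss_ha
  }
  if (nrow(exp_cells) > 0 && config$expansion_gain_ha > 0) {
    delta[in_exp] <- delta[in_exp] + config$expansion_gain_ha / nrow(exp_cells)
  }
  epoch2_base <- pmax(0, baseline + delta)

  yearly <- function(base, epoch) {
    purrr::map_dfr(seq_len(config$epoch_years), function(y) {
      noise <- withr::with_seed(
        child_seed(config$seed, sprintf("year-%d-%d", epoch, y)),
        rnorm(n, 0, config$year_noise_sd)
      )
      tibble::tibble(
        row = cells$row, col = cells$col, epoch = as.integer(epoch),
        year = as.integer(y), area_ha = pmax(0, base * (1 + noise))
      )
    })
  }
  out <- dplyr::bind_rows(yearly(baseline, 1), yearly(epoch2_base, 2))

  shares <- c(irrigated = config$irrigated_fraction, rainfed = 1 - config$irrigated_fraction)
  out <- purrr::map_dfr(config$water_regimes, function(wr) {
    share <- if (length(config$water_regimes) == 1) 1 else shares[[wr]]
    dplyr::mutate(out, crop = config$crop, water_regime = wr, area_ha = .data$area_ha * share)
  })
  out <- dplyr::select(
    out, "row", "col", "epoch", "year", "crop", "water_regime", "area_ha"
  )
  attr(out, "config") <- config
  out
}

#' Climate parameters for the synthetic weather generator
#'
#' Describes a smooth north--south climate: mean temperature increasing
#' southward (row 0 is north), a sinusoidal seasonal cycle peaking in northern
#' summer, rainfall with its own gradient, and year-level perturbations scaled
#' by a single inter-annual variability fraction.
#'
#' @param mean_temp Annual-mean temperature at row 0 (degrees C).
#' @param mean_temp_gradient Degrees C per row (positive = warmer southward).
#' @param seasonal_amplitude Half-range of the seasonal temperature cycle (C).
#' @param diurnal_range Fixed daily `tmax - tmin` (C).
#' @param annual_rain Expected annual rainfall at row 0 (mm).
#' @param rain_gradient mm of annual rain per row (positive = wetter southward).
#' @param rain_days_fraction Probability that any day is a rain day, in `[0, 1]`.
#' @param radiation_mean Mean daily global radiation (MJ m-2 d-1).
#' @param radiation_seasonal Relative seasonal modulation of radiation.
#' @param interannual_sd Fractional year-to-year variability: rainfall and
#'   radiation year factors are `N(1, sd)` (truncated at 0), and the yearly
#'   temperature offset is `N(0, 4 * sd)` degrees C. Zero makes every year
#'   identical.
#' @param lat_top Latitude of row 0 in degrees (used for extraterrestrial
#'   radiation in PET).
#' @param lat_per_row Degrees of latitude per row (negative moving south for a
#'   10-km cell is about -0.09).
#' @return A `climate_params` list.
#' @export
climate_params <- function(mean_temp = 12,
                           mean_temp_gradient = 0.4,
                           seasonal_amplitude = 8,
                           diurnal_range = 10,
                           annual_rain = 900,
                           rain_gradient = 10,
                           rain_days_fraction = 0.35,
                           radiation_mean = 16,
                           radiation_seasonal = 0.2,
                           interannual_sd = 0.05,
                           lat_top = 40,
                           lat_per_row = -0.09) {
  assert_scalar_number(annual_rain, "annual_rain", lower = 0)
  assert_scalar_number(rain_days_fraction, "rain_days_fraction", 0, 1)
  assert_scalar_number(interannual_sd, "interannual_sd", lower = 0)
  assert_scalar_number(radiation_mean, "radiation_mean", lower = 0)
  assert_scalar_number(diurnal_range, "diurnal_range", lower = 0)
  structure(
    list(
      mean_temp = mean_temp, mean_temp_gradient = mean_temp_gradient,
      seasonal_amplitude = seasonal_amplitude, diurnal_range = diurnal_range,
      annual_rain = annual_rain, rain_gradient = rain_gradient,
      rain_days_fraction = rain_days_fraction, radiation_mean = radiation_mean,
      radiation_seasonal = radiation_seasonal, interannual_sd = interannual_sd,
      lat_top = lat_top, lat_per_row = lat_per_row
    ),
    class = "climate_params"
  )
}

# Expected (noise-free) daily climatology for a given row: the deterministic
# part of generate_weather(). Shared by the weather generator and the per-cell
# climate-zoning metrics so zones reflect the same climate the stations see.
row_climatology <- function(row, params, doy = 1:365) {
  tmean <- params$mean_temp + params$mean_temp_gradient * row +
    params$seasonal_amplitude * cos(2 * pi * (doy - 200) / 365)
  srad <- params$radiation_mean *
    (1 + params$radiation_seasonal * cos(2 * pi * (doy - 200) / 365))
  annual_rain <- max(0, params$annual_rain + params$rain_gradient * row)
  list(tmean = tmean, srad = srad, annual_rain = annual_rain)
}

#' Generate multi-year daily weather for one station
#'
#' Daily weather is the row's deterministic climatology (seasonal sinusoid in
#' temperature and radiation) perturbed by year-level factors drawn with SD
#' `interannual_sd`, plus Bernoulli rain occurrence. All rain days within a
#' year carry the same depth, chosen so the expected annual total equals the
#' row's configured annual rainfall; rain days have radiation reduced by 20%.
#' With `interannual_sd = 0` and `rain_days_fraction = 1` every year is
#' identical. Years are 365 days (no leap days).
#'
#' @param station_cell `list(row =, col =)` or a one-row data frame with
#'   `row`/`col` (0-based).
#' @param years Number of years (>= 1).
#' @param params A [climate_params()].
#' @param seed Integer seed.
#' @return Tibble with `year`, `doy`, `month`, `tmin_c`, `tmax_c`,
#'   `srad_mj_m2`, `rain_mm`; attributes `row`, `col`, `lat`, `params`.
#'   Every day satisfies `tmax_c >= tmin_c`, `srad_mj_m2 > 0`, `rain_mm >= 0`.
#' @export
generate_weather <- function(station_cell, years, params, seed) {
  if (!is.numeric(years) || length(years) != 1 || years < 1) {
    abort("`years` must be >= 1.")
  }
  stopifnot(inherits(params, "climate_params"))
  years <- as.integer(years)
  row <- station_cell$row[1]
  col <- station_cell$col[1]

  doy <- 1:365
  clim <- row_climatology(row, params, doy)
  month_of_doy <- rep(1:12, times = c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))[doy]

  withr::with_seed(as.integer(seed), {
    temp_shift <- rnorm(years, 0, 4 * params$interannual_sd)
    rain_factor <- pmax(0, rnorm(years, 1, params$interannual_sd))
    rad_factor <- pmax(0.1, rnorm(years, 1, params$interannual_sd))
    out <- purrr::map_dfr(seq_len(years), function(y) {
      is_rain <- runif(365) < params$rain_days_fraction
      depth <- if (params$rain_days_fraction > 0) {
        clim$annual_rain * rain_factor[y] / (365 * params$rain_days_fraction)
      } else {
        0
      }
      tmean <- clim$tmean + temp_shift[y]
      tibble::tibble(
        year = as.integer(y), doy = doy, month = as.integer(month_of_doy),
        tmin_c = tmean - params$diurnal_range / 2,
        tmax_c = tmean + params$diurnal_range / 2,
        srad_mj_m2 = pmax(0.1, clim$srad * rad_factor[y] * ifelse(is_rain, 0.8, 1)),
        rain_mm = ifelse(is_rain, depth, 0)
      )
    })
    attr(out, "row") <- row
    attr(out, "col") <- col
    attr(out, "lat") <- params$lat_top + params$lat_per_row * row
    attr(out, "params") <- params
    out
  })
}

#' Place weather stations preferentially on high-area cells
#'
#' Samples `n` distinct cells without replacement with probability
#' proportional to harvested area, emulating the tendency of station networks
#' to cover the main production areas.
#'
#' @param area_grid Tibble with `row`, `col`, `area_ha` (one record per cell;
#'   aggregate over regimes/years first).
#' @param n Number of stations (>= 1; at most the number of non-zero cells).
#' @param seed Integer seed.
#' @return Tibble `station_id`, `row`, `col`.
#' @export
generate_stations <- function(area_grid, n, seed) {
  assert_columns(area_grid, c("row", "col", "area_ha"), "area_grid")
  if (n < 1) abort("`n` must be >= 1.")
  nonzero <- dplyr::filter(area_grid, .data$area_ha > 0)
  if (n > nrow(nonzero)) {
    abort(sprintf("cannot place %d distinct stations on %d non-zero cells.", n, nrow(nonzero)))
  }
  withr::with_seed(as.integer(seed), {
    idx <- sample.int(nrow(nonzero), n, replace = FALSE, prob = nonzero$area_ha)
  })
  tibble::tibble(
    station_id = seq_len(n),
    row = as.integer(nonzero$row[idx]), col = as.integer(nonzero$col[idx])
  )
}

#' Generate dominant soil types per buffer
#'
#' Each buffer receives its 2--3 dominant soil types with plant-available
#' water capacities drawn uniformly on `paw_range` and area shares that sum
#' exactly to one.
#'
#' @param buffer_count Number of buffers.
#' @param seed Integer seed.
#' @param n_soils Candidate numbers of soils per buffer (default `2:3`).
#' @param paw_range Range of plant-available water capacity (mm).
#' @return Tibble `buffer_id`, `soil_id`, `paw_capacity_mm`, `area_share`.
#' @export
generate_soils <- function(buffer_count, seed, n_soils = 2:3, paw_range = c(50, 250)) {
  stopifnot(buffer_count >= 1, all(n_soils >= 1))
  withr::with_seed(as.integer(seed), {
    purrr::map_dfr(seq_len(buffer_count), function(b) {
      k <- if (length(n_soils) == 1) n_soils else sample(n_soils, 1)
      w <- rexp(k) + 0.1 # bounded away from 0 so every share is material
      tibble::tibble(
        buffer_id = b, soil_id = seq_len(k),
        paw_capacity_mm = runif(k, paw_range[1], paw_range[2]),
        area_share = w / sum(w)
      )
    })
  })
}
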