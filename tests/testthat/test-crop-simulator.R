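test_that("unstressed season yield equals the closed-form radiation sum", {
  # constant weather on the thermal optimum, canopy forced to full cover
  cv <- cultivar(
    gdd_to_maturity = 1500, base_temp = 10, rue = 3, max_lai = 1e4,
    harvest_index = 0.5, standard_moisture = 0.155,
    t_opt_lo = 20, t_opt_hi = 30, t_lethal = 42
  )
  w <- const_weather(200, tmean = 25, srad = 16)
  soil <- soil_profile(150)
  res <- simulate_season(w, cv, soil, "irrigated", sowing_doy = 1)
  n_days <- ceiling(1500 / 15) # daily GDD = 25 - 10
  expected <- 0.5 * 3 * (0.5 * 16) * n_days * 0.01 / (1 - 0.155)
  expect_equal(res$yield_t_ha, expected, tolerance = 1e-9)
  expect_equal(res$season_length, n_days)
  expect_equal(
    res$yield_t_ha, res$biomass_t_ha * cv$harvest_index / (1 - cv$standard_moisture)
  )
})

test_that("zero radiation gives zero biomass and yield", {
  cv <- cultivar_maize()
  w <- const_weather(250, tmean = 25, srad = 0)
  res <- simulate_season(w, cv, soil_profile(100), "irrigated")
  expect_equal(res$yield_t_ha, 0)
  expect_equal(res$biomass_t_ha, 0)
})

test_that("abundant rain makes rainfed equal irrigated", {
  cv <- cultivar_rice()
  w <- const_weather(300, tmean = 26, srad = 15, rain = 60)
  soil <- soil_profile(200)
  irr <- simulate_season(w, cv, soil, "irrigated", sowing_doy = 10)
  rf <- simulate_season(w, cv, soil, "rainfed", initial_soil_water = 200, sowing_doy = 10)
  expect_equal(rf$yield_t_ha, irr$yield_t_ha, tolerance = 1e-12)
  expect_equal(rf$water_stress_days, 0L)
})

test_that("a season that cannot reach maturity is flagged and warned", {
  cv <- cultivar_rice(gdd_to_maturity = 4000)
  w <- const_weather(120, tmean = 20)
  expect_warning(
    res <- simulate_season(w, cv, soil_profile(100), "irrigated"),
    "incomplete"
  )
  expect_true(res$incomplete)
  expect_gt(res$yield_t_ha, 0)
})

test_that("soil water initialization follows fixed fractions and the fallow bucket", {
  soil <- soil_profile(180)
  expect_equal(initialize_soil_water("fixed_fraction", soil = soil, fraction = 1), 180)
  expect_equal(initialize_soil_water("fixed_fraction", soil = soil, fraction = 0), 0)
  expect_error(
    initialize_soil_water("fixed_fraction", soil = soil, fraction = 1.2),
    "0, 1"
  )

  # dry fallow: strictly decreasing store that matches a step-by-step oracle
  w <- const_weather(150, tmean = 24, rain = 0)
  w$pet_mm <- potential_evapotranspiration(w)
  got <- initialize_soil_water(
    "fallow_spinup",
    weather = w, soil = soil, sowing_doy = 100,
    start_doy = 20, initial_store_mm = 120
  )
  store <- 120
  for (i in 20:99) {
    store <- min(180, store + w$rain_mm[i])
    store <- store - min(0.5 * w$pet_mm[i], store)
  }
  expect_equal(got, store, tolerance = 1e-9)
  expect_lt(got, 120)
})

test_that("annual yield sums seasons and rejects overlap", {
  cv <- cultivar(
    gdd_to_maturity = 1000, base_temp = 10, rue = 3, max_lai = 5,
    harvest_index = 0.5, standard_moisture = 0.14,
    t_opt_lo = 20, t_opt_hi = 30, t_lethal = 42
  )
  w <- const_weather(365, tmean = 25, srad = 16)
  soil <- soil_profile(150)
  single <- crop_sequence(50, cv)
  one <- annual_yield_potential(w, single, soil, "irrigated")
  season <- simulate_season(w, cv, soil, "irrigated", sowing_doy = 50)
  expect_equal(as.numeric(one), season$yield_t_ha)

  # identical constant forcing: a two-slot sequence doubles the yield exactly
  double <- crop_sequence(c(50, 200), cv)
  two <- annual_yield_potential(w, double, soil, "irrigated")
  expect_equal(as.numeric(two), 2 * season$yield_t_ha, tolerance = 1e-12)
  expect_equal(nrow(attr(two, "seasons")), 2)

  clash <- crop_sequence(c(50, 80), cv) # slot 2 sows before slot 1 matures
  expect_error(annual_yield_potential(w, clash, soil, "irrigated"), "overlapping")
})

test_that("site yields are share-weighted over soils and sequences", {
  cv <- cultivar_rice()
  params <- climate_params(mean_temp = 20, mean_temp_gradient = 0)
  w <- generate_weather(list(row = 0, col = 0), 3, params, 77)
  s1 <- soil_profile(80, 1)
  seq1 <- list(crop_sequence(100, cv))
  site <- site_yield_potential(NULL, list(s1), seq1, w, "rainfed")
  yearly <- site$yearly_yield[[1]]
  for (y in 1:3) {
    expect_equal(
      unname(yearly[y]),
      as.numeric(annual_yield_potential(
        ensure_pet_for_test(w[w$year == y, ]), seq1[[1]], s1, "rainfed"
      ))
    )
  }
  expect_equal(site$mean_annual_yield, mean(yearly))
  expect_equal(site$crop_intensity, 1)

  # two soils, equal shares: per-year mean of the two single-soil series
  sa <- soil_profile(60, 0.5)
  sb <- soil_profile(220, 0.5)
  both <- site_yield_potential(NULL, list(sa, sb), seq1, w, "rainfed")
  ya <- site_yield_potential(NULL, list(soil_profile(60, 1)), seq1, w, "rainfed")$yearly_yield[[1]]
  yb <- site_yield_potential(NULL, list(soil_profile(220, 1)), seq1, w, "rainfed")$yearly_yield[[1]]
  expect_equal(both$yearly_yield[[1]], (ya + yb) / 2, tolerance = 1e-12)

  # 3 soils x 2 sequences with random shares: brute-force combination oracle
  set.seed(4)
  sw <- rexp(3)
  sw <- sw / sum(sw)
  qw <- rexp(2)
  qw <- qw / sum(qw)
  soils <- list(
    soil_profile(70, sw[1]), soil_profile(140, sw[2]), soil_profile(210, sw[3])
  )
  seqs <- list(
    crop_sequence(90, cv, area_share = qw[1]),
    crop_sequence(110, cv, area_share = qw[2])
  )
  got <- site_yield_potential(NULL, soils, seqs, w, "rainfed")$yearly_yield[[1]]
  wp <- ensure_pet_for_test(w)
  oracle <- sapply(1:3, function(y) {
    wy <- wp[wp$year == y, ]
    total <- 0
    for (i in 1:3) {
      for (j in 1:2) {
        total <- total + sw[i] * qw[j] * as.numeric(
          annual_yield_potential(wy, seqs[[j]], soils[[i]], "rainfed")
        )
      }
    }
    total
  })
  expect_equal(unname(got), oracle, tolerance = 1e-9)

  bad <- list(soil_profile(70, 0.6), soil_profile(140, 0.6))
  expect_error(site_yield_potential(NULL, bad, seq1, w, "rainfed"), "sum to 1")
})

test_that("dominance, capacity monotonicity, RUE linearity and water balance hold", {
  set.seed(8)
  n <- 150
  for (i in seq_len(n)) {
    sc <- random_scenario()
    irr <- suppressWarnings(simulate_season(
      sc$weather, sc$cultivar, sc$soil, "irrigated",
      initial_soil_water = sc$init_water, sowing_doy = sc$sowing
    ))
    rf <- suppressWarnings(simulate_season(
      sc$weather, sc$cultivar, sc$soil, "rainfed",
      initial_soil_water = sc$init_water, sowing_doy = sc$sowing, daily = TRUE
    ))
    expect_gte(irr$yield_t_ha, rf$yield_t_ha - 1e-9)

    wetter <- soil_profile(sc$soil$paw_capacity_mm * 1.5)
    rf2 <- suppressWarnings(simulate_season(
      sc$weather, sc$cultivar, wetter, "rainfed",
      initial_soil_water = sc$init_water, sowing_doy = sc$sowing
    ))
    expect_gte(rf2$yield_t_ha, rf$yield_t_ha - 1e-9)

    cv2 <- sc$cultivar
    cv2$rue <- 2 * cv2$rue
    irr2 <- suppressWarnings(simulate_season(
      sc$weather, cv2, sc$soil, "irrigated",
      initial_soil_water = sc$init_water, sowing_doy = sc$sowing
    ))
    expect_equal(irr2$biomass_t_ha, 2 * irr$biomass_t_ha, tolerance = 1e-9)

    resid <- rf$rain_mm - rf$overflow_mm - rf$transpiration_mm -
      rf$evaporation_mm - rf$delta_storage_mm
    expect_lt(abs(resid), 1e-6)
    trace <- attr(rf, "daily")
    expect_true(all(trace$storage_mm >= -1e-9))
    expect_true(all(trace$storage_mm <= sc$soil$paw_capacity_mm + 1e-9))
  }
})
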