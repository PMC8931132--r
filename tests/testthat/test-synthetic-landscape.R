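test_that("null-change config yields epoch difference of noise only, zero without noise", {
  cfg <- landscape_config(grid_shape = c(10, 10), year_noise_sd = 0, seed = 3)
  g <- generate_area_grids(cfg)
  e1 <- epoch_mean(dplyr::filter(g, epoch == 1))
  e2 <- epoch_mean(dplyr::filter(g, epoch == 2))
  expect_equal(e2$area_ha, e1$area_ha, tolerance = 1e-12)

  cfg2 <- landscape_config(grid_shape = c(10, 10), year_noise_sd = 0.02, seed = 3)
  g2 <- generate_area_grids(cfg2)
  d <- net_change(
    epoch_mean(dplyr::filter(g2, epoch == 2)),
    epoch_mean(dplyr::filter(g2, epoch == 1))
  )
  e1b <- epoch_mean(dplyr::filter(g2, epoch == 1))
  expect_lt(max(abs(d$delta_ha) / e1b$area_ha), 0.1)
})

test_that("area grids are byte-identical under a fixed seed and non-negative", {
  cfg <- landscape_config(
    grid_shape = c(12, 12),
    urban_centers = list(list(cell = c(8, 6), strength = 30000)),
    contraction_radius = 2,
    expansion_region = list(rows = c(0, 1), cols = c(0, 11)),
    expansion_gain_ha = 20000, seed = 11
  )
  g1 <- generate_area_grids(cfg)
  g2 <- generate_area_grids(cfg)
  expect_identical(serialize(g1, NULL), serialize(g2, NULL))
  expect_true(all(g1$area_ha >= 0))
})

test_that("contraction kernel integrates to the configured strength and shows up in the epochs", {
  center <- list(cell = c(10, 10), strength = 40000)
  k <- contraction_kernel(center, c(21, 21), radius = 2)
  expect_equal(sum(k$loss_ha), 40000)
  expect_true(all(k$loss_ha > 0))
  # loss decays with distance
  d <- sqrt((k$row - 10)^2 + (k$col - 10)^2)
  expect_true(all(diff(k$loss_ha[order(d)]) <= 1e-9))

  cfg <- landscape_config(
    grid_shape = c(21, 21), base_area_ha = 8000, base_area_cv = 0.1,
    urban_centers = list(center), contraction_radius = 2, seed = 5
  )
  g <- generate_area_grids(cfg)
  delta <- net_change(
    epoch_mean(dplyr::filter(g, epoch == 2)),
    epoch_mean(dplyr::filter(g, epoch == 1))
  )
  expect_lt(abs(sum(delta$delta_ha) - (-40000)) / 40000, 0.1)
})

test_that("overlapping contraction and expansion descriptors are rejected", {
  cfg <- landscape_config(
    grid_shape = c(12, 12),
    urban_centers = list(list(cell = c(2, 2), strength = 1000)),
    contraction_radius = 2,
    expansion_region = list(rows = c(0, 4), cols = c(0, 11)),
    expansion_gain_ha = 5000
  )
  expect_error(generate_area_grids(cfg), "overlaps")
})

test_that("degenerate weather variance makes every year identical", {
  params <- climate_params(
    seasonal_amplitude = 0, interannual_sd = 0, rain_days_fraction = 1
  )
  w <- generate_weather(list(row = 5, col = 5), 3, params, 42)
  y1 <- dplyr::filter(w, year == 1)[, -1]
  for (y in 2:3) {
    expect_equal(dplyr::filter(w, year == y)[, -1], y1)
  }
})

test_that("annual rainfall matches the configured total in the long run", {
  params <- climate_params(annual_rain = 800, rain_gradient = 0, interannual_sd = 0.1)
  w <- generate_weather(list(row = 0, col = 0), 200, params, 9)
  annual <- tapply(w$rain_mm, w$year, sum)
  expect_lt(abs(mean(annual) - 800) / 800, 0.05)
})

test_that("weather is physically consistent and the thermal gradient is monotone", {
  params <- climate_params(mean_temp_gradient = 0.4)
  w_north <- generate_weather(list(row = 0, col = 0), 2, params, 1)
  w_south <- generate_weather(list(row = 20, col = 0), 2, params, 1)
  expect_true(all(w_north$tmax_c >= w_north$tmin_c))
  expect_true(all(w_north$srad_mj_m2 > 0))
  expect_true(all(w_north$rain_mm >= 0))
  # northern row (row 0) is cooler when temperature increases southward
  expect_lt(mean(w_north$tmin_c + w_north$tmax_c), mean(w_south$tmin_c + w_south$tmax_c))
  expect_error(generate_weather(list(row = 0, col = 0), 0, params, 1), ">= 1")
})

test_that("stations sample distinct cells proportional to area", {
  grid1 <- tibble::tibble(row = 0L, col = 0:3, area_ha = c(100, 0, 0, 0))
  expect_error(generate_stations(grid1, 2, 1), "distinct")
  uniform <- tidyr::expand_grid(row = 0:9, col = 0:9) |>
    dplyr::mutate(area_ha = 10)
  expect_identical(
    generate_stations(uniform, 20, 7),
    generate_stations(uniform, 20, 7)
  )
  # uniform grid: aggregated station counts consistent with uniformity
  counts <- integer(100)
  set.seed(99)
  for (i in 1:200) {
    s <- generate_stations(uniform, 30, sample.int(1e6, 1))
    idx <- s$row * 10 + s$col + 1
    counts[idx] <- counts[idx] + 1
  }
  expect_gt(stats::chisq.test(counts)$p.value, 0.01)
})

test_that("soil generation respects shares and capacity bounds", {
  one <- generate_soils(3, seed = 1, n_soils = 1)
  expect_true(all(one$area_share == 1))
  big <- purrr::map_dfr(1:40, function(s) {
    dplyr::mutate(generate_soils(25, seed = s), seed = s)
  }) |>
    dplyr::mutate(buffer_id = paste(seed, buffer_id))
  share_sums <- tapply(big$area_share, big$buffer_id, sum)
  expect_true(all(abs(share_sums - 1) < 1e-12))
  expect_true(all(big$paw_capacity_mm >= 50 & big$paw_capacity_mm <= 250))
  expect_true(all(big$area_share > 0 & big$area_share <= 1))
})
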