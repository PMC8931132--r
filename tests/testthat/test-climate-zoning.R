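test_that("growing degree days match closed forms and a brute-force oracle", {
  expect_equal(growing_degree_days(rep(25, 100), base_temp = 10), 1500)
  expect_equal(growing_degree_days(rep(5, 50), base_temp = 10), 0)
  expect_error(growing_degree_days(25, base_temp = 10, cap = 5), "cap")
  expect_error(growing_degree_days(numeric(0), 10), "empty")

  t <- 15 + 10 * sin(2 * pi * (1:365) / 365)
  oracle <- 0
  for (d in seq_along(t)) {
    oracle <- oracle + max(0, min(t[d], 30) - 8)
  }
  expect_equal(growing_degree_days(t, 8, cap = 30), oracle, tolerance = 1e-9)
  # additivity over disjoint periods
  expect_equal(
    growing_degree_days(t[1:100], 8) + growing_degree_days(t[101:365], 8),
    growing_degree_days(t, 8)
  )
})

test_that("temperature seasonality is the population SD of climatological monthly means", {
  w <- const_weather(365, tmean = 18)
  w$tmean_c <- 18
  expect_equal(temperature_seasonality(w), 0)

  # months alternate +5 / -5 around zero -> two-point population SD = 5
  w2 <- const_weather(365)
  w2$tmean_c <- ifelse(w2$month %% 2 == 1, 5, -5)
  expect_equal(temperature_seasonality(w2), 5)

  # sinusoid of amplitude A: SD close to A/sqrt(2), and exactly equal to an
  # independent monthly-mean computation
  a <- 7
  w3 <- const_weather(365)
  w3$tmean_c <- 20 + a * cos(2 * pi * (w3$doy - 200) / 365)
  monthly <- tapply(w3$tmean_c, w3$month, mean)
  oracle <- sqrt(mean((monthly - mean(monthly))^2))
  got <- temperature_seasonality(w3)
  expect_equal(got, oracle, tolerance = 1e-12)
  expect_equal(got, a / sqrt(2), tolerance = 0.02 * a)

  expect_error(temperature_seasonality(w3[1:100, ]), "incomplete|12 months")
})

test_that("Hargreaves PET reproduces an independent hand calculation", {
  # 20 degrees south, 3 September (doy 246): hand-computed solar geometry
  # gives Ra = 32.1940 MJ m-2 d-1; with tmax 28, tmin 16 the Hargreaves
  # equation gives 4.1652 mm.
  expect_equal(extraterrestrial_radiation(-20, 246), 32.1940, tolerance = 1e-4)
  day <- tibble::tibble(doy = 246, tmin_c = 16, tmax_c = 28)
  expect_equal(
    potential_evapotranspiration(day, lat = -20), 4.16521,
    tolerance = 1e-4
  )
  # polar winter: essentially no extraterrestrial radiation, PET -> 0
  dark <- tibble::tibble(doy = 355, tmin_c = -20, tmax_c = -10)
  expect_lt(potential_evapotranspiration(dark, lat = 80), 1e-6)
  # monotone in the diurnal temperature range at fixed mean
  narrow <- tibble::tibble(doy = 100, tmin_c = 18, tmax_c = 22)
  wide <- tibble::tibble(doy = 100, tmin_c = 14, tmax_c = 26)
  expect_gt(
    potential_evapotranspiration(wide, lat = 20),
    potential_evapotranspiration(narrow, lat = 20)
  )
  bad <- tibble::tibble(doy = 1, tmin_c = 10, tmax_c = 5)
  expect_error(potential_evapotranspiration(bad, lat = 0), "tmax")
  expect_error(potential_evapotranspiration(narrow, lat = NULL), "latitude")
})

test_that("aridity index is the precip/PET ratio with scale consistency", {
  expect_equal(aridity_index(1500, 1500), 1.0)
  expect_equal(aridity_index(0, 1200), 0.0)
  expect_equal(aridity_index(600, 1500), 0.4)
  expect_equal(aridity_index(600 * 3.7, 1500 * 3.7), 0.4)
  expect_error(aridity_index(500, 0), "> 0")
})

test_that("zone delimitation matches a brute-force distinct-triple oracle", {
  flat <- tidyr::expand_grid(row = 0:4, col = 0:4) |>
    dplyr::mutate(gdd = 4200, seasonality = 6, aridity = 0.8)
  z <- delimit_zones(flat)
  expect_equal(length(unique(z$zone_id)), 1)

  # one metric crossing one edge -> exactly two zones
  grad <- tidyr::expand_grid(row = 0:9, col = 0:2) |>
    dplyr::mutate(gdd = 500 + 100 * row, seasonality = 6, aridity = 0.8)
  z2 <- delimit_zones(grad)
  expect_equal(length(unique(z2$zone_id)), 2)

  set.seed(14)
  rnd <- tidyr::expand_grid(row = 0:11, col = 0:11) |>
    dplyr::mutate(
      gdd = runif(dplyr::n(), 0, 9000),
      seasonality = runif(dplyr::n(), 0, 22),
      aridity = runif(dplyr::n(), 0, 1.4)
    )
  edges <- zone_bin_defaults()
  z3 <- delimit_zones(rnd, edges)
  oracle <- unique(paste(
    findInterval(rnd$gdd, edges$gdd),
    findInterval(rnd$seasonality, edges$seasonality),
    findInterval(rnd$aridity, edges$aridity)
  ))
  expect_equal(length(unique(z3$zone_id)), length(oracle))

  # the partition is invariant under cell-order permutation
  perm <- rnd[sample.int(nrow(rnd)), ]
  z4 <- delimit_zones(perm, edges)
  joined <- dplyr::inner_join(
    dplyr::select(z3, row, col, a = zone_id),
    dplyr::select(z4, row, col, b = zone_id),
    by = c("row", "col")
  )
  expect_equal(joined$a, joined$b)

  expect_error(
    delimit_zones(rnd, list(gdd = c(5, 1), seasonality = 1:2, aridity = 1:2)),
    "increasing"
  )
})
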