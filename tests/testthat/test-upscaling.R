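site_row <- function(yield, balance, cz = 1L, flag = "contracting", id = 1L) {
  tibble::tibble(
    buffer_id = id, cz_id = cz, mean_annual_yield = yield,
    cv_pct = 10, crop_intensity = 1, irrigated_share = 1,
    net_balance = balance, flag = flag
  )
}

test_that("zone-level weighting uses absolute net balances", {
  one <- site_row(12.5, -4000)
  expect_equal(cz_weighted_yield(one), 12.5)
  two <- dplyr::bind_rows(site_row(10, -3000), site_row(14, -1000, id = 2L))
  expect_equal(cz_weighted_yield(two), 11.0)

  set.seed(2)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    d <- purrr::map_dfr(seq_len(n), function(j) {
      site_row(runif(1, 2, 18), -runif(1, 100, 9000), id = j)
    })
    oracle <- 0
    wsum <- 0
    for (j in seq_len(n)) {
      oracle <- oracle + abs(d$net_balance[j]) * d$mean_annual_yield[j]
      wsum <- wsum + abs(d$net_balance[j])
    }
    expect_equal(cz_weighted_yield(d), oracle / wsum, tolerance = 1e-12)
    # bounded by inputs; invariant under uniform weight rescaling
    expect_gte(cz_weighted_yield(d), min(d$mean_annual_yield) - 1e-12)
    expect_lte(cz_weighted_yield(d), max(d$mean_annual_yield) + 1e-12)
    scaled <- dplyr::mutate(d, net_balance = net_balance * 3.7)
    expect_equal(cz_weighted_yield(scaled), cz_weighted_yield(d), tolerance = 1e-12)
  }

  expect_error(cz_weighted_yield(site_row(10, 0)), "zero total weight")
  mixed <- dplyr::bind_rows(site_row(10, -100), site_row(12, 100, flag = "expanding", id = 2L))
  expect_error(cz_weighted_yield(mixed), "all be contracting or all expanding")
})

test_that("national weighting renormalises zone shares over zones present", {
  expect_equal(national_weighted_yield(c(`1` = 9.5), c(`1` = 0.3, `2` = 0.7)), 9.5)
  expect_equal(national_weighted_yield(c(`1` = 12, `2` = 16), c(`1` = 0.25, `2` = 0.25)), 14)
  set.seed(6)
  for (i in 1:20) {
    n <- sample(2:6, 1)
    v <- setNames(runif(n, 3, 18), seq_len(n))
    s <- setNames(runif(n, 0.05, 0.5), seq_len(n))
    oracle <- sum((s / sum(s)) * v)
    expect_equal(national_weighted_yield(v, s), oracle, tolerance = 1e-12)
  }
  expect_error(national_weighted_yield(numeric(0), c(`1` = 1)), "no climate zones")
  expect_error(national_weighted_yield(c(`9` = 5), c(`1` = 1)), "positive share")
})

test_that("the yield ratio behaves like a ratio", {
  expect_equal(national_yield_ratio(10, 10), 1.0)
  expect_equal(
    national_yield_ratio(12.3, 8.1) * national_yield_ratio(8.1, 12.3), 1,
    tolerance = 1e-12
  )
  expect_error(national_yield_ratio(10, 0), "> 0")
})

test_that("yield stability is the sample CV in percent", {
  expect_equal(yield_stability_cv(rep(7.7, 12)), 0)
  expect_equal(yield_stability_cv(c(8, 12)), 100 * 2 * sqrt(2) / 10, tolerance = 1e-12)
  set.seed(10)
  x <- runif(15, 5, 15)
  expect_equal(yield_stability_cv(x), 100 * sd(x) / mean(x))
  expect_error(yield_stability_cv(9), "2 years")
  expect_error(yield_stability_cv(c(-4, -6)), "> 0")
})

test_that("current yields average the most recent five years, area-weighted", {
  flat <- tidyr::expand_grid(year = 2006:2010, admin_unit = "a") |>
    dplyr::mutate(buffer_id = 1L, yield_t_ha = 1.8, area_weight = 1)
  expect_equal(current_yield_summary(flat)$current_yield_t_ha, 1.8)

  two <- dplyr::bind_rows(
    dplyr::mutate(flat, admin_unit = "a", yield_t_ha = 2),
    dplyr::mutate(flat, admin_unit = "b", yield_t_ha = 4)
  )
  expect_equal(current_yield_summary(two)$current_yield_t_ha, 3.0)

  # only the most recent 5 of 8 years count
  set.seed(3)
  tbl <- tidyr::expand_grid(year = 2003:2010, admin_unit = c("a", "b")) |>
    dplyr::mutate(
      buffer_id = 1L, yield_t_ha = runif(16, 1, 5),
      area_weight = rep(c(0.7, 0.3), 8)
    )
  got <- current_yield_summary(tbl, window = 5)$current_yield_t_ha
  recent <- tbl[tbl$year >= 2006, ]
  ya <- mean(recent$yield_t_ha[recent$admin_unit == "a"])
  yb <- mean(recent$yield_t_ha[recent$admin_unit == "b"])
  expect_equal(got, (0.7 * ya + 0.3 * yb) / 1.0, tolerance = 1e-12)
})

test_that("reports are symmetric for symmetric inputs and flag empty sides", {
  sites <- dplyr::bind_rows(
    site_row(11, -5000, cz = 1L, flag = "contracting", id = 1L),
    site_row(11, 5000, cz = 1L, flag = "expanding", id = 2L)
  )
  rep1 <- build_report(sites, c(`1` = 1))
  expect_equal(rep1$ratio, 1.0)
  expect_equal(
    rep1$sides$yield_t_ha[1], rep1$sides$yield_t_ha[2]
  )
  expect_s3_class(tidy(rep1), "tbl_df")
  expect_equal(nrow(tidy(rep1)), 2)
  expect_equal(glance(rep1)$yield_ratio_1dp, 1.0)

  lone <- site_row(11, -5000)
  rep2 <- build_report(lone, c(`1` = 1))
  expect_false(rep2$ratio_defined)
  expect_true(is.na(rep2$ratio))

  # swapping sides inverts the ratio
  asym <- dplyr::bind_rows(
    site_row(15, -5000, flag = "contracting"),
    site_row(10, 4000, flag = "expanding", id = 2L)
  )
  fwd <- build_report(asym, c(`1` = 1))
  swapped <- dplyr::mutate(
    asym,
    flag = ifelse(flag == "contracting", "expanding", "contracting")
  )
  bwd <- build_report(swapped, c(`1` = 1))
  expect_equal(fwd$ratio, 1 / bwd$ratio, tolerance = 1e-12)
})
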