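#' Balance-weighted mean yield within a climate zone
#'
#' Sites of one side (contracting or expanding) within one climate zone are
#' averaged with weights equal to the absolute net area balance of their
#' buffers: a site that lost (or gained) more cropland counts for more.
#' Absolute balances keep the weights positive on both sides.
#'
#' @param sites Tibble with at least `mean_annual_yield` and `net_balance`;
#'   all rows should share `cz_id` and `flag` (checked when present).
#' @param value Column to aggregate (default `mean_annual_yield`); used to
#'   aggregate crop intensity, CV, etc. the same way.
#' @return Weighted mean (t ha-1 for yields).
#' @export
cz_weighted_yield <- function(sites, value = "mean_annual_yield") {
  assert_columns(sites, c(value, "net_balance"), "sites")
  if (nrow(sites) < 1) abort("at least one site is required.")
  if ("cz_id" %in% names(sites) && length(unique(sites$cz_id)) != 1) {
    abort("sites must share one climate zone; aggregate per zone first.")
  }
  if ("flag" %in% names(sites)) {
    fl <- unique(as.character(sites$flag))
    if (length(fl) != 1 || !fl %in% c("contracting", "expanding")) {
      abort("sites must all be contracting or all expanding.")
    }
  }
  w <- abs(sites$net_balance)
  if (sum(w) <= 0) abort("zero total weight: all net balances are zero.")
  sum(w * sites[[value]]) / sum(w)
}

#' National mean from per-zone values and zone area shares
#'
#' Share-weighted mean over the climate zones present, with shares
#' renormalised over those zones (a side of the comparison rarely touches
#' every zone).
#'
#' @param cz_values Named numeric vector of per-zone values (names = zone id).
#' @param cz_area_shares Named numeric vector of national area share per zone.
#' @return National weighted mean.
#' @export
national_weighted_yield <- function(cz_values, cz_area_shares) {
  if (length(cz_values) == 0) abort("no climate zones to aggregate.")
  shares <- cz_area_shares[names(cz_values)]
  if (any(is.na(shares)) || any(shares <= 0)) {
    abort("every zone in `cz_values` needs a positive share in `cz_area_shares`.")
  }
  shares <- shares / sum(shares)
  sum(shares * cz_values)
}

#' National yield ratio
#'
#' The headline statistic: yield of contracting (converted) cropland divided
#' by yield of expanding (new) cropland. A ratio above one means the new land
#' is less productive than the land lost, so proportionally more land is
#' needed to replace each hectare converted. Reported at one decimal in
#' tables; full precision is retained here.
#'
#' @param contracting_yield,expanding_yield National weighted annual yield
#'   potential (t ha-1) of each side; `expanding_yield` must be > 0.
#' @return Dimensionless ratio.
#' @examples
#' round(national_yield_ratio(15.2, 11.8), 1) # 1.3
#' @export
national_yield_ratio <- function(contracting_yield, expanding_yield) {
  if (!is.finite(expanding_yield) || expanding_yield <= 0) {
    abort("`expanding_yield` must be > 0.")
  }
  contracting_yield / expanding_yield
}

#' Inter-annual yield stability (CV)
#'
#' Sample standard deviation of the yearly annual-yield series divided by its
#' mean, in percent. Sample (n - 1) SD is used because the series are short
#' (10--15 years).
#'
#' @param yearly_series Numeric vector of annual yields, length >= 2 with
#'   positive mean.
#' @return CV in percent.
#' @examples
#' yield_stability_cv(c(8, 12)) # 28.28...
#' @export
yield_stability_cv <- function(yearly_series) {
  if (length(yearly_series) < 2) abort("need at least 2 years for a CV.")
  m <- mean(yearly_series)
  if (!is.finite(m) || m <= 0) abort("mean yield must be > 0 for a CV.")
  100 * stats::sd(yearly_series) / m
}

#' Current-yield summary per buffer from administrative statistics
#'
#' Mean reported yield over the most recent `window` years, area-weighted
#' over the administrative units intersecting each buffer. The short window
#' avoids biasing current yields with technology-adoption trends.
#'
#' @param admin_yields Tibble with `buffer_id`, `admin_unit`, `year`,
#'   `yield_t_ha`, `area_weight`.
#' @param window Number of most recent years (default 5).
#' @return Tibble `buffer_id`, `current_yield_t_ha`, `n_units`, `years_used`.
#' @export
current_yield_summary <- function(admin_yields, window = 5) {
  assert_columns(
    admin_yields, c("buffer_id", "admin_unit", "year", "yield_t_ha", "area_weight"),
    "admin_yields"
  )
  if (window < 1) abort("`window` must be >= 1.")
  admin_yields |>
    dplyr::group_by(.data$buffer_id) |>
    dplyr::group_modify(function(d, key) {
      years <- sort(unique(d$year), decreasing = TRUE)
      use <- head(years, window)
      if (length(use) == 0) abort("empty year window for a buffer.")
      per_unit <- d |>
        dplyr::filter(.data$year %in% use) |>
        dplyr::group_by(.data$admin_unit) |>
        dplyr::summarise(
          yield = mean(.data$yield_t_ha),
          w = mean(.data$area_weight), .groups = "drop"
        )
      tibble::tibble(
        current_yield_t_ha = sum(per_unit$w * per_unit$yield) / sum(per_unit$w),
        n_units = nrow(per_unit),
        years_used = length(use)
      )
    }) |>
    dplyr::ungroup()
}
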