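#' Assemble the national yield-ratio report
#'
#' Aggregates per-site results to climate-zone and national level separately
#' for the contracting and expanding sides, then forms the national yield
#' ratio. Within each zone, sites are averaged with absolute net-balance
#' weights ([cz_weighted_yield()]); across zones, values are averaged with
#' national area shares renormalised over the zones present on that side
#' ([national_weighted_yield()]). Crop intensity, irrigation proportion and
#' inter-annual CV are aggregated with the same two-stage weights, producing
#' a report with one column per side in the style of a national comparison
#' table.
#'
#' @param sites Tibble with `buffer_id`, `cz_id`, `mean_annual_yield`,
#'   `cv_pct`, `crop_intensity`, `irrigated_share`, `net_balance`, `flag`
#'   (factor/character: contracting, none, expanding). Sites flagged `none`
#'   are ignored.
#' @param cz_shares Named numeric vector of national harvested-area share per
#'   zone id (see [cz_area_shares()]).
#' @param crop Optional crop name stored in the report metadata.
#' @return A `yield_ratio_report`: list with `sides` (one row per side:
#'   national weighted yield, crop intensity, irrigation %, CV, site count,
#'   total absolute balance), `per_cz` (zone-level detail), `ratio`,
#'   `ratio_1dp`, `ratio_defined`, `crop`. If either side has no sites the
#'   report is still emitted with `ratio_defined = FALSE`.
#' @export
build_report <- function(sites, cz_shares, crop = NA_character_) {
  assert_columns(
    sites,
    c(
      "buffer_id", "cz_id", "mean_annual_yield", "cv_pct", "crop_intensity",
      "irrigated_share", "net_balance", "flag"
    ),
    "sites"
  )
  used <- dplyr::filter(sites, as.character(.data$flag) %in% c("contracting", "expanding"))
  metrics <- c(
    yield_t_ha = "mean_annual_yield", crop_intensity = "crop_intensity",
    irrigated_share = "irrigated_share", cv_pct = "cv_pct"
  )

  per_cz <- used |>
    dplyr::group_by(flag = as.character(.data$flag), .data$cz_id) |>
    dplyr::group_modify(function(d, key) {
      vals <- purrr::map_dbl(metrics, function(col) {
        if (all(is.na(d[[col]]))) NA_real_ else cz_weighted_yield(d, value = col)
      })
      tibble::tibble(
        !!!as.list(vals),
        n_sites = nrow(d), abs_balance = sum(abs(d$net_balance))
      )
    }) |>
    dplyr::ungroup()

  side_row <- function(side) {
    d <- dplyr::filter(per_cz, .data$flag == side)
    if (nrow(d) == 0) {
      return(tibble::tibble(
        side = side, yield_t_ha = NA_real_, crop_intensity = NA_real_,
        irrigated_pct = NA_real_, cv_pct = NA_real_,
        n_sites = 0L, n_cz = 0L, abs_balance = 0
      ))
    }
    nat <- purrr::map_dbl(names(metrics), function(col) {
      v <- setNames(d[[col]], d$cz_id)
      v <- v[!is.na(v)]
      if (length(v) == 0) NA_real_ else national_weighted_yield(v, cz_shares)
    })
    names(nat) <- names(metrics)
    tibble::tibble(
      side = side,
      yield_t_ha = nat[["yield_t_ha"]],
      crop_intensity = nat[["crop_intensity"]],
      irrigated_pct = 100 * nat[["irrigated_share"]],
      cv_pct = nat[["cv_pct"]],
      n_sites = sum(d$n_sites), n_cz = nrow(d), abs_balance = sum(d$abs_balance)
    )
  }
  sides <- dplyr::bind_rows(side_row("contracting"), side_row("expanding"))

  cy <- sides$yield_t_ha[sides$side == "contracting"]
  ey <- sides$yield_t_ha[sides$side == "expanding"]
  defined <- is.finite(cy) && is.finite(ey) && ey > 0
  ratio <- if (defined) national_yield_ratio(cy, ey) else NA_real_
  structure(
    list(
      sides = sides, per_cz = per_cz, ratio = ratio,
      ratio_1dp = if (defined) round(ratio, 1) else NA_real_,
      ratio_defined = defined, crop = crop
    ),
    class = "yield_ratio_report"
  )
}

#' @export
print.yield_ratio_report <- function(x, ...) {
  cat("National yield-ratio report")
  if (!is.na(x$crop)) cat(sprintf(" (%s)", x$crop))
  cat("\n\n")
  fmt <- function(v, digits = 1) ifelse(is.na(v), "-", formatC(v, format = "f", digits = digits))
  s <- x$sides
  rows <- rbind(
    c("Parameter", "Converted (contracting)", "New (expanding)"),
    c("Crop intensity (crops year-1)", fmt(s$crop_intensity)),
    c("Irrigation proportion (%)", fmt(s$irrigated_pct, 0)),
    c("Annual yield potential (t ha-1)", fmt(s$yield_t_ha)),
    c("Yield stability (CV in %)", fmt(s$cv_pct, 0)),
    c("Sites (buffers)", as.character(s$n_sites)),
    c("Climate zones", as.character(s$n_cz))
  )
  widths <- apply(nchar(rows), 2, max)
  for (i in seq_len(nrow(rows))) {
    padded <- mapply(formatC, rows[i, ], width = widths, MoreArgs = list(flag = "-"))
    cat(paste(padded, collapse = "  "), "\n")
  }
  cat(sprintf(
    "\nNational yield ratio: %s\n",
    if (x$ratio_defined) sprintf("%.1f (full precision %.4f)", x$ratio_1dp, x$ratio) else "undefined (one side empty)"
  ))
  invisible(x)
}

#' Tidy a yield-ratio report
#'
#' @param x A `yield_ratio_report`.
#' @param ... Unused.
#' @return One row per side with the national aggregates.
#' @method tidy yield_ratio_report
#' @export
tidy.yield_ratio_report <- function(x, ...) {
  x$sides
}

#' One-row summary of a yield-ratio report
#'
#' @param x A `yield_ratio_report`.
#' @param ... Unused.
#' @return Tibble with the national ratio and side yields.
#' @method glance yield_ratio_report
#' @export
glance.yield_ratio_report <- function(x, ...) {
  s <- x$sides
  tibble::tibble(
    yield_ratio = x$ratio, yield_ratio_1dp = x$ratio_1dp,
    ratio_defined = x$ratio_defined,
    contracting_yield_t_ha = s$yield_t_ha[s$side == "contracting"],
    expanding_yield_t_ha = s$yield_t_ha[s$side == "expanding"],
    n_sites = sum(s$n_sites)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
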