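#' Default crop-sequence assignment rule
#'
#' Assigns cropping systems by thermal regime: sites in warm zones (zonation
#' GDD, base 0 C capped at 30 C, above `double_crop_gdd`) carry a mix of
#' double and single cropping; cooler sites are single-cropped. Double-crop
#' slots use a shorter-duration cultivar (70% of the thermal time to
#' maturity), as is standard practice where two crops must fit in one year.
#'
#' @param double_crop_gdd Zonation GDD above which double cropping is
#'   feasible (C-days, default 7000).
#' @param double_share Share of harvested area under the double-crop sequence
#'   in warm zones (default 0.7, giving crop intensity 1.7 there).
#' @param single_sowing,double_sowings Sowing days of year.
#' @return A function `(zone_gdd, cv) -> list of crop_sequence` taking the
#'   site's zonation GDD and its default cultivar.
#' @export
default_sequence_rule <- function(double_crop_gdd = 7000, double_share = 0.7,
                                  single_sowing = 120, double_sowings = c(60, 200)) {
  force(double_crop_gdd)
  function(zone_gdd, cv) {
    if (is.finite(zone_gdd) && zone_gdd > double_crop_gdd) {
      short <- do.call(
        cultivar,
        utils::modifyList(
          unclass(cv),
          list(gdd_to_maturity = 0.7 * cv$gdd_to_maturity)
        )
      )
      list(
        crop_sequence(double_sowings, short, area_share = double_share),
        crop_sequence(single_sowing, cv, area_share = 1 - double_share)
      )
    } else {
      list(crop_sequence(single_sowing, cv, area_share = 1))
    }
  }
}

#' Configure the end-to-end pipeline
#'
#' Bundles every stage's parameters under one master seed, which fans out to
#' per-component child seeds ([child_seed()]) so each stage is independently
#' reproducible.
#'
#' @param landscape A [landscape_config()]; its seed is overwritten with a
#'   child of `seed`.
#' @param climate A [climate_params()].
#' @param selection A [selection_config()].
#' @param weather_years Years of daily weather per station (10--15 typical).
#' @param n_stations Stations to place.
#' @param water_regime Regime simulated: `"irrigated"` or `"rainfed"`.
#' @param cultivar Default [cultivar()]; `NULL` picks the crop's default.
#' @param sequence_rule Function `(zone_gdd, cultivar) -> list of
#'   crop_sequence`; see [default_sequence_rule()].
#' @param n_soils Soil types per buffer (passed to [generate_soils()]).
#' @param bin_edges Climate-zone bin edges (see [zone_bin_defaults()]).
#' @param expansion_cultivar Optional cultivar override for buffers flagged
#'   as expanding (new cropland regions may grow different genotypes).
#' @param contraction_sequences,expansion_sequences Optional fixed sequence
#'   lists overriding `sequence_rule` for buffers flagged as contracting or
#'   expanding, respectively.
#' @param ensure_region_stations Guarantee at least one station in each
#'   change region (emulating the addition of sites where the station network
#'   misses regions of change).
#' @param include_flagged After the coverage-based selection, append
#'   unselected candidate buffers whose net balance is significant. These
#'   additions sit outside the sequential rule (they mirror the practice of
#'   adding sites in regions of change that the standard network misses), so
#'   the pairwise overlap guarantee applies to the sequential phase only.
#' @param init_fraction Soil water fraction at the start of each year.
#' @param seed Master seed.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(landscape = landscape_config(),
                            climate = climate_params(),
                            selection = selection_config(),
                            weather_years = 10,
                            n_stations = 8,
                            water_regime = c("irrigated", "rainfed"),
                            cultivar = NULL,
                            sequence_rule = default_sequence_rule(),
                            n_soils = 2,
                            bin_edges = zone_bin_defaults(),
                            expansion_cultivar = NULL,
                            contraction_sequences = NULL,
                            expansion_sequences = NULL,
                            ensure_region_stations = TRUE,
                            include_flagged = TRUE,
                            init_fraction = 0.5,
                            seed = 1) {
  water_regime <- match.arg(water_regime)
  stopifnot(inherits(landscape, "landscape_config"), inherits(climate, "climate_params"))
  if (is.null(cultivar)) {
    cultivar <- if (landscape$crop == "rice") cultivar_rice() else cultivar_maize()
  }
  landscape$seed <- child_seed(seed, "landscape")
  structure(
    list(
      landscape = landscape, climate = climate, selection = selection,
      weather_years = as.integer(weather_years), n_stations = as.integer(n_stations),
      water_regime = water_regime, cultivar = cultivar,
      sequence_rule = sequence_rule, n_soils = n_soils, bin_edges = bin_edges,
      expansion_cultivar = expansion_cultivar,
      contraction_sequences = contraction_sequences,
      expansion_sequences = expansion_sequences,
      ensure_region_stations = isTRUE(ensure_region_stations),
      include_flagged = isTRUE(include_flagged),
      init_fraction = init_fraction, seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

# Which change region a cell belongs to: "contracting" (inside a contraction
# kernel's support), "expanding" (inside the expansion region) or "core".
station_region <- function(row, col, landscape) {
  gs <- landscape$grid_shape
  exp_cells <- expansion_cells(landscape$expansion_region, gs)
  if (nrow(exp_cells) > 0 &&
    any(exp_cells$row == row & exp_cells$col == col)) {
    return("expanding")
  }
  for (uc in landscape$urban_centers) {
    d <- sqrt((row - uc$cell[1])^2 + (col - uc$cell[2])^2)
    if (d <= 3 * landscape$contraction_radius) {
      return("contracting")
    }
  }
  "core"
}

#' Run the full analysis pipeline
#'
#' Orchestrates all stages on one synthetic landscape: area-grid generation,
#' climate zonation, station placement, buffer construction and sequential
#' selection, multi-year crop simulation per site, epoch change detection and
#' buffer flagging, and the national yield-ratio report. Everything is driven
#' by the config's master seed, so a fixed seed yields an identical result.
#'
#' @param config A [pipeline_config()].
#' @return A `pipeline_result` list: `report` ([build_report()]), `sites`,
#'   `buffers` (selected `buffer_zone`s), `stations`, `zones`, `cz_shares`,
#'   `change` ([classify_change()] grid), `selection` (trace tibble),
#'   `grids` (yearly area grids), `config`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  ls_cfg <- config$landscape
  seed <- config$seed

  grids <- generate_area_grids(ls_cfg)
  e1 <- epoch_mean(dplyr::filter(grids, .data$epoch == 1))
  e2 <- epoch_mean(dplyr::filter(grids, .data$epoch == 2))
  totals <- function(g) {
    g |>
      dplyr::group_by(.data$row, .data$col) |>
      dplyr::summarise(area_ha = sum(.data$area_ha), .groups = "drop")
  }
  e1_tot <- totals(e1)
  e2_tot <- totals(e2)
  delta <- net_change(e2_tot, e1_tot)
  change <- classify_change(delta, e1_tot)
  national_area <- sum(e1_tot$area_ha)

  metrics <- climate_metrics_grid(ls_cfg$grid_shape, config$climate)
  zones <- delimit_zones(metrics, config$bin_edges)
  czs <- cz_area_shares(e1_tot, zones)

  # stations weighted by the two-epoch mean area, so regions that only gain
  # cropland can still host a site
  w_grid <- dplyr::inner_join(
    dplyr::rename(e1_tot, a1 = "area_ha"), dplyr::rename(e2_tot, a2 = "area_ha"),
    by = c("row", "col")
  ) |>
    dplyr::mutate(area_ha = (.data$a1 + .data$a2) / 2) |>
    dplyr::select("row", "col", "area_ha")
  stations <- generate_stations(w_grid, config$n_stations, child_seed(seed, "stations"))

  if (config$ensure_region_stations) {
    stations <- ensure_stations(stations, ls_cfg, delta, w_grid)
  }
  stations$region <- vapply(
    seq_len(nrow(stations)),
    function(i) station_region(stations$row[i], stations$col[i], ls_cfg),
    character(1)
  )

  candidates <- lapply(seq_len(nrow(stations)), function(i) {
    make_clipped_buffer(
      stations[i, ], config$selection$radius_km, zones, e1,
      cell_km = 10, national_area = national_area
    )
  })

  sel <- select_buffers(candidates, national_area, config$selection, cz_shares = czs)
  selected <- sel$selected
  trace <- sel$trace

  balances <- vapply(candidates, function(b) buffer_net_balance(delta, b), numeric(1))
  names(balances) <- vapply(candidates, function(b) as.character(b$station_id), character(1))
  flags <- flag_significant(balances, ls_cfg$crop)

  if (config$include_flagged) {
    sel_ids <- vapply(selected, `[[`, integer(1), "station_id")
    extra_idx <- which(as.character(flags) != "none" &
      !vapply(candidates, function(b) b$station_id %in% sel_ids, logical(1)))
    extra_idx <- extra_idx[order(-abs(balances[extra_idx]))]
    for (i in extra_idx) {
      b <- candidates[[i]]
      selected[[length(selected) + 1]] <- b
      trace <- dplyr::bind_rows(trace, tibble::tibble(
        station_id = b$station_id, cz_id = b$cz_id,
        harvested_area = b$harvested_area,
        national_share = b$harvested_area / national_area,
        decision = "selected", reason = "significant_net_balance",
        coverage_after = national_coverage(selected, national_area)
      ))
    }
  }
  if (length(selected) == 0) {
    abort("pipeline produced no selected buffers; enlarge the landscape or relax selection.")
  }

  soils_tbl <- generate_soils(length(selected), child_seed(seed, "soils"), n_soils = config$n_soils)
  zone_gdd <- setNames(metrics$gdd, paste(metrics$row, metrics$col))

  sites <- purrr::map_dfr(seq_along(selected), function(b_idx) {
    b <- selected[[b_idx]]
    region <- stations$region[match(b$station_id, stations$station_id)]
    flag <- as.character(flags[[match(b$station_id, names(balances))]])
    cv <- if (flag == "expanding" && !is.null(config$expansion_cultivar)) {
      config$expansion_cultivar
    } else {
      config$cultivar
    }
    seqs <- if (flag == "contracting" && !is.null(config$contraction_sequences)) {
      config$contraction_sequences
    } else if (flag == "expanding" && !is.null(config$expansion_sequences)) {
      config$expansion_sequences
    } else {
      config$sequence_rule(zone_gdd[[paste(b$row, b$col)]], cv)
    }
    soils <- soils_tbl |>
      dplyr::filter(.data$buffer_id == b_idx) |>
      purrr::pmap(function(buffer_id, soil_id, paw_capacity_mm, area_share) {
        soil_profile(paw_capacity_mm, area_share)
      })
    weather <- generate_weather(
      list(row = b$row, col = b$col), config$weather_years, config$climate,
      child_seed(seed, sprintf("weather-%s", b$station_id))
    )
    site <- site_yield_potential(
      b, soils, seqs, weather, config$water_regime,
      init_fraction = config$init_fraction
    )
    site$region <- region
    site$net_balance <- balances[[as.character(b$station_id)]]
    site$flag <- flags[[match(b$station_id, names(balances))]]
    site
  })

  report <- build_report(sites, czs, crop = ls_cfg$crop)
  structure(
    list(
      report = report, sites = sites, buffers = selected, stations = stations,
      zones = zones, cz_shares = czs, change = change, selection = trace,
      grids = grids, config = config
    ),
    class = "pipeline_result"
  )
}

# Guarantee a station inside each change region: if weighted sampling missed
# one, the lowest-area station outside any change region is moved to the
# region's highest-|change| cell (deterministic).
ensure_stations <- function(stations, ls_cfg, delta, w_grid) {
  regions <- vapply(
    seq_len(nrow(stations)),
    function(i) station_region(stations$row[i], stations$col[i], ls_cfg),
    character(1)
  )
  need <- character(0)
  if (length(ls_cfg$urban_centers) > 0 && !"contracting" %in% regions) {
    need <- c(need, "contracting")
  }
  if (!is.null(ls_cfg$expansion_region) && ls_cfg$expansion_gain_ha > 0 &&
    !"expanding" %in% regions) {
    need <- c(need, "expanding")
  }
  for (reg in need) {
    target <- if (reg == "contracting") {
      d <- dplyr::arrange(delta, .data$delta_ha, .data$row, .data$col)
      d[1, c("row", "col")]
    } else {
      ec <- expansion_cells(ls_cfg$expansion_region, ls_cfg$grid_shape)
      d <- dplyr::semi_join(w_grid, ec, by = c("row", "col")) |>
        dplyr::arrange(dplyr::desc(.data$area_ha), .data$row, .data$col)
      d[1, c("row", "col")]
    }
    core_idx <- which(regions == "core")
    if (length(core_idx) == 0) break
    areas <- w_grid$area_ha[match(
      paste(stations$row, stations$col),
      paste(w_grid$row, w_grid$col)
    )]
    victim <- core_idx[which.min(areas[core_idx])]
    stations$row[victim] <- as.integer(target$row)
    stations$col[victim] <- as.integer(target$col)
    regions[victim] <- reg
  }
  stations
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "<pipeline_result> %d x %d grid, %d selected buffers, %d zones\n\n",
    x$config$landscape$grid_shape[1], x$config$landscape$grid_shape[2],
    length(x$buffers), length(unique(x$zones$zone_id))
  ))
  print(x$report)
  invisible(x)
}
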