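#' Selection rules for the buffer network
#'
#' Thresholds governing which climate zones and station buffers enter the
#' upscaling: zones must hold more than `min_cz_share` of national harvested
#' area, a buffer more than `min_buffer_share`; accepted buffers must overlap
#' every previously accepted buffer by less than `max_overlap` (overlap
#' measured relative to the candidate under test); selection stops once the
#' unique-cell coverage first reaches `coverage_target` of national area.
#'
#' @param min_cz_share Minimum national area share of an eligible climate
#'   zone (default 0.05).
#' @param min_buffer_share Minimum national area share of an eligible buffer
#'   (default 0.01).
#' @param max_overlap Maximum pairwise overlap fraction (default 0.20).
#' @param coverage_target National coverage at which selection stops
#'   (default 0.50).
#' @param radius_km Buffer radius (default 100).
#' @return A `selection_config` list.
#' @export
selection_config <- function(min_cz_share = 0.05, min_buffer_share = 0.01,
                             max_overlap = 0.20, coverage_target = 0.50,
                             radius_km = 100) {
  for (nm in c("min_cz_share", "min_buffer_share", "max_overlap", "coverage_target")) {
    assert_scalar_number(get(nm), nm, lower = 1e-12, upper = 1)
  }
  assert_scalar_number(radius_km, "radius_km", lower = 1e-9)
  structure(
    list(
      min_cz_share = min_cz_share, min_buffer_share = min_buffer_share,
      max_overlap = max_overlap, coverage_target = coverage_target,
      radius_km = radius_km
    ),
    class = "selection_config"
  )
}

#' Build a station buffer clipped to its climate zone
#'
#' Member cells are those whose center lies within `radius_km` of the station
#' cell's center (Euclidean distance on the equal-area lattice, `cell_km` km
#' per cell edge) and that share the station's climate zone. Harvested area is
#' summed over member cells, per water regime where the grid distinguishes
#' regimes.
#'
#' @param station One-row data frame or list with `station_id`, `row`, `col`.
#' @param radius_km Buffer radius in km.
#' @param cz_map Tibble with `row`, `col`, `zone_id` (see [delimit_zones()]).
#' @param area_grid Tibble with `row`, `col`, `area_ha` and optionally
#'   `water_regime` (typically an epoch-mean grid).
#' @param cell_km Cell edge length in km (default 10).
#' @param national_area Optional national harvested area (ha) used to fill
#'   `national_share`.
#' @return A `buffer_zone`: list with `station_id`, `cz_id`, `cells` (tibble
#'   `row`, `col`, `cell`, `area_ha`), `harvested_area`, `area_by_regime`,
#'   `national_share`.
#' @export
make_clipped_buffer <- function(station, radius_km, cz_map, area_grid,
                                cell_km = 10, national_area = NULL) {
  assert_columns(cz_map, c("row", "col", "zone_id"), "cz_map")
  assert_columns(area_grid, c("row", "col", "area_ha"), "area_grid")
  srow <- station$row[1]
  scol <- station$col[1]
  ncol_grid <- max(cz_map$col) + 1L
  if (srow < 0 || scol < 0 || srow > max(cz_map$row) || scol >= ncol_grid) {
    abort("station lies outside the grid.")
  }
  sz <- cz_map$zone_id[cz_map$row == srow & cz_map$col == scol]
  if (length(sz) != 1) abort("station cell has no unique climate zone.")

  cell_totals <- area_grid |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(area_ha = sum(.data$area_ha), .groups = "drop")
  members <- cz_map |>
    dplyr::filter(
      .data$zone_id == sz,
      cell_distance_km(.data$row, .data$col, srow, scol, cell_km) <= radius_km
    ) |>
    dplyr::select("row", "col") |>
    dplyr::left_join(cell_totals, by = c("row", "col")) |>
    dplyr::mutate(
      area_ha = dplyr::coalesce(.data$area_ha, 0),
      cell = cell_index(.data$row, .data$col, ncol_grid)
    ) |>
    dplyr::select("row", "col", "cell", "area_ha")

  by_regime <- if ("water_regime" %in% names(area_grid)) {
    area_grid |>
      dplyr::semi_join(members, by = c("row", "col")) |>
      dplyr::group_by(.data$water_regime) |>
      dplyr::summarise(area_ha = sum(.data$area_ha), .groups = "drop") |>
      (\(d) setNames(d$area_ha, d$water_regime))()
  } else {
    c(total = sum(members$area_ha))
  }
  total <- sum(members$area_ha)
  structure(
    list(
      station_id = station$station_id[1] %||% NA_integer_,
      row = as.integer(srow), col = as.integer(scol),
      cz_id = as.integer(sz), cells = members,
      harvested_area = total, area_by_regime = by_regime,
      national_share = if (!is.null(national_area)) total / national_area else NA_real_
    ),
    class = "buffer_zone"
  )
}

#' @export
print.buffer_zone <- function(x, ...) {
  cat(sprintf(
    "<buffer_zone> station %s at (%d, %d), zone %d: %d cells, %.0f ha (share %.3f)\n",
    x$station_id, x$row, x$col, x$cz_id, nrow(x$cells), x$harvested_area,
    x$national_share
  ))
  invisible(x)
}

#' Overlap fraction between two buffers
#'
#' Shared member cells as a fraction of the first buffer's cell count. The
#' first argument is the candidate under test during selection, so the
#' measure is candidate-relative (the stricter, order-consistent reading of
#' the "< 20% overlap" rule).
#'
#' @param a,b `buffer_zone` objects on the same grid.
#' @return Fraction in `[0, 1]`.
#' @export
overlap_fraction <- function(a, b) {
  if (nrow(a$cells) == 0) {
    return(0)
  }
  length(intersect(a$cells$cell, b$cells$cell)) / nrow(a$cells)
}

#' National coverage of a buffer set
#'
#' Harvested area of the union of member cells (each cell counted once,
#' however many buffers contain it) divided by national harvested area.
#'
#' @param selected List of `buffer_zone` objects.
#' @param national_area National harvested area (ha), > 0.
#' @return Fraction in `[0, 1]` (for buffers drawn from the national grid).
#' @export
national_coverage <- function(selected, national_area) {
  if (national_area <= 0) abort("`national_area` must be > 0.")
  if (length(selected) == 0) {
    return(0)
  }
  cells <- dplyr::bind_rows(lapply(selected, `[[`, "cells")) |>
    dplyr::distinct(.data$cell, .keep_all = TRUE)
  sum(cells$area_ha) / national_area
}

#' Sequentially select station buffers
#'
#' The greedy rule of the upscaling framework: candidates (already restricted
#' to eligible climate zones) are ranked by harvested area, largest first
#' (ties by `station_id` ascending); a candidate is accepted iff it holds more
#' than `min_buffer_share` of national harvested area and overlaps every
#' already-accepted buffer by less than `max_overlap` (candidate-relative);
#' selection stops at the first crossing of `coverage_target` unique-cell
#' national coverage.
#'
#' @param candidates List of `buffer_zone` objects. If `cz_shares` (named
#'   vector of national area share per `cz_id`) is supplied, candidates in
#'   zones at or below `min_cz_share` are dropped first.
#' @param national_area National harvested area (ha).
#' @param config A [selection_config()].
#' @param cz_shares Optional named numeric vector, share per zone id.
#' @return List with `selected` (list of accepted `buffer_zone`s in
#'   acceptance order), `coverage` (final fraction) and `trace` (tibble:
#'   `station_id`, `cz_id`, `harvested_area`, `national_share`, `decision`,
#'   `reason`, `coverage_after`).
#' @export
select_buffers <- function(candidates, national_area, config = selection_config(),
                           cz_shares = NULL) {
  stopifnot(inherits(config, "selection_config"))
  if (national_area <= 0) abort("`national_area` must be > 0.")
  trace <- list()
  if (!is.null(cz_shares)) {
    keep <- vapply(
      candidates,
      function(b) isTRUE(cz_shares[[as.character(b$cz_id)]] > config$min_cz_share),
      logical(1)
    )
    for (b in candidates[!keep]) {
      trace[[length(trace) + 1]] <- tibble::tibble(
        station_id = b$station_id, cz_id = b$cz_id,
        harvested_area = b$harvested_area,
        national_share = b$harvested_area / national_area,
        decision = "rejected", reason = "cz_below_min_share",
        coverage_after = NA_real_
      )
    }
    candidates <- candidates[keep]
  }
  if (length(candidates) == 0) {
    return(list(
      selected = list(), coverage = 0,
      trace = dplyr::bind_rows(trace)
    ))
  }
  areas <- vapply(candidates, `[[`, numeric(1), "harvested_area")
  sids <- vapply(candidates, function(b) as.numeric(b$station_id), numeric(1))
  ord <- order(-areas, sids)
  candidates <- candidates[ord]

  selected <- list()
  coverage <- 0
  for (b in candidates) {
    share <- b$harvested_area / national_area
    if (coverage >= config$coverage_target) {
      decision <- "rejected"
      reason <- "coverage_target_reached"
    } else if (!(share > config$min_buffer_share)) {
      decision <- "rejected"
      reason <- "below_min_buffer_share"
    } else {
      ovl <- vapply(selected, function(s) overlap_fraction(b, s), numeric(1))
      if (length(ovl) > 0 && any(ovl >= config$max_overlap)) {
        decision <- "rejected"
        reason <- "overlap"
      } else {
        selected[[length(selected) + 1]] <- b
        coverage <- national_coverage(selected, national_area)
        decision <- "selected"
        reason <- "selected"
      }
    }
    trace[[length(trace) + 1]] <- tibble::tibble(
      station_id = b$station_id, cz_id = b$cz_id,
      harvested_area = b$harvested_area, national_share = share,
      decision = decision, reason = reason,
      coverage_after = coverage
    )
  }
  list(selected = selected, coverage = coverage, trace = dplyr::bind_rows(trace))
}

#' National area share per climate zone
#'
#' @param area_grid Tibble `row`, `col`, `area_ha` (cell totals).
#' @param cz_map Tibble `row`, `col`, `zone_id`.
#' @return Named numeric vector: national harvested-area share per zone id.
#' @export
cz_area_shares <- function(area_grid, cz_map) {
  assert_columns(area_grid, c("row", "col", "area_ha"), "area_grid")
  d <- area_grid |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(area_ha = sum(.data$area_ha), .groups = "drop") |>
    dplyr::left_join(dplyr::select(cz_map, "row", "col", "zone_id"), by = c("row", "col")) |>
    dplyr::group_by(.data$zone_id) |>
    dplyr::summarise(area_ha = sum(.data$area_ha), .groups = "drop")
  setNames(d$area_ha / sum(d$area_ha), d$zone_id)
}
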