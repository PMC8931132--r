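#' Epoch-mean harvested-area grid
#'
#' Cell-wise arithmetic mean over the yearly grids of one epoch window
#' (3-year windows damp short-term area fluctuation from prices or weather).
#'
#' @param yearly_grids Tibble with `row`, `col`, `year`, `area_ha` and
#'   optionally `crop`/`water_regime` (kept as grouping columns). All years
#'   must cover the same cell set.
#' @return Tibble `row`, `col` (plus any grouping columns), `area_ha`.
#' @export
epoch_mean <- function(yearly_grids) {
  assert_columns(yearly_grids, c("row", "col", "year", "area_ha"), "yearly_grids")
  extra <- intersect(c("crop", "water_regime"), names(yearly_grids))
  per_year <- dplyr::count(yearly_grids, .data$year)
  if (length(unique(per_year$n)) != 1) {
    abort("yearly grids have mismatched shapes (different cell counts per year).")
  }
  yearly_grids |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c("row", "col", extra)))) |>
    dplyr::summarise(area_ha = mean(.data$area_ha), .groups = "drop")
}

#' Net harvested-area change between two epoch means
#'
#' Cell-wise `epoch2 - epoch1`; positive values are expansion.
#'
#' @param epoch2_mean,epoch1_mean Epoch-mean grids from [epoch_mean()] with
#'   identical cell sets (and regime columns, if present).
#' @return Tibble `row`, `col` (plus grouping columns), `delta_ha`.
#' @export
net_change <- function(epoch2_mean, epoch1_mean) {
  extra <- intersect(c("crop", "water_regime"), names(epoch1_mean))
  keys <- c("row", "col", extra)
  assert_columns(epoch2_mean, c(keys, "area_ha"), "epoch2_mean")
  assert_columns(epoch1_mean, c(keys, "area_ha"), "epoch1_mean")
  if (nrow(epoch2_mean) != nrow(epoch1_mean)) {
    abort("epoch grids have mismatched shapes.")
  }
  joined <- dplyr::inner_join(
    dplyr::rename(epoch2_mean, a2 = "area_ha"),
    dplyr::rename(epoch1_mean, a1 = "area_ha"),
    by = keys
  )
  if (nrow(joined) != nrow(epoch1_mean)) {
    abort("epoch grids cover different cell sets.")
  }
  joined |>
    dplyr::mutate(delta_ha = .data$a2 - .data$a1) |>
    dplyr::select(dplyr::all_of(keys), "delta_ha")
}

#' Classify per-cell area change
#'
#' Cells with at least `display_min` hectares of cropland (epoch-1 mean) are
#' classified: contracting when the change is below `-change_threshold`,
#' expanding when above `+change_threshold`, otherwise none. Inequalities are
#' strict, so a change of exactly the threshold classifies as "none"; cells
#' below the display minimum are masked out of classification entirely.
#'
#' @param delta Tibble `row`, `col`, `delta_ha` from [net_change()].
#' @param epoch_area Epoch-1 mean grid (`row`, `col`, `area_ha`) used for the
#'   display mask.
#' @param display_min Minimum cropland per cell to display/classify (ha,
#'   default 50).
#' @param change_threshold Absolute change defining contraction/expansion
#'   (ha, default 250).
#' @return A `change_grid` tibble: `row`, `col`, `area_ha`, `delta_ha`,
#'   `displayed`, `change_class` (factor contracting/none/expanding; NA when
#'   masked).
#' @export
classify_change <- function(delta, epoch_area, display_min = 50, change_threshold = 250) {
  assert_columns(delta, c("row", "col", "delta_ha"), "delta")
  assert_columns(epoch_area, c("row", "col", "area_ha"), "epoch_area")
  if (display_min < 0 || change_threshold < 0) abort("thresholds must be >= 0.")
  cell_area <- epoch_area |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(area_ha = sum(.data$area_ha), .groups = "drop")
  cell_delta <- delta |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(delta_ha = sum(.data$delta_ha), .groups = "drop")
  out <- dplyr::inner_join(cell_area, cell_delta, by = c("row", "col")) |>
    dplyr::mutate(
      displayed = .data$area_ha >= display_min,
      change_class = dplyr::case_when(
        !.data$displayed ~ NA_character_,
        .data$delta_ha < -change_threshold ~ "contracting",
        .data$delta_ha > change_threshold ~ "expanding",
        TRUE ~ "none"
      ),
      change_class = factor(.data$change_class, levels = c("contracting", "none", "expanding"))
    )
  class(out) <- c("change_grid", class(out))
  attr(out, "thresholds") <- c(display_min = display_min, change_threshold = change_threshold)
  out
}

#' Net area balance of a buffer
#'
#' Sum of per-cell net change over the buffer's member cells.
#'
#' @param delta Tibble `row`, `col`, `delta_ha`.
#' @param buffer A `buffer_zone`.
#' @return Net balance in hectares (positive = expansion).
#' @export
buffer_net_balance <- function(delta, buffer) {
  assert_columns(delta, c("row", "col", "delta_ha"), "delta")
  delta |>
    dplyr::group_by(.data$row, .data$col) |>
    dplyr::summarise(delta_ha = sum(.data$delta_ha), .groups = "drop") |>
    dplyr::semi_join(buffer$cells, by = c("row", "col")) |>
    dplyr::pull("delta_ha") |>
    sum()
}

#' Flag buffers with significant net area balance
#'
#' A buffer counts as expanding (contracting) when its decadal net balance
#' exceeds the crop-specific significance threshold: 15 000 ha for rice,
#' 10 000 ha for maize. Inequalities are strict; a balance of exactly the
#' threshold is "none".
#'
#' @param balance Net balance in hectares (vectorised).
#' @param crop `"rice"` or `"maize"`.
#' @return Factor with levels contracting/none/expanding.
#' @export
flag_significant <- function(balance, crop) {
  thresholds <- c(rice = 15000, maize = 10000)
  if (length(crop) != 1 || !crop %in% names(thresholds)) {
    abort("`crop` must be one of: rice, maize.")
  }
  th <- thresholds[[crop]]
  out <- dplyr::case_when(
    balance > th ~ "expanding",
    balance < -th ~ "contracting",
    TRUE ~ "none"
  )
  factor(out, levels = c("contracting", "none", "expanding"))
}
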