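#' Derive a child seed from a master seed and a component tag
#'
#' A single user-facing seed fans out to independent per-component seeds so
#' that, e.g., regenerating weather does not perturb the area grids. The
#' derivation is a fixed multiplicative hash of the tag, reduced modulo
#' 2^31 - 1; it is deterministic across platforms and sessions.
#'
#' @param seed Integer master seed.
#' @param tag Character scalar naming the component (and, optionally, an
#'   index such as a station id appended by the caller).
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @examples
#' child_seed(42, "weather-1")
#' @export
child_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(tag), length(tag) == 1)
  m <- 2147483647 # 2^31 - 1, prime
  h <- as.numeric(seed) %% m
  for (k in utf8ToInt(tag)) {
    h <- (h * 131 + k) %% m
  }
  as.integer(h %% (m - 2) + 1)
}

# 0-based, row-major cell index used as a compact set representation for
# buffer membership. `ncol` is the grid's column count.
cell_index <- function(row, col, ncol) {
  as.integer(row) * as.integer(ncol) + as.integer(col)
}

# Euclidean distance between cell centers, in km, on the equal-area lattice.
cell_distance_km <- function(row1, col1, row2, col2, cell_km) {
  sqrt((row1 - row2)^2 + (col1 - col2)^2) * cell_km
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a finite numeric scalar.", name))
  }
  if (x < lower || x > upper) {
    abort(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  invisible(x)
}

assert_columns <- function(df, cols, name = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf("`%s` is missing columns: %s.", name, paste(missing, collapse = ", ")))
  }
  invisible(df)
}

# Piecewise-linear interpolation through (x, y) vertices, constant beyond the
# ends. Used for the temperature response function.
piecewise_linear <- function(x, xs, ys) {
  stats::approx(xs, ys, xout = x, rule = 2, ties = "ordered")$y
}
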