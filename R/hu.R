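# ---- density-to-HU mapping --------------------------------------------------

#' Piecewise-linear density-to-HU conversion table
#'
#' Breakpoints must have strictly increasing densities; between breakpoints
#' the HU value is linearly interpolated, and beyond the terminal breakpoints
#' it is linearly extrapolated from the terminal segments.
#'
#' @param density numeric vector of densities, g/cm^3, strictly increasing.
#' @param hu numeric vector of HU values at those densities.
#' @return An object of class `"hu_table"`.
#' @export
hu_table <- function(density, hu) {
  density <- as.numeric(density); hu <- as.numeric(hu)
  if (length(density) < 2L) stop("HU table needs at least 2 breakpoints")
  if (length(density) != length(hu)) stop("density and hu lengths differ")
  if (any(diff(density) <= 0)) stop("HU table densities must be strictly increasing")
  structure(list(density = density, hu = hu), class = "hu_table")
}

#' Default density-to-HU table
#'
#' Standard CT calibration anchors: air (0.00120 g/cm^3, -1000 HU), water
#' (1.000, 0) and a cortical-bone point (1.92, 1524).  Fully replaceable via
#' [read_hu_table()]; contour-based volume checks are independent of this
#' table.
#'
#' @return An [hu_table()].
#' @export
default_hu_table <- function() {
  hu_table(c(0.00120, 1.000, 1.92), c(-1000, 0, 1524))
}

#' Read a density-to-HU table file
#'
#' Two-column text file: `<density g/cm3> <HU>` per line, `#` comments
#' tolerated.
#'
#' @param path path to the table file.
#' @return An [hu_table()].
#' @export
read_hu_table <- function(path) {
  tk <- read_tokens(path)
  if (length(tk$tokens) < 2L) parse_err(tk, 1L, "HU table needs >= 2 rows")
  n <- length(tk$tokens)
  d <- numeric(n); h <- numeric(n)
  for (i in seq_len(n)) {
    row <- as_num_checked(tk$tokens[[i]], tk, i, "HU table row")
    if (length(row) < 2L) parse_err(tk, i, "row needs density and HU")
    d[i] <- row[1L]; h[i] <- row[2L]
  }
  hu_table(d, h)
}

# round half away from zero, the CT-pixel convention used throughout
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Convert densities to Hounsfield units
#'
#' Piecewise-linear interpolation through the table breakpoints with linear
#' extrapolation beyond them, rounded half-away-from-zero to integer HU and
#' clamped to the 12-bit-plus-sign CT range [-1024, 3071].
#'
#' @param d numeric vector of densities, g/cm^3 (>= 0).
#' @param table an [hu_table()] (default [default_hu_table()]).
#' @return Integer vector of HU values.
#' @examples
#' density_to_hu(c(0.00120, 1.0))   # -1000, 0
#' @export
density_to_hu <- function(d, table = default_hu_table()) {
  stopifnot(inherits(table, "hu_table"))
  d <- as.numeric(d)
  if (any(d < 0, na.rm = TRUE)) stop("densities must be >= 0")
  x <- table$density; y <- table$hu
  n <- length(x)
  hu <- stats::approx(x, y, xout = pmin(pmax(d, x[1]), x[n]),
                      method = "linear", ties = "ordered")$y
  lo <- d < x[1]
  if (any(lo))
    hu[lo] <- y[1] + (d[lo] - x[1]) * (y[2] - y[1]) / (x[2] - x[1])
  hi <- d > x[n]
  if (any(hi))
    hu[hi] <- y[n] + (d[hi] - x[n]) * (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  as.integer(pmin(pmax(round_half_away(hu), -1024), 3071))
}

#' Map a density grid to a HU grid
#'
#' Elementwise application of [density_to_hu()]; the result has the same
#' dimensions as the density grid.
#'
#' @param dgrid a `density_grid` from [voxelize_phantom()].
#' @param table an [hu_table()].
#' @return Integer array of HU values with attribute `"grid"` (the
#'   [voxel_grid()]).
#' @export
hu_grid <- function(dgrid, table = default_hu_table()) {
  stopifnot(inherits(dgrid, "density_grid"))
  h <- density_to_hu(as.vector(dgrid$density), table)
  out <- array(h, dgrid$grid$dims)
  attr(out, "grid") <- dgrid$grid
  out
}
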