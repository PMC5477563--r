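#' Regular latitude/longitude grid specification
#'
#' Describes a regular geographic grid by its number of rows and columns,
#' cell steps in degrees, and the position of its north-west corner. Rows run
#' north to south, columns west to east (north-up convention, as in most
#' raster software).
#'
#' @param n_rows,n_cols Number of rows (latitude) and columns (longitude).
#' @param lat_step,lon_step Cell size in degrees; both must be positive.
#' @param lat_origin Latitude of the grid origin. With `registration =
#'   "edge"` this is the northern *edge* of the first row; with `"center"` it
#'   is the center of the first row.
#' @param lon_origin Longitude of the grid origin (western edge or first-cell
#'   center, depending on `registration`).
#' @param registration `"edge"` (origin on the outer cell edge, the GeoTIFF
#'   convention) or `"center"`.
#'
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(360, 540, lat_step = 0.5, lon_step = 2 / 3)
#' dim_grid(g)
#' @export
grid_spec <- function(n_rows, n_cols, lat_step, lon_step,
                      lat_origin = 90, lon_origin = -180,
                      registration = c("edge", "center")) {
  registration <- match.arg(registration)
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 1L || n_cols < 1L)
    stop("grid must have at least one row and one column", call. = FALSE)
  if (!is.finite(lat_step) || !is.finite(lon_step) || lat_step <= 0 || lon_step <= 0)
    stop("lat_step and lon_step must be positive", call. = FALSE)
  tol <- 1e-6
  if (n_rows * lat_step > 180 + tol)
    stop("grid spans more than 180 degrees of latitude", call. = FALSE)
  if (n_cols * lon_step > 360 + tol)
    stop("grid spans more than 360 degrees of longitude", call. = FALSE)
  # normalize to edge registration internally
  if (registration == "center") {
    lat_origin <- lat_origin + lat_step / 2
    lon_origin <- lon_origin - lon_step / 2
  }
  structure(
    list(n_rows = n_rows, n_cols = n_cols,
         lat_step = lat_step, lon_step = lon_step,
         lat_origin = lat_origin, lon_origin = lon_origin,
         registration = "edge"),
    class = "grid_spec")
}

#' @rdname grid_spec
#' @param g A `grid_spec`.
#' @export
dim_grid <- function(g) c(rows = g$n_rows, cols = g$n_cols)

#' Cell-center coordinates of a grid
#'
#' @param g A `grid_spec`.
#' @return `grid_lats()` gives the `n_rows` cell-center latitudes ordered
#'   north to south; `grid_lons()` the `n_cols` cell-center longitudes west
#'   to east.
#' @export
grid_lats <- function(g) g$lat_origin - (seq_len(g$n_rows) - 0.5) * g$lat_step

#' @rdname grid_lats
#' @export
grid_lons <- function(g) g$lon_origin + (seq_len(g$n_cols) - 0.5) * g$lon_step

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("<grid_spec> %d rows x %d cols, %.6g x %.6g deg cells\n",
              x$n_rows, x$n_cols, x$lat_step, x$lon_step))
  cat(sprintf("  lat: %.4f .. %.4f (N edge %.4f)  lon: %.4f .. %.4f (W edge %.4f)\n",
              min(grid_lats(x)), max(grid_lats(x)), x$lat_origin,
              min(grid_lons(x)), max(grid_lons(x)), x$lon_origin))
  invisible(x)
}

#' The native global reanalysis grid
#'
#' The global single-level diagnostics grid of 540 columns by 360 rows
#' (2/3 degree of longitude by 1/2 degree of latitude; each cell covers 1/3
#' of a square degree).
#'
#' @return A `grid_spec` with 360 rows and 540 columns.
#' @export
native_grid_global <- function() {
  grid_spec(360L, 540L, lat_step = 0.5, lon_step = 2 / 3,
            lat_origin = 90, lon_origin = -180)
}

grids_equal <- function(a, b, tol = 1e-7) {
  a$n_rows == b$n_rows && a$n_cols == b$n_cols &&
    abs(a$lat_step - b$lat_step) < tol && abs(a$lon_step - b$lon_step) < tol &&
    abs(a$lat_origin - b$lat_origin) < tol && abs(a$lon_origin - b$lon_origin) < tol
}

stopifnot_grid <- function(g) {
  if (!inherits(g, "grid_spec")) stop("expected a grid_spec", call. = FALSE)
  invisible(g)
}
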