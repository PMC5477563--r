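#' Hourly climate cube
#'
#' Container for hourly gridded 2 m air temperature (Kelvin) and 2 m
#' specific humidity (kg water per kg air) on a regular lat/lon grid.
#' Arrays are dimensioned `[row, col, time]` with rows north to south.
#'
#' @param grid A [grid_spec()].
#' @param time `POSIXct` (UTC) timestamps, strictly increasing.
#' @param temperature Numeric array `[n_rows, n_cols, n_time]`, Kelvin,
#'   strictly positive.
#' @param humidity Numeric array of the same shape, kg/kg, non-negative.
#' @return An object of class `hourly_cube`.
#' @export
hourly_cube <- function(grid, time, temperature, humidity) {
  stopifnot_grid(grid)
  if (!inherits(time, "POSIXct")) stop("time must be POSIXct", call. = FALSE)
  n <- length(time)
  if (n > 1 && any(diff(as.numeric(time)) <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  want <- c(grid$n_rows, grid$n_cols, n)
  for (nm in c("temperature", "humidity")) {
    a <- get(nm)
    if (!is.array(a) || !identical(dim(a), as.integer(want)))
      stop(sprintf("%s must be an array of dim [%d, %d, %d]", nm,
                   want[1], want[2], want[3]), call. = FALSE)
  }
  if (any(temperature <= 0, na.rm = TRUE))
    stop("temperature must be positive (Kelvin)", call. = FALSE)
  if (any(humidity < 0, na.rm = TRUE))
    stop("humidity must be non-negative", call. = FALSE)
  structure(list(grid = grid, time = time,
                 temperature = temperature, humidity = humidity),
            class = "hourly_cube")
}

#' @export
print.hourly_cube <- function(x, ...) {
  cat(sprintf("<hourly_cube> %d x %d cells, %d hourly records\n",
              x$grid$n_rows, x$grid$n_cols, length(x$time)))
  if (length(x$time))
    cat(sprintf("  %s .. %s UTC\n", format(min(x$time), tz = "UTC"),
                format(max(x$time), tz = "UTC")))
  invisible(x)
}

#' Extract one cell's hourly series from a cube
#'
#' @param cube An [hourly_cube()].
#' @param row,col Cell indices (row 1 is the northernmost).
#' @param what `"temperature_C"` (Kelvin converted to Celsius) or
#'   `"humidity"`.
#' @return A data frame with columns `timestamp` and the requested variable.
#' @export
cell_series <- function(cube, row, col, what = c("temperature_C", "humidity")) {
  what <- match.arg(what)
  v <- if (what == "temperature_C") cube$temperature[row, col, ] - 273.15
       else cube$humidity[row, col, ]
  out <- data.frame(timestamp = cube$time)
  out[[what]] <- as.numeric(v)
  out
}

#' Monthly climatology of temperature extremes and humidity summaries
#'
#' Per cell and calendar month: minimum and maximum temperature (degrees
#' Celsius) and minimum, mean and maximum specific humidity (kg/kg),
#' reduced from hourly records.
#'
#' @param grid A [grid_spec()].
#' @param year Calendar year the climatology describes.
#' @param tmin,tmax,hmin,hmean,hmax Numeric arrays `[n_rows, n_cols, 12]`.
#' @return An object of class `monthly_clim`.
#' @export
monthly_climatology <- function(grid, year, tmin, tmax, hmin, hmean, hmax) {
  stopifnot_grid(grid)
  want <- as.integer(c(grid$n_rows, grid$n_cols, 12L))
  for (nm in c("tmin", "tmax", "hmin", "hmean", "hmax")) {
    a <- get(nm)
    if (!is.array(a) || !identical(dim(a), want))
      stop(sprintf("%s must be an array of dim [%d, %d, 12]", nm,
                   want[1], want[2]), call. = FALSE)
  }
  bad <- which(tmin > tmax + 1e-12)
  if (length(bad))
    stop("tmin exceeds tmax for some cell-months", call. = FALSE)
  if (any(hmin > hmean + 1e-15, na.rm = TRUE) ||
      any(hmean > hmax + 1e-15, na.rm = TRUE))
    stop("humidity ordering hmin <= hmean <= hmax violated", call. = FALSE)
  if (any(hmin < 0, na.rm = TRUE))
    stop("humidity must be non-negative", call. = FALSE)
  structure(list(grid = grid, year = year, tmin = tmin, tmax = tmax,
                 hmin = hmin, hmean = hmean, hmax = hmax),
            class = "monthly_clim")
}

#' @export
print.monthly_clim <- function(x, ...) {
  cat(sprintf("<monthly_clim> year %s, %d x %d cells, 12 months\n",
              as.character(x$year), x$grid$n_rows, x$grid$n_cols))
  invisible(x)
}
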