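#' Read hourly CF-style NetCDF files into a cube
#'
#' Reads one or more NetCDF-3 files holding hourly 2 m temperature and
#' specific humidity on a shared regular lat/lon grid, concatenates them
#' along time and returns a time-sorted [hourly_cube()]. Files written with
#' south-up (ascending) latitudes are normalized to the package's north-up
#' convention.
#'
#' @param paths Character vector of file paths.
#' @param temp_var,hum_var NetCDF variable names (defaults `T2M`, `QV2M`).
#' @return An [hourly_cube()].
#' @export
read_hourly_netcdf <- function(paths, temp_var = "T2M", hum_var = "QV2M") {
  if (length(paths) == 0) stop("no input files", call. = FALSE)
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("input file(s) not found: ", paste(missing, collapse = ", "),
         call. = FALSE)
  pieces <- lapply(paths, read_one_netcdf, temp_var = temp_var,
                   hum_var = hum_var)
  g <- pieces[[1]]$grid
  for (p in pieces[-1])
    if (!grids_equal(g, p$grid))
      stop("inconsistent grids across input files", call. = FALSE)
  time <- do.call(c, lapply(pieces, function(p) p$time))
  ord <- order(time)
  time <- time[ord]
  if (anyDuplicated(as.numeric(time)))
    stop("non-monotone time axis: duplicate timestamps across files",
         call. = FALSE)
  nt <- length(time)
  flat_t <- array(NA_real_, dim = c(g$n_rows, g$n_cols, nt))
  flat_h <- array(NA_real_, dim = c(g$n_rows, g$n_cols, nt))
  at <- 0L
  for (p in pieces) {
    k <- length(p$time)
    flat_t[, , (at + 1L):(at + k)] <- p$temperature
    flat_h[, , (at + 1L):(at + k)] <- p$humidity
    at <- at + k
  }
  hourly_cube(g, time, flat_t[, , ord, drop = FALSE],
              flat_h[, , ord, drop = FALSE])
}

read_one_netcdf <- function(path, temp_var, hum_var) {
  nc <- nc3_read(path)
  for (v in c(temp_var, hum_var))
    if (is.null(nc$vars[[v]]))
      stop(sprintf("variable '%s' missing from %s", v, path), call. = FALSE)
  tv <- nc$vars[[temp_var]]
  if (length(tv$dims) != 3)
    stop(sprintf("variable '%s' must have dimensions (time, lat, lon)",
                 temp_var), call. = FALSE)
  dn <- tv$dims
  time_dim <- dn[1]; lat_dim <- dn[2]; lon_dim <- dn[3]
  tvar <- nc$vars[[time_dim]]
  if (is.null(tvar)) stop("no time coordinate variable", call. = FALSE)
  time <- nc3_decode_time(tvar$data, tvar$atts$units %||% "")
  if (length(time) > 1 && any(diff(as.numeric(time)) <= 0))
    stop(sprintf("non-monotone time axis in %s", path), call. = FALSE)
  lat <- nc$vars[[lat_dim]]$data
  lon <- nc$vars[[lon_dim]]$data
  if (is.null(lat) || is.null(lon))
    stop("missing lat/lon coordinate variables", call. = FALSE)
  nlat <- length(lat); nlon <- length(lon)
  unflatten <- function(v) {
    # stored (time, lat, lon), lon fastest
    aperm(array(v, dim = c(nlon, nlat, length(time))), c(2, 1, 3))
  }
  temp <- unflatten(tv$data)
  hum <- unflatten(nc$vars[[hum_var]]$data)
  south_up <- nlat > 1 && lat[2] > lat[1]
  if (south_up) {
    lat <- rev(lat)
    temp <- temp[rev(seq_len(nlat)), , , drop = FALSE]
    hum <- hum[rev(seq_len(nlat)), , , drop = FALSE]
  }
  lat_step <- if (nlat > 1) abs(stats::median(diff(lat))) else 1
  lon_step <- if (nlon > 1) abs(stats::median(diff(lon))) else 1
  g <- grid_spec(nlat, nlon, lat_step, lon_step,
                 lat_origin = max(lat) + lat_step / 2,
                 lon_origin = min(lon) - lon_step / 2)
  list(grid = g, time = time, temperature = temp, humidity = hum)
}

days_in_month <- function(year, month) {
  first <- as.Date(sprintf("%d-%02d-01", year, month))
  nxt <- if (month == 12) as.Date(sprintf("%d-01-01", year + 1))
         else as.Date(sprintf("%d-%02d-01", year, month + 1))
  as.integer(nxt - first)
}

#' Monthly extremes of temperature and humidity summaries for one month
#'
#' Reduces all hourly records of one calendar month to per-cell minimum and
#' maximum temperature (converted K to degrees C) and minimum, arithmetic
#' mean and maximum specific humidity. Monthly temperature extremes are the
#' min/max over *all hourly values* of the month, not means of daily
#' extremes (this differs from interpolated-station climatologies built
#' from daily data).
#'
#' @param cube An [hourly_cube()].
#' @param year,month Calendar year and month (1-12).
#' @param min_coverage Minimum fraction of the month's hours that must be
#'   present (default 0.9); months below it raise an error naming the month
#'   and the observed fraction, so gaps are handled explicitly.
#' @return A list of `n_rows x n_cols` matrices `tmin`, `tmax` (degrees C)
#'   and `hmin`, `hmean`, `hmax` (kg/kg).
#' @export
monthly_extremes <- function(cube, year, month, min_coverage = 0.9) {
  if (!month %in% 1:12) stop("month must be in 1..12", call. = FALSE)
  lt <- as.POSIXlt(cube$time, tz = "UTC")
  sel <- which(lt$year + 1900L == year & lt$mon + 1L == month)
  hours_in_month <- days_in_month(year, month) * 24L
  frac <- length(sel) / hours_in_month
  if (frac < min_coverage)
    stop(sprintf(
      "insufficient coverage for %d-%02d: %.3f of the month's hours (need %.3f)",
      year, month, frac, min_coverage), call. = FALSE)
  tt <- cube$temperature[, , sel, drop = FALSE]
  hh <- cube$humidity[, , sel, drop = FALSE]
  list(tmin = apply(tt, c(1, 2), min) - 273.15,
       tmax = apply(tt, c(1, 2), max) - 273.15,
       hmin = apply(hh, c(1, 2), min),
       hmean = apply(hh, c(1, 2), mean),
       hmax = apply(hh, c(1, 2), max))
}

#' Build the monthly climatology for one calendar year
#'
#' Assembles twelve [monthly_extremes()] records into a [monthly_climatology()].
#'
#' @inheritParams monthly_extremes
#' @return A [monthly_climatology()].
#' @export
build_year_climatology <- function(cube, year, min_coverage = 0.9) {
  g <- cube$grid
  arr <- function() array(NA_real_, dim = c(g$n_rows, g$n_cols, 12L))
  tmin <- arr(); tmax <- arr(); hmin <- arr(); hmean <- arr(); hmax <- arr()
  for (m in 1:12) {
    e <- monthly_extremes(cube, year, m, min_coverage = min_coverage)
    tmin[, , m] <- e$tmin; tmax[, , m] <- e$tmax
    hmin[, , m] <- e$hmin; hmean[, , m] <- e$hmean; hmax[, , m] <- e$hmax
  }
  monthly_climatology(g, year, tmin, tmax, hmin, hmean, hmax)
}
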