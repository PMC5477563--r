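#' Parameters for the synthetic climate generator
#'
#' The generator emulates the gross structure of a reanalysis temperature
#' field: a latitudinal gradient, an annual cycle of opposite phase in the
#' two hemispheres peaking in mid-January (austral summer), a diurnal cycle
#' peaking at 14:00 UTC, and i.i.d. Gaussian noise. Specific humidity is
#' coupled to temperature through an exponential (Clausius-Clapeyron-like)
#' relation and clipped to a physical range.
#'
#' @param mean_temp_equator Annual-mean temperature at the equator, degrees C.
#' @param lapse_per_deg_lat Cooling per degree of absolute latitude, degrees C.
#' @param seasonal_amplitude Amplitude of the annual cycle, degrees C.
#' @param diurnal_amplitude Amplitude of the daily cycle, degrees C.
#' @param noise_sd Standard deviation of per-hour Gaussian noise, degrees C.
#' @param humidity_ref Specific humidity at 0 degrees C, kg/kg; must lie in
#'   (0, 0.04].
#' @param humidity_temp_coeff Exponential humidity-temperature coupling,
#'   per degree C (about 0.06 reproduces the observed ~6-7 % increase of
#'   saturation humidity per degree).
#' @param seed Integer RNG seed; the cube is bit-reproducible for a fixed
#'   seed.
#' @return An object of class `synth_params`.
#' @export
synth_params <- function(mean_temp_equator = 26, lapse_per_deg_lat = 0.55,
                         seasonal_amplitude = 12, diurnal_amplitude = 5,
                         noise_sd = 2, humidity_ref = 0.004,
                         humidity_temp_coeff = 0.06, seed = 1L) {
  if (seasonal_amplitude < 0 || diurnal_amplitude < 0 || noise_sd < 0)
    stop("amplitudes and noise_sd must be non-negative", call. = FALSE)
  if (!(humidity_ref > 0 && humidity_ref <= 0.04))
    stop("humidity_ref must lie in (0, 0.04]", call. = FALSE)
  structure(list(mean_temp_equator = mean_temp_equator,
                 lapse_per_deg_lat = lapse_per_deg_lat,
                 seasonal_amplitude = seasonal_amplitude,
                 diurnal_amplitude = diurnal_amplitude,
                 noise_sd = noise_sd, humidity_ref = humidity_ref,
                 humidity_temp_coeff = humidity_temp_coeff,
                 seed = as.integer(seed)),
            class = "synth_params")
}

#' Generate a synthetic hourly climate cube
#'
#' Produces hourly 2 m temperature and specific humidity on `grid` for every
#' hour in `[start, end)` (dates, UTC; `end` is exclusive). Temperature at a
#' cell with latitude `lat`, day-of-year `d` and hour-of-day `h` is
#' `mean_temp_equator - lapse*|lat| + A_s*s(lat)*cos(2*pi*(d-15)/365.25) +
#' A_d*cos(2*pi*(h-14)/24) + N(0, noise_sd)` degrees C (stored in Kelvin),
#' where `s(lat) = -sign(lat)` so the annual cycle peaks in mid-January in
#' the southern hemisphere. Humidity is
#' `humidity_ref * exp(humidity_temp_coeff * T_C)` clipped to
#' `[1e-6, 0.04]` kg/kg, computed from the noisy temperature so that
#' humidity is monotone in temperature.
#'
#' @param grid A [grid_spec()].
#' @param start,end `Date`s (or strings coercible to dates); `start < end`.
#' @param params A [synth_params()].
#' @return An [hourly_cube()] (temperature in Kelvin).
#' @export
gen_climate_cube <- function(grid, start, end, params = synth_params()) {
  stopifnot_grid(grid)
  start <- as.Date(start); end <- as.Date(end)
  if (is.na(start) || is.na(end) || start >= end)
    stop("start must be an earlier date than end", call. = FALSE)
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(end, "00:00:00"), tz = "UTC")
  time <- seq(t0, t1 - 3600, by = 3600)
  nt <- length(time); nr <- grid$n_rows; nc <- grid$n_cols
  lat <- grid_lats(grid)
  doy <- as.integer(strftime(time, "%j", tz = "UTC"))
  hod <- as.integer(strftime(time, "%H", tz = "UTC"))

  seasonal_t <- params$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25)
  diurnal_t <- params$diurnal_amplitude * cos(2 * pi * (hod - 14) / 24)
  base_lat <- params$mean_temp_equator - params$lapse_per_deg_lat * abs(lat)
  sign_lat <- -sign(lat)

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(params$seed)

  temp <- array(0, dim = c(nr, nc, nt))
  # build per time slice: T[r,c,t] = base(r) + sign(r)*seasonal(t) + diurnal(t)
  for (t in seq_len(nt)) {
    slice <- base_lat + sign_lat * seasonal_t[t] + diurnal_t[t]
    temp[, , t] <- matrix(slice, nr, nc)
  }
  if (params$noise_sd > 0)
    temp <- temp + array(stats::rnorm(nr * nc * nt, sd = params$noise_sd),
                         dim = c(nr, nc, nt))
  hum <- pmin(pmax(params$humidity_ref *
                     exp(params$humidity_temp_coeff * temp), 1e-6), 0.04)
  hourly_cube(grid, time, temp + 273.15, hum)
}

#' Weather-station time series
#'
#' @param station_id Station identifier.
#' @param lat,lon Station coordinates in degrees.
#' @param timestamp `POSIXct` (UTC), strictly increasing, with a constant
#'   step of `step_hours` hours.
#' @param temperature_C Observed 2 m temperature, degrees C.
#' @param step_hours Sampling step, 1 or 6 hours.
#' @return An object of class `station_series` (a data frame with columns
#'   `timestamp` and `temperature_C`, plus station metadata attributes).
#' @export
station_series <- function(station_id, lat, lon, timestamp, temperature_C,
                           step_hours = 1L) {
  if (!step_hours %in% c(1L, 6L))
    stop("step_hours must be 1 or 6", call. = FALSE)
  if (length(timestamp) != length(temperature_C))
    stop("timestamp and temperature_C lengths differ", call. = FALSE)
  d <- diff(as.numeric(timestamp))
  if (length(d) && any(d <= 0))
    stop("timestamps must be strictly increasing", call. = FALSE)
  if (length(d) && any(abs(d - step_hours * 3600) > 1e-6))
    stop("timestamp step inconsistent with step_hours", call. = FALSE)
  out <- data.frame(timestamp = timestamp, temperature_C = temperature_C)
  attr(out, "station_id") <- as.character(station_id)
  attr(out, "lat") <- lat; attr(out, "lon") <- lon
  attr(out, "step_hours") <- as.integer(step_hours)
  class(out) <- c("station_series", "data.frame")
  out
}

#' @export
print.station_series <- function(x, ...) {
  cat(sprintf("<station_series> %s at (%.3f, %.3f), %d records every %d h\n",
              attr(x, "station_id"), attr(x, "lat"), attr(x, "lon"),
              nrow(x), attr(x, "step_hours")))
  invisible(x)
}

#' Generate a synthetic station series linearly related to a truth series
#'
#' The station value is `(truth - intercept)/slope + N(0, noise_sd)` at
#' every `step_hours`-th instant of the truth series, so that an ordinary
#' least squares regression of the truth (gridded) series on the station
#' series recovers `(slope, intercept)` up to noise.
#'
#' @param truth A data frame with columns `timestamp` (hourly `POSIXct`) and
#'   `temperature_C`, e.g. from [cell_series()].
#' @param slope Positive regression slope linking station to truth.
#' @param intercept Regression intercept, degrees C.
#' @param noise_sd Station measurement noise SD, degrees C.
#' @param step_hours Subsampling step, 1 or 6.
#' @param seed Integer RNG seed.
#' @param station_id,lat,lon Station metadata.
#' @return A [station_series()].
#' @export
gen_station_series <- function(truth, slope, intercept, noise_sd = 0,
                               step_hours = 1L, seed = 1L,
                               station_id = "SYNTH", lat = 0, lon = 0) {
  if (!is.finite(slope) || slope <= 0)
    stop("slope must be positive", call. = FALSE)
  if (!step_hours %in% c(1L, 6L))
    stop("step_hours must be 1 or 6", call. = FALSE)
  keep <- seq(1L, nrow(truth), by = step_hours)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old_seed))
    assign(".Random.seed", old_seed, envir = globalenv()))
  set.seed(seed)
  vals <- (truth$temperature_C[keep] - intercept) / slope +
    stats::rnorm(length(keep), sd = noise_sd)
  station_series(station_id, lat, lon, truth$timestamp[keep], vals,
                 step_hours = as.integer(step_hours))
}

#' Generate a single-cell monthly climatology from a preset or table
#'
#' @param preset `"constant"` (all twelve months at `c_temp` degrees C and
#'   humidity `h`), `"toy-seasonal"` (a tabulated mid-latitude annual cycle
#'   shipped with the package), or a 12-row data frame with columns
#'   `tmin, tmax, hmin, hmean, hmax`.
#' @param c_temp,h Constants for the `"constant"` preset.
#' @param year Year label for the returned climatology.
#' @return A single-cell [monthly_climatology()].
#' @export
gen_monthly_climatology <- function(preset = "constant", c_temp = 10,
                                    h = 0.005, year = 2000L) {
  if (is.character(preset)) {
    tab <- switch(preset,
      "constant" = data.frame(tmin = rep(c_temp, 12), tmax = rep(c_temp, 12),
                              hmin = rep(h, 12), hmean = rep(h, 12),
                              hmax = rep(h, 12)),
      "toy-seasonal" = utils::read.csv(system.file(
        "extdata", "toy_seasonal_climatology.csv", package = "humidclim")),
      stop(sprintf("unknown preset '%s'", preset), call. = FALSE))
  } else {
    tab <- as.data.frame(preset)
  }
  need <- c("tmin", "tmax", "hmin", "hmean", "hmax")
  if (nrow(tab) != 12L || !all(need %in% names(tab)))
    stop("climatology table needs 12 rows and columns tmin, tmax, hmin, hmean, hmax",
         call. = FALSE)
  g <- grid_spec(1L, 1L, lat_step = 1, lon_step = 1,
                 lat_origin = 1, lon_origin = 0)
  arr <- function(v) array(v, dim = c(1L, 1L, 12L))
  monthly_climatology(g, year, arr(tab$tmin), arr(tab$tmax),
                      arr(tab$hmin), arr(tab$hmean), arr(tab$hmax))
}
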