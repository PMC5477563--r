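# Small shared fixtures, built in code at test time.

small_grid <- function(nr = 4, nc = 6, step = 1, lat0 = 10, lon0 = 0) {
  grid_spec(nr, nc, lat_step = step, lon_step = step,
            lat_origin = lat0, lon_origin = lon0)
}

# quiet cube: no seasonal/diurnal/noise structure unless asked for
flat_cube <- function(grid = small_grid(2, 3), start = "2001-01-01",
                      end = "2001-03-01", temp_C = 10, h = 0.005) {
  p <- synth_params(mean_temp_equator = temp_C, lapse_per_deg_lat = 0,
                    seasonal_amplitude = 0, diurnal_amplitude = 0,
                    noise_sd = 0, humidity_ref = h, humidity_temp_coeff = 0)
  gen_climate_cube(grid, start, end, p)
}

# independent recomputation of the generator's deterministic part (degC)
expected_deterministic_temp <- function(lat, time, p) {
  doy <- as.integer(strftime(time, "%j", tz = "UTC"))
  hod <- as.integer(strftime(time, "%H", tz = "UTC"))
  p$mean_temp_equator - p$lapse_per_deg_lat * abs(lat) +
    p$seasonal_amplitude * (-sign(lat)) * cos(2 * pi * (doy - 15) / 365.25) +
    p$diurnal_amplitude * cos(2 * pi * (hod - 14) / 24)
}
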