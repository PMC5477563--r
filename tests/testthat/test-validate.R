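test_that("collocation at a cell center pairs the full common series", {
  g <- small_grid(3, 3, lat0 = 3)  # centers at 2.5, 1.5, 0.5
  cube <- gen_climate_cube(g, "2001-01-01", "2001-01-31",
                           synth_params(noise_sd = 1, seed = 50))
  truth <- cell_series(cube, 2, 2)
  st <- gen_station_series(truth, 1, 0, 0, station_id = "C",
                           lat = 1.5, lon = 1.5)
  pairs <- collocate(cube, st)
  expect_equal(nrow(pairs), nrow(truth))
  expect_equal(pairs$grid, truth$temperature_C)
  expect_equal(pairs$station, truth$temperature_C)
})

test_that("6-hourly station over 30 days pairs 120 records", {
  g <- small_grid(2, 2, lat0 = 2)
  cube <- gen_climate_cube(g, "2001-01-01", "2001-01-31", synth_params())
  truth <- cell_series(cube, 1, 1)
  st <- gen_station_series(truth, 1, 0, 0, step_hours = 6L,
                           lat = 1.5, lon = 0.5)
  pairs <- collocate(cube, st)
  expect_equal(nrow(pairs), 120)
})

test_that("edge stations break ties to the lowest row then column", {
  g <- small_grid(2, 2, lat0 = 2)  # lat centers 1.5, 0.5; lon centers 0.5, 1.5
  temp <- array(rep(c(281, 282, 283, 284), 3), c(2, 2, 3)) # distinct cells
  cube <- hourly_cube(g, as.POSIXct("2001-01-01", tz = "UTC") + 3600 * (0:2),
                      temp, array(0.005, c(2, 2, 3)))
  st <- station_series("EDGE", lat = 1.0, lon = 1.0,
                       cube$time, c(0, 0, 0), step_hours = 1L)
  pairs <- collocate(cube, st)
  expect_equal(pairs$grid, rep(281 - 273.15, 3))  # cell (1,1) wins
  out <- station_series("OUT", lat = 45, lon = 0.5, cube$time,
                        c(0, 0, 0), step_hours = 1L)
  expect_error(collocate(cube, out), "outside")
})

test_that("a noiseless linear relation is recovered exactly", {
  x <- seq(-30, 10, length.out = 200)
  pairs <- data.frame(grid = 0.86 * x - 1.57, station = x)
  s <- series_stats(pairs)
  expect_equal(s$pearson_r, 1)
  expect_equal(s$slope, 0.86)
  expect_equal(s$intercept, -1.57)
  expect_equal(s$r_squared, 1)
  expect_equal(s$residual_iqr, 0)
  expect_error(series_stats(data.frame(grid = 1:5, station = rep(2, 5))),
               "zero variance")
})

test_that("planted regression parameters are recovered at n = 10000", {
  g <- small_grid(1, 1, lat0 = -70)
  p <- synth_params(seasonal_amplitude = 20, diurnal_amplitude = 5,
                    noise_sd = 0, seed = 60)
  cube <- gen_climate_cube(g, "2001-01-01", "2002-06-01", p)
  truth <- cell_series(cube, 1, 1)[1:10000, ]
  cases <- list(c(0.86, -1.57), c(0.73, -8.9), c(0.69, -11))
  for (cs in cases) {
    st <- gen_station_series(truth, slope = cs[1], intercept = cs[2],
                             noise_sd = 2, seed = 61, lat = -69.5, lon = 0.5)
    pairs <- data.frame(grid = truth$temperature_C, station = st$temperature_C)
    s <- series_stats(pairs)
    expect_lt(abs(s$slope - cs[1]), 0.02)
    expect_lt(abs(s$intercept - cs[2]), 0.3)
  }
})

test_that("residual quartiles follow the linear-interpolation rule", {
  # x chosen orthogonal to the planted residuals so OLS returns them exactly
  x <- c(1, 2, 3, 2, 1)
  res <- c(-2, -1, 0, 1, 2)
  pairs <- data.frame(grid = 5 + 2 * x + res, station = x)
  s <- series_stats(pairs)
  expect_equal(sort(s$residuals), res, ignore_attr = TRUE)
  expect_equal(s$residual_q1, -1)  # hand-enumerated type-7 quartiles
  expect_equal(s$residual_q3, 1)
  expect_equal(s$residual_iqr, 2)
})

test_that("statistics are order-invariant and scale-invariant where expected", {
  set.seed(62)
  pairs <- data.frame(grid = rnorm(500, 0, 3), station = rnorm(500, 0, 3))
  pairs$grid <- pairs$grid + 0.7 * pairs$station
  s1 <- series_stats(pairs)
  s2 <- series_stats(pairs[sample(500), ])
  expect_equal(s1$slope, s2$slope)
  expect_equal(s1$residual_iqr, s2$residual_iqr)
  s3 <- series_stats(data.frame(grid = 10 * pairs$grid,
                                station = 10 * pairs$station))
  expect_equal(s1$pearson_r, s3$pearson_r)
  expect_equal(s1$r_squared, s3$r_squared)
  expect_equal(s1$r_squared, s1$pearson_r^2, tolerance = 1e-12)
})

test_that("per-month residual summaries cover the twelve months", {
  g <- small_grid(1, 1, lat0 = -60)
  cube <- gen_climate_cube(g, "2001-01-01", "2002-01-01",
                           synth_params(noise_sd = 2, seed = 63))
  truth <- cell_series(cube, 1, 1)
  st <- gen_station_series(truth, 0.86, -1.57, noise_sd = 2, seed = 64,
                           lat = -60.5, lon = 0.5)
  s <- series_stats(collocate(cube, st))
  expect_equal(dim(s$per_month), c(12L, 5L))
  expect_true(all(is.finite(s$per_month)))
  expect_true(all(s$per_month[, "q1"] <= s$per_month[, "median"]))
})

test_that("station bioclim of a constant station is degenerate", {
  ts <- seq(as.POSIXct("2001-01-01", tz = "UTC"),
            as.POSIXct("2001-12-31 23:00", tz = "UTC"), by = 3600)
  st <- station_series("CONST", -60, 0, ts, rep(10, length(ts)))
  b <- station_bioclim(st, 2001)
  expect_equal(unname(b["BIO1"]), 10)
  expect_equal(unname(b["BIO2"]), 0)
  expect_equal(unname(b["BIO4"]), 0)
  expect_equal(unname(b["BIO7"]), 0)
})

test_that("station bioclim matches the cube pipeline when the station IS a cell", {
  g <- small_grid(2, 2, lat0 = -60)
  cube <- gen_climate_cube(g, "2001-01-01", "2002-01-01",
                           synth_params(noise_sd = 1, seed = 65))
  truth <- cell_series(cube, 1, 2)
  st <- gen_station_series(truth, 1, 0, 0, lat = -60.5, lon = 1.5)
  b <- station_bioclim(st, 2001)
  set <- annual_bioclim(build_year_climatology(cube, 2001), "mean")
  for (v in names(b))
    expect_equal(unname(b[v]), set$layers[[v]][1, 2], tolerance = 1e-12)
})

test_that("insufficient station coverage names the failing months", {
  ts <- seq(as.POSIXct("2001-01-01", tz = "UTC"),
            as.POSIXct("2001-10-15", tz = "UTC"), by = 3600)
  st <- station_series("GAP", -60, 0, ts, rnorm(length(ts), -5))
  expect_error(station_bioclim(st, 2001), "2001-10.*2001-11.*2001-12")
})

test_that("buffers cover 1/3 square degree and clip at the poles", {
  b <- buffer_zones(data.frame(lat = 10, lon = 20))
  expect_equal(b$area, 1 / 3, tolerance = 1e-9)
  expect_equal(b$lon_max - b$lon_min, sqrt(1 / 3), tolerance = 1e-12)
  two <- buffer_zones(data.frame(lat = c(10, 10), lon = c(20, 20)))
  g <- small_grid(40, 40, step = 0.1, lat0 = 12, lon0 = 18)
  m1 <- humidclim:::buffer_mask(g, two[1, ])
  m2 <- humidclim:::buffer_mask(g, two)
  expect_identical(m1, m2)  # coincident buffers never double-count
  polar <- buffer_zones(data.frame(lat = 89.9, lon = 0))
  expect_equal(polar$lat_max, 90)
  expect_lt(polar$area, 1 / 3)
})

test_that("Tukey fences flag hand-enumerated outliers", {
  expect_equal(iqr_outliers(rep(3, 10)), rep(FALSE, 10))
  res <- c(1, 2, 3, 4, 100)
  # type-7 quartiles: Q1 = 2, Q3 = 4, IQR = 2, fences [-1, 7]
  expect_equal(iqr_outliers(res), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_error(iqr_outliers(1:3), "at least 4")
})

test_that("Tukey-fence rate on a normal sample matches the closed form", {
  set.seed(66)
  x <- rnorm(100000)
  rate <- mean(iqr_outliers(x))
  # P(|Z| > 2.6980) for the asymptotic fences
  expect_lt(abs(rate - 0.00698), 0.002)
})

test_that("raster comparison recovers identity, shifts and planted outliers", {
  g <- small_grid(40, 60, step = 0.1, lat0 = 2, lon0 = 0)
  lats <- grid_lats(g); lons <- grid_lons(g)
  a <- outer(lats, lons, function(la, lo) 15 + 0.5 * lo - 0.8 * la)
  stations <- data.frame(lat = c(1.2, 0.3, -0.9, 1.5, -1.4, 0.1),
                         lon = c(0.8, 2.1, 3.4, 4.6, 1.9, 5.2))
  buf <- buffer_zones(stations)
  idn <- raster_compare(a, a, g, buf)
  expect_equal(idn$stats$pearson_r, 1)
  expect_equal(idn$stats$slope, 1)
  expect_equal(idn$outlier_area_fraction, 0)
  sh <- raster_compare(a, a + 5, g, buf)
  expect_equal(sh$stats$slope, 1, tolerance = 1e-12)
  expect_equal(sh$stats$intercept, -5, tolerance = 1e-12)
  expect_equal(sum(sh$outlier_mask), 0)
})

test_that("3 percent planted corruption is flagged at the right area fraction", {
  g <- small_grid(40, 60, step = 0.1, lat0 = 2, lon0 = 0)
  lats <- grid_lats(g); lons <- grid_lons(g)
  a <- outer(lats, lons, function(la, lo) 15 + 0.5 * lo - 0.8 * la)
  stations <- data.frame(lat = c(1.2, 0.3, -0.9, 1.5, -1.4, 0.1),
                         lon = c(0.8, 2.1, 3.4, 4.6, 1.9, 5.2))
  buf <- buffer_zones(stations)
  mask <- humidclim:::buffer_mask(g, buf)
  sel <- which(mask)
  set.seed(67)
  # uniform noise has zero Tukey-fence rate, so flags isolate the plants
  b <- a + matrix(runif(length(a), -0.5, 0.5), nrow(a))
  iqr_noise <- 0.5
  n_bad <- round(0.03 * length(sel))
  bad <- sample(sel, n_bad)
  b[bad] <- b[bad] + 10 * iqr_noise
  cmp <- raster_compare(a, b, g, buf)
  expect_true(all(cmp$outlier_mask[bad]))
  expect_lt(abs(cmp$outlier_area_fraction - 0.03), 0.01)
})
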