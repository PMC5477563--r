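# Independent brute-force implementation of the 19 bioclimatic variables,
# written as explicit loops straight from the variable definitions and
# sharing no code with the package's vectorized path. Used as the oracle in
# equivalence tests. Input: 12-vectors of monthly tmin, tmax (degC) and
# moisture (kg/kg). Output: pre-rescale values, like annual_bioclim().

oracle_bioclim <- function(tmin, tmax, moist, cv_offset = 0) {
  tavg <- numeric(12)
  for (m in 1:12) tavg[m] <- (tmin[m] + tmax[m]) / 2

  bio1 <- 0
  for (m in 1:12) bio1 <- bio1 + tavg[m] / 12

  bio2 <- 0
  for (m in 1:12) bio2 <- bio2 + (tmax[m] - tmin[m]) / 12

  ss <- 0
  for (m in 1:12) ss <- ss + (tavg[m] - bio1)^2
  bio4 <- 100 * sqrt(ss / 11)

  bio5 <- tmax[1]; bio6 <- tmin[1]
  for (m in 2:12) {
    if (tmax[m] > bio5) bio5 <- tmax[m]
    if (tmin[m] < bio6) bio6 <- tmin[m]
  }
  bio7 <- bio5 - bio6
  bio3 <- if (bio7 == 0) NA_real_ else 100 * bio2 / bio7

  # quarter = three cyclically consecutive months starting at each month
  wet_sum <- numeric(12); t_mean <- numeric(12)
  for (i in 1:12) {
    s <- 0; tm <- 0
    for (k in 0:2) {
      j <- ((i - 1 + k) %% 12) + 1
      s <- s + moist[j]
      tm <- tm + tavg[j] / 3
    }
    wet_sum[i] <- s; t_mean[i] <- tm
  }
  argmax_first <- function(v) {
    best <- 1
    for (i in 2:12) if (v[i] > v[best]) best <- i
    best
  }
  argmin_first <- function(v) {
    best <- 1
    for (i in 2:12) if (v[i] < v[best]) best <- i
    best
  }
  iw <- argmax_first(wet_sum); id <- argmin_first(wet_sum)
  ih <- argmax_first(t_mean); ic <- argmin_first(t_mean)

  bio8 <- t_mean[iw]; bio9 <- t_mean[id]
  bio10 <- t_mean[ih]; bio11 <- t_mean[ic]

  bio12 <- 0
  for (m in 1:12) bio12 <- bio12 + moist[m]
  bio13 <- moist[1]; bio14 <- moist[1]
  for (m in 2:12) {
    if (moist[m] > bio13) bio13 <- moist[m]
    if (moist[m] < bio14) bio14 <- moist[m]
  }
  ms <- moist + cv_offset
  mbar <- 0
  for (m in 1:12) mbar <- mbar + ms[m] / 12
  ssm <- 0
  for (m in 1:12) ssm <- ssm + (ms[m] - mbar)^2
  bio15 <- if (mbar == 0) NA_real_ else 100 * sqrt(ssm / 11) / mbar

  bio16 <- wet_sum[iw]; bio17 <- wet_sum[id]
  bio18 <- wet_sum[ih]; bio19 <- wet_sum[ic]

  c(BIO1 = bio1, BIO2 = bio2, BIO3 = bio3, BIO4 = bio4, BIO5 = bio5,
    BIO6 = bio6, BIO7 = bio7, BIO8 = bio8, BIO9 = bio9, BIO10 = bio10,
    BIO11 = bio11, BIO12 = bio12, BIO13 = bio13, BIO14 = bio14,
    BIO15 = bio15, BIO16 = bio16, BIO17 = bio17, BIO18 = bio18,
    BIO19 = bio19)
}

# random single-cell climatology table with valid orderings
random_clim_table <- function() {
  tmin <- runif(12, -30, 20)
  tmax <- tmin + runif(12, 0, 15)
  hmin <- runif(12, 0.0005, 0.01)
  hmax <- hmin + runif(12, 0, 0.01)
  hmean <- hmin + runif(12) * (hmax - hmin)
  data.frame(tmin = tmin, tmax = tmax, hmin = hmin, hmean = hmean,
             hmax = hmax)
}

# package path: single-cell climatology -> named pre-rescale vector
pkg_bioclim_vector <- function(tab, version = "mean", cv_offset = 0) {
  clim <- gen_monthly_climatology(tab)
  set <- annual_bioclim(clim, version = version, cv_offset = cv_offset)
  vapply(paste0("BIO", 1:19), function(v) set$layers[[v]][1, 1], numeric(1))
}
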