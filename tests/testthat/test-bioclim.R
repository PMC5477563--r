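test_that("cyclic window sums wrap past December", {
  expect_equal(cyclic_windows(rep(1, 12)), rep(3, 12))
  v <- c(1, rep(0, 11))
  w <- cyclic_windows(v)
  expect_equal(which(w == 1), c(1, 11, 12))
  expect_equal(sum(w), 3)
  expect_error(cyclic_windows(1:11), "12 values")
  # modular-index oracle on random vectors
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(12)
    oracle <- sapply(1:12, function(s)
      x[s] + x[(s %% 12) + 1] + x[((s + 1) %% 12) + 1])
    expect_equal(cyclic_windows(x), oracle)
  }
})

test_that("window selection takes the extreme with earliest-month ties", {
  expect_equal(select_window(as.numeric(1:12), "max"), 12)
  expect_equal(select_window(rep(1, 12), "max"), 1)
  expect_equal(select_window(rep(1, 12), "min"), 1)
  set.seed(2)
  for (i in 1:50) {
    x <- sample(1:6, 12, replace = TRUE)  # ties likely
    scan_max <- 1; scan_min <- 1
    for (j in 2:12) {
      if (x[j] > x[scan_max]) scan_max <- j
      if (x[j] < x[scan_min]) scan_min <- j
    }
    expect_equal(select_window(x, "max"), scan_max)
    expect_equal(select_window(x, "min"), scan_min)
  }
})

test_that("constant climatology hits the closed-form bioclim values", {
  tab <- gen_monthly_climatology("constant", c_temp = 10, h = 0.005)
  set <- annual_bioclim(tab, version = "mean", cv_offset = 0)
  l <- lapply(set$layers, function(m) m[1, 1])
  expect_equal(l$BIO1, 10); expect_equal(l$BIO2, 0)
  expect_equal(l$BIO4, 0); expect_equal(l$BIO5, 10)
  expect_equal(l$BIO6, 10); expect_equal(l$BIO7, 0)
  expect_true(is.na(l$BIO3))
  expect_equal(l$BIO12, 0.06)  # pre-rescale 12-month sum
  expect_equal(l$BIO13, 0.005); expect_equal(l$BIO14, 0.005)
  expect_equal(l$BIO15, 0)
  expect_equal(l$BIO16, 0.015); expect_equal(l$BIO17, 0.015)
})

test_that("all 19 variables match the brute-force oracle on random climatologies", {
  set.seed(101)
  for (i in 1:1000) {
    tab <- random_clim_table()
    version <- sample(c("min", "mean", "max"), 1)
    moist <- tab[[paste0("h", version)]]
    got <- pkg_bioclim_vector(tab, version = version)
    want <- oracle_bioclim(tab$tmin, tab$tmax, moist)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("oracle equivalence also holds with the classic +1 CV offset", {
  set.seed(55)
  for (i in 1:50) {
    tab <- random_clim_table()
    got <- pkg_bioclim_vector(tab, version = "mean", cv_offset = 1)
    want <- oracle_bioclim(tab$tmin, tab$tmax, tab$hmean, cv_offset = 1)
    expect_equal(got, want, tolerance = 1e-12)
    # on kg/kg values the +1 offset collapses the CV towards zero
    expect_lt(got["BIO15"],
              pkg_bioclim_vector(tab, version = "mean")["BIO15"])
  }
})

test_that("temperature variables are identical across humidity versions", {
  set.seed(7)
  temp_vars <- paste0("BIO", c(1:7, 10, 11))
  for (i in 1:25) {
    tab <- random_clim_table()
    vmin <- pkg_bioclim_vector(tab, "min")
    vmean <- pkg_bioclim_vector(tab, "mean")
    vmax <- pkg_bioclim_vector(tab, "max")
    expect_identical(vmin[temp_vars], vmean[temp_vars])
    expect_identical(vmean[temp_vars], vmax[temp_vars])
  }
})

test_that("moisture variables are cellwise monotone across versions", {
  set.seed(8)
  mono_vars <- paste0("BIO", c(12, 13, 14, 16, 17, 18, 19))
  for (i in 1:25) {
    tab <- random_clim_table()
    vmin <- pkg_bioclim_vector(tab, "min")
    vmean <- pkg_bioclim_vector(tab, "mean")
    vmax <- pkg_bioclim_vector(tab, "max")
    # BIO18/BIO19 windows are temperature-selected, hence shared; BIO16/17
    # windows are version-specific but their extremal sums still order
    expect_true(all(vmin[mono_vars] <= vmean[mono_vars] + 1e-12))
    expect_true(all(vmean[mono_vars] <= vmax[mono_vars] + 1e-12))
  }
})

test_that("month rotation leaves rotation-invariant variables unchanged", {
  set.seed(9)
  inv_vars <- paste0("BIO", c(1:7, 10:17))
  for (i in 1:10) {
    tab <- random_clim_table()
    r <- sample(1:11, 1)
    rot <- tab[((seq_len(12) - 1 + r) %% 12) + 1, ]
    a <- pkg_bioclim_vector(tab, "mean")
    b <- pkg_bioclim_vector(rot, "mean")
    expect_equal(a[inv_vars], b[inv_vars], tolerance = 1e-12)
    # selected window start months rotate accordingly
    w1 <- select_window(cyclic_windows(tab$hmean), "max")
    w2 <- select_window(cyclic_windows(rot$hmean), "max")
    expect_equal(((w1 - 1 - r) %% 12) + 1, w2)
  }
})

test_that("isothermality is bounded by 100 wherever defined", {
  set.seed(10)
  for (i in 1:100) {
    tab <- random_clim_table()
    b <- pkg_bioclim_vector(tab, "mean")
    if (!is.na(b["BIO3"])) expect_lte(b["BIO3"], 100 + 1e-9)
    expect_gte(b["BIO3"], 0)
  }
})

test_that("ecological rescale divides the moisture sums once and only once", {
  tab <- gen_monthly_climatology("constant", c_temp = 10, h = 0.005)
  raw <- annual_bioclim(tab, "mean")
  out <- apply_ecological_rescale(raw)
  expect_equal(out$layers$BIO12[1, 1], 0.005)  # 0.06 / 12
  expect_equal(out$layers$BIO16[1, 1], 0.005)  # 0.015 / 3
  expect_equal(out$layers$BIO1[1, 1], raw$layers$BIO1[1, 1])
  expect_error(apply_ecological_rescale(out), "already applied")
})

test_that("post-rescale monthly/annual moisture ordering holds", {
  set.seed(11)
  for (i in 1:1000) {
    tab <- random_clim_table()
    set <- apply_ecological_rescale(
      annual_bioclim(gen_monthly_climatology(tab), "mean"))
    b12 <- set$layers$BIO12[1, 1]
    expect_lte(set$layers$BIO14[1, 1], b12 + 1e-15)
    expect_lte(b12, set$layers$BIO13[1, 1] + 1e-15)
    expect_lte(set$layers$BIO17[1, 1], b12 + 1e-12)
    expect_lte(b12, set$layers$BIO16[1, 1] + 1e-12)
  }
})

test_that("decadal means are idempotent, linear and validated", {
  tab <- gen_monthly_climatology("constant", c_temp = 0, h = 0.005)
  tab2 <- gen_monthly_climatology("constant", c_temp = 10, h = 0.005)
  a <- annual_bioclim(tab, "mean"); b <- annual_bioclim(tab2, "mean")
  same <- decadal_mean(rep(list(a), 10), period = "80s")
  expect_equal(same$layers, a$layers)
  expect_equal(same$period, "80s")
  mix <- decadal_mean(list(a, b))
  expect_equal(mix$layers$BIO1[1, 1], 5)
  # linearity: mean of BIO7 equals mean(BIO5) - mean(BIO6)
  set.seed(12)
  sets <- lapply(1:5, function(i)
    annual_bioclim(gen_monthly_climatology(random_clim_table()), "mean"))
  dec <- decadal_mean(sets)
  expect_equal(dec$layers$BIO7, dec$layers$BIO5 - dec$layers$BIO6,
               tolerance = 1e-12)
  cmix <- annual_bioclim(tab, "max")
  expect_error(decadal_mean(list(a, cmix)), "versions")
  expect_error(decadal_mean(list(a, apply_ecological_rescale(b))), "rescale")
})

test_that("missing monthly inputs blank all 19 variables for the cell", {
  tab <- random_clim_table()
  clim <- gen_monthly_climatology(tab)
  clim$tmin[1, 1, 5] <- NA
  set <- annual_bioclim(clim, "mean")
  for (v in paste0("BIO", 1:19)) expect_true(is.na(set$layers[[v]][1, 1]))
})

test_that("decade labels partition the 30-year span", {
  expect_equal(decade_years("80s"), 1981:1990)
  expect_equal(decade_years("90s"), 1991:2000)
  expect_equal(decade_years("00s"), 2001:2010)
})
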