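Package: humidclim
Title: Bioclimatic Variable Rasters from Hourly Gridded Temperature and Specific Humidity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds the 19 bioclimatic variables (BIO1-BIO19) used in species
    distribution modelling from hourly gridded 2 m air temperature and 2 m
    specific humidity, using specific humidity in place of precipitation as
    the moisture axis. Reduces CF-style NetCDF hourly cubes to monthly
    climatologies of temperature extremes and humidity min/mean/max, computes
    annual and decadal bioclimatic sets in three humidity versions (monthly
    minimum, mean or maximum), downscales decadal layers to 10, 5 and 2.5
    arc-minute grids with a regularized thin-plate spline, and exports
    integer-scaled single-band GeoTIFFs under a fixed naming convention.
    Includes a synthetic-data generator for hourly climate cubes and weather
    station series, and validation statistics: grid-to-station collocation
    with ordinary least squares regression and residual interquartile range,
    station-side bioclimatic summaries, and buffer-zone raster comparison
    with Tukey-fence outlier mapping.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
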