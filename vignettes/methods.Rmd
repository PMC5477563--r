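---
title: "Methods: building humidity-based bioclimatic rasters from hourly fields"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: building humidity-based bioclimatic rasters from hourly fields}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`humidclim` turns hourly gridded 2 m air temperature and 2 m specific
humidity into the 19 bioclimatic predictors used in species distribution
modelling, with specific humidity as the moisture axis, and ships the
validation statistics used to compare such gridded products against
weather-station records. This vignette documents the model choices, the
tunable parameters, the numerical conventions, and what the test suite
does and does not demonstrate.

## From hourly fields to monthly climatologies

The unit of input is an *hourly cube*: temperature (Kelvin) and specific
humidity (kg water / kg air) on a regular latitude/longitude grid with a
strictly increasing hourly time axis, interchange format CF-style
NetCDF-3 (`T2M`, `QV2M`, dimensions `time`/`lat`/`lon`; the package
normalizes south-up files to its north-up convention). For each calendar
year and month, every cell is reduced to five numbers: `tmin`, `tmax`
(min/max over *all hourly values* of the month, converted K → °C by
subtracting 273.15) and `hmin`, `hmean`, `hmax` (min, arithmetic mean,
max of hourly humidity).

Two conventions deserve emphasis:

* **Monthly extremes are hourly extremes.** Station-interpolated
  climatologies usually build monthly values from daily extremes;
  reading the extremes directly off hourly data yields wider monthly
  ranges (BIO2, BIO5–BIO7 respond to this). Users comparing against
  daily-derived layers should expect this systematic difference.
* **Coverage is explicit.** A month is only reduced if at least
  `min_coverage` (default 0.9) of its hours are present; otherwise the
  reduction fails naming the month and the observed fraction. Gaps in
  real station or gridded series (e.g. a station silent for half a year)
  must be handled deliberately, never silently.

`hmean` is the plain arithmetic mean of the hourly values; no
time-weighting is applied, since the time axis is regular.

## The 19 variables and the three humidity versions

With monthly mean temperature t̄ = (tmin + tmax)/2 and a monthly moisture
series m (one of `hmin`/`hmean`/`hmax`, selected by the *version*
V_min/V_mean/V_max), the pre-rescale set is:

| group | definition |
|---|---|
| BIO1, BIO2 | mean of t̄; mean of (tmax − tmin) |
| BIO3 | 100·BIO2/BIO7 (undefined where BIO7 = 0) |
| BIO4 | 100 × sample SD (n − 1) of the 12 t̄ values |
| BIO5, BIO6, BIO7 | max tmax; min tmin; BIO5 − BIO6 |
| BIO8, BIO9 | mean t̄ of the quarter with max/min Σm |
| BIO10, BIO11 | max/min over quarters of mean t̄ |
| BIO12, BIO13, BIO14 | Σm; max m; min m |
| BIO15 | 100·sd(m + c)/mean(m + c), sample SD |
| BIO16, BIO17 | Σm of the quarter with max/min Σm |
| BIO18, BIO19 | Σm of the warmest/coldest quarter (by mean t̄) |

*Quarters* are the 12 cyclically consecutive 3-month windows (December
wraps to {12, 1, 2}); ties in window selection go to the earliest start
month. Humid/arid quarters rank windows by the moisture *sum*; with all
12 months present this ranking is identical to ranking by the mean.

Since cumulative specific humidity has no ecological meaning, the
*ecological rescale* divides BIO12 by 12 and BIO16–BIO19 by 3, turning
sums into annual and quarterly means. The operation records itself in the
set (`rescaled` flag) and refuses double application.

**The BIO15 offset `c` (`cv_offset`).** Precipitation-oriented
implementations add +1 (mm) to the monthly series before the coefficient
of variation, to tolerate all-zero months. On kg/kg values (order 0.01)
an offset of 1 collapses the CV to nearly zero, so the package defaults
to `cv_offset = 0` (ecologically meaningful CV of humidity) and offers
`cv_offset = 1` for literal emulation of the classic recipe. Neither
choice is asserted to match any published layer set. With `cv_offset = 0`
and a zero moisture mean, BIO15 is missing.

**Versions.** BIO1–BIO7, BIO10 and BIO11 depend only on temperature and
are bit-identical across versions; the moisture variables are cellwise
monotone V_min ≤ V_mean ≤ V_max (BIO18/BIO19 windows are
temperature-selected and therefore shared across versions). Both facts
are enforced as test invariants.

**Missing data.** A cell-year with any missing monthly input is missing
in all 19 outputs. Decades are plain arithmetic means of annual sets
(80s = 1981–1990, 90s = 1991–2000, 00s = 2001–2010, partitioning a
30-year span); mixing grids, versions or rescale states is an error.

## Downscaling: local regularized thin-plate spline

Decadal float layers are interpolated to 10, 5 and 2.5 arc-minute
cell-center grids. For each target cell center the `n_neighbors` nearest
non-missing source cell centers are gathered (window search on the
regular source grid; with `longitude_wrap` the search and the distances
wrap across the antimeridian) and a 2-D thin-plate spline with kernel
φ(r) = r²·log r plus an affine polynomial part is solved:

```
[ K + w·I   P ] [ a ]   [ z ]        P = [1  x  y],  evaluated at the
[   Pᵀ      0 ] [ b ] = [ 0 ]        target point (local origin)
```

`weight` (w ≥ 0) is added to the kernel diagonal; it trades fidelity at
the data points against curvature. Three exact properties follow from
this formulation and are tested: w = 0 interpolates exactly through the
source values (node reproduction ≤ 1e−6); affine fields — hence
constants — are reproduced exactly for *any* w, because the polynomial
part absorbs them; and the output is linear in the input layer for fixed
neighborhoods (≤ 1e−9).

Defaults `weight = 0.1`, `n_neighbors = 12` mirror the documented
defaults of the widely used GIS regularized-spline tool this emulates;
that tool's exact tension semantics are proprietary, so numerical
equality with rasters produced by it is not claimed anywhere. A local
(moving-neighborhood) spline is used rather than one global spline: a
global fit over a native grid of ~200,000 cells is a dense O(n³) solve
and computationally out of reach, and the GIS tool is likewise
neighborhood-based. Coordinates are treated in plain degrees (no
projection; no latitude weighting of distances); poles are clamped; no
land/sea mask is applied — the `extent` argument lets users crop.
Degenerate neighborhoods (a singular spline system, e.g. collinear
points) fall back to inverse-distance weighting with a warning count.

Interpolation happens on float layers *before* integer quantization, and
the ecological rescale is applied before quantization as well, although
the original step order lists integer conversion first — dividing
already-quantized integers would discard precision for no benefit. Each
of the 19 layers is interpolated independently, so the identity
BIO7 = BIO5 − BIO6 holds only approximately after downscaling; on a
smooth synthetic set the maximum violation is measured in the tests and
required below 0.1 °C.

## Integer export

GeoTIFF layers are signed 16-bit, nodata −32768, geographic WGS 84,
north-up, rounding half-away-from-zero. Scale factors: ×10 for the °C
variables (BIO1–BIO11), ×100000 for the kg/kg variables
(BIO12–BIO14, BIO16–BIO19). BIO15 is a percentage; scaling a CV of
tens of percent by 100000 cannot fit any 16-bit integer, so BIO15 is
stored ×100 (precision 0.01 %). Scaled magnitudes above 32767 raise an
overflow error naming the cell — never a silent wraparound. The
round-trip error is bounded by half a quantum (0.05 °C, 5e−6 kg/kg)
and tested on 10,000 random values. File and folder names follow
`resolution_version_decade[_BIOn]`, a bijection over the 513 valid
combinations (3 resolutions × 3 versions × 3 decades × 19 variables).

The NetCDF-3 classic and single-band GeoTIFF codecs are implemented in
the package (fixed dimensions, uncompressed strips — exactly the subset
the pipeline needs) so the tool has no external geospatial system
dependencies; both were cross-validated against independent readers
during development.

## Validation statistics

*Collocation* pairs a station with the nearest cell center (ties to the
lowest row, then column index; no bilinear interpolation — raw cells are
what is being validated) on the exact common timestamps; 6-hourly
stations are matched at their reported hours. *series_stats* then
reports Pearson's r, an OLS fit, R² (= r² for simple OLS, asserted to
1e−12), and the quartiles/IQR of the residuals, plus per-calendar-month
five-number residual summaries. The regression is oriented with the
**gridded series as response** and the station as predictor, so "the
gridded data run colder" reads as slope < 1 with a negative intercept;
the orientation is switchable. The scalar "bias" summary is the residual
IQR itself, not ±IQR/2.

Note one statistical consequence of validating against noisy stations:
with observation noise on the predictor, OLS attenuates the slope by
var(signal)/(var(signal) + b²σ²). The synthetic recovery tests plant
slopes of 0.69–0.86 with 2 °C station noise on a high-variance
(Antarctic-like, 20 °C seasonal amplitude) series, which keeps the
attenuation inside the ±0.02 recovery band at n = 10,000; the same
attenuation applies to real comparisons.

*Buffer comparison* restricts two rasters to square degree-space buffers
of area 1/3 square degree (side √(1/3) ≈ 0.577°) around stations — the
native cell area; a square avoids great-circle polygon machinery since
only the area is specified. Overlapping buffers are unioned (no double
counting), polar buffers are clipped with the clipped area reported.
Outlier cells are flagged from the OLS residuals by the Tukey fences
Q1 − 1.5·IQR / Q3 + 1.5·IQR, and the outlier *area* fraction uses
cos(latitude) cell weights. All quantiles in the package use linear
interpolation between order statistics (R type 7). Residuals that are
pure floating-point dust relative to the response scale (an exactly
linear relation between the rasters) are treated as exact fits, so
identical or shifted rasters report zero outliers. For a normal sample
the fences asymptotically flag a fraction 2·P(Z > 2.698) ≈ 0.007, which
the tests reproduce by Monte Carlo at n = 100,000 (±0.002).

*Station-side bioclim* builds monthly extremes from the station's own
observations (extremes of the available records, at the station's 1- or
6-hour step) and applies the temperature-only formulas (BIO1–BIO7,
BIO10, BIO11); when the station series is a cube cell itself, this path
and the gridded path agree exactly, which is tested.

## The synthetic generator: what it does and does not emulate

`gen_climate_cube()` produces temperature as
`T(lat, d, h) = T_eq − γ·|lat| + A_s·s(lat)·cos(2π(d − 15)/365.25) +
A_d·cos(2π(h − 14)/24) + ε`, with `s(lat) = −sign(lat)` (annual cycle
peaking mid-January in the southern hemisphere), ε i.i.d. Gaussian per
cell-hour, and humidity `q_ref·exp(k·T_C)` clipped to [1e−6, 0.04]
kg/kg, computed from the noisy temperature so humidity is monotone in
temperature. Defaults: T_eq = 26 °C, γ = 0.55 °C/°, A_s = 12 °C,
A_d = 5 °C, σ = 2 °C, q_ref = 0.004 kg/kg, k = 0.06 /°C — a
Clausius–Clapeyron-like ~6 %/°C coupling giving ~0.019 kg/kg in the
tropics and ~4e−4 at −40 °C. The calendar is proleptic Gregorian UTC
with leap days; the diurnal peak is a single UTC phase (no local-solar
offset — monthly min/max extraction is insensitive to phase); the day
index is constant within a day so a zero-noise cube has an exactly
10 °C daily range at A_d = 5.

What it deliberately lacks: spatial noise correlation, topography,
weather systems, humidity saturation physics, land/sea contrast. Passing
tests therefore demonstrate the *correctness of the transformations* —
aggregation, formulas, interpolation, quantization, statistics — not the
climatological realism of any output layer.

`gen_station_series()` inverts a planted linear relation: station =
(truth − intercept)/slope + noise, subsampled to a 1- or 6-hour step, so
regressing the gridded series on the station recovers the planted
(slope, intercept) up to the attenuation discussed above.

## Problem sizes and runtime choices

The test suite and the acceptance script run a deliberately desk-scale
study: a 36 × 18-cell native grid (0.5° cells over an 18° × 9° region),
one decade of ten synthetic years round-tripped through NetCDF, one
humidity version, downscaled to all three output resolutions
(~122,000 target cells × 19 layers) and packaged as 57 GeoTIFFs;
statistical checks use n = 10,000 collocation pairs, 1,000 random
single-cell climatologies against a brute-force oracle, and n = 100,000
for the Tukey-fence rate. These sizes exercise every code path,
including the cyclic window logic and both humidity coupling regimes,
while keeping a full run in minutes on one core. A global native grid
(540 × 360) is supported by the same code; only wall-clock time grows.

## Known limitations

* No record-dimension or NetCDF-4/HDF5 input; no curvilinear or
  rotated-pole grids; no sub-hourly data.
* No precipitation mode: the moisture axis is specific humidity by
  design.
* The spline is not claimed to match any proprietary implementation
  numerically; an ordinary-kriging alternative is left as a pluggable
  extension.
* No quality filtering of hourly values before taking extremes; outliers
  in the input propagate into BIO5/BIO6.
* Buffer geometry is square in degree space; at extreme latitudes the
  true ground area of a buffer varies strongly (cos-latitude weighting
  is applied to *area fractions*, not to buffer shapes).
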