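---
title: "AHP-weighted land suitability for coffee: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{AHP-weighted land suitability for coffee: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agrisuit)
```

This vignette is the package's account of its science: the model, the
choices that were genuinely open, the numerical conventions, and what the
synthetic tests do and do not establish about real data.

## The model

Land suitability for coffee is computed by weighted linear combination over
14 thematic criteria grouped under four main factors:

* **climatological** — mean annual rainfall (mm), average annual
  temperature (°C), annual mean minimum and maximum temperature (°C);
* **edaphic** — soil pH, texture class, cation exchange capacity
  (cmol+/kg), soil organic matter (%);
* **physiographic** — elevation (m a.s.l.), slope (%), aspect;
* **socioeconomic** — land use / land cover, distance to roads and to
  rivers (m).

Each raw layer is reclassified to an ordinal score $x_i \in \{1,2,3\}$
(unsuitable / sub-suitable / suitable) by fixed agronomic thresholds, and
the per-pixel suitability score is $S = \sum_i w_i x_i$ with
$\sum_i w_i = 1$, so $S \in [1, 3]$ wherever all inputs are valid.

### AHP weights

Weights come from reciprocal pairwise comparison matrices on the Saaty 1–9
scale (fractional judgments such as 3/2 permitted, parsed exactly as
rationals). The package uses the *column-normalise and row-average*
estimator — divide each entry by its column sum, then average rows — because
that is how the reference weight tables are computed by hand; the principal
eigenvector (available through the power-iteration oracle used in the test
suite) agrees with it to well under one printed unit for near-consistent
matrices, and is deliberately **not** the default so that printed tables
are reproduced digit for digit.

Consistency is diagnosed with $\lambda_{max}$ estimated as the mean of
$(A w)_i / w_i$ over rows (the "weighted sum and priority" form, again
matching hand computation rather than an eigendecomposition),
$CI = (\lambda_{max} - n)/(n-1)$ and $CR = CI / RI(n)$. The RI table is
Saaty's (0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49 for
$n = 1..10$); RI tables differ slightly between authors, so
`ahp_consistency(ri = ...)` exposes the table. `compose_weights()` refuses
any hierarchy containing a matrix with $CR$ above the threshold (default
0.1) unless forced, naming the offending matrix.

Two quirks of the shipped worked hierarchy (`coffee_hierarchy()`) are worth
recording. First, the published meteorological matrix is not exactly
reciprocal in one pair (the average-temperature / maximum-temperature
judgments are recorded as 2 and 2/3); the fixture keeps the matrix verbatim
— its printed weights only reproduce with those entries — and is built with
a loosened reciprocity tolerance, while `pairwise_matrix()` itself enforces
$a_{ij} a_{ji} = 1$ to $10^{-9}$ by default. Second, the socioeconomic
main-factor weight computes to 0.0972; the reference table truncates it to
0.09. Neither affects the composite ordering of criteria.

### Reclassification rules

`coffee_criteria()` ships the full threshold set. Continuous intervals are
**lower-closed, upper-open** $[a, b)$: a boundary value belongs to the
class whose interval starts there, so rainfall 1600 mm is suitable and
1800 mm is sub-suitable. This convention is applied uniformly; it is the
only self-consistent reading of threshold rows written as touching ranges.

Aspect is binned into eight 45° compass sectors centred on the cardinal and
intercardinal bearings (N = [337.5°, 22.5°)); the cool, shaded N/NE/NW
slopes score 3, E/W score 2, and S/SW/SE score 1. Flat cells have no
defined aspect (flagged −1 by `aspect_degrees()`) and score 3 by default on
the rationale that flat ground carries no aspect penalty; `aspect_to_score()`
exposes this as `flat_score`.

The minimum-temperature row of the shipped rule set scores ">18 °C" as
suitable, which a cool highland study region will rarely attain — real
landscapes there will see mostly 2s for this criterion. The rules are
encoded as published; users with a divergent agronomic reference can
replace any `criterion_spec` without touching the pipeline.

Unknown categorical codes fail loudly by default (no silent default score);
a `default_score` can be set per criterion.

Elevation is additionally classifiable into the six traditional Ethiopian
agro-ecological zones (Berha < 500 m through High Wurch > 3700 m) with
`classify_agroecology()`; the bands partition every finite elevation.

### Derived surfaces

* **Temperature surfaces** are interpolated from station records with
  inverse distance weighting, $z(c) = \sum_s v_s d_{cs}^{-p} / \sum_s
  d_{cs}^{-p}$, power $p = 2$, all stations used (with a handful of
  stations a neighbourhood cutoff is pointless; both are arguments). IDW is
  an exact interpolator — a cell centre within `eps` of a station returns
  the station value — and its output is bounded by the station value range.
  Station latitude/longitude must be projected to the raster's planar frame
  before interpolation; the synthetic tests use an identity projection.
* **Average annual temperature** is taken as the cellwise mean of the
  minimum and maximum surfaces when no dedicated average layer is supplied;
  whether the reference product was derived that way is not stated, so the
  pipeline accepts a precomputed layer instead.
* **Slope and aspect** use the Horn 3×3 finite-difference gradient with
  replicated borders; slope is reported in percent
  ($100\sqrt{g_x^2+g_y^2}$) to match the threshold table's unit, and aspect
  is the direction of steepest **descent** in degrees clockwise from north
  (the common GIS convention; stated prominently because the N/NE/NW rule
  depends on it). Replicated borders mean edge cells of an inclined plane
  see roughly half the true gradient — an accepted edge effect; properties
  are asserted on interior cells.
* **Distance to roads/rivers** is the exact point-to-segment Euclidean
  distance from each cell centre to the nearest polyline, in metres — no
  raster-dilation approximation at these problem sizes.

### SAR coffee mapping

Ground-truth coffee points are overlaid on a calibrated backscatter scene
(any single dB band; the method is date- and polarization-agnostic, and
assumes speckle filtering and terrain correction already happened). The
cell under each point is sampled without interpolation — cell footprints
are half-open, points on shared edges resolve to the right/lower cell,
points on nodata are flagged and excluded. The threshold interval is the
exact minimum/maximum of the sampled values (`trim_fraction = 0`;
positive trims use inverse-ECDF order statistics to shed outliers — whether
the reference analysis trimmed is unstated, so the default is no trim).
The mask is **closed** on both ends: boundary dB values count as coffee.
Area follows as cell count × pixel area.

### Overlay, classification, accuracy

`weighted_overlay()` enforces co-registration (shape, pixel size, origin)
and a unit weight sum, and propagates nodata strictly: any missing
criterion voids the cell, preventing silently under-weighted scores. An
optional `reweight_missing` mode renormalises weights over present layers
per cell; it is off by default.

The continuous score is cut at two breaks into three classes. The reference
analysis never states its break rule, so any order-preserving choice is
admissible; the default is the equal-width thirds of $[1,3]$ (5/3, 7/3),
always recorded in the run report. Areas are tabulated per class in km²
and percent of valid area.

Classification accuracy against reference data uses the standard confusion
matrix: overall accuracy is the trace over the total, Cohen's kappa is
$(p_o - p_e)/(1 - p_e)$ with $p_e$ from the row/column marginals; kappa is
reported as undefined (`NA` with a warning) when $p_e = 1$.

## The synthetic landscape generator

`generate_landscape()` emulates the structure of a highland coffee zone so
every stage has known ground truth:

* smoothed Gaussian random fields (white noise, separable Gaussian blur,
  affine rescale) for elevation (1329–3088 m), rainfall (1093.02–1667 mm),
  pH (4–7.5), SOM (0–6 %), CEC (0–43 cmol+/kg) — endpoints attained
  exactly by construction;
* minimum/maximum temperature as affine functions of elevation through a
  lapse rate (default 0.0065 °C/m, the standard environmental lapse rate,
  consistent with the shipped station table) plus small smooth noise, so
  DEM–temperature correlation is strongly negative by design;
* land cover with the 2021 reference class shares (agroforestry 44.54 %,
  farmland 41.34 %, forest 7.33 %, settlement 4.85 %, wetland 1.22 %,
  grassland 0.72 %) and soil texture with the reference clay/loam/sandy-loam
  shares, both realised by rank-assignment on a smoothed field — classes
  are spatially coherent and proportions exact up to integer rounding;
* coffee patches as the top `coffee_fraction` of an independent smooth
  field restricted to agroforestry cells; patch cells receive dB values
  inside [−19.034781, −10.773612], background cells inside a disjoint
  interval (default [−26, −21]). With `db_noise_sd` > 0, noise is truncated
  at ±2σ and values are drawn with a 2σ interior margin — "confined" noise
  that cannot move a cell across the threshold;
* ground-truth points sampled inside patches, always including the cells
  with the lowest and highest patch dB so the derived min/max interval
  spans the whole planting (the analogue of stations carrying exact local
  temperatures: the generator gives the estimator exact ground truth);
* stations at random cells with the exact local layer values; roads and
  rivers as random edge-to-edge polylines.

Everything derives from one seed; a fixed seed reproduces the landscape
bit for bit.

**What passing tests show, and what they do not.** The synthetic fields are
smooth, isotropic and independent across criteria (except the designed
DEM–temperature coupling); real landscapes have anisotropy, cross-correlated
soils and terrain, registration error, SAR speckle and mixed pixels. Tests
on this generator establish the *correctness of the computations* —
weights, reclassification, overlay arithmetic, threshold recovery — not the
*field accuracy* of the method. In particular the exact (Jaccard = 1) patch
recovery is a property of the constructed separation between coffee and
background dB, not a claim about Sentinel-1 scenes; the reference
real-data figures (583 km² coffee cover, the class-area table, 88.18 %
overall accuracy / 0.86 kappa) require the original rasters and are out of
scope here.

## Numerical conventions

* Ordering conventions: row 1 is the northernmost row; geo-coordinates are
  cell centres for point sampling and cell edges for extents; point-in-cell
  uses half-open footprints with shared edges resolving right/down.
* Nodata is `NA` in memory, a sentinel (−9999, or 255 for class masks) on
  disk; nodata cells never enter statistics.
* Comparisons against printed tables round half away from zero
  (`round_half_up()`) at the printed precision, as decision-analysis tables
  conventionally do.
* Reciprocity, weight-sum and co-registration tolerances are $10^{-9}$,
  $10^{-6}$ and $10^{-6}$ respectively; trimmed thresholds use type-1
  (inverse ECDF) quantiles so they are always observed order statistics.
* Default problem sizes: unit tests run on grids between 8×8 and 64×64 with
  one 128×128 proportion check; the end-to-end property check runs the full
  pipeline at 512×512, a size chosen to exercise memory/runtime behaviour
  while keeping the whole suite comfortably under a minute.

## Limitations

* No reprojection: all inputs must share one planar grid (a
  nearest-neighbour resample utility is the only geometry adjustment).
* The AHP implementation is single-decision-maker; no group aggregation,
  fuzzy AHP or incomplete-matrix completion.
* SAR preprocessing (calibration, speckle filtering, terrain correction)
  and optical classification are upstream of this package; it consumes
  calibrated dB and categorical LULC rasters.
* Raster I/O is plain-text ASCII grid — robust and dependency-free, but not
  suited to very large scenes.
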