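---
title: "Methods: cover-crop detection, sequence accounting, and SOC estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cover-crop detection, sequence accounting, and SOC estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covertrace)
```

## The problem

Regional cover-crop accounting asks three linked questions on a 30-m pixel
grid: *where* are winter cover crops (a binary classification of cultivated
pixels from winter reflectance composites), *how do they sit inside cropping
sequences* (which summer cash crops bracket a covered winter), and *what do
they amount to* (county acreage, split into government-subsidized and
voluntary shares, and the soil organic carbon that acreage could sequester).
`covertrace` implements each stage behind explicit contracts, and ships a
synthetic-scene generator so the whole chain is testable against known truth.

## Detection model and assumptions

A winter field with an established cover crop is green; bare or
residue-covered fields are not. The package encodes this as an NDVI rule:
ground-truth points labelled *cover* whose winter NDVI is **not strictly
greater than 0.3** are discarded before training. The rule exists because
program ground-truth points are sometimes recorded at the farmstead rather
than in the field; such points land on non-field pixels with low NDVI. Only
cover-labelled points are filtered — the *none* class legitimately contains
low-NDVI bare fields, so filtering it would delete the negatives. The
boundary is strict: NDVI = 0.3 exactly is dropped, 0.31 is kept.

Classification is pluggable. The default is an in-package random forest
(CART trees, Gini splits, bootstrap + `mtry` feature subsampling) over the
features `{NDVI, red, NIR}`; a pure threshold rule (`NDVI > 0.3`) is kept as
a second, independent route so forest predictions can be checked against a
closed-form classifier on separable scenes. The feature list is
configuration, not hard-coded, because real deployments composite multiple
bands and indices. A random seed is mandatory and threaded through the
train/validation split (stratified, 70/30 by default) and the forest fit.

Winter wheat is treated as a cover crop rather than a grain crop; the
`winter_wheat_grain_share()` proxy (harvested wheat over total cropland,
yearly percent) bounds the error of that assumption as a standalone report —
it is *not* applied as a correction to acreage.

## Sequence accounting

Crop rasters are reclassified to seven classes (Corn, Cotton, Rice, Sorghum,
Soybean, Double Crops, Minor Crops); a consolidated level folds rice,
sorghum, double crops and minor crops into *Other Crops*. Fallow/idle land
must stay in the cropping sequence; which class houses it is genuinely open,
and the package defaults to Minor Crops with the mapping exposed as
configuration.

`combine_rasters()` cross-tabulates 2–3 co-registered categorical layers:
every unique value tuple is a pattern, labels render as
`"Soybean – CC – Soybean"`, and tables sort by area descending with
lexicographic tie-breaks so output is deterministic. Three conventions
matter:

* **Winter alignment.** The cover layer for the winter between years *t* and
  *t + 1* is indexed by *t*, pairing it with year *t*'s crop raster.
* **Denominator.** Percentages divide by the accountable pixels of that
  combine: a pixel with nodata in *any* input leaves numerator and
  denominator together. Area is conserved exactly in pixel counts.
* **No suppression.** Published rotation tables often show exact zeros that
  suggest a minimum-area reporting rule; none is stated anywhere we could
  verify, so no suppression is applied by default (a reporting threshold is
  exposed as configuration via `top_k`).

Per-pixel area is `pixel_size_m² × 0.000247105` acres/m² (0.22239 acres for
a 30-m pixel), carried in double precision and rounded only at report time.

## Adoption decomposition

`voluntary = total − government` is computed row-wise and exactly on
`(county, year)` keys. Negative voluntary acreage — the classifier
under-predicting against the subsidy ledger — is retained and flagged,
never clamped, because silent clamping would break the ledger identity that
downstream SOC additivity relies on. The Pearson correlation between
government and voluntary acres defaults to county-year pairs; a yearly
level is provided, but no published correlation value is treated as a
reproduction target because the pairing level behind such values is
generally unstated.

## SOC model

For cover-crop acreage `CCA` (acres) the model chains: total above- and
belowground biomass in tons (`T_AG = AG·CCA/2000`, `T_BG = BG·CCA/2000`),
incorporation of aboveground residue (`I_AG = T_AG·(1−P)` — the fraction
`P` stays on the surface to satisfy the ~30% conservation-tillage residue
threshold), biomass reaching the soil (`T_BS = T_BG + I_AG`), carbon input
(`C_S = T_BS·Conc`), and carbon surviving microbial processing
(`T_SCM = C_S·E`). The rate `R = T_SCM/CCA` cancels the acreage:

```{r}
soc_rate()           # tons C/acre/year
convert_rate(soc_rate())  # Mg/ha/year
```

Defaults: `AG = 3500` and `BG = 1747` lbs/acre (a conservative total of
5247 lbs/acre split roughly 2/3 : 1/3; `soc_params_biomass()` exposes the
total-plus-fraction parameterization), `P = 0.30`, `Conc = 0.50`,
`E = 0.50`. Full precision (0.524625) is carried internally; printed output
rounds to two decimals. Published per-year SOC tables computed from the same
constants imply an effective rate of ≈0.52467 — a <0.01% discrepancy whose
rounding source (1747 vs 1750 lbs/acre belowground) is unstated — so table
comparisons in the tests use a relative tolerance of 1e-3 rather than a
guess at the original spreadsheet. Likewise a printed 1.16 Mg/ha/year
corresponds to the two-decimal 0.52 rather than the exact 0.5246
(0.52 × 2.2417 = 1.166), so the conversion is asserted only at ±0.01 Mg/ha.
The unit factor is exact: 1 ton/acre = 907.18474 kg / 0.40468564224 ha =
2.2417022 Mg/ha, and the conversion round-trips to 1e-12.

## The synthetic generator: what it emulates, and what it does not

`generate_scene()` produces, on one shared grid: per-year crop rasters
evolving under a row-stochastic rotation matrix (default: soybean-dominant
with a strong rice/soybean alternation, first-year shares roughly matching
regional planted acreage); an i.i.d. cultivated mask (default 90%
cultivated); per-winter Bernoulli cover truth at the configured adoption
rate (default 0.3, optionally per class); winter NDVI drawn from truncated
normals — covered pixels `N(0.65, 0.08)`, bare `N(0.12, 0.07)`, both
truncated to [−1, 1] — with red/NIR solved from a uniform brightness so the
band ratio reproduces the drawn NDVI exactly; rectangular county strips; and
ground-truth points (default 400/winter) of which a configured fraction of
the cover-labelled ones (default 10%) is displaced onto non-cultivated
pixels with the label kept, emulating farmstead GPS fixes.

Default choices a scientist should know: the NDVI separation puts >99.99%
of covered pixels above the 0.3 threshold (the bare class leaves ~0.5%
above it — that is the detection noise); the subsidy ledger covers 25% of
true covered acres with 5% multiplicative noise, clamped to never exceed
truth; one winter composite stands in for the November–March 16-day series
(the compositing window is a modelling choice here, not something the
abstraction preserves).

What the generator does **not** emulate: clouds and atmospheric effects,
spatially correlated fields (pixels are independent given class), mixed
pixels at field boundaries, multi-sensor fusion, or label noise in the
*none* class. A green classification test therefore establishes that the
pipeline recovers a world with clean radiometry and honest negatives — not
that any particular real-world accuracy is attained.

## Numerical and degenerate-case choices

* Nodata is `NA` (written as −9999 in ASCII grids) and excluded from every
  count, numerator and denominator.
* All rasters must be exactly co-registered; there is no resampling, and a
  geometry mismatch is an error, never a silent alignment.
* Forest ties (even vote) go to the first class level (`cover`);
  zero-variance correlations, single-label training sets, empty cover point
  sets after filtering, and first-year-zero trend baselines are errors, not
  warnings.
* `NDVI = 0/0` (red = NIR = 0) is nodata, not zero.
* Stage outputs are files; each pipeline stage re-reads its inputs from
  disk, so any stage reruns standalone and manifests carry md5 checksums.

## Build choices forced by the environment

The package targets a plain scientific-R installation: rasters are
matrix-backed with ESRI ASCII grid / GeoJSON / CSV serialisation rather than
GeoTIFF (no GDAL-backed R package is assumed), and the random forest is
implemented in-package (no forest package is assumed). Both sit behind the
same interfaces a GIS-backed implementation would use, so swapping in
`terra` I/O or `ranger` models would not change any contract.

## Known limitations

Sequences are two-summer windows; persistence of a rotation beyond that
window is out of scope. The SOC model is a static humification chain —
linear in acreage, with no decomposition kinetics, soil-texture dependence,
depth resolution, or saturation — and is intended as a conservative
what-if estimate, not a process model. Classification accuracy on real
imagery is not claimed anywhere: acceptance is property-based parameter
recovery on synthetic truth.
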