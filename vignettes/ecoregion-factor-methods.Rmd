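---
title: "Computing Ecoregion Factors: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computing Ecoregion Factors: model, assumptions and design choices}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecofactor)
```

## The problem

Life cycle impact assessment (LCIA) methods that score biodiversity damage
from land use need a way to express that a hectare converted in, say, the
Madagascar humid forests matters more globally than a hectare in a
low-diversity region. The Ecoregion Factor (EF) is that weight: a
dimensionless multiplier per terrestrial ecoregion, with the least-valued
ecoregion as the baseline 1, by which a generic per-area biodiversity
impact is scaled to its location. `ecofactor` implements the full
computation of the EF — from spatial input layers to the ecoregion-level
and country-level deliverable tables — plus a synthetic-data generator
that makes every stage testable against exact, closed-form expectations.

## The model

Four indicators are computed per ecoregion, each a proxy for a dimension
of biodiversity-supporting conditions rather than a direct species count:

* **SGF** — share of the ecoregion covered by grassland or forest
  (ecosystem diversity), a zonal class fraction of a categorical
  land-cover raster;
* **SW** — share covered by designated wetlands (ecosystem diversity), a
  polygon-overlay area fraction;
* **GEP** — composite global extinction probability (species diversity):
  the zonal means of four per-taxon rasters (amphibians, birds, reptiles,
  mammals) summed;
* **SRA** — share of roadless area (a proxy for connectivity and genetic
  diversity), again a polygon-overlay fraction.

Each indicator is min–max normalized across all ecoregions with complete
data, so 0 is the lowest and 1 the highest observed value. The normalized
indicators are aggregated with equal weights by one minus the root mean
square of their complements:

$$EF_{raw} = 1 - \sqrt{\tfrac{1}{4}\left[(1-SGF)^2 + (1-SW)^2 +
(1-GEP)^2 + (1-SRA)^2\right]}$$

This fuzzy-logic-style form penalizes a severely degraded single
dimension harder than an arithmetic mean would: biodiversity is not
maintained when any one dimension collapses. $EF_{raw} \in [0,1]$, is
symmetric in the four indicators and non-decreasing in each — properties
the test suite checks against an independent transcription of the formula
and 10,000 random perturbation pairs.

The raw factors are then divided by the minimum of the set, making the
least-valued ecoregion the reference baseline 1 and every other ecoregion
a multiple of it. By default the observed minimum of the dataset at hand
is used; `ref_min` lets a user pin an external reference minimum (such as
a published global dataset's) so a regional subset can be expressed on
that scale. An ecoregion scoring 0 on all four normalized indicators
would make the scaling undefined; the package raises an error for this
degenerate case rather than guessing.

Country-level factors are the area-weighted mean of the min-scaled EF
over all ecoregions intersecting the country,
$EF_c = \sum_i w_i EF_i / \sum_i w_i$ with $w_i$ the intersection areas.
Only retained (EF-bearing) ecoregions enter numerator and denominator; a
country whose entire area falls in non-retained ecoregions is omitted
rather than imputed.

## Retention and normalization order

Only ecoregions for which all four input layers contain valid data
receive a factor (`valid` in the indicator table). Normalization
statistics are computed **after** exclusion, over valid rows only, so a
data-deficient ecoregion can never distort the scale. Degenerate spread
(an indicator constant across all valid ecoregions) is an error, not a
silent zero-fill — a silent fill would corrupt the factor ranking
unnoticed.

## Spatial conventions

* **Pixel inclusion.** Zonal statistics use the pixel-center-in-polygon
  rule, consistently for class shares and means. It is unbiased for area
  fractions and matches common zonal-statistics defaults. No-data cells
  are excluded from numerator and denominator; a region with zero valid
  cells is missing, feeding the retention rule.
* **Areas.** Overlay shares and country weights are computed in an
  equal-area frame. For geographic (lon/lat) data the package uses the
  exact spherical area of coordinate-aligned rectangles,
  $R^2\,\Delta\lambda\,\Delta\sin\varphi$ on the authalic sphere
  ($R = 6371007.2$ m) — a cylindrical equal-area mapping under which
  rectangles stay rectangles, so area arithmetic remains exact. With
  `planar = TRUE` (the default, used for synthetic worlds) areas are
  planar CRS units and all oracles are exact closed forms.
* **Dissolve before intersect.** Coverage layers (wetland sites can
  overlap) are unioned before intersection, so shares never exceed 1.
* **Geometry domain.** All geometries are unions of axis-aligned
  rectangles. This is a deliberate restriction: it gives every area,
  intersection and union a closed form (coordinate compression for
  unions), which is what lets end-to-end pipeline output be compared to
  analytic truth at machine precision. Real-world polygon datasets would
  need a preprocessing step outside this package's scope.

## The synthetic world

`simulateWorld()` emulates the structure of the real input stack — an
ecoregion map, national boundaries, a categorical land-cover raster, a
wetland polygon database, a roadless-area layer, four per-taxon
extinction-probability grids and a species-richness validation layer —
as a miniature planet with exactly known ground truth:

* ecoregions are an $R \times C$ grid of square cells tiling a world
  rectangle; countries are vertical strips whose internal boundaries are
  offset from the grid so countries straddle several ecoregions;
* the land-cover raster is pixel-aligned to the ecoregion edges and is
  painted so each region's grassland+forest fraction is the nearest
  representable value `round(target * P)/P` for `P` pixels — the
  **achieved** value, not the target, is stored as truth;
* wetland and roadless layers are centred sub-rectangles shrunk by
  `sqrt(share)` per side, so their area shares are exact;
* taxon rasters are constant within each region, so zonal means are
  exact and the composite is a plain sum;
* richness is a positive linear transform (1000 units per EF unit) of
  the closed-form EF truth plus Gaussian noise; with zero noise the
  Spearman correlation with EF is exactly 1. The noise distribution is
  uncritical since Spearman depends only on ranks.

Default indicator targets are drawn per region from ranges typical of
the real layers: SGF and SRA uniform on [0.05, 0.95] (both span nearly
the full range across the world's ecoregions), SW uniform on [0, 0.4]
(designated wetlands cover minor fractions), per-taxon extinction
probabilities uniform on [0, 0.3]. The default richness noise of 100
units (a tenth of the EF-truth slope) yields a strong but imperfect rank
correlation, like the moderate-to-strong relationship expected of a
composite indicator against measured richness.

Generation is a pure function of its arguments: the same seed reproduces
every layer bit-for-bit, and the caller's RNG stream is left untouched.

What passing synthetic tests does **not** show: behaviour on curved,
multi-part, invalid or sliver geometries, mixed raster resolutions and
reprojection, or the empirical correlation value of any real dataset.
The synthetic world verifies the arithmetic of the method, not the
ecology of the inputs.

## Numerical choices

* Double precision throughout; exported values are unrounded. CSV and
  workbook writers serialize doubles with 17 significant digits, so round
  trips are exact and reruns byte-identical.
* Min-scaling divides by the exact observed minimum, so the baseline is
  exactly 1 (the minimum element divided by itself), not 1 within
  rounding.
* Spearman's rho is implemented as the Pearson correlation of midranks
  via the sum formula; ranks of perfectly concordant data can land a few
  ulps off $\pm 1$ through the square root, and are snapped to exactly
  $\pm 1$ within `8 * .Machine$double.eps`. The p-value uses the
  t approximation $t = \rho\sqrt{(n-2)/(1-\rho^2)}$ with $n-2$ degrees of
  freedom (standard for n in the hundreds); at $|\rho| = 1$ the limit
  value is reported, floored at the smallest positive double so p stays
  in (0, 1]. An exact permutation p-value is available for $n \le 10$.
* Intersection slivers below $10^{-10}$ of a country's area are dropped
  from the weights to keep boundary-coincident rectangles from
  contributing floating-point dust.

## File formats

All on-disk formats are plain text: vector layers as CSV with a WKT
geometry column (loadable by standard GIS tools), rasters as ESRI ASCII
grids, inter-stage tables as CSV (inspectable and diffable), the
two-worksheet deliverable as a SpreadsheetML 2003 XML workbook that
spreadsheet applications open directly, and the validation report as
JSON. Worksheet names (*Ecoregion level*, *Country level*) and column
order (`ECO_NAME`, `BIOME_NAME`, `ECO_ID`, `EF`; `COUNTRY`, `ISO_CC`,
`EF`) are treated as a bit-exact contract, since downstream LCA tooling
keys on them.

## A worked run

```{r run}
world <- simulateWorld(n_rows = 4, n_cols = 4, n_countries = 3,
                       pixels_per_cell = 10, seed = 42)
res <- runWorldPipeline(world)
head(res$ef_table, 3)
res$country_table
res$correlation
```

The pipeline EF can be compared against the closed-form EF computed
directly from the generator's stored truth:

```{r truth}
max(abs(res$ef_table$ef - truthEF(world)$ef))
```

## Problem sizes

The shipped test suite and the acceptance script run on worlds between
3 × 3 and 20 × 20 ecoregions with 5–20 pixels per cell side — sizes at
which every oracle comparison is exact and a full pipeline run takes
well under a second, chosen so the whole verification cycle stays
interactive.

## Known limitations

* Rectangle-only geometries; no reprojection or resampling of
  mismatched grids (inputs must be co-registered).
* The 70 real data-deficient ecoregions' geography, coastlines and
  islands are not emulated; retention is exercised by knocking out
  raster coverage instead.
* The validation stage pairs per-ecoregion zonal-mean richness with EF;
  pairing per-pixel values would be an alternative reading and is not
  implemented.
* Country exclusion uses the only unambiguous rule — zero retained
  ecoregion overlap; no minimum-coverage threshold is applied.
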