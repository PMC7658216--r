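---
title: "Methods: reactive-nitrogen input budgeting and mass-conserving downscaling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reactive-nitrogen input budgeting and mass-conserving downscaling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbudget)
```

## The problem

Reactive nitrogen (Nr — every N species other than inert N~2~) enters
landscapes through fertilizer, manure and excretion recycling, biological
fixation, irrigation, straw return and atmospheric deposition, and enters
surface waters through runoff, wastewater and deposition. National and
provincial statistics resolve these inputs only to administrative units;
ecological and health applications need them on a fine grid. `nbudget`
implements the two halves of that workflow:

1. **accounting** — per-region N-input fluxes to six receiving land-use
   types (cropland, forest, grassland, surface water, built-up, unused)
   from activity data and coefficient libraries, rolled up into a
   24-flux national budget;
2. **mapping** — dasymetric, exactly mass-conserving disaggregation of
   each regional flux onto a 1 km grid using proxy surfaces (land-use
   masks, population, GDP, livestock density, satellite trace-gas
   columns), plus watershed aggregation of the surface-water inputs.

Because real statistical-yearbook inputs and the proprietary coefficient
protocols behind published national budgets are not redistributable, the
package ships a seeded synthetic-country generator whose ground truth is
known exactly; every stage is validated against it.

## The accounting model

All internal magnitudes are kg N/yr; reports convert to Tg N/yr
(1 Tg = 10^9^ kg) and round half-up to one decimal.

* **Livestock manure** to a receiving land use $l$:
  $\mathrm{MANURE}_l = \sum_a \mathrm{POP}_a \times \mathrm{EXCRE}_a
  \times \mathrm{RE}_{a,l}$, where $\mathrm{POP}_a$ is head count of
  animal category $a$, $\mathrm{EXCRE}_a$ the excretion factor
  (kg N/head/yr) and $\mathrm{RE}_{a,l}$ the fraction returned to $l$.
  Cropland and grassland carry separate return-rate vectors (the
  published budget books manure under both, without stating whether one
  rate set is shared; we keep them independent and configurable).
* **Human excretion** to cropland:
  $(\mathrm{POP}_{ur}\,\mathrm{RE}_{ur} +
  \mathrm{POP}_{ru}\,\mathrm{RE}_{ru}) \times \mathrm{EXCRE}_{hu}$.
* **Biological N fixation**: cropland BNF is
  $\sum_c \mathrm{area}_c \times r_{fix,c}$ over crops; forest and
  grassland BNF are class area times a single class rate.
* **Uniform-rate items** (straw recycle, irrigation, irrigation for
  artificial grassland): one national rate (kg N/ha/yr) times the
  region's relevant land-use area.
* **Fertilizer** is activity data (kg N/yr per county, assumed to be N
  nutrient mass, not product mass), read directly; separate columns for
  cropland, artificial forest and grassland applications.
* **Surface water** receives seven items: three runoff terms
  (coefficient × source-subsystem N input: total cropland input, total
  manure return, total forest input), human wastewater
  (per-capita × total population), industrial wastewater
  (intensity × GDP), WTP effluent (per-capita × urban population), and
  deposition.
* **Deposition** is externally prescribed as one national total per
  land-use class and enters the budget as given; satellite columns
  influence only *where* it falls (below).

Two modelling choices deserve emphasis. First, *forest runoff* is
described in the source literature only as following "the spatial
distribution of forest areas"; we implement it as coefficient × forest N
input, allocated over forest area — an interpretation, flagged as such.
Second, a *zero-receiving-area gate*: a region with no cropland
(grassland) books no manure or excretion return to cropland (grassland),
since nothing can be applied to absent land. Both are applied identically
in the budget and in the generator's ground truth.

## Coefficients

Every rate is configuration — the package prints and ships illustrative
defaults (`default_coefficients()`), because the underlying accounting
protocols do not publish a single canonical set:

| group | default | units | rationale |
|---|---|---|---|
| `excre_an` | pigs 8, cattle 40, sheep 8, poultry 0.5 | kg N/head/yr | typical excretion-factor magnitudes |
| `re_an` (cropland) | 0.2–0.4 by category | fraction | order of manure-recycling shares |
| `excre_hu`, `re_ur`, `re_ru` | 4, 0.10, 0.40 | kg N/p/yr, fractions | rural return far exceeds urban |
| `r_fix` | soybean 80; rice 20; wheat/maize 10; forest 8; grassland 4 | kg N/ha/yr | legumes fix an order more than cereals |
| `uniform_rates` | straw 15, irrigation 5, artificial-grassland irrigation 0.5 | kg N/ha/yr | small relative to fertilizer |
| `runoff_coeffs` | cropland 0.05, livestock 0.11, forest 0.11 | fraction | consistent with published budget ratios (e.g. cropland runoff ≈ 5% of cropland input) |
| wastewater | 1.4 kg N/person, 1.5 kg N/urban person, 3×10⁻⁵ kg N/GDP unit | — | per-capita discharge magnitudes |
| `deposition_totals` | per-class totals | kg N/yr | the published per-class values at national scale; the synthetic spec uses desk-scale values |

Fractions are validated to [0, 1], rates to ≥ 0, and every animal
category present in a region must have coefficients (a gap is an error
naming the category).

## Mass-conserving allocation

`allocate()` distributes a regional total $F_r$ over that region's
eligible cells proportionally to a non-negative proxy $w$:
$x_i = F_r\, w_i / \sum_{j \in r} w_j$. One normalization per region
makes zonal re-aggregation the identity up to floating-point summation
(audited at ≤ 10⁻⁹ relative throughout), and the result is invariant to
rescaling the proxy. Conventions: row 1 of every grid is north; cell
values are whole-cell totals (kg N/cell); a cell belongs to the region
containing its center, so boundary cells belong to exactly one region
and conservation is exact by construction; ties in class assignment
resolve to the lowest class code. Fallbacks when a region has flux but
no usable weights: zero proxy sum → uniform over eligible cells; no
eligible cells → uniform over all region cells with a warning. Cells are
treated as equal-area (the synthetic grid is an equal-area local
projection); latitude-dependent cell areas are out of scope here.

Proxy assignments in the pipeline: fertilizer, BNF, irrigation and straw
uniformly over the class mask (within-county crop weighting is unknown,
so uniform-over-cropland is the stated assumption); manure by livestock
density on the class mask; human excretion by population on cropland;
wastewater items by population / urban population / GDP surfaces;
deposition by the column index.

## Deposition compositing

Daily NO~2~ and NH~3~ column fields (0.25°-style coarse grid, here 8 km)
are composited to monthly means by the per-cell arithmetic mean over
valid observations; a cell observed on no day is nodata. The two monthly
maps are each max-normalized, combined with weights (default 0.5/0.5,
configurable) and clamped at zero to form a deposition *index*. The
source methods never state a column-to-deposition conversion, so the
index is used purely as a spatial weight: configured national totals per
land-use class are allocated over each class's cells by the index, after
nearest-cell (block-constant) transfer to the fine grid — chosen over
interpolation so the class-wise renormalization stays exactly
conserving. Annual surfaces are assumed (the mean of monthly composites);
deposition seasonality is not modelled.

## The synthetic country

The generator emulates the input side of a national budget at desk
scale: a 200 × 200 grid of 1 km cells (seconds per run; unit tests use
40 × 40), 2 × 2 provinces each tiled into 5 × 5 counties, a categorical
land-use raster drawn cell-wise from configured class fractions, and
proxy surfaces built as Gaussian "city/farm" bumps over a low uniform
floor — reproducing the qualitative hotspot structure of real N-input
maps. County activity tables are *zonal sums of the surfaces*, so table
and raster agree exactly; daily columns are a known truth surface (tied
to the GDP and livestock patterns) with multiplicative Gaussian noise
(sd 0.1) and Bernoulli(0.8) observation masks; watersheds are a 2 × 3
tiling. All randomness flows from one seed through R's default
Mersenne–Twister generator, giving bit-identical bundles per seed.

What it does **not** emulate — and what passing tests therefore do not
establish about real data: irregular administrative and basin geometries
(rectangles only), correlated survey errors and reporting biases in
yearbook data, latitude-dependent cell areas, seasonal deposition,
within-county crop geography, and any internal N cycling (volatilization,
uptake, denitrification). The synthetic totals are 2–3 orders of
magnitude below national-scale values; homogeneity of every flux in the
activity data makes the scale choice immaterial to correctness.

## Numerical choices

* Conservation audits use relative error ≤ 10⁻⁹ (double-precision sums
  over ≤ 4 × 10⁴ cells leave ample margin).
* Report rounding: half-up at one decimal in Tg, applied only at
  presentation; subtotals and shares are computed unrounded.
* QA/QC screening flags records strictly outside per-item
  [p0.5, p99.5] sample quantiles (interpolation type 7); exclusion is
  opt-in and can renormalize group totals; emptying a group is an error.
  The exact rule used in published budget QC is unstated, so the
  percentile screen is a documented stand-in.
* Degenerate inputs: empty column series, all-nodata grids, zero-proxy
  regions, absent land-use classes and infeasible tilings all have
  defined behaviour (error or documented fallback) exercised by tests.
* On-disk formats are plain text with 17-significant-digit floats, so
  round trips are exact: ESRI ASCII grids for rasters, CSV for tables,
  GeoJSON for polygons, YAML for coefficients, JSON + long CSV for the
  daily column stacks.

## Limitations

Budget scope is inputs only; no internal cycling or losses, no in-stream
retention or routing, no health or impact layers. Coefficient defaults
are illustrative, not calibrated; any real-world application must supply
its own library. The water land-use map books each basin's inputs
uniformly onto that basin's water cells (falling back to all basin cells
when a basin has no water), which is a bookkeeping convention rather
than hydrography.
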