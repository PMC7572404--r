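---
title: "Methods: oasis change, constraint frequency and grey incidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: oasis change, constraint frequency and grey incidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oasisdyn)
```

`oasisdyn` analyses multi-decadal oasis change in arid inland basins from
co-registered grids and county panels. This vignette records the models,
the assumptions behind them, the defaults and why they were chosen, and
what the synthetic tests do and do not demonstrate.

## Grids and geometry

All layers are `raster_grid` objects: a numeric matrix (`NA` = nodata), a
square cell size in metres, a top-left origin in a projected system, and a
CRS tag compared only for equality. The default cell size is 90 m, the
scale at which the constraint statistics are tabulated. Rows run north to
south. Two deliberate restrictions:

* **No resampling.** Every overlay requires exact geometry agreement
  (shape, cell size, origin within an absolute 1e-6 m, equal CRS tag);
  `assemble_stack()` errors on the first mismatching layer rather than
  interpolating, because silent resampling of binary masks corrupts areas.
* **Equal-area assumption.** Areas are `count × cell_size²`; the grid is
  assumed to live in an equal-area projection. No geodesic correction is
  attempted.

Rasters are stored as single-band ESRI ASCII grids — a plain-text,
self-describing format that diffs cleanly under version control; the
nodata sentinel on write is −9999. Masks may hold only {0, 1} outside
nodata and zone rasters only non-negative integer labels; both contracts
are enforced at read time.

## Change dynamics

For an ordered series of binary masks, the **stable** oasis is the cell-wise
intersection (oasis in every period) and the **maximum** oasis the union
(oasis at least once). Nodata in any period propagates to both — a cell
with partial coverage is never declared stable. Change maps label each
cell 0 stable desert, 1 expansion, 2 retreat, 3 stable oasis, and satisfy
the conservation identities
`#stable-oasis + #expansion = #oasis(end)` and
`#stable-oasis + #retreat = #oasis(start)`, which the tests verify on
random series against per-cell loops.

`change_metrics()` uses an inclusive span default of `n_years = 30` for a
1986–2015 record, the convention that turns the endpoint areas into the
familiar ~140 km²/yr average. Zonal summaries report both per-year shares
and the full per-period table, so a basin's share can be read off any
single map or averaged across periods.

## Terrain covariates

Slope and aspect come from Horn's 3×3 weighted finite differences — the
de-facto GIS standard — with slope `atan(|∇z|)` in degrees and aspect the
compass bearing of steepest descent. Border cells and any cell whose
window touches nodata are nodata. Cells with slope below `flat_threshold`
(default 0.01°) take the aspect sentinel −1: a "slope = 0" class defined
exactly is numerically fragile, so flatness is a small threshold,
configurable where a coarser definition of level ground is wanted. Aspect
classes are eight 45° sectors, half-open on the clockwise side
(N = [337.5, 360) ∪ [0, 22.5)), so every boundary value has exactly one
class. `categorical_frequency(..., exclude = 0)` reproduces the
"sloped-oasis" view in which shares are taken among non-flat cells only.

## The distribution-frequency constraint model

For a covariate layer and an oasis mask, the distribution frequency of bin
`b` is the fraction of valid oasis cells falling in it; cells nodata in
either layer leave both numerator and denominator. Bins are half-open with
configurable width — defaults 50 m (elevation), 1° (slope), 10 mm
(precipitation), 25 mm (AWD), 0.5 °C (temperature), fine enough to resolve
peaks ~50 m apart on the elevation axis. Zero-frequency bins inside the
observed range are kept (they constrain the fit); empty bins outside it
are dropped.

The suitability envelope is summarised by a least-squares Gaussian
`f(x) = y0 + a·exp(−(x−μ)²/2σ²)` fitted to the binned curve — deliberately
to the curve, not by maximum likelihood on cell values, because the binned
curve is the analysis object and the fit must describe it. The offset `y0`
is included by default (frequency curves carry flat tails); a no-offset
variant is a flag. Initialisation uses the frequency-weighted mean and sd,
`a₀ = max f`, `y₀ = 0`; on non-convergence the optimiser restarts from a
bounded, deterministic ladder of jittered centres and spreads. σ is
bounded positive and reported as its absolute value. Significance is the
F-test of the fitted curve against the constant model, reported with r²;
degenerate inputs are defined conservatively (constant curve: r² = 0,
p = 1; machine-exact fit: p = 0).

`compare_stable_maximum()` runs the pipeline on both extents and reports
peaks and spreads side by side; `σ(maximum) > σ(stable)` formalises the
"flatter curve" reading that expansion occupies marginal conditions.
`threshold_support()` gives the fraction of oasis cells at or beyond a
covariate threshold, e.g. water depth ≥ 400 mm.

## Accessibility water depth

`AWD = R + P` in millimetres. `R` spreads each gauged station's annual
volume uniformly over the oasis cells of its service zone
(`depth = volume / (n_cells × cell_area)`, 1 m³ over 1 m² = 1000 mm);
uniformity follows from treating the allocation as an average over the
irrigation command area — distance- or canal-weighted schemes are out of
scope. Cells in overlapping service zones sum their depths; a station with
positive volume and no oasis cells in its zone is an error, never a silent
drop, because its water would vanish from the balance. Allocation in a
given analysis year uses that year's mask; the stable/maximum constraint
analysis uses the multi-year mean AWD grid (`awd_mean_grid()`), since no
single year is privileged there. A consequence worth noting: cells that
are oasis only in late periods receive runoff only in those years, so the
union extent sits at systematically lower mean AWD than the core — the
marginal-water signature, not an artefact. AWD is deliberately a two-term
index: groundwater, canal losses, evapotranspiration and routing are
outside its definition.

## Grey incidence

The attribution model is Deng's classic degree of grey incidence (the
formulas in `?grey_relational_degree`), chosen as the default because it
is the standard reading of "grey relational degree"; the *relative degree*
variant (Deng's coefficient on zero-start images of initial-value-scaled
series) is available behind `variant = "relative"` for analyses that
should compare growth rates rather than levels. Defaults: `ρ = 0.5` (the
conventional distinguishing coefficient), mean normalization (robust when
a series starts near zero; initial-value normalization is available).
`Δmin`/`Δmax` are scoped within each region's comparator set, so each
region's row of the output table is self-contained and adding a region
never changes another's degrees. Years are aligned by common-year
intersection, never interpolated; a missing series yields a flagged `NA`
cell. Ranking aggregates by mean (or median) across regions; exact ties
share a rank, are flagged, and are listed alphabetically.

## The synthetic basin

`generate_basin()` emulates the full input suite with known truth. Design
choices that matter:

* **Terrain.** A northern plain from 1100 to 1900 m, *linear* in the
  north–south coordinate, under a quadratic rise to a 4200 m ridge. The
  linear plain makes the candidate-cell elevation density uniform, so the
  stable core — sampled with probability ∝ exp(−(z−μ*)²/2σ*²), μ* = 1500 m,
  σ* = 150 m — follows a truncated Gaussian symmetric about μ* (the plain
  edges sit 2.7σ* away), keeping the fitted peak unbiased. A convex
  profile would concentrate candidates at low elevation and drag the
  recovered peak percent-scale low. The default 240-row grid keeps the
  plain gradient near 5.6 m per cell (≈3.6° slope), inside the 6° suitability
  limit; the mountain flank exceeds it and is excluded, as intended.
* **Dynamics.** The core is present in all periods. Expansion cells are
  sampled at lower elevation with wider spread (1440 m, 195 m), with a 3×
  sampling bonus for cells touching the current oasis, and arrive evenly
  over periods 2..n; a small retreat set (5% of the core) is present only
  in period 1. Hence the intersection recovers the core exactly, the union
  peaks lower and spreads wider, and the record is expansion-dominated
  with a realistic ~38% area growth.
* **Water.** One gauged station per basin, volumes sized to sustain a mean
  600 mm allocated depth over that basin's oasis (5% yearly noise), so
  stable-oasis water depth stays above the 400 mm threshold by
  construction. The panel's AWD column is computed through the real
  allocation pipeline, not drawn directly.
* **Panel.** Population-like series are proportional to regional oasis
  area with 1.5–2% noise; GDP-like series follow their own exponential
  growth (4.5–10%/yr, against ~1%/yr area growth); per-capita GDP is the
  quotient. Under mean normalization this yields the configured incidence
  ordering population-like > AWD > GDP-like, which the tests require in at
  least 19 of 20 regenerated basins.
* **Determinism.** All draws flow from one seed; a fixed seed reproduces
  the basin byte for byte.

What passing these tests shows — and does not. They show the statistics
recover known structure planted under the stated noise model:
spatially unstructured sampling noise, Gaussian climate noise, uniform
allocation. They do not show robustness to classification error in real
masks, spatially correlated climate fields, irrigation command areas that
deviate from zone rasters, or drivers whose co-movement with area is
confounded — the generator targets statistical structure, not physical
realism (no routing, no actual downscaling).

## Problem sizes and runtime choices

The default basin is 240×200 cells with a 2500-cell core. The test suite
uses tall-narrow variants (240 rows, 40–80 columns, cores of 300–900) that
preserve the plain's gentle gradient while keeping the whole suite around
twenty seconds; replicated-seed checks use 20 basins. The acceptance
script regenerates the default basin once and 20 reduced basins for the
ranking-recovery rate.

## Known limitations

* ESRI ASCII is the only raster format; georeferencing is minimal
  (corner + cell size + opaque CRS tag) and no reprojection is offered.
* The Gaussian fit assumes a unimodal envelope; bimodal frequency curves
  will be summarised poorly (inspect `r_squared`).
* Grey incidence measures co-movement, not causation, and cannot separate
  interacting drivers.
* Area computation presumes an equal-area grid; inputs in geographic
  coordinates must be projected upstream.
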