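# oasisdyn

Oasis change dynamics, constraint frequency and grey-incidence attribution
in arid inland basins.

## The problem

Oases — the vegetated, settled land-cover complexes of arid basins — expand
and retreat over decades under the joint control of terrain, water and
human pressure. Given co-registered grids (binary oasis masks for several
periods, a DEM, gridded precipitation and temperature, basin/county/station
zone rasters) and county statistical panels, `oasisdyn` answers three
questions:

1. **How did the oasis change?** Per-period areas, per-cell change maps
   (expansion / retreat / stable), the *stable* oasis (cells that are oasis
   in every period — the intersection) and the *maximum* oasis (oasis in at
   least one period — the union), with zonal summaries per basin or county.

2. **What constrains where oases exist?** The *distribution frequency*
   statistic: for each bin of a covariate (elevation, slope, aspect,
   precipitation, water depth, temperature), the fraction of oasis cells
   falling in it,

   `f(b) = n_oasis(b) / n_oasis`,

   fitted with a Gaussian curve `f(x) = y0 + a·exp(−(x−μ)² / 2σ²)` whose
   peak `μ` and spread `σ` locate and bound the suitable envelope. A wider
   `σ` for the maximum than for the stable extent is the signature of
   expansion into marginal conditions. Water availability is expressed as
   the **Accessibility Water Depth** grid, `AWD = R + P` (mm), where `R`
   spreads each gauged station's annual runoff volume uniformly over the
   oasis cells of its service zone and `P` is precipitation depth.

3. **What drives the change?** Deng's degree of grey incidence between the
   normalized oasis-area series `x₀` and each normalized driver series
   `xᵢ`:

   `ξᵢ(k) = (Δmin + ρ·Δmax) / (Δᵢ(k) + ρ·Δmax)`, `γᵢ = mean_k ξᵢ(k)`,

   with `Δᵢ(k) = |x₀(k) − xᵢ(k)|` and distinguishing coefficient
   `ρ = 0.5`. Factors (population, rural labour, GDP and its sector
   components, precipitation, AWD) are ranked by aggregate `γ` per region.

A seeded synthetic-basin generator (`generate_basin()`) emulates all of the
above inputs with known ground truth — stable core, elevation optimum,
water threshold, intended driver ranking — so every stage is testable end
to end.

## Worked example

```r
library(oasisdyn)

# published 1986 -> 2015 endpoint arithmetic
change_metrics(10707.7, 14950.1, n_years = 30)
#> $percent_change  39.62009
#> $factor           1.396201
#> $annual_increase 141.4133

# a full synthetic basin with known truth
b <- generate_basin(basin_config(seed = 1))
oasis_area(stable_oasis(b$series))
#> [1] 20.25

cmp <- compare_stable_maximum(b$series, b$stack$layers$dem, 50,
                              covariate_name = "elevation")
c(cmp$peak_stable, cmp$peak_maximum, cmp$sigma_stable, cmp$sigma_maximum)
#> [1] 1500.5039 1488.0026  153.7794  159.9259

rank_factors(panel_grd(b$panel))[1:4, ]
#>             factor     gamma rank  tied
#> 1   rural_laborers 0.9885268    1 FALSE
#> 2 total_population 0.9779703    2 FALSE
#> 3              AWD 0.8754791    3 FALSE
#> 4    precipitation 0.8743456    4 FALSE
```

The stable area of 20.25 km² is the 2500-cell core at 90 m resolution; the
fitted elevation peak recovers the generator's 1500 m optimum within 0.04%,
the union curve peaks lower and spreads wider than the core curve, and the
population-like drivers outrank AWD, which outranks every GDP-like series —
the configured ordering.

A staged, file-based run (`simulate → change → awd → constraints → grd →
report`) is available through `run_pipeline()` or the wrapper script in
`inst/cli/oasisdyn.R`.

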