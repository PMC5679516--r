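# lekshed

Protected-area effectiveness analysis for greater sage-grouse
(*Centrocercus urophasianus*), built around annual maximum male lek counts.

State "Core Area" policies protect sage-grouse by capping oil and gas
development inside designated polygons. Two questions follow for anyone
monitoring such a policy: do leks inside the protected polygons fail less
often than leks outside, and does drilling pressed up against the boundary
erode protection *inside* it (an edge effect)? `lekshed` implements the full
analysis chain for both questions, plus a synthetic landscape generator that
stands in for the restricted state lek-count and well databases, so every
stage is reproducible and testable end to end.

## The statistics at the core

**Lek collapse.** A lek is collapsed in year *t* if zero males were observed
in *t*, *t*−1 and *t*−2; only leks surveyed in all three years are eligible,
and each year is assessed independently.

**Collapse probability.** For each year and spatial stratum with *x* collapsed
of *n* eligible leks, the collapse probability gets a conjugate beta-binomial
update, Beta(α + x, β + n − x), with a flat Beta(1, 1) prior by default
(Jeffreys available) and a 95% central or HPD credible interval. The
across-year summary is the unweighted mean of the yearly posterior means.

**Strata.** Leks are classified by exact signed distance to the nearest core
boundary: non-core, all core, within 1.61 km (1 mi) of the boundary, within
4.83 km (3 mi), and "core-core" (>4.83 km inside).

**Edge effect.** Well density (wells/km², lagged one year behind the counts)
is measured in buffer rings outside the core boundaries, and each core
stratum's yearly collapse probability is regressed on it by OLS on the logit
scale: logit *p*ₜ = a + β·DDₜ₋₁. A positive β means collapse rises with
adjacent development. A logit-link prediction converts a fit into percent
change in core lek attendance relative to zero adjacent development.

## Worked example

A small synthetic landscape, the collapse analysis, and the headline
summaries:

```r
library(lekshed)

cfg <- landscape_config(
  extent = c(xmin = 0, ymin = 0, xmax = 150000, ymax = 150000),
  n_cores = 6, n_leks = 400, n_wells = 5000,
  n_well_fields = 3, field_radius_km = c(6, 12), seed = 42
)
land   <- simulate_landscape(cfg)
strata <- assign_strata(land$leks, land$cores)

panel  <- collapse_panel(land$counts)
series <- posterior_series(aggregate_collapse(panel, strata))
stratum_mean_collapse(series)
#> # A tibble: 5 × 3
#>   stratum         mean_probability n_years
#>   <chr>                      <dbl>   <int>
#> 1 core_all                   0.131      13
#> 2 core_core                  0.148      13
#> 3 core_within_1mi            0.144      13
#> 4 core_within_3mi            0.129      13
#> 5 non_core                   0.201      13
```

Core leks collapse in roughly 13% of eligible lek-years versus 20% outside
cores (the generator's default calibration targets are 10.9% and 20.4%; at
400 leks a single realization wanders a point or two). The yearly posteriors
behind those means:

```r
head(series[series$stratum == "core_all",
            c("year", "x", "n", "mean", "ci_low", "ci_high")], 4)
#>    year     x     n  mean ci_low ci_high
#> 1  2001    13   117 0.118 0.0664   0.181
#> 2  2002    16   118 0.142 0.0855   0.209
#> 3  2003    17   113 0.157 0.0963   0.228
#> 4  2004    16   118 0.142 0.0855   0.209
```

Attendance is heavier inside cores, and most males display there:

```r
welch_attendance_test(land$counts, strata)
#> # A tibble: 1 × 7
#>       t    df  p_value mean_core mean_noncore n_core n_noncore
#>   <dbl> <dbl>    <dbl>     <dbl>        <dbl>  <int>     <int>
#> 1 -18.5 3737. 5.34e-73      20.6         8.65   2542      1261

mean(core_male_share(land$counts, strata)$pct_males_core)
#> [1] 82.9
```

So ~21 males/lek inside cores versus ~9 outside (Welch t on pooled lek-years,
Satterthwaite df), and about 83% of all counted males attend core leks. For
the edge-effect side, `buffer_density_series()` produces the lagged ring
densities, `regression_battery()` fits the nine stratum-by-density
regressions (with `tidy()`/`glance()` accessors and `autoplot()` methods),
and `predict_attendance_change()` turns a logit fit into an
attendance-decline curve. `run_pipeline()` chains every stage from the three
input files (leks CSV, wells CSV, cores GeoJSON) to a directory of tidy CSVs
plus a JSON run manifest, and `inst/cli/lekshed.R` wraps simulation and
analysis for shell use.

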