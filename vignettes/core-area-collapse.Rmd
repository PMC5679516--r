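---
title: "Methods: lek collapse, Core Area edge effects, and the synthetic landscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lek collapse, Core Area edge effects, and the synthetic landscape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`lekshed` assesses how well protected "Core Area" polygons conserve greater
sage-grouse (*Centrocercus urophasianus*), using the annual maximum count of
males attending each lek as the population index. The package implements the
full analysis chain — a lek-collapse statistic, stratified Bayesian collapse
probabilities, lagged development densities in buffer rings outside the
protected boundary, edge-effect regressions, and an attendance-change
prediction — together with a synthetic landscape generator, because the state
lek and well databases the analysis is designed for are available only by
request. Everything downstream of the generator treats its output exactly as
it would treat the real files (CSV counts, CSV well records, GeoJSON
polygons), so the pipeline is fully testable end to end.

## The collapse statistic

A lek is **collapsed** in year $t$ if zero males were observed in years
$t-2$, $t-1$ and $t$. The lek-year is **eligible** for assessment only when a
count exists in all three years: an explicit zero is data, an unsurveyed year
is not, and no imputation is performed. Each year is assessed independently,
so a lek can collapse, recover, and collapse again; with data starting in
1999, the first assessable year is 2001. `collapse_panel()` produces the
per-lek-per-year eligibility/collapse panel and `aggregate_collapse()` sums it
into per-year, per-stratum counts $(x_t, n_t)$. The window is parameterised
(`window = 3` is the definition above; `window = 1` degenerates to "zero count
this year" and is used as an internal consistency check). A recorded count
that is not a non-negative integer is treated as missing, with a warning — we
take the view that an ambiguous record is no record.

## Stratification and boundary distance

Strata follow statute-mile bands around the protected boundary, rendered
exactly as the regulations print them (1 mi = 1.61 km, 3 mi = 4.83 km, not
1609.344 m; configurable): non-core leks (outside all cores), all core leks,
core leks within 1.61 km of the boundary, core leks within 4.83 km, and
"core-core" leks more than 4.83 km inside. The core bands are nested by
construction. `signed_boundary_distance()` computes exact planar Euclidean
distance to the nearest boundary segment, signed positive inside; a lek
exactly on the boundary counts as inside at distance zero, reading the
protective designation inclusively. The four-way partition
(non-core / ≤1 mi / 1–3 mi / core-core) plus the nesting relations are
asserted as invariants in the test suite.

## Development density and the lag contract

`ring_density()` measures wells per km² in the region outside all cores within
a buffer of the boundary. The default mode counts points exactly: membership
comes from the signed distance ($-b \le d < 0$), and the area is the closed
form $\sum_i (\mathrm{perimeter}_i \cdot b + \pi b^2)$, valid because
generated cores are convex and separated by more than twice the widest buffer.
If input polygons violate those assumptions (rings touching a neighbouring
core, non-convex cores, cores hugging the extent edge), the area falls back to
grid integration clipped to exclude core interiors, with a warning. A raster
`"focal"` mode (1-km cells, circular moving-window mean) is provided for
parity with GIS focal-statistics workflows, whose exact neighbourhood
parameters are not recoverable; the exact ring count is the default because it
is reproducible. The statewide statistic is a single pooled, area-weighted
value per year and buffer.

Densities are always **lagged one year** behind the count: only structures
already standing in year $t-1$ could have affected birds counted in year $t$.
Wells enter the analysis from their `first_year` (a structure present) to
their `last_year` (open-ended when the structure still stands); producing and
abandoned wells are deliberately pooled.

## Bayesian collapse probability

For each year and stratum the collapse probability gets an independent
conjugate update: with prior $\mathrm{Beta}(\alpha, \beta)$ and data
$(x_t, n_t)$, the posterior is $\mathrm{Beta}(\alpha + x_t, \beta + n_t -
x_t)$, reported with its mean and a 95% credible interval. The default prior
is the flat $\mathrm{Beta}(1,1)$ — the plainest reading of an "uninformed"
prior — with Jeffreys $\mathrm{Beta}(0.5, 0.5)$ as a preset, since binomial
interval software often defaults to it; reports record which was used. The
default interval is central (equal-tailed Beta quantiles); a
highest-posterior-density interval is available, computed by minimising the
interval width over the lower-tail mass to an accuracy of $10^{-10}$
(well inside the $10^{-8}$ mass tolerance the HPD test asserts). The
across-year summary is the unweighted arithmetic mean of yearly posterior
means — not a pooled $x/n$ — matching the year-independent framing. Interval
overlap between strata is evaluated on closed intervals (touching endpoints
overlap).

## Edge-effect regressions and attendance prediction

`fit_edge_regression()` regresses a stratum's yearly collapse probability on
the lagged outside-boundary density by OLS. The default fits the **logit** of
the posterior mean: a linear model of a probability cannot produce the bounded
declines the attendance prediction needs, and the logit is the natural link
for a binomial probability. Identity scale is available. The battery
(`regression_battery()`) fits all four core strata against both buffer
densities (eight fits) plus a control of all-core collapse against the lagged
*inside*-core density — nine fits, reported with $\beta$, SE, $r^2$, $F$ with
$(1, n-2)$ degrees of freedom and the two-sided $p$. Regressions default to
the 2002–2013 count years (12 points). **Sign convention:** a positive
$\beta$ means collapse probability rises with adjacent development. The
package tests this sign only against the generator's ground truth, since
printed regression tables for this design are not sign-consistent with their
accompanying prose and the original coding cannot be recovered.

`predict_attendance_change()` converts a logit-scale fit into percent change
in core lek attendance: the fitted slope is kept, the intercept is shifted so
$p(0)$ equals a chosen baseline, and expected attendance is
$(1 - p(d)) \cdot \bar{m}_\text{active}$ under the *minimal* mapping that a
collapsed lek contributes zero males while active-lek attendance is
unaffected by development. Percent change is relative to zero adjacent
development, hence exactly 0 at $d = 0$ and bounded below by $-100\%$. This
mapping is an assumption, flagged here prominently: nothing in the collapse
statistic itself measures attendance on active leks.

## The synthetic landscape generator

The generator is first-class, tested code, designed to reproduce the
statistical structure the analysis consumes — not any real geography.

**Geometry.** `generate_core_areas()` places disjoint axis-aligned rectangular
cores of log-normally varied size and aspect, with a minimum gap (12 km
default, above twice the widest buffer) and an inset from the extent edge, and
scales their joint area to exactly the target fraction. The defaults emulate a
~252,000 km² state-scale extent with 31 cores covering 24%. Rectangles keep
every downstream geometric quantity exact; infeasible configurations error
rather than degrade.

**Points.** Leks (default 2,382) fall inside a core with probability 0.66,
uniformly within their stratum. Wells (default 72,562) come in three layers:
a thin uniform scatter inside cores at 0.05 wells/km² (held below the
regulatory cap of 1 well per 2.6 km²; real protected areas sit far below
their cap), clustered drilling "fields" outside cores with geometrically
decaying intensities whose peak approaches 11.33 wells/km², and diffuse
background drilling. Field discs may abut core boundaries; candidate wells
falling inside a core are rejected and re-drawn, so wells accumulate just
outside boundaries — the landscape feature the edge-effect analysis targets.
55% of structures predate the study; the rest appear during 1999–2013 with
linearly increasing rate, so lagged densities grow over time. A small
fraction (5%) of structures are removed, exercising the open-ended
`last_year` logic.

**Counts.** Each lek carries a latent two-state activity chain: active leks
turn inactive with an annual entry probability, inactive leks reactivate with
exit probability 0.4 (mean inactive spell 2.5 years, consistent with the
short collapse-and-recovery cycles the yearly statistic shows). Collapse is
therefore *measured*, never drawn directly — three consecutive zeros arise
from inactive spells (and occasionally from low active counts). For core
leks the entry probability is
$\mathrm{logit}^{-1}(\mathrm{logit}(e_0) + s \cdot D_{i,t-1})$ where
$D_{i,t-1}$ is the lagged density of outside-core wells within 4.83 km of lek
$i$; a lek deeper than that radius has $D = 0$ exactly, so deep-core leks
feel no edge. The slope $s \ge 0$ by convention (it acts on *inactivity*, so
"development harms birds" is a positive $s$); negative values are rejected at
construction. Active lek-years draw negative binomial counts
($\mathrm{Var} = \mu + \mu^2/k$, default $k = 2$, consistent with the large
standard errors of reported attendance means) whose mean follows a shared
sinusoidal year effect (period 7.5 years, within the 6–9-year population
cycles described for this species; amplitude 0.4 of the mean). Attendance
means (22 core, 9 non-core males/lek) are interpreted as *realized* males per
lek including zeros, so the active-lek mean is scaled by
$1/(1 - \bar\pi_i)$ with $\bar\pi_i$ the lek's stationary inactivity — this
makes the simulated males-per-lek and the core male share reproduce the
attendance table they are calibrated to.

**Missingness.** Each lek gets a survey propensity drawn from a Beta
distribution with mean $1 - 0.36$ and concentration 1, and lek-years are
surveyed independently at that propensity. The marginal unsurveyed rate is
0.36 (matching ~1,530 of 2,382 leks surveyed per year), but monitoring effort
is persistent per lek — some leks are counted nearly every year, others
rarely — which is how agency lek databases behave and which governs how many
leks achieve the three consecutive surveys the collapse statistic needs. The
missingness test uses the propensity-adjusted (beta-binomial) standard error
rather than the plain binomial one.

**Calibration.** The analysis measures a three-year run statistic, not the
per-year entry rate, so `calibrate_collapse_rate()` closes the loop by
bisection: each candidate entry rate is evaluated by simulating a stratum
(default 20,000 leks × 15 years — far above the $10^4$ lek-years needed for a
stable estimate) with the full count model under common random numbers, and
the rate is accepted when the measured collapse frequency hits the target
within ±0.01. A target of zero returns an entry rate of exactly zero;
unreachable targets (given the exit rate) raise a calibration error carrying
the reachable range. Calibration is idempotent to within its own Monte Carlo
noise, which the test suite asserts.

## The calibrated recovery study

`run_recovery_study()` is the end-to-end experiment the acceptance machinery
runs: one fixed landscape at full scale; a *baseline* pass calibrated to the
core (0.109) and non-core (0.204) collapse targets with no edge coupling,
measuring the all-core and non-core across-year mean posterior probabilities
and the core male share; and an *edge* pass in which the deep-core rate is
calibrated to the core-core target (0.092), a second calibration finds the
entry rate matching the near-boundary target (0.118), and the edge slope is
set so leks within 1 mile of the boundary reach that rate at their mean
lagged adjacent density.

Each pass averages **8 independent count realizations** on the one fixed
landscape. A single realization of 2,382 leks carries roughly half a
percentage point of binomial noise on a stratum mean (more for the small
near-boundary stratum, and inflated further by the overlap of consecutive
three-year windows); averaging realizations estimates the calibrated process
probability rather than one noisy draw of it. All randomness flows from one
master seed through named substreams, so the whole study is reproducible
byte-for-byte. At these sizes the full study runs in well under two minutes
on a single core.

## Numerical and design choices

* **Boundary points are inside** (distance 0): the protective designation is
  read inclusively; the rule only matters for measure-zero configurations.
* **Buffers are 1.61/4.83 km exactly as printed**, not exact metric miles.
* **Ring areas** use the convex closed form when its assumptions verifiably
  hold and fall back to clipped grid integration (250-m cells) otherwise.
* **Degenerate inputs error loudly**: infeasible core coverage, empty core
  sets, $x > n$, probabilities at 0/1 under the logit, zero-variance designs,
  duplicate years, unlabeled leks.
* **Replicate problem sizes** in the property tests are chosen for power, not
  realism: the null-calibration battery uses a 600-lek mini-landscape, while
  the sign-recovery experiment uses a dense 6,000-lek / 16,000-well
  mini-landscape with a low deep-core base rate (0.005) and strong coupling
  (slope 16), so the logit response sweeps its steep region as drilling
  accumulates; weaker couplings are recovered with the right sign only at the
  rate regression power allows.

## What passing tests do and do not show

The generator reproduces the *moments the analysis consumes*: stratum
attendance means and their ratio, the marginal survey rate, calibrated
three-year collapse frequencies, growing lagged densities, and a
near-boundary coupling. It does not reproduce spatial autocorrelation of
attendance, observer effects, lek complexes, true drilling economics, or any
real geography; recovery of the calibration targets shows the pipeline
measures what the generator encodes, not that the generator is Wyoming.

Two limitations deserve emphasis. First, the attendance prediction rests on
the minimal collapse-to-attendance mapping described above. Second — and the
test suite quantifies this deliberately — the yearly collapse series is
autocorrelated by construction (overlapping three-year windows; multi-year
inactive spells), while the OLS battery's nominal standard errors assume
independent years. Against a steadily growing density covariate this makes
the nominal two-standard-error criterion anticonservative: under a true null
coupling, fitted slopes land within 2 SE of zero in only about 70% of
replicates, not 95%. The acceptance suite asserts the nominal rate and is
expected to flag this; treat small regression $p$-values from this design,
here or anywhere, with corresponding caution.
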