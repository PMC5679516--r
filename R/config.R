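#' Landscape configuration for the synthetic study region
#'
#' Bundles the geometry and sampling parameters of the synthetic landscape:
#' a rectangular study extent in projected meters, a set of disjoint protected
#' "core" polygons covering a target fraction of the extent, lek locations split
#' between core and non-core ground, and oil/gas well locations with per-well
#' first/last structure-present years. Defaults emulate a statewide sagebrush
#' landscape: ~252,000 km2 extent, 31 cores covering 24% of it, 2,382 leks with
#' 66% inside cores, and 72,562 wells whose density is capped at 1 well per
#' 2.6 km2 inside cores and reaches ~11.33 wells/km2 in the densest fields
#' outside them.
#'
#' @param extent Named numeric vector `c(xmin, ymin, xmax, ymax)` in meters.
#' @param n_cores Number of core polygons.
#' @param core_area_fraction Fraction of the extent the cores jointly cover.
#' @param n_leks,core_lek_fraction Total leks and the probability a lek falls
#'   inside a core.
#' @param n_wells Total wells on the landscape.
#' @param inside_well_density_cap Maximum allowed well density inside cores
#'   (wells/km2); default is the regulatory 1 well per 2.6 km2.
#' @param inside_well_intensity Realized mean well density inside cores
#'   (wells/km2); must not exceed the cap.
#' @param outside_well_density_max Approximate peak well density in the densest
#'   drilling field outside cores (wells/km2).
#' @param n_well_fields Number of clustered drilling "fields" outside cores.
#' @param field_radius_km Range (min, max) of field radii in km.
#' @param field_well_share Share of outside wells allocated to fields rather
#'   than diffuse background drilling.
#' @param pre_study_well_share Share of wells whose structure predates the first
#'   study year (the rest are spudded during the study with increasing rate).
#' @param well_removal_rate Probability a well structure is removed before the
#'   last study year (removed wells get a finite `last_year`).
#' @param core_margin_m Minimum distance from a core to the extent edge (m).
#' @param core_gap_m Minimum gap between two cores (m); keep it above twice the
#'   widest analysis buffer so outside buffer rings never overlap another core.
#' @param years Inclusive vector of consecutive survey years.
#' @param seed Integer seed controlling every random draw in the generator.
#'
#' @return An object of class `landscape_config` (a validated list).
#' @seealso [generate_core_areas()], [generate_points()]
#' @export
landscape_config <- function(extent = c(xmin = 0, ymin = 0, xmax = 600000, ymax = 420000),
                             n_cores = 31,
                             core_area_fraction = 0.24,
                             n_leks = 2382,
                             core_lek_fraction = 0.66,
                             n_wells = 72562,
                             inside_well_density_cap = 1 / 2.6,
                             inside_well_intensity = 0.05,
                             outside_well_density_max = 11.33,
                             n_well_fields = 8,
                             field_radius_km = c(12, 30),
                             field_well_share = 0.7,
                             pre_study_well_share = 0.55,
                             well_removal_rate = 0.05,
                             core_margin_m = 6000,
                             core_gap_m = 12000,
                             years = 1999:2013,
                             seed = 1L) {
  extent <- as.double(extent)
  names(extent) <- c("xmin", "ymin", "xmax", "ymax")
  if (extent["xmax"] <= extent["xmin"] || extent["ymax"] <= extent["ymin"]) {
    abort("`extent` must have positive width and height.", class = "lekshed_config_error")
  }
  if (!(core_area_fraction > 0 && core_area_fraction < 1)) {
    abort("`core_area_fraction` must lie strictly between 0 and 1.",
      class = "lekshed_config_error"
    )
  }
  if (core_lek_fraction < 0 || core_lek_fraction > 1) {
    abort("`core_lek_fraction` must lie in [0, 1].", class = "lekshed_config_error")
  }
  if (inside_well_intensity > inside_well_density_cap) {
    abort("`inside_well_intensity` exceeds `inside_well_density_cap`.",
      class = "lekshed_config_error"
    )
  }
  years <- sort(as.integer(years))
  if (length(years) < 3L || !all(diff(years) == 1L)) {
    abort("`years` must be at least 3 consecutive years (the collapse window).",
      class = "lekshed_config_error"
    )
  }
  stopifnot(n_cores >= 1, n_leks >= 1, n_wells >= 0)
  structure(
    list(
      extent = extent, n_cores = as.integer(n_cores),
      core_area_fraction = core_area_fraction, n_leks = as.integer(n_leks),
      core_lek_fraction = core_lek_fraction, n_wells = as.integer(n_wells),
      inside_well_density_cap = inside_well_density_cap,
      inside_well_intensity = inside_well_intensity,
      outside_well_density_max = outside_well_density_max,
      n_well_fields = as.integer(n_well_fields),
      field_radius_km = as.double(field_radius_km),
      field_well_share = field_well_share,
      pre_study_well_share = pre_study_well_share,
      well_removal_rate = well_removal_rate,
      core_margin_m = core_margin_m, core_gap_m = core_gap_m,
      years = years, seed = as.integer(seed)
    ),
    class = "landscape_config"
  )
}

#' @export
print.landscape_config <- function(x, ...) {
  km2 <- extent_area_km2(x$extent)
  cat("<landscape_config>\n")
  cat(sprintf(
    "  extent %.0f x %.0f km (%.0f km2), %d cores covering %.0f%%\n",
    (x$extent["xmax"] - x$extent["xmin"]) / 1000,
    (x$extent["ymax"] - x$extent["ymin"]) / 1000,
    km2, x$n_cores, 100 * x$core_area_fraction
  ))
  cat(sprintf(
    "  %d leks (%.0f%% in cores), %d wells, years %d-%d, seed %d\n",
    x$n_leks, 100 * x$core_lek_fraction, x$n_wells,
    min(x$years), max(x$years), x$seed
  ))
  invisible(x)
}

#' Attendance and collapse dynamics of the synthetic lek counts
#'
#' Parameters of the count simulator: per-stratum mean attendance, negative
#' binomial overdispersion, a shared multi-year population cycle, a latent
#' two-state (active/inactive) Markov chain whose inactive-entry probability can
#' be coupled to oil/gas development adjacent to the core boundary, and survey
#' missingness.
#'
#' Attendance means are interpreted as realized males/lek including zero counts
#' from inactive leks; the simulator scales the active-lek mean accordingly.
#' `edge_logit_slope` acts on the logit of the inactive-entry probability of
#' core leks per unit of lagged adjacent well density (wells/km2): a positive
#' slope means more development just outside the boundary pushes nearby core
#' leks toward inactivity (and hence collapse). Negative slopes are rejected.
#'
#' @param core_mean_males,noncore_mean_males Mean males/lek by stratum.
#' @param overdispersion Negative binomial size parameter `k`; count variance is
#'   `mean + mean^2 / k`, so larger values approach Poisson counts.
#' @param cycle_period_years Period of the shared sinusoidal year effect
#'   (population cycles of roughly 6-9 years).
#' @param cycle_amplitude Amplitude of the cycle as a fraction of the mean.
#' @param base_inactive_entry_rate_core,base_inactive_entry_rate_noncore Annual
#'   probability an active lek turns inactive, absent any edge effect.
#' @param inactive_exit_rate Annual probability an inactive lek reactivates.
#' @param edge_logit_slope Edge coupling, per (wells/km2); must be >= 0.
#' @param adjacency_radius_km Radius used to measure development adjacent to a
#'   core lek (wells outside cores within this distance).
#' @param missing_rate Marginal probability a lek-year goes unsurveyed.
#' @param survey_persistence Concentration of the per-lek Beta survey
#'   propensity; small values mean some leks are monitored nearly every year
#'   while others are rarely visited, large values approach independent
#'   lek-year missingness.
#'
#' @return An object of class `attendance_dynamics` (a validated list).
#' @seealso [simulate_counts()], [calibrate_collapse_rate()]
#' @export
attendance_dynamics <- function(core_mean_males = 22,
                                noncore_mean_males = 9,
                                overdispersion = 2,
                                cycle_period_years = 7.5,
                                cycle_amplitude = 0.4,
                                base_inactive_entry_rate_core = 0.17,
                                base_inactive_entry_rate_noncore = 0.50,
                                inactive_exit_rate = 0.4,
                                edge_logit_slope = 0,
                                adjacency_radius_km = 4.83,
                                missing_rate = 0.36,
                                survey_persistence = 1) {
  rates <- c(
    base_inactive_entry_rate_core, base_inactive_entry_rate_noncore,
    inactive_exit_rate, missing_rate
  )
  if (any(rates < 0 | rates > 1)) {
    abort("All rates/probabilities must lie in [0, 1].", class = "lekshed_config_error")
  }
  if (core_mean_males <= 0 || noncore_mean_males <= 0) {
    abort("Attendance means must be positive.", class = "lekshed_config_error")
  }
  if (edge_logit_slope < 0) {
    abort(paste(
      "`edge_logit_slope` must be >= 0: the slope acts on inactive-entry,",
      "so a negative effect of development on birds is a positive slope here."
    ), class = "lekshed_config_error")
  }
  if (cycle_amplitude < 0 || cycle_amplitude > 1) {
    abort("`cycle_amplitude` must lie in [0, 1].", class = "lekshed_config_error")
  }
  stopifnot(overdispersion > 0, cycle_period_years > 0, survey_persistence > 0)
  structure(
    list(
      core_mean_males = core_mean_males, noncore_mean_males = noncore_mean_males,
      overdispersion = overdispersion, cycle_period_years = cycle_period_years,
      cycle_amplitude = cycle_amplitude,
      base_inactive_entry_rate_core = base_inactive_entry_rate_core,
      base_inactive_entry_rate_noncore = base_inactive_entry_rate_noncore,
      inactive_exit_rate = inactive_exit_rate,
      edge_logit_slope = edge_logit_slope,
      adjacency_radius_km = adjacency_radius_km,
      missing_rate = missing_rate, survey_persistence = survey_persistence
    ),
    class = "attendance_dynamics"
  )
}

#' @export
print.attendance_dynamics <- function(x, ...) {
  cat("<attendance_dynamics>\n")
  cat(sprintf(
    "  mean males core %.1f / non-core %.1f, NB size %.2f, cycle %.1f yr x %.0f%%\n",
    x$core_mean_males, x$noncore_mean_males, x$overdispersion,
    x$cycle_period_years, 100 * x$cycle_amplitude
  ))
  cat(sprintf(
    "  entry core %.4f / non-core %.4f, exit %.2f, edge slope %.3f per wells/km2\n",
    x$base_inactive_entry_rate_core, x$base_inactive_entry_rate_noncore,
    x$inactive_exit_rate, x$edge_logit_slope
  ))
  cat(sprintf(
    "  missing rate %.2f (persistence %.2f)\n",
    x$missing_rate, x$survey_persistence
  ))
  invisible(x)
}

extent_area_km2 <- function(extent) {
  (extent["xmax"] - extent["xmin"]) * (extent["ymax"] - extent["ymin"]) / 1e6
}
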