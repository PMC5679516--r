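# Core count simulator shared by simulate_counts() and the calibration loop.
#
# All randomness is drawn up front in a fixed order (entry, exit, counts,
# survey), so two runs with the same seed and the same problem dimensions
# consume the RNG stream identically regardless of parameter values. That
# gives the bisection in calibrate_collapse_rate() common random numbers and
# hence a (near) monotone objective.
#
# entry: n x T matrix of inactive-entry probabilities; exit: scalar;
# mean_males: length-n realized mean males/lek (zeros included); season:
# length-T multiplicative year effect; size: NB size; propensity: length-n
# survey probability. Returns matrices `males` (NA where unsurveyed) and
# `inactive`.
sim_count_matrix <- function(entry, exit, mean_males, size, season, propensity) {
  n <- nrow(entry)
  tt <- ncol(entry)
  u_entry <- matrix(runif(n * tt), n, tt)
  u_exit <- matrix(runif(n * tt), n, tt)
  # stationary inactivity, lek-averaged over years, sets the active-lek mean so
  # the realized mean (zeros included) matches mean_males
  denom <- entry + exit
  pi_t <- ifelse(denom > 0, entry / denom, 0)
  pibar <- rowMeans(pi_t)
  mu_active <- mean_males / pmax(1 - pibar, 0.05)
  mu <- outer(mu_active, season)
  draws <- matrix(rnbinom(n * tt, size = size, mu = as.vector(mu)), n, tt)
  u_surv <- matrix(runif(n * tt), n, tt)

  inactive <- matrix(FALSE, n, tt)
  inactive[, 1] <- u_entry[, 1] < pi_t[, 1]
  for (t in seq_len(tt)[-1]) {
    inactive[, t] <- ifelse(inactive[, t - 1], u_exit[, t] >= exit, u_entry[, t] < entry[, t])
  }
  males <- draws
  males[inactive] <- 0L
  males[u_surv >= propensity] <- NA_integer_
  list(males = males, inactive = inactive)
}

count_matrix_to_long <- function(males, lek_ids, years) {
  obs <- which(!is.na(males), arr.ind = TRUE)
  tibble(
    lek_id = lek_ids[obs[, 1]],
    year = years[obs[, 2]],
    males = as.integer(males[obs])
  ) %>% arrange(.data$lek_id, .data$year)
}

season_effect <- function(years, amplitude, period) {
  1 + amplitude * sin(2 * pi * (years - years[1]) / period)
}

draw_propensity <- function(n, missing_rate, persistence) {
  if (missing_rate <= 0) return(rep(1, n))
  if (missing_rate >= 1) return(rep(0, n))
  rbeta(n, persistence * (1 - missing_rate), persistence * missing_rate)
}

#' Simulate annual maximum male counts on a synthetic landscape
#'
#' Each lek carries a latent two-state activity chain: an active lek turns
#' inactive with an annual entry probability and an inactive lek reactivates
#' with `inactive_exit_rate`. For core leks the entry probability is
#' `plogis(qlogis(base) + edge_logit_slope * adjacent density)`, where adjacent
#' density is the lagged (previous-year) density of wells outside cores within
#' `adjacency_radius_km` of the lek; leks deeper inside a core than that radius
#' have adjacent density exactly zero. Active lek-years draw a negative
#' binomial count whose mean follows the shared population cycle; inactive
#' lek-years count zero. Lek-years are unsurveyed (absent from the output) with
#' lek-specific probability drawn from a Beta distribution with mean
#' `1 - missing_rate`.
#'
#' @param leks Tibble with `lek_id`, `x`, `y`.
#' @param wells Tibble with `x`, `y`, `first_year`, `last_year` (only used when
#'   `edge_logit_slope > 0`).
#' @param cores A [core_areas] object on the same projected extent.
#' @param dyn An [attendance_dynamics()].
#' @param years Consecutive survey years.
#' @param seed Integer seed.
#' @param adjacency Optional precomputed [lek_adjacent_density()] table for
#'   these leks and years (saves the spatial query when simulating many count
#'   realizations on one landscape).
#' @return Long tibble `lek_id, year, males` with one row per surveyed
#'   lek-year; counts are non-negative integers.
#' @export
simulate_counts <- function(leks, wells, cores, dyn, years, seed, adjacency = NULL) {
  stopifnot(inherits(dyn, "attendance_dynamics"), inherits(cores, "core_areas"))
  years <- sort(as.integer(years))
  n <- nrow(leks)
  tt <- length(years)
  d <- signed_boundary_distance(leks, cores)
  is_core <- d >= 0

  adj <- matrix(0, n, tt)
  if (dyn$edge_logit_slope > 0) {
    near <- which(is_core & d < dyn$adjacency_radius_km * 1000)
    if (length(near)) {
      dens <- adjacency %||% lek_adjacent_density(
        leks[near, ], wells, cores, years,
        radius_km = dyn$adjacency_radius_km
      )
      dens <- dens[dens$lek_id %in% leks$lek_id[near], , drop = FALSE]
      m <- tidyr::pivot_wider(dens,
        id_cols = "lek_id", names_from = "year", values_from = "density"
      )
      adj[near, ] <- as.matrix(m[match(leks$lek_id[near], m$lek_id), as.character(years)])
    }
  }

  base <- ifelse(is_core, dyn$base_inactive_entry_rate_core,
    dyn$base_inactive_entry_rate_noncore
  )
  entry <- matrix(base, n, tt)
  if (dyn$edge_logit_slope > 0) {
    core_rows <- which(is_core)
    entry[core_rows, ] <- plogis(
      qlogis(base[core_rows]) + dyn$edge_logit_slope * adj[core_rows, , drop = FALSE]
    )
    entry[is.nan(entry)] <- 0 # qlogis(0) = -Inf with zero slope term
  }

  mean_males <- ifelse(is_core, dyn$core_mean_males, dyn$noncore_mean_males)
  season <- season_effect(years, dyn$cycle_amplitude, dyn$cycle_period_years)

  with_seed(seed, {
    propensity <- draw_propensity(n, dyn$missing_rate, dyn$survey_persistence)
    sim <- sim_count_matrix(
      entry, dyn$inactive_exit_rate, mean_males,
      dyn$overdispersion, season, propensity
    )
  })
  count_matrix_to_long(sim$males, leks$lek_id, years)
}

# Stand-alone single-stratum simulation used by calibration and tests: n
# identical leks, constant entry probability, no geometry.
simulate_stratum_counts <- function(n_leks, years, entry_rate, dyn,
                                    stratum = c("core", "noncore"), seed,
                                    adjacent_density = 0) {
  stratum <- match.arg(stratum)
  years <- sort(as.integer(years))
  e <- if (adjacent_density > 0 && dyn$edge_logit_slope > 0) {
    plogis(qlogis(entry_rate) + dyn$edge_logit_slope * adjacent_density)
  } else {
    entry_rate
  }
  entry <- matrix(e, n_leks, length(years))
  mean_males <- rep(
    if (stratum == "core") dyn$core_mean_males else dyn$noncore_mean_males,
    n_leks
  )
  season <- season_effect(years, dyn$cycle_amplitude, dyn$cycle_period_years)
  with_seed(seed, {
    propensity <- draw_propensity(n_leks, dyn$missing_rate, dyn$survey_persistence)
    sim <- sim_count_matrix(
      entry, dyn$inactive_exit_rate, mean_males,
      dyn$overdispersion, season, propensity
    )
  })
  count_matrix_to_long(sim$males, sprintf("lek_%05d", seq_len(n_leks)), years)
}

#' Measure the realized collapse frequency of a dynamics configuration
#'
#' Simulates a single stratum of leks under `dyn` with the stratum's base
#' inactive-entry rate and returns the pooled 3-consecutive-zero collapse
#' frequency (collapsed lek-years / eligible lek-years) measured by
#' [collapse_panel()]. This is the downstream statistic the calibration in
#' [calibrate_collapse_rate()] drives to a target.
#'
#' @param dyn An [attendance_dynamics()].
#' @param stratum `"core"` or `"noncore"`.
#' @param seed Integer seed.
#' @param n_leks,years Simulation size (defaults give ~60,000 lek-years).
#' @param window Collapse window in years.
#' @return The measured collapse frequency (scalar in \[0, 1\]).
#' @export
measure_collapse_rate <- function(dyn, stratum = c("core", "noncore"), seed,
                                  n_leks = 4000, years = 1999:2013, window = 3) {
  stratum <- match.arg(stratum)
  rate <- if (stratum == "core") {
    dyn$base_inactive_entry_rate_core
  } else {
    dyn$base_inactive_entry_rate_noncore
  }
  counts <- simulate_stratum_counts(n_leks, years, rate, dyn, stratum, seed)
  panel <- collapse_panel(counts, window = window)
  sum(panel$collapsed) / sum(panel$eligible)
}

#' Calibrate the inactive-entry rate to a target measured collapse frequency
#'
#' The quantity the analysis measures is the frequency of three consecutive
#' zero counts among eligible lek-years, not the per-year inactive-entry rate,
#' so the entry rate is tuned by bisection: each candidate rate is evaluated by
#' simulating `n_leks` leks over `years` (with the full count model, including
#' the population cycle, overdispersed active counts and missingness) under
#' common random numbers, and the bracket is narrowed until the measured
#' frequency hits `target` within `tol`.
#'
#' @param target Target measured collapse frequency in (0, 1); `0` is allowed
#'   and returns an entry rate of exactly 0.
#' @param dyn An [attendance_dynamics()]; all parameters other than the
#'   calibrated entry rate are held fixed.
#' @param stratum Which stratum's base entry rate to calibrate.
#' @param seed Integer seed for the evaluation simulations.
#' @param n_leks,years Simulation size per evaluation.
#' @param tol Absolute tolerance on the measured frequency.
#' @param max_iter Bisection iterations.
#' @return `dyn` with the calibrated base entry rate. Errors with a diagnostic
#'   if the target is unreachable given the exit rate.
#' @export
calibrate_collapse_rate <- function(target, dyn, stratum = c("core", "noncore"),
                                    seed = 1L, n_leks = 4000, years = 1999:2013,
                                    tol = 0.01, max_iter = 40) {
  stratum <- match.arg(stratum)
  if (target < 0 || target >= 1) {
    abort("`target` must lie in [0, 1).", class = "lekshed_calibration_error")
  }
  field <- paste0("base_inactive_entry_rate_", stratum)
  set_rate <- function(e) {
    dyn[[field]] <- e
    dyn
  }
  if (target == 0) {
    return(set_rate(0))
  }
  eval_rate <- function(e) {
    counts <- simulate_stratum_counts(n_leks, years, e, dyn, stratum, seed)
    panel <- collapse_panel(counts, window = 3)
    sum(panel$collapsed) / sum(panel$eligible)
  }
  lo <- 0
  hi <- 0.95
  f_lo <- eval_rate(lo)
  f_hi <- eval_rate(hi)
  if (target < f_lo - tol || target > f_hi + tol) {
    abort(sprintf(
      paste(
        "Calibration target %.3f unreachable: measured collapse frequency",
        "spans [%.4f, %.4f] for entry rates in [0, 0.95] at exit rate %.2f."
      ),
      target, f_lo, f_hi, dyn$inactive_exit_rate
    ), class = "lekshed_calibration_error")
  }
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- eval_rate(mid)
    if (abs(f_mid - target) <= tol / 4 || (hi - lo) < 1e-6) break
    if (f_mid < target) lo <- mid else hi <- mid
  }
  if (abs(f_mid - target) > tol) {
    abort(sprintf(
      "Calibration did not converge: best measured frequency %.4f vs target %.4f.",
      f_mid, target
    ), class = "lekshed_calibration_error")
  }
  set_rate(mid)
}
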