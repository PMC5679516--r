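make_static_landscape <- function(seed = 41) {
  cfg <- mini_config(seed = seed)
  cores <- generate_core_areas(cfg)
  pts <- generate_points(cfg, cores)
  list(cfg = cfg, cores = cores, leks = pts$leks, wells = pts$wells)
}

test_that("count simulation is deterministic and produces valid counts", {
  L <- make_static_landscape()
  dyn <- attendance_dynamics()
  a <- simulate_counts(L$leks, L$wells, L$cores, dyn, years = L$cfg$years, seed = 5)
  b <- simulate_counts(L$leks, L$wells, L$cores, dyn, years = L$cfg$years, seed = 5)
  expect_identical(a, b)
  expect_true(all(a$males >= 0))
  expect_true(all(a$males == round(a$males)))
  expect_true(all(a$year %in% L$cfg$years))
})

test_that("missingness matches the configured rate given lek-level propensity", {
  L <- make_static_landscape()
  dyn <- attendance_dynamics(missing_rate = 0.36, survey_persistence = 1)
  counts <- simulate_counts(L$leks, L$wells, L$cores, dyn, years = L$cfg$years, seed = 9)
  n <- nrow(L$leks)
  tt <- length(L$cfg$years)
  observed_rate <- 1 - nrow(counts) / (n * tt)
  m <- dyn$missing_rate
  # per-lek surveyed total is beta-binomial: Var = T m(1-m) + T(T-1) m(1-m)/(c+1)
  var_lek <- tt * m * (1 - m) * (1 + (tt - 1) / (dyn$survey_persistence + 1))
  sd_rate <- sqrt(n * var_lek) / (n * tt)
  expect_lt(abs(observed_rate - m), 3 * sd_rate)
})

test_that("an absorbing inactive state yields all-zero counts", {
  L <- make_static_landscape()
  dyn <- attendance_dynamics(
    base_inactive_entry_rate_core = 1, base_inactive_entry_rate_noncore = 1,
    inactive_exit_rate = 0
  )
  counts <- simulate_counts(L$leks, L$wells, L$cores, dyn, years = L$cfg$years, seed = 2)
  expect_true(all(counts$males == 0))
})

test_that("without cycle, inactivity or overdispersion the counts sit at the mean", {
  L <- make_static_landscape()
  dyn <- attendance_dynamics(
    cycle_amplitude = 0, overdispersion = 1e7,
    base_inactive_entry_rate_core = 0, base_inactive_entry_rate_noncore = 0,
    missing_rate = 0
  )
  counts <- simulate_counts(L$leks, L$wells, L$cores, dyn, years = L$cfg$years, seed = 3)
  st <- assign_strata(L$leks, L$cores)
  labelled <- dplyr::left_join(counts, st[, c("lek_id", "core_all")], by = "lek_id")
  core_mean <- mean(labelled$males[labelled$core_all])
  nc_mean <- mean(labelled$males[!labelled$core_all])
  expect_lt(abs(core_mean - dyn$core_mean_males), 0.2)
  expect_lt(abs(nc_mean - dyn$noncore_mean_males), 0.2)
  # near-Poisson: variance close to the mean, nothing like overdispersed
  expect_lt(var(labelled$males[labelled$core_all]), 2 * dyn$core_mean_males)
})

test_that("realized attendance hits the stratum means with inactivity present", {
  L <- make_static_landscape(seed = 43)
  dyn <- attendance_dynamics()
  counts <- simulate_counts(L$leks, L$wells, L$cores, dyn, years = L$cfg$years, seed = 4)
  st <- assign_strata(L$leks, L$cores)
  labelled <- dplyr::left_join(counts, st[, c("lek_id", "core_all")], by = "lek_id")
  expect_lt(abs(mean(labelled$males[labelled$core_all]) - dyn$core_mean_males), 2.5)
  expect_lt(abs(mean(labelled$males[!labelled$core_all]) - dyn$noncore_mean_males), 1.5)
})

test_that("zero edge slope leaves near-boundary and deep-core collapse equal", {
  L <- make_static_landscape(seed = 47)
  cfg <- L$cfg
  cfg$n_leks <- 1200L # >= 10^4 core lek-years
  pts <- generate_points(cfg, L$cores)
  dyn <- attendance_dynamics(edge_logit_slope = 0)
  counts <- simulate_counts(pts$leks, L$wells, L$cores, dyn, years = cfg$years, seed = 6)
  st <- assign_strata(pts$leks, L$cores)
  agg <- aggregate_collapse(collapse_panel(counts), st)
  rate <- function(stratum) {
    sub <- agg[agg$stratum == stratum, ]
    sum(sub$x) / sum(sub$n)
  }
  expect_lt(abs(rate("core_within_3mi") - rate("core_core")), 0.03)
})

test_that("a larger edge slope monotonically raises near-boundary collapse", {
  L <- make_static_landscape(seed = 53)
  st <- assign_strata(L$leks, L$cores)
  rates <- vapply(c(0, 3, 8), function(slope) {
    dyn <- attendance_dynamics(edge_logit_slope = slope)
    counts <- simulate_counts(L$leks, L$wells, L$cores, dyn,
      years = L$cfg$years, seed = 8
    )
    agg <- aggregate_collapse(collapse_panel(counts), st)
    sub <- agg[agg$stratum == "core_within_1mi", ]
    sum(sub$x) / sum(sub$n)
  }, numeric(1))
  expect_true(all(diff(rates) >= 0))
  expect_gt(rates[3], rates[1])
})

test_that("negative edge slopes are rejected with the sign convention explained", {
  expect_error(attendance_dynamics(edge_logit_slope = -1), "inactive-entry")
})

test_that("collapse-rate calibration hits its target and handles the extremes", {
  dyn <- attendance_dynamics()
  expect_equal(
    calibrate_collapse_rate(0, dyn, "core")$base_inactive_entry_rate_core, 0
  )
  cal <- calibrate_collapse_rate(0.109, dyn, "core", seed = 61)
  fresh <- measure_collapse_rate(cal, "core", seed = 62, n_leks = 20000)
  expect_gte(fresh, 0.099)
  expect_lte(fresh, 0.119)
  cal2 <- calibrate_collapse_rate(0.204, dyn, "noncore", seed = 63)
  fresh2 <- measure_collapse_rate(cal2, "noncore", seed = 64, n_leks = 20000)
  expect_gte(fresh2, 0.194)
  expect_lte(fresh2, 0.214)
  expect_error(
    calibrate_collapse_rate(0.6, dyn, "core", seed = 65),
    class = "lekshed_calibration_error"
  )
})

test_that("re-calibrating to an achieved target barely moves the entry rate", {
  dyn <- attendance_dynamics()
  cal <- calibrate_collapse_rate(0.109, dyn, "core", seed = 71, n_leks = 20000)
  achieved <- measure_collapse_rate(cal, "core", seed = 72, n_leks = 20000)
  recal <- calibrate_collapse_rate(achieved, cal, "core", seed = 73, n_leks = 20000)
  expect_lt(
    abs(recal$base_inactive_entry_rate_core - cal$base_inactive_entry_rate_core),
    0.03
  )
})
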