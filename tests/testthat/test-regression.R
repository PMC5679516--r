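test_that("simple exact fits recover slope and fit quality", {
  d <- tibble::tibble(year = 1:3, probability = c(0, 1, 2), density = c(0, 1, 2))
  fit <- suppressWarnings(fit_edge_regression(d, scale = "identity"))
  expect_equal(fit$beta, 1)
  expect_equal(fit$r2, 1)
  flat <- fit_edge_regression(
    tibble::tibble(year = 1:3, probability = c(0, 1, 0), density = c(0, 1, 2)),
    scale = "identity"
  )
  expect_equal(flat$beta, 0)
  expect_equal(flat$r2, 0, tolerance = 1e-12)
})

test_that("OLS output matches the normal-equations oracle to 1e-10", {
  withr::with_seed(77, {
    d <- tibble::tibble(
      year = 2002:2013,
      density = runif(12, 0.2, 3),
      probability = plogis(-2 + 0.6 * density + rnorm(12, 0, 0.3))
    )
  })
  fit <- fit_edge_regression(d, scale = "logit")
  ref <- oracle_ols(d$density, qlogis(d$probability))
  expect_equal(fit$beta, ref$beta, tolerance = 1e-10)
  expect_equal(fit$intercept, ref$intercept, tolerance = 1e-10)
  expect_equal(fit$se_beta, ref$se_beta, tolerance = 1e-10)
  expect_equal(fit$r2, ref$r2, tolerance = 1e-10)
  expect_equal(fit$f_value, ref$f, tolerance = 1e-10)
  expect_equal(fit$p_value, ref$p, tolerance = 1e-10)
  # internal consistency of F, r2, p
  expect_equal(fit$f_value, fit$r2 / (1 - fit$r2) * (fit$n_years - 2), tolerance = 1e-9)
  expect_equal(fit$p_value, pf(fit$f_value, 1, fit$n_years - 2, lower.tail = FALSE))
  # broom-style accessors
  expect_equal(tidy(fit)$estimate[2], fit$beta)
  expect_equal(glance(fit)$r.squared, fit$r2)
})

test_that("rescaling the covariate rescales the slope accordingly", {
  withr::with_seed(78, {
    d <- tibble::tibble(
      year = 2002:2013, density = runif(12, 0.5, 4),
      probability = plogis(rnorm(12, -1.5, 0.5))
    )
  })
  f1 <- fit_edge_regression(d)
  d2 <- dplyr::mutate(d, density = density * 3.25)
  f2 <- fit_edge_regression(d2)
  expect_equal(f2$beta, f1$beta / 3.25, tolerance = 1e-10)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-10)
})

test_that("degenerate designs and invalid probabilities are rejected", {
  base <- tibble::tibble(year = 1:5, probability = runif(5, 0.1, 0.3), density = 1:5)
  expect_error(
    fit_edge_regression(dplyr::mutate(base, density = 2)),
    class = "lekshed_validation_error"
  )
  expect_error(
    fit_edge_regression(dplyr::mutate(base, probability = c(0, 0.2, 0.3, 0.4, 0.5))),
    class = "lekshed_validation_error"
  )
  expect_error(
    fit_edge_regression(base[1:2, ]),
    class = "lekshed_validation_error"
  )
  dup <- base
  dup$year[2] <- dup$year[1]
  expect_error(fit_edge_regression(dup), class = "lekshed_validation_error")
})

make_series_fixture <- function(seed = 90) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      year = 2001:2013,
      stratum = c("core_all", "core_within_1mi", "core_within_3mi", "core_core")
    )
    grid$x <- rbinom(nrow(grid), 40, 0.12)
    grid$n <- 40L
    posterior_series(grid)
  })
}

test_that("the battery fits all strata-by-buffer pairs plus the inside control", {
  series <- make_series_fixture()
  dens <- tidyr::expand_grid(count_year = 2001:2013, buffer_km = c(1.61, 4.83))
  withr::with_seed(91, dens$density <- runif(nrow(dens), 0.3, 2))
  inside <- tibble::tibble(count_year = 2001:2013, density = runif(13, 0, 0.1))
  bat <- regression_battery(series, dens, inside_densities = inside)
  expect_equal(nrow(bat), 9)
  expect_equal(sum(bat$x_density == "inside"), 1)
  expect_setequal(
    unique(bat$y_stratum),
    c("core_all", "core_within_1mi", "core_within_3mi", "core_core")
  )
  expect_true(all(bat$n_years == 12))
  expect_true(all(bat$r2 >= 0 & bat$r2 <= 1))
  # a missing stratum-year is diagnosed
  expect_error(
    regression_battery(series[series$year != 2005, ], dens),
    class = "lekshed_validation_error"
  )
})

test_that("attendance-change prediction follows the stated logit arithmetic", {
  # build a fit whose slope is exact by fitting points on a logit line
  dstar <- 2
  beta <- (qlogis(0.2) - qlogis(0.1)) / dstar
  d <- tibble::tibble(
    year = 1:5, density = seq(0, 4, by = 1),
    probability = plogis(qlogis(0.1) + beta * seq(0, 4, by = 1))
  )
  fit <- suppressWarnings(fit_edge_regression(d))
  pred <- predict_attendance_change(fit,
    baseline_p = 0.1, mean_males_active = 20,
    densities = c(0, dstar)
  )
  expect_equal(pred$pct_change[1], 0)
  expect_equal(pred$collapse_probability[2], 0.2, tolerance = 1e-9)
  expect_equal(pred$pct_change[2], 100 * (0.8 / 0.9 - 1), tolerance = 1e-6)

  flat <- suppressWarnings(fit_edge_regression(
    tibble::tibble(year = 1:4, density = 1:4, probability = rep(0.15, 4) + 1e-12)
  ))
  flat$beta <- 0
  p0 <- predict_attendance_change(flat, baseline_p = 0.15, densities = 0:5)
  expect_true(all(p0$pct_change == 0))

  curve <- predict_attendance_change(fit, baseline_p = 0.1, densities = seq(0, 50, 1))
  expect_true(all(diff(curve$pct_change) < 0)) # monotone for beta > 0
  expect_true(all(curve$pct_change >= -100))
})
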