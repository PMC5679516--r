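#' Edge-effect regression of collapse probability on adjacent well density
#'
#' Ordinary least squares of a stratum's yearly collapse probability against
#' the lagged well density outside the core boundary, one observation per
#' count year. On the default `"logit"` scale the posterior-mean probability is
#' logit-transformed before fitting, so the slope is per (wells/km2) on the
#' log-odds of collapse and predictions stay inside (0, 1); `"identity"` fits
#' the raw probability. Under this package's sign convention a *positive*
#' slope means collapse probability rises with adjacent development.
#'
#' @param data Tibble with one row per count year: columns `year`,
#'   `probability` (in (0,1) for the logit scale) and `density` (wells/km2,
#'   already lagged by the caller).
#' @param scale `"logit"` (default) or `"identity"`.
#' @return An object of class `edge_regression` with the fitted [stats::lm]
#'   model, `beta`, `intercept`, `se_beta`, `r2`, `f_value`, `df`, `p_value`
#'   and `n_years`. Supports [tidy()], [glance()] and [ggplot2::autoplot()].
#' @examples
#' d <- tibble::tibble(year = 2002:2013, probability = plogis(-2 + 0.5 * (1:12) / 6),
#'                     density = (1:12) / 6)
#' fit_edge_regression(d)
#' @export
fit_edge_regression <- function(data, scale = c("logit", "identity")) {
  scale <- match.arg(scale)
  req <- c("year", "probability", "density")
  if (!all(req %in% names(data))) {
    abort("`data` needs columns year, probability, density.",
      class = "lekshed_validation_error"
    )
  }
  if (anyDuplicated(data$year)) {
    abort("Duplicate years in regression input.", class = "lekshed_validation_error")
  }
  n <- nrow(data)
  if (n < 3) {
    abort("Need at least 3 paired years.", class = "lekshed_validation_error")
  }
  if (sd(data$density) == 0) {
    abort("Zero variance in well density: degenerate design.",
      class = "lekshed_validation_error"
    )
  }
  y <- data$probability
  if (scale == "logit") {
    if (any(y <= 0 | y >= 1)) {
      abort("Probabilities must lie strictly in (0, 1) for the logit scale.",
        class = "lekshed_validation_error"
      )
    }
    y <- qlogis(y)
  }
  model <- lm(y ~ density, data = data.frame(y = y, density = data$density))
  sm <- summary(model)
  beta <- unname(coef(model)[2])
  se_beta <- sm$coefficients[2, 2]
  r2 <- sm$r.squared
  f <- unname(sm$fstatistic[1])
  df2 <- n - 2L
  structure(
    list(
      model = model, scale = scale, data = as_tibble(data),
      beta = beta, intercept = unname(coef(model)[1]),
      se_beta = se_beta, r2 = r2, f_value = f, df = c(1L, df2),
      p_value = pf(f, 1, df2, lower.tail = FALSE), n_years = n
    ),
    class = "edge_regression"
  )
}

#' @export
print.edge_regression <- function(x, ...) {
  cat(sprintf(
    "<edge_regression> (%s scale, %d years)\n  beta = %.3f (SE %.3f), r2 = %.3f, F(1,%d) = %.2f, p = %.4g\n",
    x$scale, x$n_years, x$beta, x$se_beta, x$r2, x$df[2], x$f_value, x$p_value
  ))
  invisible(x)
}

#' @rdname tidiers
#' @param x An `edge_regression` object.
#' @param ... Unused.
#' @export
tidy.edge_regression <- function(x, ...) {
  sm <- unname(summary(x$model)$coefficients)
  tibble(
    term = c("(Intercept)", "density"),
    estimate = sm[, 1], std.error = sm[, 2],
    statistic = sm[, 3], p.value = sm[, 4]
  )
}

#' @rdname tidiers
#' @export
glance.edge_regression <- function(x, ...) {
  tibble(
    r.squared = x$r2, statistic = x$f_value, p.value = x$p_value,
    df = x$df[1], df.residual = x$df[2], nobs = x$n_years, scale = x$scale
  )
}

#' Pairwise edge-effect regression battery
#'
#' Fits the full cross of the four core strata (`core_all, core_within_1mi,
#' core_within_3mi, core_core`) against the two lagged outside-boundary buffer
#' densities, plus one control fit of all-core collapse probability against
#' the lagged well density *inside* cores - nine fits in all.
#'
#' @param series Posterior series from [posterior_series()], covering all four
#'   core strata for every year in `years`.
#' @param densities Buffer densities from [buffer_density_series()].
#' @param inside_densities Optional inside-core control densities from
#'   [inside_density_series()]; the control fit is skipped when `NULL`.
#' @param years Count years used for the fits; the default drops the first
#'   assessable collapse year so every fit has 12 yearly points.
#' @param scale Passed to [fit_edge_regression()].
#' @return Tibble with one row per fit: `y_stratum`, `x_density`
#'   (`"dd_1.61km"`, `"dd_4.83km"` or `"inside"`), the coefficient summary
#'   columns, and a list-column `fit` holding each `edge_regression`.
#' @export
regression_battery <- function(series, densities, inside_densities = NULL,
                               years = 2002:2013, scale = "logit") {
  strata <- c("core_all", "core_within_1mi", "core_within_3mi", "core_core")
  gaps <- tidyr::expand_grid(stratum = strata, year = as.integer(years)) %>%
    dplyr::anti_join(series, by = c("stratum", "year"))
  if (nrow(gaps)) {
    abort(sprintf(
      "Missing stratum-years in posterior series: %s",
      paste(sprintf("%s/%d", gaps$stratum, gaps$year)[seq_len(min(5, nrow(gaps)))],
        collapse = ", "
      )
    ), class = "lekshed_validation_error")
  }
  buffers <- sort(unique(densities$buffer_km))
  specs <- tidyr::expand_grid(y_stratum = strata, buffer_km = buffers)
  fits <- purrr::pmap(specs, function(y_stratum, buffer_km) {
    d <- series %>%
      filter(.data$stratum == y_stratum, .data$year %in% years) %>%
      select(year = "year", probability = "mean") %>%
      left_join(
        densities %>%
          filter(.data$buffer_km == !!buffer_km) %>%
          select(year = "count_year", density = "density"),
        by = "year"
      )
    fit_edge_regression(d, scale = scale)
  })
  out <- specs %>%
    mutate(
      x_density = sprintf("dd_%.2fkm", .data$buffer_km),
      fit = fits
    ) %>%
    select("y_stratum", "x_density", "fit")
  if (!is.null(inside_densities)) {
    d <- series %>%
      filter(.data$stratum == "core_all", .data$year %in% years) %>%
      select(year = "year", probability = "mean") %>%
      left_join(
        inside_densities %>% select(year = "count_year", density = "density"),
        by = "year"
      )
    out <- bind_rows(out, tibble(
      y_stratum = "core_all", x_density = "inside",
      fit = list(fit_edge_regression(d, scale = scale))
    ))
  }
  out %>%
    mutate(
      beta = purrr::map_dbl(.data$fit, "beta"),
      se = purrr::map_dbl(.data$fit, "se_beta"),
      r2 = purrr::map_dbl(.data$fit, "r2"),
      f_value = purrr::map_dbl(.data$fit, "f_value"),
      p_value = purrr::map_dbl(.data$fit, "p_value"),
      n_years = purrr::map_int(.data$fit, "n_years")
    )
}

#' Predicted percent change in core-area lek attendance
#'
#' Applies a logit-scale edge regression to predict how lek attendance inside
#' cores responds to development density adjacent to the boundary. The fitted
#' slope is kept and the intercept shifted so the collapse probability at zero
#' density equals `baseline_p`; expected attendance is proportional to
#' `(1 - p(d)) * mean_males_active` under the minimal assumption that collapsed
#' leks contribute zero males and active-lek attendance is unaffected by
#' development. Percent change is relative to zero adjacent development, so it
#' is exactly 0 at `density = 0` and bounded below by -100%.
#'
#' @param fit A logit-scale `edge_regression`.
#' @param baseline_p Collapse probability at zero adjacent density, in (0, 1).
#' @param mean_males_active Mean males attending an active lek.
#' @param densities Density grid (wells/km2) to evaluate.
#' @return Tibble `density, collapse_probability, expected_males, pct_change`.
#' @export
predict_attendance_change <- function(fit, baseline_p,
                                      mean_males_active = 22,
                                      densities = seq(0, 12, by = 0.1)) {
  stopifnot(inherits(fit, "edge_regression"))
  if (fit$scale != "logit") {
    abort("Attendance prediction requires a logit-scale fit.",
      class = "lekshed_validation_error"
    )
  }
  if (baseline_p <= 0 || baseline_p >= 1) {
    abort("`baseline_p` must lie strictly in (0, 1).",
      class = "lekshed_validation_error"
    )
  }
  p <- plogis(qlogis(baseline_p) + fit$beta * densities)
  expected <- (1 - p) * mean_males_active
  structure(
    tibble(
      density = densities,
      collapse_probability = p,
      expected_males = expected,
      pct_change = 100 * ((1 - p) / (1 - baseline_p) - 1)
    ),
    class = c("attendance_prediction", "tbl_df", "tbl", "data.frame")
  )
}
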