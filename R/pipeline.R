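#' End-to-end analysis pipeline
#'
#' Runs the full chain - stratify leks, build the collapse panel, aggregate per
#' stratum, fit yearly beta-binomial posteriors, compute lagged buffer-ring and
#' inside-core well densities, fit the edge-effect regression battery, predict
#' attendance change, and tabulate attendance summaries - and writes every
#' result as tidy CSV plus a JSON run manifest (settings, package version,
#' input checksums).
#'
#' @param leks_csv,wells_csv,cores_geojson Input paths (see [write_leks_csv()],
#'   [write_wells_csv()], [write_cores_geojson()] for the formats).
#' @param out_dir Output directory.
#' @param window Collapse window (years).
#' @param buffers_km Outside-boundary buffer distances in km.
#' @param prior Prior preset for [beta_prior()].
#' @param ci Credible-interval type (`"central"` or `"hpd"`).
#' @param scale Regression scale (`"logit"` or `"identity"`).
#' @param regression_years Count years entering the regressions.
#' @param seed Recorded in the manifest (the analysis itself is deterministic).
#' @return Invisibly, a named list of the result tibbles.
#' @export
run_pipeline <- function(leks_csv, wells_csv, cores_geojson, out_dir,
                         window = 3, buffers_km = c(1.61, 4.83),
                         prior = "uniform", ci = "central", scale = "logit",
                         regression_years = 2002:2013, seed = 1L) {
  for (p in c(leks_csv, wells_csv, cores_geojson)) {
    if (!file.exists(p)) {
      abort(sprintf("Input file not found: %s", p), class = "lekshed_config_error")
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  lk <- read_leks_csv(leks_csv)
  wells <- read_wells_csv(wells_csv)
  cores <- read_cores_geojson(cores_geojson)

  strata <- assign_strata(lk$leks, cores, buffers_km = buffers_km)
  panel <- collapse_panel(lk$counts, window = window)
  cc <- aggregate_collapse(panel, strata)
  series <- posterior_series(cc, prior = beta_prior(prior), ci = ci)
  strat_means <- stratum_mean_collapse(series)

  count_years <- sort(unique(panel$year))
  dens <- buffer_density_series(cores, wells, count_years, buffers_km = buffers_km)
  inside <- inside_density_series(cores, wells, count_years)
  battery <- regression_battery(series, dens,
    inside_densities = inside,
    years = intersect(regression_years, count_years), scale = scale
  )

  summ <- annual_summary(lk$counts, strata)
  tab1 <- attendance_table(summ)
  share <- core_male_share(lk$counts, strata)
  welch <- welch_attendance_test(lk$counts, strata)

  baseline <- strat_means$mean_probability[strat_means$stratum == "core_all"]
  best <- battery %>% filter(.data$x_density != "inside")
  pred_fit <- best$fit[[which.max(abs(best$beta / best$se))]]
  prediction <- if (scale == "logit") {
    predict_attendance_change(pred_fit, baseline_p = baseline)
  }

  results <- list(
    strata = strata,
    collapse_panel = panel, collapse_counts = cc,
    posterior_series = series, stratum_means = strat_means,
    densities = dens, inside_densities = inside,
    regression_battery = battery %>% select(-"fit"),
    annual_summary = summ, attendance_table = tab1,
    core_male_share = share, welch_test = welch,
    attendance_prediction = prediction
  )

  for (nm in names(results)) {
    if (!is.null(results[[nm]]) && is.data.frame(results[[nm]])) {
      readr::write_csv(results[[nm]], file.path(out_dir, paste0(nm, ".csv")), na = "")
    }
  }

  manifest <- list(
    package = "lekshed",
    version = as.character(utils::packageVersion("lekshed")),
    settings = list(
      window = window, buffers_km = buffers_km, prior = prior, ci = ci,
      scale = scale, regression_years = regression_years, seed = seed
    ),
    inputs = list(
      leks_csv = unname(tools::md5sum(leks_csv)),
      wells_csv = unname(tools::md5sum(wells_csv)),
      cores_geojson = unname(tools::md5sum(cores_geojson))
    ),
    outputs = paste0(names(Filter(Negate(is.null), results)), ".csv")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(results)
}
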