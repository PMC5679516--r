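#' Annual attendance summaries by core membership
#'
#' Per year and stratum (core, non-core, total): leks surveyed, total males,
#' males per lek, minimum and maximum count, leks with zero males, and the
#' percentage of surveyed leks with zero males. A lek contributes to a year
#' only when it was surveyed that year; explicit zero counts are included.
#'
#' @param counts Long tibble `lek_id, year, males`.
#' @param strata Output of [assign_strata()].
#' @return Tibble `year, stratum, n_leks, total_males, males_per_lek,
#'   min_males, max_males, n_zero, pct_zero`.
#' @seealso [attendance_table()] for the across-year mean +/- SE table,
#'   [core_male_share()] for the yearly core share of males.
#' @export
annual_summary <- function(counts, strata) {
  labelled <- counts %>%
    left_join(strata %>% select("lek_id", "core_all"), by = "lek_id")
  if (anyNA(labelled$core_all)) {
    abort("Some leks in `counts` have no stratum label.", class = "lekshed_data_error")
  }
  one <- function(df, label) {
    df %>%
      group_by(year = .data$year) %>%
      summarise(
        stratum = label,
        n_leks = dplyr::n(),
        total_males = sum(.data$males),
        males_per_lek = mean(.data$males),
        min_males = min(.data$males),
        max_males = max(.data$males),
        n_zero = sum(.data$males == 0),
        pct_zero = 100 * mean(.data$males == 0),
        .groups = "drop"
      )
  }
  bind_rows(
    one(filter(labelled, .data$core_all), "core"),
    one(filter(labelled, !.data$core_all), "non_core"),
    one(labelled, "total")
  ) %>% arrange(.data$stratum, .data$year)
}

#' Across-year attendance table (means +/- SE)
#'
#' Condenses [annual_summary()] into one row per stratum with across-year means
#' and standard errors (SD over years / sqrt(years)), the format used for
#' multi-year monitoring summaries.
#'
#' @param summary Output of [annual_summary()].
#' @return Tibble with mean and SE columns per summary statistic.
#' @export
attendance_table <- function(summary) {
  se <- function(v) sd(v) / sqrt(length(v))
  summary %>%
    group_by(stratum = .data$stratum) %>%
    summarise(
      n_years = dplyr::n(),
      mean_total_leks = mean(.data$n_leks), se_total_leks = se(.data$n_leks),
      mean_males_per_lek = mean(.data$males_per_lek),
      se_males_per_lek = se(.data$males_per_lek),
      mean_total_males = mean(.data$total_males), se_total_males = se(.data$total_males),
      mean_zero_leks = mean(.data$n_zero), se_zero_leks = se(.data$n_zero),
      mean_pct_zero = mean(.data$pct_zero), se_pct_zero = se(.data$pct_zero),
      .groups = "drop"
    )
}

#' Yearly percentage of males counted on core-area leks
#'
#' Per year, core males divided by all males counted that year (x100); the
#' across-year unweighted mean of these percentages is the headline core
#' male-share statistic.
#'
#' @inheritParams annual_summary
#' @return Tibble `year, core_males, total_males, pct_males_core`.
#' @export
core_male_share <- function(counts, strata) {
  counts %>%
    left_join(strata %>% select("lek_id", "core_all"), by = "lek_id") %>%
    group_by(year = .data$year) %>%
    summarise(
      core_males = sum(.data$males[.data$core_all]),
      total_males = sum(.data$males),
      pct_males_core = 100 * .data$core_males / .data$total_males,
      .groups = "drop"
    )
}

#' Welch two-sample comparison of core vs non-core lek attendance
#'
#' Unequal-variance t test with Satterthwaite degrees of freedom on the pooled
#' lek-year males/lek observations, core vs non-core. Pooling lek-years (not
#' yearly means) is what yields the characteristic thousands of fractional
#' degrees of freedom.
#'
#' @inheritParams annual_summary
#' @return Tibble `t, df, p_value, mean_core, mean_noncore, n_core, n_noncore`.
#' @export
welch_attendance_test <- function(counts, strata) {
  labelled <- counts %>%
    left_join(strata %>% select("lek_id", "core_all"), by = "lek_id")
  core <- labelled$males[labelled$core_all]
  noncore <- labelled$males[!labelled$core_all]
  if (length(core) < 2 || length(noncore) < 2) {
    abort("Both samples need at least 2 observations.", class = "lekshed_validation_error")
  }
  if (sd(core) == 0 && sd(noncore) == 0) {
    abort("Zero variance in both samples.", class = "lekshed_validation_error")
  }
  tt <- t.test(noncore, core, var.equal = FALSE)
  tibble(
    t = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    mean_core = mean(core), mean_noncore = mean(noncore),
    n_core = length(core), n_noncore = length(noncore)
  )
}
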