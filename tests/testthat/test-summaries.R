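two_lek_fixture <- function(core_males = 10, noncore_males = 10) {
  list(
    counts = tibble::tibble(
      lek_id = c("c1", "n1"), year = 2005L,
      males = c(core_males, noncore_males)
    ),
    strata = tibble::tibble(lek_id = c("c1", "n1"), core_all = c(TRUE, FALSE))
  )
}

test_that("core male share covers the simple and degenerate cases", {
  fx <- two_lek_fixture()
  expect_equal(core_male_share(fx$counts, fx$strata)$pct_males_core, 50)
  only_core <- list(
    counts = fx$counts[1, ],
    strata = fx$strata[1, ]
  )
  expect_equal(core_male_share(only_core$counts, only_core$strata)$pct_males_core, 100)
})

test_that("annual summaries match a brute-force recount on a 50-lek fixture", {
  counts <- random_counts(seed = 55)
  ids <- sort(unique(counts$lek_id))
  strata <- tibble::tibble(lek_id = ids, core_all = seq_along(ids) %% 2 == 0)
  summ <- annual_summary(counts, strata)
  for (yy in sample(unique(counts$year), 4)) {
    for (lab in c("core", "non_core", "total")) {
      members <- switch(lab,
        core = ids[strata$core_all],
        non_core = ids[!strata$core_all],
        total = ids
      )
      sub <- counts[counts$year == yy & counts$lek_id %in% members, ]
      row <- summ[summ$year == yy & summ$stratum == lab, ]
      expect_equal(row$n_leks, nrow(sub))
      expect_equal(row$total_males, sum(sub$males))
      expect_equal(row$males_per_lek, mean(sub$males))
      expect_equal(row$min_males, min(sub$males))
      expect_equal(row$max_males, max(sub$males))
      expect_equal(row$n_zero, sum(sub$males == 0))
      expect_equal(row$pct_zero, 100 * mean(sub$males == 0))
    }
  }
  # additivity and permutation invariance
  wide <- tidyr::pivot_wider(summ[, c("year", "stratum", "n_leks", "total_males")],
    names_from = "stratum", values_from = c("n_leks", "total_males")
  )
  expect_equal(wide$n_leks_core + wide$n_leks_non_core, wide$n_leks_total)
  expect_equal(wide$total_males_core + wide$total_males_non_core, wide$total_males_total)
  shuffled <- counts[sample(nrow(counts)), ]
  expect_equal(annual_summary(shuffled, strata), summ)
})

test_that("the across-year table reports means with SD/sqrt(years) errors", {
  counts <- random_counts(seed = 56)
  ids <- sort(unique(counts$lek_id))
  strata <- tibble::tibble(lek_id = ids, core_all = seq_along(ids) %% 2 == 0)
  summ <- annual_summary(counts, strata)
  tab <- attendance_table(summ)
  core_rows <- summ[summ$stratum == "core", ]
  expect_equal(
    tab$mean_males_per_lek[tab$stratum == "core"],
    mean(core_rows$males_per_lek)
  )
  expect_equal(
    tab$se_males_per_lek[tab$stratum == "core"],
    sd(core_rows$males_per_lek) / sqrt(nrow(core_rows))
  )
})

test_that("the Welch comparison matches the textbook formulas", {
  counts <- random_counts(seed = 57)
  ids <- sort(unique(counts$lek_id))
  strata <- tibble::tibble(lek_id = ids, core_all = seq_along(ids) %% 2 == 0)
  got <- welch_attendance_test(counts, strata)
  labelled <- dplyr::left_join(counts, strata, by = "lek_id")
  ref <- oracle_welch(
    labelled$males[!labelled$core_all],
    labelled$males[labelled$core_all]
  )
  expect_equal(got$t, ref$t, tolerance = 1e-8)
  expect_equal(got$df, ref$df, tolerance = 1e-8)
  expect_equal(got$p_value, ref$p, tolerance = 1e-8)
  # flipping the labels negates the statistic
  flipped <- welch_attendance_test(counts, dplyr::mutate(strata, core_all = !core_all))
  expect_equal(flipped$t, -got$t, tolerance = 1e-10)
  # identical samples give t = 0
  fx <- tibble::tibble(
    lek_id = c("a", "b", "c", "d"), year = 2005L, males = c(3, 7, 3, 7)
  )
  st <- tibble::tibble(lek_id = c("a", "b", "c", "d"), core_all = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(welch_attendance_test(fx, st)$t, 0)
  # both samples constant is degenerate
  cst <- dplyr::mutate(fx, males = 5)
  expect_error(welch_attendance_test(cst, st), class = "lekshed_validation_error")
})
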