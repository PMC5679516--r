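#' Lek-collapse panel from annual maximum male counts
#'
#' A lek is collapsed in year `t` when zero males were observed in `t` and the
#' `window - 1` preceding years (default window 3: the assessed year plus the
#' two previous). A lek-year is eligible for assessment only when a count was
#' recorded in every year of the window; an explicit zero is data, a missing
#' survey is not. Each year is assessed independently, so recovery after a
#' collapse does not carry over. The first assessable year is the first data
#' year plus `window - 1` (1999 data gives a first collapse year of 2001).
#'
#' @param counts Long tibble `lek_id, year, males`; one row per surveyed
#'   lek-year. Non-integer or negative `males` values are treated as missing
#'   (with a warning).
#' @param window Number of consecutive zero-count years defining collapse
#'   (default 3).
#' @return Tibble `lek_id, year, eligible, collapsed`, with one row per lek and
#'   assessable year; `collapsed` implies `eligible`.
#' @examples
#' counts <- tibble::tibble(
#'   lek_id = "A", year = 1999:2003, males = c(3, 0, 0, 0, 2)
#' )
#' collapse_panel(counts) # collapsed only in 2002
#' @export
collapse_panel <- function(counts, window = 3) {
  stopifnot(window >= 1)
  if (nrow(counts) == 0L) {
    return(tibble(
      lek_id = character(), year = integer(),
      eligible = logical(), collapsed = logical()
    ))
  }
  males <- as.double(counts$males)
  bad <- !is.na(males) & (!is_whole(males) | males < 0)
  if (any(bad)) {
    warn(sprintf("%d non-integer or negative counts treated as missing.", sum(bad)))
    males[bad] <- NA_real_
  }
  counts$males <- males

  years <- seq(min(counts$year), max(counts$year))
  ids <- sort(unique(counts$lek_id))
  m <- matrix(NA_real_, length(ids), length(years),
    dimnames = list(ids, as.character(years))
  )
  m[cbind(match(counts$lek_id, ids), match(counts$year, years))] <- counts$males

  if (length(years) < window) {
    return(tibble(
      lek_id = character(), year = integer(),
      eligible = logical(), collapsed = logical()
    ))
  }
  assess <- seq(window, length(years))
  obs <- !is.na(m)
  zero <- obs & m == 0
  elig <- matrix(TRUE, length(ids), length(assess))
  coll <- matrix(TRUE, length(ids), length(assess))
  for (k in seq_len(window) - 1L) {
    elig <- elig & obs[, assess - k, drop = FALSE]
    coll <- coll & zero[, assess - k, drop = FALSE]
  }
  tibble(
    lek_id = rep(ids, times = length(assess)),
    year = rep(years[assess], each = length(ids)),
    eligible = as.vector(elig),
    collapsed = as.vector(coll)
  ) %>% arrange(.data$lek_id, .data$year)
}

#' Aggregate a collapse panel into per-year, per-stratum counts
#'
#' Sums collapsed (`x`) and eligible (`n`) leks per year within each spatial
#' stratum. Strata are membership flags, not a partition: a lek inside a core
#' and within 1.61 km of the boundary contributes to `core_all`,
#' `core_within_1mi` and `core_within_3mi` alike.
#'
#' @param panel Output of [collapse_panel()].
#' @param strata Output of [assign_strata()] (or any tibble with `lek_id` and
#'   logical membership columns). Every lek in the panel must be present.
#' @param strata_cols Which membership columns to aggregate over; defaults to
#'   all logical columns of `strata`.
#' @return Tibble `year, stratum, x, n` with `0 <= x <= n`.
#' @export
aggregate_collapse <- function(panel, strata, strata_cols = NULL) {
  strata_cols <- strata_cols %||% names(strata)[vapply(strata, is.logical, logical(1))]
  if (length(strata_cols) == 0L) {
    abort("`strata` has no logical membership columns.", class = "lekshed_data_error")
  }
  missing_ids <- setdiff(unique(panel$lek_id), strata$lek_id)
  if (length(missing_ids)) {
    abort(sprintf(
      "%d leks in the panel have no stratum label (e.g. %s).",
      length(missing_ids), missing_ids[1]
    ), class = "lekshed_data_error")
  }
  joined <- left_join(panel, strata[, c("lek_id", strata_cols)], by = "lek_id")
  purrr::map_dfr(strata_cols, function(col) {
    joined %>%
      filter(.data[[col]]) %>%
      group_by(year = .data$year) %>%
      summarise(
        x = sum(.data$collapsed & .data$eligible),
        n = sum(.data$eligible),
        .groups = "drop"
      ) %>%
      mutate(stratum = col, .after = "year")
  }) %>%
    arrange(.data$stratum, .data$year)
}
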