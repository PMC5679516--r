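# Small landscapes and hand-built geometries shared across test files.

mini_config <- function(seed = 1L, n_leks = 300L, n_wells = 4000L) {
  landscape_config(
    extent = c(xmin = 0, ymin = 0, xmax = 150000, ymax = 150000),
    n_cores = 6, core_area_fraction = 0.24,
    n_leks = n_leks, core_lek_fraction = 0.66,
    n_wells = n_wells, outside_well_density_max = 8,
    n_well_fields = 3, field_radius_km = c(6, 12),
    seed = seed
  )
}

square_core <- function(x0 = 0, y0 = 0, side = 10000) {
  core_areas(
    list(rbind(
      c(x0, y0), c(x0 + side, y0), c(x0 + side, y0 + side), c(x0, y0 + side)
    )),
    extent = c(
      xmin = x0 - 20000, ymin = y0 - 20000,
      xmax = x0 + side + 20000, ymax = y0 + side + 20000
    )
  )
}

# long count tibble from a named-by-year vector for one lek
lek_series <- function(lek_id, years, males) {
  keep <- !is.na(males)
  tibble::tibble(lek_id = lek_id, year = years[keep], males = males[keep])
}

# 50-lek random count fixture with missing years and frequent zeros
random_counts <- function(seed = 42, n_leks = 50, years = 1999:2013) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n_leks), function(i) {
      surveyed <- runif(length(years)) > 0.3
      males <- rbinom(length(years), 30, 0.25) * rbinom(length(years), 1, 0.6)
      tibble::tibble(
        lek_id = sprintf("L%02d", i),
        year = years[surveyed], males = males[surveyed]
      )
    })
  })
}
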