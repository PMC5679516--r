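test_that("signed boundary distance matches simple geometry and conventions", {
  sq <- square_core(0, 0, 10000)
  pts <- data.frame(
    x = c(5000, -2000, 0, 5000, 11000),
    y = c(5000, 5000, 5000, 0, 5000)
  )
  d <- signed_boundary_distance(pts, sq)
  expect_equal(d, c(5000, -2000, 0, 0, -1000))
  expect_error(
    signed_boundary_distance(pts, core_areas(list())),
    class = "lekshed_config_error"
  )
})

test_that("signed distances agree with a densely sampled boundary oracle", {
  cfg <- mini_config(seed = 21)
  cores <- generate_core_areas(cfg)
  withr::with_seed(10, {
    pts <- data.frame(x = runif(100, 0, 150000), y = runif(100, 0, 150000))
  })
  d <- signed_boundary_distance(pts, cores)
  for (i in seq_len(nrow(pts))) {
    ref <- oracle_boundary_distance(pts$x[i], pts$y[i], cores$polygons, spacing = 0.5)
    expect_lt(abs(abs(d[i]) - ref), 1)
    inside_ref <- any(vapply(
      cores$polygons,
      function(p) oracle_in_polygon(pts$x[i], pts$y[i], p), logical(1)
    ))
    if (abs(d[i]) > 1) expect_equal(d[i] >= 0, inside_ref)
  }
})

test_that("strata are assigned by the statute-mile bands and partition the leks", {
  sq <- square_core(0, 0, 20000)
  leks <- tibble::tibble(
    lek_id = c("in_1mi", "in_3mi", "deep", "outside", "edge"),
    x = c(1000, 8000, 10000, -3000, 0),
    y = c(10000, 2000, 10000, 10000, 10000)
  )
  st <- assign_strata(leks, sq)
  expect_equal(
    st$stratum,
    c("core_within_1mi", "core_1_to_3mi", "core_core", "non_core", "core_within_1mi")
  )
  expect_true(st$core_within_3mi[st$lek_id == "in_1mi"])
  expect_true(st$core_all[st$lek_id == "in_3mi"])
  expect_false(st$core_within_1mi[st$lek_id == "in_3mi"])
  expect_false(st$core_core[st$lek_id == "in_3mi"])
  # partition: exactly one partition label each, and nesting holds
  cfg <- mini_config(seed = 23)
  cores <- generate_core_areas(cfg)
  pts <- generate_points(cfg, cores)
  stt <- assign_strata(pts$leks, cores)
  one_of <- stt$non_core + (stt$core_within_1mi) +
    (stt$core_within_3mi & !stt$core_within_1mi) + stt$core_core
  expect_true(all(one_of == 1))
  expect_true(all(stt$core_within_1mi <= stt$core_within_3mi))
  expect_true(all(stt$core_within_3mi <= stt$core_all))
  expect_true(all(stt$core_all == !stt$non_core))
})

test_that("ring density equals wells over exact ring area in a known geometry", {
  sq <- square_core(0, 0, 5000)
  # 1-km ring around a 5-km square: 4*5*1 + pi = 23.14159 km2
  ring_area <- 20 + pi
  wells <- tibble::tibble(
    well_id = as.character(1:10),
    x = c(rep(-500, 5), rep(5500, 5)),
    y = seq(250, 4750, length.out = 10)[c(1, 3, 5, 7, 9, 2, 4, 6, 8, 10)],
    first_year = 2000L, last_year = NA_integer_
  )
  expect_equal(ring_density(sq, wells, 1, 2005), 10 / ring_area)
  expect_equal(ring_density(sq, wells, 1, 1999), 0) # none present yet
})

test_that("ring density matches an exhaustive point-in-ring oracle", {
  cfg <- mini_config(seed = 31, n_wells = 800)
  cores <- generate_core_areas(cfg)
  wells <- generate_points(cfg, cores)$wells
  for (buffer_km in c(1.61, 4.83)) {
    got <- ring_density(cores, wells, buffer_km, 2010)
    present <- wells[lekshed:::wells_present(wells, 2010), ]
    n_ring <- sum(vapply(seq_len(nrow(present)), function(i) {
      oracle_in_ring(present$x[i], present$y[i], cores$polygons,
        buffer_km * 1000,
        spacing = 2
      )
    }, logical(1)))
    area <- lekshed:::ring_area_exact_km2(cores, buffer_km * 1000)
    expect_equal(got, n_ring / area, tolerance = 1e-6)
  }
})

test_that("ring density is translation invariant and monotone in the well set", {
  sq <- square_core(0, 0, 8000)
  withr::with_seed(5, {
    wells <- tibble::tibble(
      well_id = as.character(1:200),
      x = runif(200, -15000, 23000), y = runif(200, -15000, 23000),
      first_year = 1990L, last_year = NA_integer_
    )
  })
  d0 <- ring_density(sq, wells, 2, 2005)
  shift <- 1e5
  sq2 <- core_areas(lapply(sq$polygons, function(p) p + shift),
    extent = sq$extent + shift
  )
  wells2 <- dplyr::mutate(wells, x = x + shift, y = y + shift)
  expect_equal(ring_density(sq2, wells2, 2, 2005), d0)
  more <- dplyr::bind_rows(wells, tibble::tibble(
    well_id = "extra", x = -1000, y = 4000, first_year = 1990L, last_year = NA_integer_
  ))
  expect_gte(ring_density(sq, more, 2, 2005), d0)
})

test_that("rings clipped by a neighbouring core fall back to grid integration", {
  two <- core_areas(
    list(
      rbind(c(0, 0), c(5000, 0), c(5000, 5000), c(0, 5000)),
      rbind(c(7000, 0), c(12000, 0), c(12000, 5000), c(7000, 5000))
    ),
    extent = c(xmin = -10000, ymin = -10000, xmax = 22000, ymax = 15000)
  )
  wells <- tibble::tibble(
    well_id = "w1", x = 6000, y = 2500, first_year = 2000L, last_year = NA_integer_
  )
  expect_warning(d <- ring_density(two, wells, 2, 2005), "grid integration")
  # clipped area must be smaller than the unclipped closed form
  suppressWarnings({
    area_grid <- lekshed:::ring_area_grid_km2(two, 2000)
  })
  expect_lt(area_grid, lekshed:::ring_area_exact_km2(two, 2000))
  expect_gt(d, 0)
})

test_that("buffer and inside density series apply the one-year lag", {
  sq <- square_core(0, 0, 5000)
  wells <- tibble::tibble(
    well_id = c("ring", "inside"),
    x = c(-500, 2500), y = c(2500, 2500),
    first_year = c(2004L, 2004L), last_year = NA_integer_
  )
  ds <- buffer_density_series(sq, wells, 2003:2006, buffers_km = c(1.61))
  expect_equal(ds$density[ds$count_year %in% 2003:2004], c(0, 0))
  expect_true(all(ds$density[ds$count_year >= 2005] > 0))
  ins <- inside_density_series(sq, wells, 2003:2006)
  expect_equal(ins$density[ins$count_year == 2004], 0)
  expect_equal(ins$density[ins$count_year == 2005], 1 / 25)
})

test_that("focal mode approximates the exact ring statistic on a diffuse field", {
  cfg <- mini_config(seed = 37, n_wells = 3000)
  cfg$n_well_fields <- 0L
  cores <- generate_core_areas(cfg)
  wells <- generate_points(cfg, cores)$wells
  exact <- ring_density(cores, wells, 4.83, 2010)
  focal <- ring_density(cores, wells, 4.83, 2010, mode = "focal")
  expect_gt(focal, 0)
  expect_lt(abs(focal - exact) / exact, 0.5)
})

test_that("lek adjacency sees only lagged outside-core wells within the radius", {
  sq <- square_core(0, 0, 20000)
  leks <- tibble::tibble(
    lek_id = c("near", "deep"), x = c(1000, 10000), y = c(10000, 10000)
  )
  wells <- tibble::tibble(
    well_id = c("adjacent", "inside_core", "far"),
    x = c(-1000, 2000, -30000), y = c(10000, 10000, 10000),
    first_year = c(2005L, 2000L, 2000L), last_year = NA_integer_
  )
  ad <- lek_adjacent_density(leks, wells, sq, 2004:2008, radius_km = 4.83)
  near <- ad[ad$lek_id == "near", ]
  expect_equal(near$density[near$year <= 2005], c(0, 0)) # lag: first seen for 2006
  expect_equal(near$density[near$year == 2006], 1 / (pi * 4.83^2))
  expect_true(all(ad$density[ad$lek_id == "deep"] == 0))
})
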