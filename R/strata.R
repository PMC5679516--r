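#' Assign leks to spatial strata relative to core-area boundaries
#'
#' Strata follow the statute-mile boundary bands used throughout the analysis:
#' non-core (outside all cores), all core leks, core leks within 1.61 km (1 mi)
#' of the boundary, core leks within 4.83 km (3 mi), and "core-core" leks more
#' than 4.83 km inside. The core bands are nested
#' (`core_within_1mi` \eqn{\subseteq} `core_within_3mi` \eqn{\subseteq}
#' `core_all`); `stratum` gives the four-way partition. A lek exactly on the
#' boundary counts as inside at distance 0.
#'
#' @param leks Tibble with `lek_id`, `x`, `y`.
#' @param cores A [core_areas] object.
#' @param buffers_km Inner band half-widths in km (near, far); the printed
#'   1.61/4.83 statute-mile conversions by default.
#' @return Tibble `lek_id, distance_m, stratum` plus logical membership columns
#'   `non_core, core_all, core_within_1mi, core_within_3mi, core_core`.
#' @export
assign_strata <- function(leks, cores, buffers_km = c(1.61, 4.83)) {
  stopifnot(length(buffers_km) == 2, buffers_km[1] < buffers_km[2])
  d <- signed_boundary_distance(leks, cores)
  near <- buffers_km[1] * 1000
  far <- buffers_km[2] * 1000
  tibble(
    lek_id = leks$lek_id,
    distance_m = d,
    non_core = d < 0,
    core_all = d >= 0,
    core_within_1mi = d >= 0 & d <= near,
    core_within_3mi = d >= 0 & d <= far,
    core_core = d > far,
    stratum = dplyr::case_when(
      d < 0 ~ "non_core",
      d <= near ~ "core_within_1mi",
      d <= far ~ "core_1_to_3mi",
      TRUE ~ "core_core"
    )
  )
}

wells_present <- function(wells, year) {
  wells$first_year <= year & (is.na(wells$last_year) | wells$last_year >= year)
}

# Exact area (km2) of the region outside all cores within buffer_m of a core
# boundary. Closed form perimeter*b + pi*b^2 per convex polygon, valid when no
# two cores are within 2*buffer_m of each other and every core sits at least
# buffer_m inside the extent; callers fall back to grid integration otherwise.
ring_area_exact_km2 <- function(cores, buffer_m) {
  per_core <- vapply(cores$polygons, polygon_perimeter_m, numeric(1))
  sum(per_core * buffer_m + pi * buffer_m^2) / 1e6
}

ring_assumptions_hold <- function(cores, buffer_m) {
  convex <- all(vapply(cores$polygons, polygon_is_convex, logical(1)))
  gap_ok <- min_core_gap_m(cores) > 2 * buffer_m
  inset <- min_extent_inset_m(cores)
  inset_ok <- is.na(inset) || inset >= buffer_m
  convex && gap_ok && inset_ok
}

# Grid-integration fallback for the ring area, clipped to the extent and to
# the exclusion of all core interiors.
ring_area_grid_km2 <- function(cores, buffer_m, cell_m = 250) {
  ext <- cores$extent
  if (is.null(ext)) {
    xs <- unlist(lapply(cores$polygons, function(p) p[, 1]))
    ys <- unlist(lapply(cores$polygons, function(p) p[, 2]))
    ext <- c(
      xmin = min(xs) - buffer_m, ymin = min(ys) - buffer_m,
      xmax = max(xs) + buffer_m, ymax = max(ys) + buffer_m
    )
  }
  area <- 0
  segs <- boundary_segments(cores$polygons)
  # integrate per core over its padded bounding box to keep the grid small
  counted <- NULL
  gx_all <- c(); gy_all <- c()
  for (poly in cores$polygons) {
    xs <- seq(max(min(poly[, 1]) - buffer_m, ext["xmin"]) + cell_m / 2,
      min(max(poly[, 1]) + buffer_m, ext["xmax"]),
      by = cell_m
    )
    ys <- seq(max(min(poly[, 2]) - buffer_m, ext["ymin"]) + cell_m / 2,
      min(max(poly[, 2]) + buffer_m, ext["ymax"]),
      by = cell_m
    )
    gx_all <- c(gx_all, rep(xs, times = length(ys)))
    gy_all <- c(gy_all, rep(ys, each = length(xs)))
  }
  # de-duplicate cells claimed by overlapping bounding boxes
  key <- paste(round(gx_all / cell_m), round(gy_all / cell_m))
  keep <- !duplicated(key)
  gx <- gx_all[keep]; gy <- gy_all[keep]
  d <- min_dist_to_segments(gx, gy, segs)
  inside <- rep(FALSE, length(gx))
  for (poly in cores$polygons) inside <- inside | points_in_polygon(gx, gy, poly)
  in_ring <- !inside & d <= buffer_m
  sum(in_ring) * (cell_m / 1000)^2
}

#' Well density in buffer rings outside core-area boundaries
#'
#' Default `"ring"` mode counts the wells present in `year` that fall in the
#' region outside all cores and within `buffer_km` of a core boundary, divided
#' by that region's area in km2 - one pooled, area-weighted statewide value,
#' exactly as if each core's ring were measured and averaged with ring-area
#' weights. Ring membership uses the signed boundary distance, so the ring
#' never includes another core's interior; when buffer rings would intersect a
#' neighbouring core or spill past the extent, the exact perimeter-based area
#' is replaced by grid integration (with a warning).
#'
#' `"focal"` mode reproduces a raster moving-window workflow for parity with
#' GIS focal statistics: wells are binned to 1-km cells, each ring cell gets
#' the mean well density in a circular window of radius `buffer_km`, and the
#' ring cells are averaged.
#'
#' @param cores A [core_areas] object.
#' @param wells Tibble with `x, y, first_year, last_year`.
#' @param buffer_km Buffer distance in km (> 0).
#' @param year Wells are counted when `first_year <= year` and `last_year` is
#'   `NA` or `>= year`. Callers implementing the count-year lag pass
#'   `count_year - 1` (see [buffer_density_series()]).
#' @param mode `"ring"` (exact counting, default) or `"focal"`.
#' @param cell_km Cell size for focal mode.
#' @return Well density in wells/km2 (scalar).
#' @export
ring_density <- function(cores, wells, buffer_km, year,
                         mode = c("ring", "focal"), cell_km = 1) {
  mode <- match.arg(mode)
  stopifnot(buffer_km > 0)
  buffer_m <- buffer_km * 1000
  present <- wells[wells_present(wells, year), , drop = FALSE]
  if (mode == "focal") {
    return(focal_ring_density(cores, present, buffer_m, cell_km))
  }
  if (ring_assumptions_hold(cores, buffer_m)) {
    area_km2 <- ring_area_exact_km2(cores, buffer_m)
  } else {
    warn(paste(
      "Buffer rings touch a neighbouring core, a non-convex polygon or the",
      "extent edge; ring area computed by grid integration (clipped to",
      "exclude core interiors)."
    ))
    area_km2 <- ring_area_grid_km2(cores, buffer_m)
  }
  if (nrow(present) == 0L) return(0)
  d <- signed_boundary_distance(present, cores)
  in_ring <- d < 0 & -d <= buffer_m
  sum(in_ring) / area_km2
}

focal_ring_density <- function(cores, present, buffer_m, cell_km) {
  ext <- cores$extent
  if (is.null(ext)) {
    abort("Focal mode needs an extent on the core set.", class = "lekshed_config_error")
  }
  cell_m <- cell_km * 1000
  nx <- ceiling((ext["xmax"] - ext["xmin"]) / cell_m)
  ny <- ceiling((ext["ymax"] - ext["ymin"]) / cell_m)
  counts <- matrix(0L, nx, ny)
  if (nrow(present)) {
    ix <- pmin(nx, pmax(1, ceiling((present$x - ext["xmin"]) / cell_m)))
    iy <- pmin(ny, pmax(1, ceiling((present$y - ext["ymin"]) / cell_m)))
    tab <- table(factor(ix, levels = seq_len(nx)), factor(iy, levels = seq_len(ny)))
    counts <- matrix(as.integer(tab), nx, ny)
  }
  # ring cell centres
  cx <- ext["xmin"] + (seq_len(nx) - 0.5) * cell_m
  cy <- ext["ymin"] + (seq_len(ny) - 0.5) * cell_m
  gx <- rep(cx, times = ny)
  gy <- rep(cy, each = nx)
  d <- min_dist_to_segments(gx, gy, boundary_segments(cores$polygons))
  inside <- rep(FALSE, length(gx))
  for (poly in cores$polygons) inside <- inside | points_in_polygon(gx, gy, poly)
  ring_idx <- which(!inside & d <= buffer_m)
  if (length(ring_idx) == 0L) return(0)
  # circular window offsets
  r_cells <- floor(buffer_m / cell_m)
  off <- expand.grid(dx = -r_cells:r_cells, dy = -r_cells:r_cells)
  off <- off[(off$dx^2 + off$dy^2) * cell_m^2 <= buffer_m^2, , drop = FALSE]
  win_area_km2 <- nrow(off) * (cell_m / 1000)^2
  ring_ix <- ((ring_idx - 1L) %% nx) + 1L
  ring_iy <- ((ring_idx - 1L) %/% nx) + 1L
  vals <- numeric(length(ring_idx))
  for (k in seq_len(nrow(off))) {
    jx <- ring_ix + off$dx[k]
    jy <- ring_iy + off$dy[k]
    ok <- jx >= 1 & jx <= nx & jy >= 1 & jy <= ny
    vals[ok] <- vals[ok] + counts[cbind(jx[ok], jy[ok])]
  }
  mean(vals / win_area_km2)
}

#' Lagged buffer-ring well densities paired with count years
#'
#' For each count year `t` and buffer, computes [ring_density()] from the wells
#' present in year `t - 1`: only completed structures already on the landscape
#' could have affected the birds counted in year `t`.
#'
#' @param cores,wells As in [ring_density()].
#' @param count_years Lek count years to pair densities with.
#' @param buffers_km Buffer distances in km.
#' @param mode Passed to [ring_density()].
#' @return Tibble `count_year, buffer_km, density`.
#' @export
buffer_density_series <- function(cores, wells, count_years,
                                  buffers_km = c(1.61, 4.83), mode = "ring") {
  grid <- tidyr::expand_grid(count_year = sort(count_years), buffer_km = buffers_km)
  grid$density <- purrr::pmap_dbl(grid, function(count_year, buffer_km) {
    ring_density(cores, wells, buffer_km, count_year - 1L, mode = mode)
  })
  grid
}

#' Lagged well density inside core areas
#'
#' Control covariate: wells inside any core present in `count_year - 1` per km2
#' of total core area.
#'
#' @inheritParams buffer_density_series
#' @return Tibble `count_year, density`.
#' @export
inside_density_series <- function(cores, wells, count_years) {
  area <- core_area_km2(cores)
  d <- signed_boundary_distance(wells, cores)
  inside <- d >= 0
  tibble(count_year = sort(count_years)) %>%
    mutate(density = vapply(.data$count_year, function(yy) {
      sum(inside & wells_present(wells, yy - 1L)) / area
    }, numeric(1)))
}

#' Lagged outside-core well density adjacent to individual leks
#'
#' For each lek and count year `t`, the density (wells/km2) of wells located
#' outside all cores within `radius_km` of the lek and present in year `t - 1`.
#' This is the development-adjacency covariate that couples near-boundary core
#' leks to drilling just outside the boundary; leks deeper inside a core than
#' `radius_km` always get 0.
#'
#' @param leks Tibble with `lek_id, x, y`.
#' @param wells Tibble with `x, y, first_year, last_year`.
#' @param cores A [core_areas] object.
#' @param years Count years.
#' @param radius_km Adjacency radius in km.
#' @return Tibble `lek_id, year, density`.
#' @export
lek_adjacent_density <- function(leks, wells, cores, years, radius_km = 4.83) {
  radius_m <- radius_km * 1000
  area_km2 <- pi * radius_km^2
  d_w <- signed_boundary_distance(wells, cores)
  outside <- which(d_w < 0)
  wx <- wells$x[outside]
  wy <- wells$y[outside]
  wfirst <- wells$first_year[outside]
  wlast <- wells$last_year[outside]
  years <- sort(as.integer(years))

  res <- vector("list", ceiling(nrow(leks) / 200))
  chunk_id <- 0L
  for (start in seq(1L, nrow(leks), by = 200L)) {
    rows <- start:min(start + 199L, nrow(leks))
    chunk_id <- chunk_id + 1L
    dx <- outer(leks$x[rows], wx, `-`)
    dy <- outer(leks$y[rows], wy, `-`)
    within <- dx * dx + dy * dy <= radius_m^2
    per_lek <- lapply(seq_along(rows), function(i) {
      idx <- which(within[i, ])
      counts <- vapply(years, function(yy) {
        py <- yy - 1L
        sum(wfirst[idx] <= py & (is.na(wlast[idx]) | wlast[idx] >= py))
      }, numeric(1))
      tibble(
        lek_id = leks$lek_id[rows[i]], year = years,
        density = counts / area_km2
      )
    })
    res[[chunk_id]] <- bind_rows(per_lek)
  }
  bind_rows(res)
}
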