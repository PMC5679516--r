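#' Generate disjoint core-area polygons covering a target fraction of the extent
#'
#' Places `n_cores` axis-aligned rectangular core polygons of log-normally
#' varied size and aspect inside the study extent, respecting a minimum gap
#' between cores and a margin to the extent edge. Rectangle areas are scaled so
#' their union covers exactly `core_area_fraction` of the extent, so the target
#' is met within any tolerance by construction. Convex, well-separated cores
#' keep the outside buffer-ring geometry exact (see [ring_density()]).
#'
#' @param cfg A [landscape_config()].
#' @return A [core_areas] object.
#' @details Placement is rejection sampling with restarts; an infeasible
#'   combination (fraction too high for disjoint placement at the configured
#'   gap and margin) raises a configuration error rather than returning
#'   overlapping cores.
#' @export
generate_core_areas <- function(cfg) {
  stopifnot(inherits(cfg, "landscape_config"))
  ext <- cfg$extent
  target_m2 <- cfg$core_area_fraction * extent_area_km2(ext) * 1e6
  with_seed(substream_seed(cfg$seed, "cores"), {
    for (restart in seq_len(25L)) {
      w_raw <- rlnorm(cfg$n_cores, meanlog = 0, sdlog = 0.45)
      areas <- target_m2 * w_raw / sum(w_raw)
      aspect <- runif(cfg$n_cores, 0.6, 1.7)
      widths <- sqrt(areas * aspect)
      heights <- areas / widths
      # place large rectangles first; they are the hardest to fit
      ord <- order(areas, decreasing = TRUE)
      placed <- matrix(NA_real_, cfg$n_cores, 4,
        dimnames = list(NULL, c("xmin", "ymin", "xmax", "ymax"))
      )
      ok <- TRUE
      for (idx in seq_along(ord)) {
        i <- ord[idx]
        w <- widths[i]; h <- heights[i]
        lox <- ext["xmin"] + cfg$core_margin_m
        hix <- ext["xmax"] - cfg$core_margin_m - w
        loy <- ext["ymin"] + cfg$core_margin_m
        hiy <- ext["ymax"] - cfg$core_margin_m - h
        if (hix <= lox || hiy <= loy) { ok <- FALSE; break }
        hit <- FALSE
        for (try in seq_len(400L)) {
          x0 <- runif(1, lox, hix); y0 <- runif(1, loy, hiy)
          cand <- c(x0, y0, x0 + w, y0 + h)
          prev <- placed[!is.na(placed[, 1]), , drop = FALSE]
          if (nrow(prev) == 0 || all(
            cand[1] - prev[, 3] > cfg$core_gap_m | prev[, 1] - cand[3] > cfg$core_gap_m |
              cand[2] - prev[, 4] > cfg$core_gap_m | prev[, 2] - cand[4] > cfg$core_gap_m
          )) {
            placed[i, ] <- cand
            hit <- TRUE
            break
          }
        }
        if (!hit) { ok <- FALSE; break }
      }
      if (ok) {
        polys <- lapply(seq_len(cfg$n_cores), function(i) {
          r <- placed[i, ]
          rbind(
            c(r["xmin"], r["ymin"]), c(r["xmax"], r["ymin"]),
            c(r["xmax"], r["ymax"]), c(r["xmin"], r["ymax"])
          )
        })
        return(core_areas(polys, extent = ext))
      }
    }
  })
  abort(paste(
    "Could not place", cfg$n_cores, "disjoint cores covering",
    sprintf("%.0f%%", 100 * cfg$core_area_fraction),
    "of the extent at the configured gap/margin; reduce the fraction,",
    "the number of cores, or the separation constraints."
  ), class = "lekshed_config_error")
}

# Uniform points inside the union of (disjoint) core polygons: pick a polygon
# with probability proportional to its area, then sample its bounding box with
# rejection (exact for the rectangles generated here).
sample_in_cores <- function(n, cores) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  areas <- vapply(cores$polygons, polygon_area_m2, numeric(1))
  pick <- sample.int(length(areas), n, replace = TRUE, prob = areas)
  out <- matrix(NA_real_, n, 2)
  for (k in unique(pick)) {
    poly <- cores$polygons[[k]]
    rows <- which(pick == k)
    m <- length(rows)
    pts <- matrix(NA_real_, m, 2)
    need <- seq_len(m)
    while (length(need)) {
      cx <- runif(length(need), min(poly[, 1]), max(poly[, 1]))
      cy <- runif(length(need), min(poly[, 2]), max(poly[, 2]))
      keep <- points_in_polygon(cx, cy, poly)
      pts[need[keep], ] <- cbind(cx[keep], cy[keep])
      need <- need[!keep]
    }
    out[rows, ] <- pts
  }
  colnames(out) <- c("x", "y")
  out
}

sample_outside_cores <- function(n, cores, ext) {
  out <- matrix(NA_real_, n, 2)
  need <- n
  filled <- 0L
  while (need > 0L) {
    m <- max(need * 2L, 100L)
    cx <- runif(m, ext["xmin"], ext["xmax"])
    cy <- runif(m, ext["ymin"], ext["ymax"])
    inside <- rep(FALSE, m)
    for (poly in cores$polygons) inside <- inside | points_in_polygon(cx, cy, poly)
    keep <- which(!inside)
    take <- head(keep, need)
    if (length(take)) {
      out[filled + seq_along(take), ] <- cbind(cx[take], cy[take])
      filled <- filled + length(take)
      need <- need - length(take)
    }
  }
  colnames(out) <- c("x", "y")
  out
}

#' Generate lek and well point patterns on a core-area landscape
#'
#' Leks are split between core and non-core ground by independent Bernoulli
#' draws with probability `core_lek_fraction` and placed uniformly within their
#' stratum. Wells are placed in three layers: a thin uniform scatter inside
#' cores at `inside_well_intensity` (never above the regulatory cap), clustered
#' drilling "fields" outside cores whose peak density approaches
#' `outside_well_density_max`, and a diffuse outside background. Field discs
#' are centred outside cores but may abut core boundaries, so wells rejected
#' from core interiors accumulate just outside the boundary - the landscape
#' feature that drives the edge-effect analysis. Each well carries the first
#' year a structure is present and (for the few removed structures) a last
#' year; first years span the study period so lagged densities grow over time.
#'
#' @param cfg A [landscape_config()].
#' @param cores The [core_areas] generated from the same config.
#' @return A list with tibbles `leks` (`lek_id, x, y`) and
#'   `wells` (`well_id, x, y, first_year, last_year`; `last_year` is `NA` for
#'   structures still standing at the end of the study).
#' @export
generate_points <- function(cfg, cores) {
  stopifnot(inherits(cfg, "landscape_config"), inherits(cores, "core_areas"))
  ext <- cfg$extent
  with_seed(substream_seed(cfg$seed, "points"), {
    ## --- leks ---
    n_core_leks <- rbinom(1, cfg$n_leks, cfg$core_lek_fraction)
    in_pts <- sample_in_cores(n_core_leks, cores)
    out_pts <- sample_outside_cores(cfg$n_leks - n_core_leks, cores, ext)
    leks <- tibble(
      lek_id = sprintf("lek_%04d", seq_len(cfg$n_leks)),
      x = c(in_pts[, "x"], out_pts[, "x"]),
      y = c(in_pts[, "y"], out_pts[, "y"])
    )

    ## --- wells inside cores (capped) ---
    core_km2 <- core_area_km2(cores)
    n_inside <- min(
      floor(cfg$inside_well_intensity * core_km2),
      floor(cfg$inside_well_density_cap * core_km2),
      cfg$n_wells
    )
    inside_xy <- sample_in_cores(n_inside, cores)

    ## --- wells outside cores: clustered fields + background ---
    n_outside <- cfg$n_wells - n_inside
    n_fields <- min(cfg$n_well_fields, max(0L, n_outside))
    field_xy <- matrix(numeric(0), 0, 2)
    if (n_fields > 0L && n_outside > 0L) {
      centers <- sample_outside_cores(n_fields, cores, ext)
      radii_m <- runif(n_fields, cfg$field_radius_km[1], cfg$field_radius_km[2]) * 1000
      # geometric decay from the hottest field toward background intensity
      peak <- 0.9 * cfg$outside_well_density_max
      dens <- peak * 0.65^(seq_len(n_fields) - 1)
      quota <- round(dens * pi * (radii_m / 1000)^2)
      budget <- round(cfg$field_well_share * n_outside)
      if (sum(quota) > budget) quota <- floor(quota * budget / sum(quota))
      pts <- vector("list", n_fields)
      for (f in seq_len(n_fields)) {
        m <- quota[f]
        if (m == 0L) { pts[[f]] <- matrix(numeric(0), 0, 2); next }
        got <- matrix(NA_real_, m, 2)
        need <- m
        filled <- 0L
        guard <- 0L
        while (need > 0L && guard < 200L) {
          guard <- guard + 1L
          k <- max(need * 2L, 50L)
          r <- radii_m[f] * sqrt(runif(k))
          th <- runif(k, 0, 2 * pi)
          cx <- centers[f, "x"] + r * cos(th)
          cy <- centers[f, "y"] + r * sin(th)
          okx <- cx > ext["xmin"] & cx < ext["xmax"] & cy > ext["ymin"] & cy < ext["ymax"]
          inside <- rep(FALSE, k)
          for (poly in cores$polygons) inside <- inside | points_in_polygon(cx, cy, poly)
          keep <- which(okx & !inside)
          take <- head(keep, need)
          if (length(take)) {
            got[filled + seq_along(take), ] <- cbind(cx[take], cy[take])
            filled <- filled + length(take)
            need <- need - length(take)
          }
        }
        pts[[f]] <- got[seq_len(filled), , drop = FALSE]
      }
      field_xy <- do.call(rbind, pts)
    }
    n_bg <- n_outside - nrow(field_xy)
    bg_xy <- sample_outside_cores(n_bg, cores, ext)
    colnames(field_xy) <- c("x", "y")

    well_xy <- rbind(inside_xy, field_xy, bg_xy)
    n_w <- nrow(well_xy)

    ## --- structure-present years ---
    yr0 <- min(cfg$years); yr1 <- max(cfg$years)
    pre <- runif(n_w) < cfg$pre_study_well_share
    first_year <- integer(n_w)
    first_year[pre] <- sample(seq(yr0 - 50L, yr0 - 1L), sum(pre), replace = TRUE)
    # drilling intensifies over the study period: linearly increasing weights
    study_years <- seq(yr0, yr1)
    wts <- seq_along(study_years)
    first_year[!pre] <- sample(study_years, sum(!pre), replace = TRUE, prob = wts)
    removed <- runif(n_w) < cfg$well_removal_rate
    last_year <- rep(NA_integer_, n_w)
    if (any(removed)) {
      last_year[removed] <- vapply(first_year[removed], function(fy) {
        lo <- max(fy, yr0)
        lo + sample.int(yr1 - lo + 1L, 1L) - 1L
      }, integer(1))
    }

    wells <- tibble(
      well_id = sprintf("well_%05d", seq_len(n_w)),
      x = well_xy[, "x"], y = well_xy[, "y"],
      first_year = first_year, last_year = last_year
    )
  })
  list(leks = leks, wells = wells)
}

#' Generate a complete synthetic landscape
#'
#' Convenience wrapper running [generate_core_areas()], [generate_points()] and
#' [simulate_counts()] from one pair of configs.
#'
#' @param cfg A [landscape_config()].
#' @param dyn An [attendance_dynamics()].
#' @return A list with `cores`, `leks`, `wells` and the long count tibble
#'   `counts` (`lek_id, year, males`; unsurveyed lek-years are absent).
#' @export
simulate_landscape <- function(cfg, dyn = attendance_dynamics()) {
  cores <- generate_core_areas(cfg)
  pts <- generate_points(cfg, cores)
  counts <- simulate_counts(pts$leks, pts$wells, cores, dyn,
    years = cfg$years, seed = substream_seed(cfg$seed, "counts")
  )
  list(cores = cores, leks = pts$leks, wells = pts$wells, counts = counts)
}
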