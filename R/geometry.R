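# Planar polygon helpers for core-area geometry. Polygons are Nx2 matrices of
# vertices in projected meters, implicitly closed (last vertex joins the first),
# counter-clockwise. All computations are exact planar Euclidean geometry.

polygon_area_m2 <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  xs <- c(x[-1], x[1]); ys <- c(y[-1], y[1])
  abs(sum(x * ys - xs * y)) / 2
}

polygon_perimeter_m <- function(poly) {
  xs <- c(poly[-1, 1], poly[1, 1]); ys <- c(poly[-1, 2], poly[1, 2])
  sum(sqrt((xs - poly[, 1])^2 + (ys - poly[, 2])^2))
}

polygon_is_convex <- function(poly, tol = 1e-9) {
  n <- nrow(poly)
  if (n < 3) return(FALSE)
  i <- seq_len(n)
  j <- c(2:n, 1L)
  k <- c(3:n, 1L, 2L)
  cr <- (poly[j, 1] - poly[i, 1]) * (poly[k, 2] - poly[j, 2]) -
    (poly[j, 2] - poly[i, 2]) * (poly[k, 1] - poly[j, 1])
  all(cr >= -tol) || all(cr <= tol)
}

# Even-odd rule, vectorized over points; points exactly on an edge are handled
# by callers via the boundary-distance test.
points_in_polygon <- function(px, py, poly) {
  vx <- poly[, 1]; vy <- poly[, 2]
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > py) != (vy[j] > py)) &
      (px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

# Segment list (x1, y1, x2, y2) for all polygon edges in a core set.
boundary_segments <- function(polygons) {
  segs <- lapply(polygons, function(p) {
    cbind(p[, 1], p[, 2], c(p[-1, 1], p[1, 1]), c(p[-1, 2], p[1, 2]))
  })
  do.call(rbind, segs)
}

# Minimum distance from each point to any segment in `segs`.
min_dist_to_segments <- function(px, py, segs) {
  best <- rep(Inf, length(px))
  for (s in seq_len(nrow(segs))) {
    x1 <- segs[s, 1]; y1 <- segs[s, 2]; x2 <- segs[s, 3]; y2 <- segs[s, 4]
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx * dx + dy * dy
    if (len2 == 0) {
      d2 <- (px - x1)^2 + (py - y1)^2
    } else {
      t <- pmin(1, pmax(0, ((px - x1) * dx + (py - y1) * dy) / len2))
      d2 <- (px - (x1 + t * dx))^2 + (py - (y1 + t * dy))^2
    }
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Signed distance from points to the nearest core-area boundary
#'
#' Computes, for each point, the Euclidean distance in meters to the nearest
#' boundary segment of any core polygon, signed positive for points inside a
#' core and negative for points outside all cores. Points exactly on a boundary
#' get distance 0 and count as inside (the protective designation is read
#' inclusively).
#'
#' @param points A data frame with numeric `x` and `y` columns (projected
#'   meters), or a two-column matrix.
#' @param cores A [core_areas] object (see [generate_core_areas()] or
#'   [read_cores_geojson()]).
#'
#' @return A numeric vector of signed distances (meters), one per point.
#' @examples
#' sq <- core_areas(list(rbind(c(0, 0), c(10000, 0), c(10000, 10000), c(0, 10000))))
#' signed_boundary_distance(data.frame(x = 5000, y = 5000), sq)  # +5000
#' signed_boundary_distance(data.frame(x = -2000, y = 5000), sq) # -2000
#' @export
signed_boundary_distance <- function(points, cores) {
  stopifnot(inherits(cores, "core_areas"))
  if (length(cores$polygons) == 0L) {
    abort("Empty core-area set.", class = "lekshed_config_error")
  }
  if (is.matrix(points)) points <- data.frame(x = points[, 1], y = points[, 2])
  px <- as.double(points$x); py <- as.double(points$y)
  d <- min_dist_to_segments(px, py, boundary_segments(cores$polygons))
  inside <- rep(FALSE, length(px))
  for (poly in cores$polygons) {
    inside <- inside | points_in_polygon(px, py, poly)
  }
  inside <- inside | d < 1e-9 # boundary points count as inside
  ifelse(inside, d, -d)
}

#' Core-area polygon set
#'
#' Light container for a set of simple, non-overlapping polygons delimiting
#' protected core areas, tagged with the study extent and a projected CRS.
#'
#' @param polygons List of Nx2 numeric matrices (vertices in projected meters,
#'   implicitly closed).
#' @param ids Character ids, one per polygon.
#' @param extent Optional named extent `c(xmin, ymin, xmax, ymax)`.
#' @param crs CRS tag recorded on output (informational; all geometry here is
#'   planar in meters).
#'
#' @return An object of class `core_areas`.
#' @export
core_areas <- function(polygons, ids = NULL, extent = NULL, crs = "EPSG:32613") {
  polygons <- lapply(polygons, function(p) {
    p <- as.matrix(p)
    storage.mode(p) <- "double"
    dimnames(p) <- NULL
    if (nrow(p) >= 2 && all(p[1, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
    if (nrow(p) < 3) abort("Each polygon needs at least 3 vertices.",
      class = "lekshed_config_error"
    )
    p
  })
  ids <- ids %||% sprintf("core_%02d", seq_along(polygons))
  structure(
    list(polygons = polygons, ids = as.character(ids), extent = extent, crs = crs),
    class = "core_areas"
  )
}

#' @export
print.core_areas <- function(x, ...) {
  cat(sprintf(
    "<core_areas> %d polygons, total area %.1f km2 (%s)\n",
    length(x$polygons), core_area_km2(x), x$crs
  ))
  invisible(x)
}

#' Total area of a core-area set in km2
#' @param cores A [core_areas] object.
#' @return Numeric scalar (km2).
#' @export
core_area_km2 <- function(cores) {
  sum(vapply(cores$polygons, polygon_area_m2, numeric(1))) / 1e6
}

core_perimeter_km <- function(cores) {
  sum(vapply(cores$polygons, polygon_perimeter_m, numeric(1))) / 1000
}

# Minimum gap between the boundaries of any two polygons in the set
# (exact for the convex polygons generated here: vertex-to-segment distance).
min_core_gap_m <- function(cores) {
  polys <- cores$polygons
  if (length(polys) < 2) return(Inf)
  gap <- Inf
  for (i in seq_along(polys)) {
    for (j in seq_along(polys)) {
      if (i == j) next
      segs <- boundary_segments(polys[j])
      gap <- min(gap, min(min_dist_to_segments(polys[[i]][, 1], polys[[i]][, 2], segs)))
    }
  }
  gap
}

# Minimum distance from any polygon vertex to the extent edge.
min_extent_inset_m <- function(cores) {
  ext <- cores$extent
  if (is.null(ext)) return(NA_real_)
  inset <- Inf
  for (p in cores$polygons) {
    inset <- min(
      inset,
      min(p[, 1] - ext["xmin"]), min(ext["xmax"] - p[, 1]),
      min(p[, 2] - ext["ymin"]), min(ext["ymax"] - p[, 2])
    )
  }
  unname(inset)
}
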