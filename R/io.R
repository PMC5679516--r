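#' Read and write lek count tables
#'
#' On disk, leks are a wide CSV: `lek_id, x, y` followed by one column per
#' survey year (blank cells are unsurveyed lek-years). In memory the package
#' works with the long tidy form `lek_id, x, y` + `lek_id, year, males`.
#'
#' @param counts Long tibble `lek_id, year, males`.
#' @param leks Tibble `lek_id, x, y`.
#' @param path CSV path.
#' @return `read_leks_csv()` returns a list with `leks` (coordinates) and
#'   `counts` (long form); the writer returns `path` invisibly.
#' @export
write_leks_csv <- function(leks, counts, path) {
  wide <- counts %>%
    mutate(year = as.character(.data$year)) %>%
    tidyr::pivot_wider(names_from = "year", values_from = "males", names_sort = TRUE)
  out <- left_join(leks, wide, by = "lek_id")
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' @rdname write_leks_csv
#' @export
read_leks_csv <- function(path) {
  wide <- readr::read_csv(path, show_col_types = FALSE)
  year_cols <- grep("^[0-9]{4}$", names(wide), value = TRUE)
  counts <- wide %>%
    select("lek_id", dplyr::all_of(year_cols)) %>%
    tidyr::pivot_longer(dplyr::all_of(year_cols),
      names_to = "year", values_to = "males"
    ) %>%
    filter(!is.na(.data$males)) %>%
    mutate(year = as.integer(.data$year), males = as.integer(.data$males)) %>%
    arrange(.data$lek_id, .data$year)
  list(leks = wide %>% select("lek_id", "x", "y"), counts = counts)
}

#' Read and write well record tables
#'
#' Wells are a CSV with columns `well_id, x, y, first_year, last_year`; a blank
#' `last_year` means the structure is still present (open-ended record).
#'
#' @param wells Tibble `well_id, x, y, first_year, last_year`.
#' @param path CSV path.
#' @return The reader returns the wells tibble; the writer returns `path`
#'   invisibly.
#' @export
write_wells_csv <- function(wells, path) {
  readr::write_csv(wells, path, na = "")
  invisible(path)
}

#' @rdname write_wells_csv
#' @export
read_wells_csv <- function(path) {
  wells <- readr::read_csv(path, show_col_types = FALSE,
    col_types = readr::cols(
      well_id = readr::col_character(), x = readr::col_double(),
      y = readr::col_double(), first_year = readr::col_integer(),
      last_year = readr::col_integer()
    )
  )
  closed <- !is.na(wells$last_year)
  if (any(wells$first_year[closed] > wells$last_year[closed])) {
    abort("Well records with first_year > last_year.", class = "lekshed_data_error")
  }
  wells
}

#' Read and write core-area polygons as GeoJSON
#'
#' Cores are stored as a GeoJSON FeatureCollection of Polygons in a projected
#' CRS (meters); the CRS tag and, when available, the study extent are recorded
#' as foreign members of the collection.
#'
#' @param cores A [core_areas] object.
#' @param path GeoJSON path.
#' @return The reader returns a [core_areas]; the writer returns `path`
#'   invisibly.
#' @export
write_cores_geojson <- function(cores, path) {
  features <- purrr::map2(cores$polygons, cores$ids, function(poly, id) {
    ring <- rbind(poly, poly[1, , drop = FALSE])
    list(
      type = "Feature",
      properties = list(id = id),
      geometry = list(
        type = "Polygon",
        coordinates = list(lapply(seq_len(nrow(ring)), function(i) unname(ring[i, ])))
      )
    )
  })
  fc <- list(
    type = "FeatureCollection",
    crs = cores$crs,
    extent = if (!is.null(cores$extent)) as.list(cores$extent),
    features = features
  )
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_cores_geojson
#' @export
read_cores_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    abort("Not a GeoJSON FeatureCollection.", class = "lekshed_data_error")
  }
  polys <- lapply(fc$features, function(f) {
    ring <- f$geometry$coordinates[[1]]
    do.call(rbind, lapply(ring, function(v) as.double(unlist(v))))
  })
  ids <- vapply(
    seq_along(fc$features),
    function(i) as.character(fc$features[[i]]$properties$id %||% sprintf("core_%02d", i)),
    character(1)
  )
  extent <- if (!is.null(fc$extent)) {
    ext <- unlist(fc$extent)
    ext[c("xmin", "ymin", "xmax", "ymax")]
  }
  core_areas(polys, ids = ids, extent = extent, crs = fc$crs %||% "unknown")
}

#' Write a full synthetic landscape to a directory
#'
#' Writes `leks.csv` (wide counts), `wells.csv` and `cores.geojson` plus a
#' `config.yaml` echo of the generator settings.
#'
#' @param landscape Output of [simulate_landscape()].
#' @param dir Output directory (created if needed).
#' @param cfg Optional [landscape_config()] to echo into `config.yaml`.
#' @return `dir`, invisibly.
#' @export
write_landscape <- function(landscape, dir, cfg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_leks_csv(landscape$leks, landscape$counts, file.path(dir, "leks.csv"))
  write_wells_csv(landscape$wells, file.path(dir, "wells.csv"))
  write_cores_geojson(landscape$cores, file.path(dir, "cores.geojson"))
  if (!is.null(cfg)) {
    cfg_list <- unclass(cfg)
    cfg_list$extent <- as.list(cfg_list$extent)
    yaml::write_yaml(cfg_list, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}
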