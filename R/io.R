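# Reading and writing the external formats the pipeline touches:
# Movebank-dialect fix CSVs, GeoJSON region polygons, stopover and
# milestone CSVs, and fit summaries as JSON.

MOVEBANK_COLS <- c("individual-local-identifier", "timestamp",
                   "location-lat", "location-long")

#' Read satellite fixes from a Movebank-dialect CSV
#'
#' Expects columns `individual-local-identifier`, `timestamp` (ISO 8601,
#' interpreted as UTC), `location-lat`, `location-long` and optionally
#' `argos-lc` (Argos location class). Rows are sorted by (bird, time) and
#' duplicate (bird, timestamp) rows collapsed keeping the best quality class.
#'
#' @param path Path to the CSV file.
#' @param lc_ranking Character vector of quality classes from best to worst;
#'   classes not listed rank after listed ones.
#' @return A tibble of fixes with columns `bird_id`, `t` (POSIXct UTC),
#'   `lat`, `lon`, `lc`.
#' @export
read_fixes <- function(path, lc_ranking = c("3", "2", "1", "0", "A", "B", "Z")) {
  if (!file.exists(path)) stop("fix file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing <- setdiff(MOVEBANK_COLS, names(raw))
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(raw) == 0) {
    return(tibble::tibble(bird_id = character(), t = as.POSIXct(character(), tz = "UTC"),
                          lat = double(), lon = double(), lc = character()))
  }
  ts <- raw[["timestamp"]]
  t <- as.POSIXct(rep(NA_character_, length(ts)), tz = "UTC")
  for (fmt in c("%Y-%m-%d %H:%M:%OS", "%Y-%m-%dT%H:%M:%OS",
                "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    idx <- which(is.na(t))
    if (length(idx) == 0) break
    t[idx] <- as.POSIXct(strptime(ts[idx], fmt, tz = "UTC"))
  }
  bad <- which(is.na(t))
  if (length(bad) > 0) {
    stop("unparseable timestamp at data row(s): ",
         paste(utils::head(bad, 5), collapse = ", "),
         " (value '", raw[["timestamp"]][bad[1]], "')", call. = FALSE)
  }
  fx <- tibble::tibble(
    bird_id = raw[["individual-local-identifier"]],
    t = t,
    lat = as.numeric(raw[["location-lat"]]),
    lon = as.numeric(raw[["location-long"]]),
    lc = if ("argos-lc" %in% names(raw)) raw[["argos-lc"]] else NA_character_
  )
  if (any(!is.finite(fx$lat)) || any(!is.finite(fx$lon))) {
    stop("non-finite coordinates in ", path)
  }
  if (any(abs(fx$lat) > 90) || any(abs(fx$lon) > 180)) {
    stop("coordinates outside WGS84 bounds in ", path)
  }
  fx |>
    dplyr::mutate(.lc_rank = lc_rank(.data$lc, lc_ranking)) |>
    dplyr::arrange(.data$bird_id, .data$t, .data$.lc_rank) |>
    dplyr::distinct(.data$bird_id, .data$t, .keep_all = TRUE) |>
    dplyr::select(-".lc_rank")
}

# Lower rank = better quality class; unknown classes rank after known ones.
lc_rank <- function(lc, ranking = c("3", "2", "1", "0", "A", "B", "Z")) {
  r <- match(lc, ranking)
  r[is.na(r)] <- length(ranking) + 1L
  r
}

#' Write fixes as a Movebank-dialect CSV
#'
#' Coordinates are written at 6 decimal places and timestamps at 1-second
#' precision, so a write/read round trip is lossless at that precision.
#'
#' @param fixes Tibble with columns `bird_id`, `t`, `lat`, `lon`, `lc`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixes <- function(fixes, path) {
  out <- data.frame(
    `individual-local-identifier` = fixes$bird_id,
    timestamp = format(fixes$t, "%Y-%m-%d %H:%M:%S", tz = "UTC"),
    `location-lat` = sprintf("%.6f", fixes$lat),
    `location-long` = sprintf("%.6f", fixes$lon),
    `argos-lc` = if (is.null(fixes$lc)) NA_character_ else fixes$lc,
    check.names = FALSE
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a named region set from GeoJSON
#'
#' Reads an RFC 7946 FeatureCollection of polygons. Every feature must carry
#' a `name` property; names must be unique. Only the outer ring of each
#' (multi)polygon is used.
#'
#' @param path Path to a GeoJSON file. The package ships a synthetic
#'   simplified region set at
#'   `system.file("extdata", "regions_synthetic.geojson", package = "migrapath")`.
#' @return A named list of polygon matrices (columns `lon`, `lat`), of class
#'   `region_set`.
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop("regions file not found: ", path)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection")
  }
  regions <- list()
  for (feat in gj$features) {
    nm <- feat$properties$name
    if (is.null(nm)) stop("GeoJSON feature without a 'name' property")
    if (nm %in% names(regions)) stop("duplicate region name: ", nm)
    geom <- feat$geometry
    ring <- switch(geom$type,
      Polygon = geom$coordinates[[1]],
      MultiPolygon = geom$coordinates[[1]][[1]],
      stop("unsupported geometry type: ", geom$type))
    coords <- do.call(rbind, lapply(ring, function(p) c(lon = p[[1]], lat = p[[2]])))
    regions[[nm]] <- coords
  }
  structure(regions, class = "region_set")
}

#' Test whether points fall inside a region polygon
#'
#' Even-odd ray casting on lon/lat with boundary-inclusive convention
#' (points on a polygon edge or vertex count as inside) and longitude
#' unwrapping so polygons near the antimeridian are handled.
#'
#' @param lat,lon Point coordinates, degrees (vectorised).
#' @param region A polygon matrix (columns lon, lat) or an element of a
#'   [read_regions()] set.
#' @return Logical vector.
#' @export
point_in_region <- function(lat, lon, region) {
  poly_lon <- unwrap_lon(region[, "lon"])
  poly_lat <- region[, "lat"]
  ctr <- mean(range(poly_lon))
  lon <- lon + 360 * round((ctr - lon) / 360)
  vapply(seq_along(lat), function(i) {
    pip_one(lat[i], lon[i], poly_lat, poly_lon)
  }, logical(1))
}

# Unwrap a ring's longitudes so consecutive vertices differ by < 180 deg.
unwrap_lon <- function(lon) {
  out <- lon
  for (i in seq_along(lon)[-1]) {
    d <- out[i] - out[i - 1]
    if (d > 180) out[i:length(out)] <- out[i:length(out)] - 360
    else if (d < -180) out[i:length(out)] <- out[i:length(out)] + 360
  }
  out
}

pip_one <- function(py, px, ring_lat, ring_lon, eps = 1e-9) {
  n <- length(ring_lat)
  # drop an explicitly closed last vertex
  if (ring_lat[1] == ring_lat[n] && ring_lon[1] == ring_lon[n]) n <- n - 1
  inside <- FALSE
  j <- n
  for (i in seq_len(n)) {
    xi <- ring_lon[i]; yi <- ring_lat[i]
    xj <- ring_lon[j]; yj <- ring_lat[j]
    # boundary test: point within eps of segment i-j
    if (on_segment(px, py, xi, yi, xj, yj, eps)) return(TRUE)
    if ((yi > py) != (yj > py)) {
      xcross <- xi + (py - yi) / (yj - yi) * (xj - xi)
      if (px < xcross) inside <- !inside
    }
    j <- i
  }
  inside
}

on_segment <- function(px, py, x1, y1, x2, y2, eps) {
  dx <- x2 - x1; dy <- y2 - y1
  len2 <- dx * dx + dy * dy
  if (len2 < eps) {
    return(abs(px - x1) < eps && abs(py - y1) < eps)
  }
  t <- ((px - x1) * dx + (py - y1) * dy) / len2
  if (t < -eps || t > 1 + eps) return(FALSE)
  qx <- x1 + t * dx; qy <- y1 + t * dy
  abs(px - qx) < eps && abs(py - qy) < eps
}

#' Path to the packaged synthetic region set
#' @return File path of the GeoJSON shipped with the package.
#' @export
default_regions_path <- function() {
  system.file("extdata", "regions_synthetic.geojson", package = "migrapath")
}

#' @rdname read_regions
#' @export
default_regions <- function() read_regions(default_regions_path())
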