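# File formats: observation and transect-layout CSVs, GeoJSON feature
# layers (plain JSON, parsed with jsonlite), YAML/JSON run configuration.

.OBS_REQUIRED <- c("transect_id", "visit", "year", "distance_m", "habitat")

#' Read a nest observation table
#'
#' Required columns: `transect_id`, `visit`, `year`, `distance_m`,
#' `habitat`; optional `x_utm`, `y_utm` (planar m) and `is_new` (0/1 marked
#' nest count flag).  Schema violations report the file, row and column.
#'
#' @param path CSV file path.
#' @return A data.frame.
#' @export
read_observations <- function(path) {
  if (!file.exists(path)) .stop_schema("observation file not found", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) .stop_schema("no observations", path)
  miss <- setdiff(.OBS_REQUIRED, names(df))
  if (length(miss))
    .stop_schema(sprintf("missing column(s): %s", paste(miss, collapse = ", ")), path)
  bad <- which(!is.finite(df$distance_m) | df$distance_m < 0)
  if (length(bad))
    .stop_schema(sprintf("invalid distance_m at row %d", bad[1L]), path)
  if ("is_new" %in% names(df)) {
    bad <- which(!df$is_new %in% c(0L, 1L))
    if (length(bad))
      .stop_schema(sprintf("is_new must be 0/1 (row %d)", bad[1L]), path)
  }
  df
}

#' Read a transect layout table
#'
#' Columns: `transect_id`, `length_km`, then one column per habitat giving
#' the length (km) of that habitat along the transect.  Habitat lengths must
#' sum to `length_km` within 1e-6.
#'
#' @param path CSV file path.
#' @return A data.frame; habitat columns are `attr(,"habitats")`.
#' @export
read_transects <- function(path) {
  if (!file.exists(path)) .stop_schema("transect file not found", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) .stop_schema("no transects", path)
  miss <- setdiff(c("transect_id", "length_km"), names(df))
  if (length(miss))
    .stop_schema(sprintf("missing column(s): %s", paste(miss, collapse = ", ")), path)
  habs <- setdiff(names(df), c("transect_id", "length_km"))
  if (length(habs)) {
    tot <- rowSums(df[, habs, drop = FALSE])
    bad <- which(abs(tot - df$length_km) > 1e-6)
    if (length(bad))
      .stop_schema(sprintf("habitat lengths do not sum to length_km (row %d, column(s) %s)",
                           bad[1L], paste(habs, collapse = "/")), path)
  }
  if (any(df$length_km <= 0)) .stop_schema("length_km must be > 0", path)
  attr(df, "habitats") <- habs
  df
}

# per-habitat one-pass effort (km) from a layout table
.effort_by_habitat <- function(layout) {
  habs <- attr(layout, "habitats")
  if (is.null(habs)) habs <- setdiff(names(layout), c("transect_id", "length_km"))
  vapply(habs, function(h) sum(layout[[h]]), numeric(1))
}

#' Read a GeoJSON feature layer
#'
#' Supports Point, MultiPoint, LineString, MultiLineString, Polygon and
#' MultiPolygon geometries in planar (projected, m) coordinates.  Polygon
#' interiors count as distance zero; only exterior rings are used.
#'
#' @param path GeoJSON file path.
#' @param kind Layer kind (`"road"`, `"river"`, `"settlement"`); default
#'   guessed from the file name, falling back to `"road"`.
#' @return A [landscape_layer()].
#' @export
read_landscape_layer <- function(path, kind = NULL) {
  if (!file.exists(path)) .stop_schema("layer file not found", path)
  if (is.null(kind)) {
    nm <- tolower(basename(path))
    kind <- if (grepl("river", nm)) "river"
    else if (grepl("settle", nm)) "settlement" else "road"
  }
  gj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
  else if (identical(gj$type, "Feature")) list(gj)
  else list(list(geometry = gj))
  geoms <- list()
  add_coords <- function(cc) matrix(unlist(cc), ncol = 2L, byrow = TRUE)
  for (f in feats) {
    g <- f$geometry
    if (is.null(g)) next
    switch(g$type,
      Point = { geoms[[length(geoms) + 1L]] <- matrix(unlist(g$coordinates), 1L) },
      MultiPoint = for (c1 in g$coordinates)
        geoms[[length(geoms) + 1L]] <- matrix(unlist(c1), 1L),
      LineString = { geoms[[length(geoms) + 1L]] <- add_coords(g$coordinates) },
      MultiLineString = for (c1 in g$coordinates)
        geoms[[length(geoms) + 1L]] <- add_coords(c1),
      Polygon = { geoms[[length(geoms) + 1L]] <- list(polygon = add_coords(g$coordinates[[1L]])) },
      MultiPolygon = for (c1 in g$coordinates)
        geoms[[length(geoms) + 1L]] <- list(polygon = add_coords(c1[[1L]])),
      .stop_schema(sprintf("unsupported geometry type '%s'", g$type), path)
    )
  }
  if (length(geoms) == 0L) .stop_schema("layer has no geometries", path)
  landscape_layer(kind, geoms)
}

#' Write a landscape layer as GeoJSON
#'
#' @param layer A [landscape_layer()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_geojson_layer <- function(layer, path) {
  stopifnot(inherits(layer, "landscape_layer"))
  feat <- lapply(layer$geometries, function(g) {
    geom <- if (is.list(g) && !is.null(g$polygon)) {
      ring <- g$polygon
      if (!all(ring[1L, ] == ring[nrow(ring), ])) ring <- rbind(ring, ring[1L, ])
      list(type = "Polygon",
           coordinates = list(lapply(seq_len(nrow(ring)), function(i) ring[i, ])))
    } else if (nrow(g) == 1L) {
      list(type = "Point", coordinates = g[1L, ])
    } else {
      list(type = "LineString",
           coordinates = lapply(seq_len(nrow(g)), function(i) g[i, ]))
    }
    list(type = "Feature", properties = list(kind = layer$kind), geometry = geom)
  })
  fc <- list(type = "FeatureCollection", features = feat)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

.write_geojson_lines <- function(geoms, path) {
  write_geojson_layer(structure(list(kind = "road", geometries = geoms),
                                class = "landscape_layer"), path)
}

# read transect polylines back from a GeoJSON written by the simulator
read_transect_lines <- function(path) {
  lyr <- read_landscape_layer(path, kind = "road")
  lyr$geometries
}

#' Read a run configuration (YAML or JSON)
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) .stop_schema("config file not found", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
}

#' Write a tidy density report CSV
#'
#' One row per estimate: `stratum`, `n`, `effort_km`, `estimate`, `cv`,
#' `ci_low`, `ci_high`, `estimator`.
#'
#' @param estimates List of `density_estimate` objects.
#' @param path Output CSV.
#' @return Invisibly, the report data.frame.
#' @export
write_density_report <- function(estimates, path = NULL) {
  df <- do.call(rbind, lapply(estimates, function(e)
    data.frame(stratum = e$stratum, n = e$n, effort_km = e$effort_km,
               estimate = e$value, cv = e$cv, ci_low = e$ci_low,
               ci_high = e$ci_high, estimator = e$estimator)))
  rownames(df) <- NULL
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
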