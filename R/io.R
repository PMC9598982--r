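# Plain-text geodata I/O: GeoJSON feature collections (points, polylines,
# polygons) via jsonlite, and CSV tables. Coordinates are in the raster's
# planar CRS (north-up, pixel-center registration).

geojson_collection <- function(features) {
  list(type = "FeatureCollection", features = features)
}

feature_props <- function(df, i, drop) {
  cols <- setdiff(names(df), drop)
  if (!length(cols)) return(stats::setNames(list(), character()))
  as.list(df[i, cols, drop = FALSE])
}

#' Write points as GeoJSON
#'
#' @param df data.frame with `x`, `y` and any property columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geojson_points <- function(df, path) {
  feats <- lapply(seq_len(nrow(df)), function(i) list(
    type = "Feature",
    geometry = list(type = "Point", coordinates = c(df$x[i], df$y[i])),
    properties = feature_props(df, i, c("x", "y"))
  ))
  jsonlite::write_json(geojson_collection(feats), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write polylines as GeoJSON
#'
#' @param df data.frame with `road_id`, `x`, `y` (consecutive vertices per
#'   polyline).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geojson_lines <- function(df, path) {
  ids <- unique(df$road_id)
  feats <- lapply(ids, function(id) {
    seg <- df[df$road_id == id, , drop = FALSE]
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = unname(as.matrix(seg[, c("x", "y")]))),
         properties = list(road_id = id))
  })
  jsonlite::write_json(geojson_collection(feats), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write polygons as GeoJSON
#'
#' Rings are closed on write (first vertex repeated) per the GeoJSON spec.
#'
#' @param df data.frame with `group`, `x`, `y` (one ring per group).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_geojson_polygons <- function(df, path) {
  ids <- unique(df$group)
  feats <- lapply(ids, function(id) {
    ring <- df[df$group == id, c("x", "y"), drop = FALSE]
    ring <- rbind(ring, ring[1, ])
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = list(unname(as.matrix(ring)))),
         properties = list(group = id))
  })
  jsonlite::write_json(geojson_collection(feats), path,
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a GeoJSON feature collection
#'
#' Supports the Point, LineString and Polygon collections written by this
#' package. Polygon rings are unclosed on read (trailing repeat vertex
#' dropped).
#'
#' @param path GeoJSON file.
#' @return data.frame of coordinates plus property columns; geometry type in
#'   attribute `geometry_type`.
#' @export
read_geojson <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(j$type) || j$type != "FeatureCollection")
    stop("not a GeoJSON FeatureCollection: ", path)
  rows <- lapply(j$features, function(f) {
    geom <- f$geometry
    props <- as.data.frame(f$properties, stringsAsFactors = FALSE)
    if (geom$type == "Point") {
      cbind(data.frame(x = geom$coordinates[[1]], y = geom$coordinates[[2]]),
            props)
    } else {
      coords <- if (geom$type == "Polygon") geom$coordinates[[1]]
                else geom$coordinates
      m <- do.call(rbind, lapply(coords, function(p) c(p[[1]], p[[2]])))
      if (geom$type == "Polygon" &&
          all(m[1, ] == m[nrow(m), ]) && nrow(m) > 1)
        m <- m[-nrow(m), , drop = FALSE]
      cbind(data.frame(x = m[, 1], y = m[, 2]),
            props[rep(1, nrow(m)), , drop = FALSE])
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "geometry_type") <- j$features[[1]]$geometry$type
  out
}

write_table_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
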