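# GeoJSON writers/readers for the package's point/line/polygon artifacts.
# Coordinates are planar metres (the analyses' working CRS); readers make
# no CRS assumption beyond that.

#' Write labelled points as GeoJSON
#'
#' @param df data.frame with `x`, `y` and any further property columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_points_geojson <- function(df, path) {
  props <- setdiff(names(df), c("x", "y"))
  feats <- lapply(seq_len(nrow(df)), function(i) {
    list(type = "Feature",
         geometry = list(type = "Point", coordinates = c(df$x[i], df$y[i])),
         properties = as.list(df[i, props, drop = FALSE]))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read points (with properties) from GeoJSON
#'
#' @param path a GeoJSON FeatureCollection of points.
#' @return data.frame with `x`, `y` and the property columns.
#' @export
read_points_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  if (is.null(gj$features)) stop("not a GeoJSON FeatureCollection: ", path)
  rows <- lapply(gj$features, function(f) {
    cc <- unlist(f$geometry$coordinates)
    c(list(x = cc[1], y = cc[2]), f$properties)
  })
  do.call(rbind, lapply(rows, function(r) as.data.frame(r)))
}

#' Write a line network as GeoJSON
#'
#' @param network list of 2-column vertex matrices.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lines_geojson <- function(network, path) {
  feats <- lapply(seq_along(network), function(i) {
    m <- network[[i]]
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = lapply(seq_len(nrow(m)),
                                              function(j) c(m[j, 1], m[j, 2]))),
         properties = list(id = i))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a line network from GeoJSON
#'
#' @param path GeoJSON FeatureCollection of LineStrings.
#' @return list of 2-column vertex matrices.
#' @export
read_lines_geojson <- function(path) {
  gj <- jsonlite::read_json(path)
  lapply(gj$features, function(f) {
    do.call(rbind, lapply(f$geometry$coordinates,
                          function(p) c(p[[1]], p[[2]])))
  })
}

#' Write recursion sites as GeoJSON (hull polygon + member points)
#'
#' @param sites list of characterized `recursion_site` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_geojson <- function(sites, path) {
  feats <- list()
  for (s in sites) {
    m <- s$members
    hull <- grDevices::chull(m$x, m$y)
    ring <- lapply(c(hull, hull[1]), function(j) c(m$x[j], m$y[j]))
    feats[[length(feats) + 1L]] <- list(
      type = "Feature",
      geometry = list(type = "Polygon", coordinates = list(ring)),
      properties = list(site = s$site_id, common = s$common,
                        n_locations = s$n_locations,
                        animals = paste(s$animal_ids, collapse = "+")))
    for (j in seq_len(nrow(m)))
      feats[[length(feats) + 1L]] <- list(
        type = "Feature",
        geometry = list(type = "Point", coordinates = c(m$x[j], m$y[j])),
        properties = list(site = s$site_id))
  }
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
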