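# GeoJSON writers for the field geometry (local planar CRS in meters).
# Hand-assembled feature lists serialized with jsonlite.

geojson_polygon_feature <- function(xmin, ymin, xmax, ymax, properties) {
  ring <- list(c(xmin, ymin), c(xmax, ymin), c(xmax, ymax),
               c(xmin, ymax), c(xmin, ymin))
  list(type = "Feature",
       geometry = list(type = "Polygon", coordinates = list(ring)),
       properties = properties)
}

geojson_write <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = 8, pretty = FALSE)
  invisible(path)
}

#' Write a field layout as GeoJSON plot polygons
#'
#' @param layout a `field_layout`.
#' @param path output `.geojson` path.
#' @param zones optional data.frame from [assign_zones()]; adds a `zone`
#'   property per plot.
#' @return `path`, invisibly.
#' @export
write_layout_geojson <- function(layout, path, zones = NULL) {
  p <- layout$plots
  zmap <- if (!is.null(zones))
    stats::setNames(as.character(zones$zone), zones$plot_id)
  features <- lapply(seq_len(nrow(p)), function(i) {
    props <- list(plot_id = p$plot_id[i], germplasm = p$germplasm[i],
                  replicate = p$replicate[i])
    if (!is.null(zmap)) props$zone <- unname(zmap[as.character(p$plot_id[i])])
    geojson_polygon_feature(p$xmin[i], p$ymin[i], p$xmax[i], p$ymax[i], props)
  })
  geojson_write(features, path)
}

# conventional LISA cluster-map palette
lisa_palette <- c(HH = "#d7191c", LL = "#2c7bb6", LH = "#abd9e9",
                  HL = "#fdae61", NS = "#bdbdbd")

#' Write LISA point results as GeoJSON
#'
#' Point features with the class label and the conventional LISA palette
#' color (H-H red, L-L blue, L-H pale blue, H-L orange, NS grey) as
#' properties.
#'
#' @param lisa plant table from [run_lisa()].
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_lisa_geojson <- function(lisa, path) {
  features <- lapply(seq_len(nrow(lisa)), function(i) {
    cls <- lisa$class[i]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(lisa$x[i], lisa$y[i])),
         properties = list(plant_id = lisa$plant_id[i],
                           plot_id = lisa$plot_id[i],
                           z = lisa$z[i], I = lisa$I[i],
                           pseudo_p = lisa$pseudo_p[i],
                           class = cls,
                           color = unname(lisa_palette[cls])))
  })
  geojson_write(features, path)
}

#' Write cluster regions as GeoJSON
#'
#' One polygon feature per member plot, tagged with the region `kind`.
#'
#' @param low,high `cluster_region` objects.
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_regions_geojson <- function(low, high, path) {
  feat_of <- function(reg) {
    r <- reg$rectangles
    lapply(seq_len(nrow(r)), function(i)
      geojson_polygon_feature(r$xmin[i], r$ymin[i], r$xmax[i], r$ymax[i],
                              list(plot_id = r$plot_id[i], kind = reg$kind)))
  }
  geojson_write(c(feat_of(low), feat_of(high)), path)
}
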