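#' Write grid cells as a GeoJSON FeatureCollection
#'
#' Each cell becomes a square polygon from its lower-left corner; every
#' non-coordinate column of `table` is attached as a feature property.
#'
#' @param table data.frame with `cell_id`, `lon_ll`, `lat_ll` and any
#'   property columns.
#' @param grid the [grid_spec()] defining the cell size.
#' @param path output file path.
#' @return invisibly, `path`.
#' @export
write_cells_geojson <- function(table, grid, path) {
  stopifnot(all(c("cell_id", "lon_ll", "lat_ll") %in% names(table)),
            inherits(grid, "grid_spec"))
  res <- grid$resolution
  prop_cols <- setdiff(names(table), c("lon_ll", "lat_ll"))
  features <- lapply(seq_len(nrow(table)), function(i) {
    x0 <- table$lon_ll[i]; y0 <- table$lat_ll[i]
    ring <- list(c(x0, y0), c(x0 + res, y0), c(x0 + res, y0 + res),
                 c(x0, y0 + res), c(x0, y0))
    props <- as.list(table[i, prop_cols, drop = FALSE])
    list(type = "Feature",
         geometry = list(type = "Polygon", coordinates = list(ring)),
         properties = props)
  })
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
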