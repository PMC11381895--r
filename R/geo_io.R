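#' Write / read tissue regions as GeoJSON
#'
#' Regions are stored as a `FeatureCollection` of `Polygon` features with
#' coordinates in pixels and a `name` property; the micron-per-pixel scale
#' travels in a top-level `um_per_px` member. Declaration order is
#' preserved.
#'
#' @param regions a [region_set()].
#' @param path file path.
#' @return `read_regions_geojson` returns a [region_set()];
#'   `write_regions_geojson` returns `path` invisibly.
#' @export
write_regions_geojson <- function(regions, path) {
  stopifnot(inherits(regions, "region_set"))
  features <- lapply(names(regions$regions), function(nm) {
    p <- regions$regions[[nm]]
    ring <- rbind(p, p[1, , drop = FALSE])        # GeoJSON rings close
    list(type = "Feature",
         properties = list(name = nm),
         geometry = list(type = "Polygon",
                         coordinates = list(unname(
                           lapply(seq_len(nrow(ring)),
                                  function(i) as.numeric(ring[i, ]))))))
  })
  doc <- list(type = "FeatureCollection", um_per_px = regions$um_per_px,
              features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_regions_geojson
#' @export
read_regions_geojson <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$type, "FeatureCollection"))
    stop_arg("%s: not a GeoJSON FeatureCollection", path)
  polys <- list()
  for (f in doc$features) {
    nm <- f$properties$name
    ring <- f$geometry$coordinates[[1]]
    m <- do.call(rbind, lapply(ring, function(v) as.numeric(unlist(v))))
    polys[[nm]] <- m
  }
  region_set(polys, um_per_px = doc$um_per_px %||% 0.5)
}
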