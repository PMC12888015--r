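#' Annotation sets: labelled polygons in image coordinates
#'
#' An `annotation_set` is a list of labelled 2-D polygons (optionally with
#' holes) in image pixel coordinates, with a provenance tag distinguishing
#' training annotations, pathologist annotations and automatic detections.
#'
#' @param polygons list of `list(outer, holes = list(), label)` where
#'   `outer` and each hole are two-column vertex matrices in pixels.
#' @param provenance one of `"training"`, `"pathologist"`, `"detection"`.
#' @return an `annotation_set`.
#' @export
annotation_set <- function(polygons = list(), provenance = "pathologist") {
  for (p in polygons) {
    stopifnot(is.matrix(p$outer) || is.data.frame(p$outer),
              !is.null(p$label))
  }
  structure(list(polygons = polygons, provenance = provenance),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  labs <- vapply(x$polygons, function(p) as.character(p$label), character(1))
  cat(sprintf("Annotation set (%s): %d polygons\n", x$provenance,
              length(x$polygons)))
  if (length(labs)) print(table(labs))
  invisible(x)
}

#' Labels of an annotation set
#' @param x an `annotation_set`.
#' @return character vector, one label per polygon.
#' @export
annotation_labels <- function(x) {
  vapply(x$polygons, function(p) as.character(p$label), character(1))
}

.close_ring <- function(m) {
  m <- as.matrix(m)
  if (!all(m[1, ] == m[nrow(m), ])) m <- rbind(m, m[1, ])
  m
}

#' Write an annotation set to GeoJSON (QuPath classification dialect)
#'
#' Emits a `FeatureCollection` of `Polygon` features with a
#' `classification: {name}` property, the dialect QuPath reads and writes.
#'
#' @param x an `annotation_set` or `detection_set` polygons.
#' @param path output `.geojson` path.
#' @return `path`, invisibly.
#' @export
write_geojson <- function(x, path) {
  feats <- lapply(x$polygons, function(p) {
    rings <- c(list(.close_ring(p$outer)),
               lapply(p$holes %||% list(), .close_ring))
    list(type = "Feature",
         geometry = list(type = "Polygon",
                         coordinates = lapply(rings, function(r)
                           lapply(seq_len(nrow(r)), function(i) c(r[i, 1], r[i, 2])))),
         properties = list(objectType = if (x$provenance == "detection")
                             "detection" else "annotation",
                           classification = list(name = as.character(p$label))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an annotation set from GeoJSON
#'
#' Accepts `Polygon` and `MultiPolygon` geometries; the class label is taken
#' from `properties$classification$name` (QuPath) or `properties$name`.
#'
#' @param path `.geojson` file.
#' @param provenance provenance tag to attach.
#' @return an `annotation_set`.
#' @export
read_geojson <- function(path, provenance = "pathologist") {
  g <- jsonlite::read_json(path)
  polys <- list()
  for (f in g$features) {
    lab <- f$properties$classification$name %||% f$properties$name %||% "unlabeled"
    geoms <- if (f$geometry$type == "Polygon") list(f$geometry$coordinates)
             else if (f$geometry$type == "MultiPolygon") f$geometry$coordinates
             else next
    for (rings in geoms) {
      to_mat <- function(r) {
        m <- do.call(rbind, lapply(r, function(pt) c(pt[[1]], pt[[2]])))
        if (nrow(m) > 1 && all(m[1, ] == m[nrow(m), ])) m <- m[-nrow(m), , drop = FALSE]
        colnames(m) <- c("x", "y"); m
      }
      polys[[length(polys) + 1L]] <- list(
        outer = to_mat(rings[[1]]),
        holes = lapply(rings[-1], to_mat),
        label = lab)
    }
  }
  annotation_set(polys, provenance)
}

# rasterise an annotation set to an integer id map (0 = none); later
# polygons overwrite earlier ones where they overlap
rasterize_annotations <- function(x, dim, px_size = 1) {
  out <- matrix(0L, dim[1], dim[2])
  for (k in seq_along(x$polygons)) {
    p <- x$polygons[[k]]
    m <- polygons_to_mask(list(list(outer = p$outer, holes = p$holes %||% list())),
                          dim, px_size = px_size)
    out[m] <- k
  }
  out
}
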