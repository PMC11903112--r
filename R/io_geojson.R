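# QuPath-dialect GeoJSON detection files: RFC 7946 FeatureCollections whose
# features carry a nucleus polygon and a classification property.

#' Read nucleus detections from a QuPath-style GeoJSON file
#'
#' Accepts an RFC 7946 FeatureCollection of Polygon or MultiPolygon
#' geometries. One shape is produced per outer ring; interior rings (holes)
#' are discarded. The cell class is read from the feature's classification
#' property, accepting both QuPath's nested `{"classification": {"name": ...}}`
#' object and a plain string, and defaults to `"tumour"` when absent.
#' Non-polygon geometries are skipped with a warning count.
#'
#' @param path GeoJSON file path.
#' @param pixel_size micrometres per pixel. When supplied, coordinates in the
#'   file are taken to be pixel units and are multiplied by `pixel_size`;
#'   when `NULL` (default) coordinates are passed through as already being
#'   in micrometres.
#' @return List of [nucleus_shape()] objects.
#' @export
read_qupath_geojson <- function(path, pixel_size = NULL) {
  gj <- tryCatch(
    jsonlite::read_json(path, simplifyVector = FALSE),
    error = function(e) stop("cannot parse GeoJSON file '", path, "': ",
                             conditionMessage(e))
  )
  if (!identical(gj$type, "FeatureCollection")) {
    stop("'", path, "' is not a GeoJSON FeatureCollection")
  }
  feats <- gj$features
  shapes <- list()
  skipped <- 0L
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    geom <- f$geometry
    if (is.null(geom$type)) {
      stop("feature ", i, " in '", path, "' has no geometry type")
    }
    rings <- switch(geom$type,
      Polygon = list(geom$coordinates[[1L]]),
      MultiPolygon = lapply(geom$coordinates, function(poly) poly[[1L]]),
      {
        skipped <- skipped + 1L
        next
      }
    )
    props <- f$properties
    cls <- .read_classification(props)
    nid <- props$nucleus_id %||% f$id %||% paste0("nucleus_", i)
    cid <- props$case_id %||% "unknown_case"
    for (k in seq_along(rings)) {
      v <- .coords_to_matrix(rings[[k]], i)
      if (!is.null(pixel_size)) v <- v * pixel_size
      id <- if (length(rings) > 1L) paste0(nid, "_part", k) else nid
      shapes[[length(shapes) + 1L]] <- tryCatch(
        nucleus_shape(v, nucleus_id = id, case_id = cid, cell_class = cls,
                      source_pixel_size = pixel_size),
        error = function(e) {
          stop("feature ", i, " in '", path, "': ", conditionMessage(e))
        }
      )
    }
  }
  if (skipped > 0L) {
    warning(skipped, " non-polygon feature(s) skipped in '", path, "'")
  }
  shapes
}

.read_classification <- function(props) {
  cls <- props$classification
  if (is.null(cls)) return("tumour")
  name <- if (is.list(cls)) cls$name else cls
  if (is.null(name)) return("tumour")
  name <- tolower(as.character(name))
  switch(name,
    tumor = , tumour = "tumour",
    lymphocyte = , immune = , "immune cells" = "lymphocyte",
    "normal epithelium" = , normal_epithelium = "normal_epithelium",
    "other"
  )
}

.coords_to_matrix <- function(ring, feature_index) {
  m <- tryCatch(
    do.call(rbind, lapply(ring, function(p) c(p[[1L]], p[[2L]]))),
    error = function(e) NULL
  )
  if (is.null(m) || !is.numeric(m)) {
    stop("feature ", feature_index, " has malformed polygon coordinates")
  }
  m
}

#' Write nucleus shapes to a QuPath-compatible GeoJSON file
#'
#' Emits an RFC 7946 FeatureCollection with Polygon geometries, closed rings
#' and QuPath's nested classification property, re-readable by
#' [read_qupath_geojson()] (and by QuPath). Coordinates are written in
#' micrometres.
#'
#' @param shapes list of [nucleus_shape()] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_qupath_geojson <- function(shapes, path) {
  feats <- lapply(shapes, function(s) {
    stopifnot(inherits(s, "nucleus_shape"))
    v <- rbind(s$vertices, s$vertices[1L, , drop = FALSE])  # close the ring
    coords <- lapply(seq_len(nrow(v)), function(i) c(v[i, 1L], v[i, 2L]))
    list(
      type = "Feature",
      geometry = list(
        type = "Polygon",
        coordinates = list(coords)
      ),
      properties = list(
        nucleus_id = s$nucleus_id,
        case_id = s$case_id,
        classification = list(name = s$cell_class)
      )
    )
  })
  gj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA,
                       always_decimal = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
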