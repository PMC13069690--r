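# GeoJSON import/export for boundary geometries. Coordinates stay in
# platform units; full numeric precision is kept so files round-trip and
# re-runs are byte-identical.

.coords_ring <- function(poly) {
  p <- .poly_close(poly)
  unname(lapply(seq_len(nrow(p)), function(i) c(p[i, 1], p[i, 2])))
}

.coords_line <- function(line) {
  unname(lapply(seq_len(nrow(line)), function(i) c(line[i, 1], line[i, 2])))
}

.feature <- function(geom_type, coords, properties) {
  list(type = "Feature",
       properties = properties,
       geometry = list(type = geom_type, coordinates = coords))
}

#' Write boundary geometries as GeoJSON
#'
#' Accepts a \code{boundary_set} (one Polygon feature per region, with
#' \code{region_id}), a \code{ring_region} (inner and outer Polygon features
#' tagged by \code{role}), a list of \code{boundary_edge}s (LineString
#' features with \code{edge_id}), or a bare polygon matrix.
#'
#' @param x Geometry object.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_geojson <- function(x, path) {
  feats <- if (inherits(x, "boundary_set")) {
    lapply(seq_along(x$polygons), function(i) {
      .feature("Polygon", list(.coords_ring(x$polygons[[i]])),
               list(region_id = x$region_ids[i]))
    })
  } else if (inherits(x, "ring_region")) {
    list(.feature("Polygon", list(.coords_ring(x$inner)),
                  list(role = "inner", dist = x$dist)),
         .feature("Polygon", list(.coords_ring(x$outer)),
                  list(role = "outer", dist = x$dist)))
  } else if (is.list(x) && length(x) > 0 && inherits(x[[1]], "boundary_edge")) {
    lapply(x, function(e) {
      .feature("LineString", .coords_line(e$polyline),
               list(edge_id = e$edge_id, parent_region = e$parent_region))
    })
  } else if (is.matrix(x) || is.data.frame(x)) {
    list(.feature("Polygon", list(.coords_ring(as.matrix(x))),
                  list(region_id = 1L)))
  } else {
    stop("unsupported geometry type for GeoJSON export")
  }
  obj <- list(type = "FeatureCollection", features = feats)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       always_decimal = FALSE)
  invisible(path)
}

#' Read geometries from GeoJSON
#'
#' Inverts \code{\link{write_geojson}}: a file of region polygons becomes a
#' \code{boundary_set}, an inner/outer pair becomes a \code{ring_region},
#' LineStrings become \code{boundary_edge}s.
#'
#' @param path GeoJSON file.
#' @return A \code{boundary_set}, \code{ring_region}, or list of
#'   \code{boundary_edge}s, depending on the file contents.
#' @export
read_geojson <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$type, "FeatureCollection")) {
    stop("expected a GeoJSON FeatureCollection")
  }
  feats <- obj$features
  as_mat <- function(coords) {
    do.call(rbind, lapply(coords, function(pt) c(as.numeric(pt[[1]]),
                                                 as.numeric(pt[[2]]))))
  }
  types <- vapply(feats, function(f) f$geometry$type, "")
  roles <- vapply(feats, function(f) {
    if (!is.null(f$properties$role)) f$properties$role else NA_character_
  }, "")
  if (all(types == "LineString")) {
    return(lapply(feats, function(f) {
      m <- as_mat(f$geometry$coordinates)
      colnames(m) <- c("x", "y")
      structure(list(edge_id = f$properties$edge_id,
                     polyline = m,
                     parent_region = f$properties$parent_region),
                class = "boundary_edge")
    }))
  }
  if (!all(types == "Polygon")) stop("mixed geometry types not supported")
  polys <- lapply(feats, function(f) {
    m <- as_mat(f$geometry$coordinates[[1]])
    colnames(m) <- c("x", "y")
    .poly_ccw(m)
  })
  if (length(polys) == 2 && setequal(stats::na.omit(roles), c("inner", "outer"))) {
    return(structure(list(inner = polys[[which(roles == "inner")]],
                          outer = polys[[which(roles == "outer")]],
                          dist = feats[[1]]$properties$dist),
                     class = "ring_region"))
  }
  structure(list(polygons = polys,
                 region_ids = seq_along(polys),
                 region_cells = NULL, kept_cells = NULL,
                 params = list()),
            class = "boundary_set")
}
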