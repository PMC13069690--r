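#' Distances from cells to the centroid of a reference population
#'
#' The reference centroid is the arithmetic mean of the reference cells'
#' coordinates; each query cell's raw distance is its Euclidean distance to
#' that centroid.
#'
#' @param cells Query cell table.
#' @param reference_cells Non-empty cell table defining the centroid
#'   (commonly the same selection as \code{cells}).
#' @return Numeric vector of raw distances, one per query cell, with the
#'   centroid coordinates in the \code{"centroid"} attribute.
#' @export
distance_to_centroid <- function(cells, reference_cells) {
  validate_cell_table(cells)
  if (!is.data.frame(reference_cells) || nrow(reference_cells) == 0) {
    stop("reference cell set is empty")
  }
  s0 <- c(mean(reference_cells$x), mean(reference_cells$y))
  d <- sqrt((cells$x - s0[1])^2 + (cells$y - s0[2])^2)
  attr(d, "centroid") <- s0
  d
}

#' Distances from cells to a boundary geometry
#'
#' Shortest Euclidean distance from each cell to the geometry's boundary
#' curve, measured against the continuous segments (not just the vertices).
#' Cells inside a polygon still get their positive distance to its outline: a
#' boundary weight indexes proximity to the outline itself. A cell exactly on
#' the curve gets distance 0.
#'
#' @param cells Query cell table.
#' @param geometry A closed polygon matrix, a \code{boundary_set} (its
#'   primary region), a \code{ring_region} (its inner polygon), or a
#'   \code{boundary_edge}.
#' @return Numeric vector of raw distances, one per query cell.
#' @export
distance_to_geometry <- function(cells, geometry) {
  validate_cell_table(cells)
  line <- if (inherits(geometry, "boundary_edge")) {
    geometry$polyline
  } else if (inherits(geometry, "ring_region")) {
    geometry$inner
  } else if (inherits(geometry, "boundary_set")) {
    geometry$polygons[[1]]
  } else {
    .poly_close(geometry)
  }
  .dist_to_polyline(cbind(cells$x, cells$y), line)
}

#' Min-max normalize raw distances to [0, 1]
#'
#' When all raw distances are equal the spread is zero; every cell is then
#' treated as maximally close (normalized distance 0, hence weight 1), rather
#' than erroring, because single-ring or perfectly symmetric selections
#' legitimately occur.
#'
#' @param d Numeric vector of raw distances (>= 1 value).
#' @return Vector in [0, 1]; minimum maps to 0 and maximum to 1 unless all
#'   values are equal (then all 0). Equality is judged at a relative spread
#'   of 1e-12 so that floating-point jitter in symmetric configurations does
#'   not get inflated to the full unit range.
#' @export
normalize_minmax <- function(d) {
  if (length(d) == 0) stop("need at least one distance")
  rng <- range(d)
  spread <- rng[2] - rng[1]
  if (spread <= 1e-12 * max(abs(rng))) return(rep(0, length(d)))
  (d - rng[1]) / spread
}

#' Apply a distance-decay kernel to normalized distances
#'
#' Maps normalized distances to spatial weights via one of four kernels:
#' inverse \code{1/(1 + d)}, Gaussian \code{exp(-d^2 / (2 sigma^2))}, linear
#' \code{1 - d}, or quadratic \code{(1 - d)^2}. All kernels give weight 1 at
#' distance 0 and are non-increasing on [0, 1]; the inverse kernel bottoms
#' out at 0.5 at distance 1.
#'
#' @param norm_dist Normalized distances in [0, 1].
#' @param decay One of \code{"inverse"}, \code{"gaussian"}, \code{"linear"},
#'   \code{"quadratic"}.
#' @param sigma Gaussian scale parameter, > 0; default 0.3 (half-weight near
#'   normalized distance 0.35).
#' @return Weight vector, same length as \code{norm_dist}.
#' @export
apply_decay <- function(norm_dist,
                        decay = c("inverse", "gaussian", "linear", "quadratic"),
                        sigma = 0.3) {
  decay <- match.arg(decay)
  if (any(norm_dist < 0 | norm_dist > 1)) {
    stop("normalized distances must lie in [0, 1]")
  }
  switch(decay,
         inverse = 1 / (1 + norm_dist),
         gaussian = {
           if (!is.numeric(sigma) || sigma <= 0) stop("sigma must be > 0")
           exp(-norm_dist^2 / (2 * sigma^2))
         },
         linear = 1 - norm_dist,
         quadratic = (1 - norm_dist)^2)
}

.make_weight_vector <- function(cells, raw, decay, sigma, reference) {
  nd <- normalize_minmax(raw)
  w <- apply_decay(nd, decay = decay, sigma = sigma)
  out <- data.frame(cell = as.character(cells$cell),
                    raw_dist = as.numeric(raw),
                    norm_dist = nd,
                    weight = w,
                    stringsAsFactors = FALSE)
  attr(out, "decay") <- decay
  attr(out, "sigma") <- sigma
  attr(out, "reference") <- reference
  class(out) <- c("weight_vector", "data.frame")
  out
}

#' Spatial weights relative to a boundary geometry
#'
#' Composition of \code{\link{distance_to_geometry}},
#' \code{\link{normalize_minmax}} and \code{\link{apply_decay}}: per-cell raw
#' distance, normalized distance and decayed weight, with full provenance
#' retained. A cell lying exactly on the geometry gets weight 1 under every
#' kernel.
#'
#' @param cells Cell table to weight.
#' @param geometry Boundary geometry (see
#'   \code{\link{distance_to_geometry}}).
#' @param decay,sigma Kernel parameters (see \code{\link{apply_decay}}).
#' @return A \code{weight_vector}: data.frame with columns \code{cell},
#'   \code{raw_dist}, \code{norm_dist}, \code{weight}; kernel and reference
#'   stored as attributes.
#' @export
compute_boundary_weights <- function(cells, geometry,
                                     decay = c("inverse", "gaussian",
                                               "linear", "quadratic"),
                                     sigma = 0.3) {
  decay <- match.arg(decay)
  raw <- distance_to_geometry(cells, geometry)
  ref <- if (inherits(geometry, "boundary_edge")) {
    paste0("boundary_edge:", geometry$edge_id)
  } else "boundary"
  .make_weight_vector(cells, raw, decay, sigma, ref)
}

#' Spatial weights relative to a population centroid
#'
#' @param cells Cell table to weight.
#' @param reference_cells Cells whose coordinate mean defines the centroid.
#' @param decay,sigma Kernel parameters (see \code{\link{apply_decay}}).
#' @return A \code{weight_vector} (see
#'   \code{\link{compute_boundary_weights}}); the centroid coordinates are
#'   recorded in the \code{"reference"} attribute.
#' @export
compute_centroid_weights <- function(cells, reference_cells,
                                     decay = c("inverse", "gaussian",
                                               "linear", "quadratic"),
                                     sigma = 0.3) {
  decay <- match.arg(decay)
  raw <- distance_to_centroid(cells, reference_cells)
  .make_weight_vector(cells, as.numeric(raw), decay, sigma,
                      list(centroid = attr(raw, "centroid")))
}

#' Write a weight vector as TSV
#'
#' @param weights A \code{weight_vector}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_weight_vector <- function(weights, path) {
  utils::write.table(as.data.frame(weights), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
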