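#' Flag spatial outliers by mean k-nearest-neighbor distance
#'
#' For every cell in the selection, computes the arithmetic mean of the
#' Euclidean distances to its \code{k_outlier} nearest neighbors (self
#' excluded, ties broken by ascending cell index) and flags the cell for
#' removal when that mean exceeds the threshold \code{tau}. Isolated cells in
#' low-density pockets get large mean kNN distances and are dropped before
#' boundary construction.
#'
#' @param cells A validated cell table (or subset).
#' @param k_outlier Number of neighbors averaged over; default 5. Must be
#'   smaller than the selection size.
#' @param tau Removal threshold in the same length units as the coordinates;
#'   must be > 0 (may be \code{Inf} to keep everything).
#' @return A data.frame with columns \code{cell}, \code{mean_knn_dist} and
#'   \code{keep} (\code{keep == mean_knn_dist <= tau}), with \code{k_outlier}
#'   and \code{tau} stored as attributes.
#' @export
remove_spatial_outliers <- function(cells, k_outlier = 5, tau) {
  validate_cell_table(cells)
  n <- nrow(cells)
  if (!is.numeric(k_outlier) || k_outlier < 1 || k_outlier >= n) {
    stop("k_outlier must satisfy 1 <= k_outlier < number of cells (", n, ")")
  }
  if (!is.numeric(tau) || is.na(tau) || tau <= 0) stop("tau must be > 0")
  k_outlier <- as.integer(k_outlier)
  nn <- .knn_search(cbind(cells$x, cells$y), k_outlier)
  dbar <- rowMeans(nn$dist)
  out <- data.frame(cell = as.character(cells$cell),
                    mean_knn_dist = dbar,
                    keep = dbar <= tau,
                    stringsAsFactors = FALSE)
  attr(out, "k_outlier") <- k_outlier
  attr(out, "tau") <- tau
  out
}

#' Detect spatially disjoint subregions of a cell selection
#'
#' A cluster of cells may occupy several disconnected patches of tissue; each
#' patch needs its own boundary polygon. Patches are found either by DBSCAN
#' (density-based, with noise points labeled \code{-1} and excluded from
#' boundary construction) or by k-means with a fixed seed.
#'
#' @param xy n x 2 coordinate matrix.
#' @param method \code{"dbscan"} or \code{"kmeans"}.
#' @param eps DBSCAN neighborhood radius (required for \code{"dbscan"}).
#' @param n_centers Number of k-means centers (required for \code{"kmeans"}).
#' @param min_pts DBSCAN core-point threshold; default 5.
#' @param seed RNG seed for k-means; default 0.
#' @return Integer label vector; subregions numbered from 1, DBSCAN noise
#'   \code{-1}.
#' @export
detect_subregions <- function(xy, method = c("dbscan", "kmeans"),
                              eps = NULL, n_centers = NULL,
                              min_pts = 5, seed = 0) {
  method <- match.arg(method)
  xy <- as.matrix(xy)
  if (method == "dbscan") {
    if (is.null(eps)) stop("dbscan requires 'eps'")
    labels <- dbscan_labels(xy, eps = eps, min_pts = min_pts)
    if (all(labels == -1L)) {
      stop("all points classified as noise; increase eps (currently ", eps, ")")
    }
  } else {
    if (is.null(n_centers)) stop("kmeans requires 'n_centers'")
    if (n_centers < 1 || n_centers > nrow(xy)) {
      stop("n_centers must be between 1 and the number of points")
    }
    old <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    set.seed(seed)
    km <- stats::kmeans(xy, centers = n_centers, nstart = 10, iter.max = 100)
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    labels <- as.integer(km$cluster)
    # renumber by first occurrence for label stability
    labels <- match(labels, unique(labels))
  }
  labels
}

#' Detect the spatial boundaries of a cell population
#'
#' Full boundary pipeline for one cluster: spatial outlier removal by mean
#' kNN distance, subregion detection (DBSCAN or k-means), and a concave-hull
#' polygon per subregion. Regions are numbered by descending polygon area, so
#' region 1 is always the primary (largest) patch.
#'
#' @param cells A validated cell table covering the whole tissue.
#' @param cluster The cluster label whose boundaries are wanted.
#' @param k_outlier,tau Outlier-removal parameters
#'   (\code{\link{remove_spatial_outliers}}).
#' @param method,eps,n_centers,min_pts,seed Subregion parameters
#'   (\code{\link{detect_subregions}}).
#' @param concavity,length_threshold Concave-hull parameters
#'   (\code{\link{concave_hull}}).
#' @return A \code{boundary_set} object: list with \code{polygons} (closed
#'   CCW coordinate matrices ordered by descending area), \code{region_ids},
#'   \code{params}, and \code{kept_cells} (ids that survived outlier removal
#'   and were not DBSCAN noise).
#' @export
get_boundary <- function(cells, cluster, k_outlier = 5, tau,
                         method = c("dbscan", "kmeans"),
                         eps = NULL, n_centers = NULL, min_pts = 5,
                         concavity = 2, length_threshold = 0, seed = 0) {
  method <- match.arg(method)
  validate_cell_table(cells)
  sel <- cells[as.character(cells$cluster) == as.character(cluster), ,
               drop = FALSE]
  if (nrow(sel) == 0) stop("unknown cluster: '", cluster, "'")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(name, ": ", conditionMessage(e), call. = FALSE)
    })
  }
  rep_out <- stage("outlier removal",
                   remove_spatial_outliers(sel, k_outlier = k_outlier, tau = tau))
  kept <- sel[rep_out$keep, , drop = FALSE]
  if (nrow(kept) < 3) stop("subregion detection: fewer than 3 cells retained")
  labels <- stage("subregion detection",
                  detect_subregions(cbind(kept$x, kept$y), method = method,
                                    eps = eps, n_centers = n_centers,
                                    min_pts = min_pts, seed = seed))
  regions <- sort(unique(labels[labels > 0]))
  polys <- list()
  members <- list()
  for (r in regions) {
    pts <- cbind(kept$x, kept$y)[labels == r, , drop = FALSE]
    if (nrow(pts) < 3) next
    poly <- stage(sprintf("boundary construction (subregion %d)", r),
                  concave_hull(pts, concavity = concavity,
                               length_threshold = length_threshold))
    polys[[length(polys) + 1]] <- poly
    members[[length(members) + 1]] <- as.character(kept$cell)[labels == r]
  }
  if (length(polys) == 0) stop("boundary construction: no subregion had >= 3 points")
  ord <- order(vapply(polys, .poly_area, 0), decreasing = TRUE)
  structure(list(polygons = polys[ord],
                 region_ids = seq_along(polys),
                 region_cells = members[ord],
                 kept_cells = unlist(members, use.names = FALSE),
                 params = list(cluster = cluster, k_outlier = k_outlier,
                               tau = tau, method = method, eps = eps,
                               n_centers = n_centers, min_pts = min_pts,
                               concavity = concavity,
                               length_threshold = length_threshold,
                               seed = seed)),
            class = "boundary_set")
}

#' @export
print.boundary_set <- function(x, ...) {
  cat("boundary_set with", length(x$polygons), "region(s)\n")
  for (i in seq_along(x$polygons)) {
    cat(sprintf("  region %d: %d vertices, area %.4g\n", i,
                nrow(x$polygons[[i]]) - 1L, .poly_area(x$polygons[[i]])))
  }
  invisible(x)
}

# resolve a polygon argument that may be a matrix, boundary_set, or ring part
.as_polygon <- function(boundary, region = 1) {
  if (inherits(boundary, "boundary_set")) {
    if (region > length(boundary$polygons)) {
      stop("boundary_set has no region ", region)
    }
    return(boundary$polygons[[region]])
  }
  .poly_ccw(boundary)
}

#' Build a neighborhood ring region around a boundary polygon
#'
#' Buffers the boundary outward by \code{dist} (Minkowski offset with round
#' joins) to form an outer boundary; the ring is the annulus between the two,
#' containing the population's immediate spatial neighbors.
#'
#' @param boundary A polygon matrix or a \code{boundary_set} (see
#'   \code{region}).
#' @param dist Buffer distance in coordinate units, > 0; default 100.
#' @param region Which region of a \code{boundary_set} to buffer; default 1
#'   (the primary region).
#' @return A \code{ring_region} object: list with \code{inner}, \code{outer}
#'   (closed CCW polygon matrices) and \code{dist}.
#' @export
build_ring_region <- function(boundary, dist = 100, region = 1) {
  if (!is.numeric(dist) || is.na(dist) || dist <= 0) stop("dist must be > 0")
  inner <- .as_polygon(boundary, region)
  off <- polyclip::polyoffset(list(.poly_to_pc(inner)), dist,
                              jointype = "round", arctol = dist / 200)
  if (length(off) == 0) stop("buffering produced no polygon")
  areas <- vapply(off, function(pc) .poly_area(.pc_to_poly(pc)), 0)
  outer <- .pc_to_poly(off[[which.max(areas)]])
  structure(list(inner = inner, outer = outer, dist = dist),
            class = "ring_region")
}

#' @export
print.ring_region <- function(x, ...) {
  cat(sprintf("ring_region: buffer %.4g; inner area %.4g, outer area %.4g\n",
              x$dist, .poly_area(x$inner), .poly_area(x$outer)))
  invisible(x)
}

#' Extract the cells lying inside a region
#'
#' Point-in-polygon extraction with a boundary-inclusive convention: a cell
#' exactly on a polygon edge or vertex counts as inside that polygon. For a
#' \code{ring_region}, a cell is in the ring when it is inside the outer
#' polygon but not inside the inner polygon, so the inner region and the ring
#' partition the outer region exactly.
#'
#' @param cells A validated cell table.
#' @param region A polygon matrix, a \code{boundary_set} (cells inside any of
#'   its polygons), or a \code{ring_region}.
#' @return The subset of \code{cells} inside the region, input order
#'   preserved. May be empty.
#' @export
cells_inside <- function(cells, region) {
  validate_cell_table(cells)
  pts <- cbind(cells$x, cells$y)
  if (inherits(region, "ring_region")) {
    keep <- .points_in_poly(pts, region$outer) &
      !.points_in_poly(pts, region$inner)
  } else if (inherits(region, "boundary_set")) {
    keep <- rep(FALSE, nrow(cells))
    for (poly in region$polygons) keep <- keep | .points_in_poly(pts, poly)
  } else {
    keep <- .points_in_poly(pts, region)
  }
  cells[keep, , drop = FALSE]
}

#' Cluster composition of a cell subset
#'
#' @param subset A non-empty cell table, typically the output of
#'   \code{\link{cells_inside}}.
#' @return A data.frame with columns \code{cluster}, \code{count} and
#'   \code{proportion}, sorted by descending proportion (ties by label).
#'   Proportions sum to 1.
#' @export
stats_cells_inside <- function(subset) {
  if (!is.data.frame(subset) || nrow(subset) == 0) {
    stop("empty region: no cells to summarise")
  }
  tab <- table(as.character(subset$cluster))
  out <- data.frame(cluster = names(tab),
                    count = as.integer(tab),
                    proportion = as.numeric(tab) / sum(tab),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$proportion, out$cluster), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare per-ring cluster compositions between two conditions
#'
#' Treats each ring as a replicate and tests, cluster by cluster, whether the
#' mean proportion differs between the two conditions with a two-sided Welch
#' t-test. Clusters absent from a ring contribute proportion 0.
#'
#' @param rings_a,rings_b Lists (>= 2 each) of composition tables as produced
#'   by \code{\link{stats_cells_inside}}.
#' @return A data.frame with one row per cluster label present in either
#'   condition: \code{cluster}, \code{mean_a}, \code{mean_b}, \code{t},
#'   \code{p}.
#' @export
compare_compositions <- function(rings_a, rings_b) {
  if (length(rings_a) < 2 || length(rings_b) < 2) {
    stop("need at least 2 rings per condition")
  }
  get_prop <- function(tabs, label) {
    vapply(tabs, function(tb) {
      i <- match(label, tb$cluster)
      if (is.na(i)) 0 else tb$proportion[i]
    }, 0)
  }
  labels <- sort(unique(c(unlist(lapply(rings_a, `[[`, "cluster")),
                          unlist(lapply(rings_b, `[[`, "cluster")))))
  res <- lapply(labels, function(lab) {
    a <- get_prop(rings_a, lab)
    b <- get_prop(rings_b, lab)
    se <- sqrt(stats::var(a) / length(a) + stats::var(b) / length(b))
    if (se == 0) {
      # both samples constant: identical means are indistinguishable (p = 1),
      # different constant means are a sure difference
      tstat <- if (mean(a) == mean(b)) 0 else sign(mean(a) - mean(b)) * Inf
      p <- if (mean(a) == mean(b)) 1 else 0
    } else {
      tt <- stats::t.test(a, b, var.equal = FALSE)
      tstat <- unname(tt$statistic)
      p <- tt$p.value
    }
    data.frame(cluster = lab, mean_a = mean(a), mean_b = mean(b),
               t = tstat, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Split a boundary polygon into directional edges at anchor points
#'
#' Each anchor is snapped to its nearest polygon vertex; the perimeter is cut
#' at the snapped vertices, giving one open polyline per arc between
#' consecutive cut points in counterclockwise order, starting from the vertex
#' nearest the first anchor. The edges jointly cover the full perimeter.
#'
#' @param boundary Polygon matrix or \code{boundary_set}.
#' @param anchors Matrix or data.frame of >= 2 anchor coordinates.
#' @param region Region of a \code{boundary_set} to split; default 1.
#' @return A list of \code{boundary_edge} objects, each a list with
#'   \code{edge_id}, \code{polyline} (open coordinate matrix) and
#'   \code{parent_region}.
#' @export
split_boundary_by_anchors <- function(boundary, anchors, region = 1) {
  poly <- .as_polygon(boundary, region)
  anchors <- as.matrix(anchors)
  if (nrow(anchors) < 2) stop("need at least 2 anchors")
  verts <- .poly_open(poly)
  nv <- nrow(verts)
  snapped <- vapply(seq_len(nrow(anchors)), function(i) {
    d2 <- (verts[, 1] - anchors[i, 1])^2 + (verts[, 2] - anchors[i, 2])^2
    which.min(d2)
  }, 0L)
  if (anyDuplicated(snapped)) {
    stop("ambiguous anchors: two anchors snap to the same polygon vertex")
  }
  start <- snapped[1]
  # order cut vertices along the perimeter starting from anchor 1's vertex
  offset <- (snapped - start) %% nv
  cuts <- snapped[order(offset)]
  a <- length(cuts)
  edges <- vector("list", a)
  for (j in seq_len(a)) {
    from <- cuts[j]
    to <- cuts[if (j == a) 1L else j + 1L]
    idx <- from
    cur <- from
    while (cur != to) {
      cur <- if (cur == nv) 1L else cur + 1L
      idx <- c(idx, cur)
    }
    edges[[j]] <- structure(list(edge_id = j,
                                 polyline = verts[idx, , drop = FALSE],
                                 parent_region = region),
                            class = "boundary_edge")
  }
  edges
}
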