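#' Concave hull of a 2D point set
#'
#' Computes a simple closed polygon enclosing all input points, starting from
#' the convex hull and iteratively "digging" edges toward the nearest interior
#' point wherever doing so is allowed by the concavity parameter and does not
#' make the boundary self-intersect. Small \code{concavity} values follow the
#' point cloud tightly; as \code{concavity} grows the result converges to the
#' convex hull.
#'
#' An edge of squared length \code{L2} is dug toward the interior point
#' nearest to it only when that point's squared distance to the closer edge
#' endpoint is at most \code{L2 / concavity^2}, and edges shorter than
#' \code{length_threshold} are never dug.
#'
#' @param xy An n x 2 matrix or data.frame of point coordinates, n >= 3, not
#'   all collinear.
#' @param concavity Relative concavity knob, > 0; default 2. \code{Inf} gives
#'   the convex hull.
#' @param length_threshold Edges shorter than this are left undug; default 0.
#' @return A closed counterclockwise polygon matrix (columns \code{x},
#'   \code{y}; first vertex repeated last) containing every input point on or
#'   inside it.
#' @export
concave_hull <- function(xy, concavity = 2, length_threshold = 0) {
  xy <- unique(as.matrix(xy))
  if (nrow(xy) < 3) stop("degenerate geometry: need at least 3 distinct points")
  if (!is.numeric(concavity) || concavity <= 0) stop("concavity must be > 0")
  ch <- rev(grDevices::chull(xy))          # chull is clockwise; reverse to CCW
  if (length(ch) < 3 || .poly_area(xy[c(ch, ch[1]), , drop = FALSE]) == 0) {
    stop("degenerate geometry: points are collinear")
  }
  # successor map over point indices along the hull, CCW
  nxt <- integer(0)
  nxt[as.character(ch)] <- c(ch[-1], ch[1])
  cand <- setdiff(seq_len(nrow(xy)), ch)   # interior points, may join the hull
  queue <- ch                              # edge = (a, nxt[a]); process by tail vertex
  sq_conc <- concavity^2
  while (length(queue) > 0 && length(cand) > 0 && is.finite(concavity)) {
    a <- queue[1]; queue <- queue[-1]
    b <- nxt[[as.character(a)]]
    pa <- xy[a, ]; pb <- xy[b, ]
    sq_len <- sum((pa - pb)^2)
    if (sq_len <= length_threshold^2) next
    max_sq <- sq_len / sq_conc
    seg_d <- .dist_to_polyline(xy[cand, , drop = FALSE], rbind(pa, pb))
    ord <- order(seg_d, cand)
    hull_v <- .hull_vertices(nxt, a)
    for (ci in ord) {
      p <- cand[ci]
      pp <- xy[p, ]
      d2 <- min(sum((pp - pa)^2), sum((pp - pb)^2))
      if (d2 > max_sq) break               # candidates are distance-ordered
      if (!.insertion_crosses(xy, hull_v, a, b, pp)) {
        nxt[[as.character(a)]] <- p
        nxt[[as.character(p)]] <- b
        cand <- cand[-ci]
        queue <- c(queue, a, p)
        break
      }
    }
  }
  v <- .hull_vertices(nxt, ch[1])
  .poly_ccw(xy[c(v, v[1]), , drop = FALSE])
}

# walk the successor map from a starting vertex
.hull_vertices <- function(nxt, start) {
  v <- integer(length(nxt))
  v[1] <- start
  cur <- start
  for (i in seq_along(nxt)[-1]) {
    cur <- nxt[[as.character(cur)]]
    v[i] <- cur
  }
  v
}

# would replacing edge (a,b) by (a,p),(p,b) cross an existing hull edge?
.insertion_crosses <- function(xy, hull_v, a, b, pp) {
  nv <- length(hull_v)
  for (i in seq_len(nv)) {
    u <- hull_v[i]
    w <- hull_v[if (i == nv) 1L else i + 1L]
    if (u == a && w == b) next             # the edge being replaced
    q1 <- xy[u, ]; q2 <- xy[w, ]
    if (u != a && w != a && .segments_cross(xy[a, ], pp, q1, q2)) return(TRUE)
    if (u != b && w != b && .segments_cross(pp, xy[b, ], q1, q2)) return(TRUE)
  }
  FALSE
}

#' Density-based subregion clustering (DBSCAN)
#'
#' Classic DBSCAN over 2D coordinates with Euclidean distance. A point with at
#' least \code{min_pts} points (itself included) within \code{eps} is a core
#' point; clusters are the connected components of core points plus their
#' border points. Point order is fixed, so labels are deterministic.
#'
#' @param xy n x 2 coordinate matrix.
#' @param eps Neighborhood radius, > 0.
#' @param min_pts Minimum neighborhood size to qualify as a core point
#'   (default 5).
#' @return Integer vector of labels: clusters numbered 1, 2, ... in order of
#'   discovery; noise points labeled \code{-1}.
#' @export
dbscan_labels <- function(xy, eps, min_pts = 5) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (!is.numeric(eps) || eps <= 0) stop("eps must be > 0")
  d <- as.matrix(stats::dist(xy))
  nb <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(nb, length, 1L) >= min_pts
  labels <- rep.int(-1L, n)
  cl <- 0L
  for (i in seq_len(n)) {
    if (labels[i] != -1L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- nb[[i]]
    while (length(frontier) > 0) {
      j <- frontier[1]
      frontier <- frontier[-1]
      if (labels[j] == -1L) {
        labels[j] <- cl
        if (core[j]) frontier <- c(frontier, nb[[j]][labels[nb[[j]]] == -1L])
      }
    }
  }
  labels
}
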