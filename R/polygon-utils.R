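# Internal polygon helpers.
#
# Polygons are numeric matrices with columns x, y, closed (first vertex
# repeated as the last row) and oriented counterclockwise. Polylines are open
# matrices.

.poly_close <- function(p) {
  p <- as.matrix(p)
  if (nrow(p) < 3) stop("polygon needs at least 3 vertices")
  if (!isTRUE(all.equal(p[1, ], p[nrow(p), ], check.attributes = FALSE))) {
    p <- rbind(p, p[1, , drop = FALSE])
  }
  colnames(p) <- c("x", "y")
  p
}

.poly_open <- function(p) {
  p <- as.matrix(p)
  if (isTRUE(all.equal(p[1, ], p[nrow(p), ], check.attributes = FALSE))) {
    p <- p[-nrow(p), , drop = FALSE]
  }
  p
}

# signed area (positive = counterclockwise), shoelace formula
.poly_signed_area <- function(p) {
  v <- .poly_open(p)
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

.poly_area <- function(p) abs(.poly_signed_area(p))

.poly_ccw <- function(p) {
  p <- .poly_close(p)
  if (.poly_signed_area(p) < 0) p <- p[rev(seq_len(nrow(p))), , drop = FALSE]
  p
}

.poly_perimeter <- function(p) {
  p <- .poly_close(p)
  sum(sqrt(rowSums(diff(p)^2)))
}

.polyline_length <- function(p) {
  p <- as.matrix(p)
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums(diff(p)^2)))
}

# boundary-inclusive point-in-polygon (a point on an edge or vertex counts
# as inside); pts is an n x 2 matrix
.points_in_poly <- function(pts, poly) {
  poly <- .poly_close(poly)
  pts <- as.matrix(pts)
  sp::point.in.polygon(pts[, 1], pts[, 2], poly[, 1], poly[, 2]) > 0
}

# strictly-interior test (edge/vertex points excluded)
.points_in_poly_strict <- function(pts, poly) {
  poly <- .poly_close(poly)
  pts <- as.matrix(pts)
  sp::point.in.polygon(pts[, 1], pts[, 2], poly[, 1], poly[, 2]) == 1
}

# shortest distances from points to an open or closed polyline (continuous
# segments, not just vertices)
.dist_to_polyline <- function(pts, line) {
  pts <- as.matrix(pts)
  line <- as.matrix(line)
  if (nrow(line) < 2) stop("degenerate geometry: fewer than 2 vertices")
  a <- line[-nrow(line), , drop = FALSE]
  b <- line[-1, , drop = FALSE]
  ab <- b - a
  len2 <- rowSums(ab^2)
  if (all(len2 == 0)) stop("degenerate geometry: zero total length")
  d <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(a))) {
    ap_x <- pts[, 1] - a[s, 1]
    ap_y <- pts[, 2] - a[s, 2]
    if (len2[s] == 0) {
      ds <- ap_x^2 + ap_y^2
    } else {
      t <- pmin(1, pmax(0, (ap_x * ab[s, 1] + ap_y * ab[s, 2]) / len2[s]))
      ds <- (ap_x - t * ab[s, 1])^2 + (ap_y - t * ab[s, 2])^2
    }
    d <- pmin(d, ds)
  }
  sqrt(pmax(d, 0))
}

# conversion to/from polyclip's list(x, y) open representation
.poly_to_pc <- function(p) {
  v <- .poly_open(p)
  list(x = v[, 1], y = v[, 2])
}

.pc_to_poly <- function(pc) {
  .poly_ccw(cbind(x = pc$x, y = pc$y))
}

# TRUE when segments (p1,p2) and (q1,q2) properly cross (strict interior
# crossing; shared endpoints / touching do not count)
.segments_cross <- function(p1, p2, q1, q2) {
  o <- function(a, b, c) {
    (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  }
  d1 <- o(q1, q2, p1); d2 <- o(q1, q2, p2)
  d3 <- o(p1, p2, q1); d4 <- o(p1, p2, q2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}
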