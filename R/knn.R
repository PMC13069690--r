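# Internal brute-force k-nearest-neighbor search.
#
# Exact Euclidean kNN with deterministic tie-breaking by ascending point
# index, which the boundary pipeline and interaction matrices rely on for
# bit-reproducible output. Chunked over query points to bound memory; the
# cell counts this package targets (10^3-10^4 per selection) make the O(n^2)
# scan cheap and exactness is worth more than a tree here.

# returns list(index = n x k matrix of neighbor row indices,
#              dist  = n x k matrix of distances), self excluded
.knn_search <- function(xy, k, chunk = 1024L) {
  xy <- as.matrix(xy)
  n <- nrow(xy)
  if (k >= n) stop("k (", k, ") must be smaller than the number of points (", n, ")")
  idx <- matrix(0L, n, k)
  dst <- matrix(0, n, k)
  sq <- rowSums(xy^2)
  starts <- seq.int(1L, n, by = chunk)
  for (s in starts) {
    e <- min(s + chunk - 1L, n)
    rows <- s:e
    # squared distances, clamped at 0 for numeric safety
    d2 <- outer(sq[rows], sq, "+") - 2 * tcrossprod(xy[rows, , drop = FALSE], xy)
    d2[d2 < 0] <- 0
    for (i in seq_along(rows)) {
      r <- rows[i]
      di <- d2[i, ]
      di[r] <- Inf                      # exclude self
      o <- order(di, seq_len(n))[seq_len(k)]  # ties by ascending index
      idx[r, ] <- o
      dst[r, ] <- sqrt(di[o])
    }
  }
  list(index = idx, dist = dst)
}
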