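# Shared fixtures and independent oracle implementations used across tests.
# Oracles are deliberately naive (brute force / hand formulas) and never call
# the code paths they check.

.fixture_cache <- new.env(parent = emptyenv())

# small reference tissue, generated once per test run
small_tissue <- function() {
  if (is.null(.fixture_cache$small)) {
    .fixture_cache$small <- generate_tissue(small_tissue_config(seed = 1))
  }
  .fixture_cache$small
}

bench_tissue <- function() {
  if (is.null(.fixture_cache$bench)) {
    .fixture_cache$bench <- generate_tissue(gradient_bench_config(seed = 1))
  }
  .fixture_cache$bench
}

# uniform random cell table with random cluster labels
random_cells <- function(n, n_clusters = 3, seed = 1) {
  set.seed(seed)
  data.frame(cell = sprintf("c%04d", seq_len(n)),
             x = runif(n, 0, 100), y = runif(n, 0, 100),
             cluster = sample(LETTERS[seq_len(n_clusters)], n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# O(n^2) mean k-NN distances by full pairwise enumeration
oracle_mean_knn <- function(xy, k) {
  n <- nrow(xy)
  vapply(seq_len(n), function(i) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    mean(sort(d[-i])[seq_len(k)])
  }, 0)
}

# brute-force interaction matrix via a full pairwise distance sort
oracle_interaction <- function(cells, k) {
  xy <- cbind(cells$x, cells$y)
  cl <- as.character(cells$cluster)
  labels <- sort(unique(cl))
  m <- matrix(0L, length(labels), length(labels),
              dimnames = list(labels, labels))
  n <- nrow(xy)
  for (i in seq_len(n)) {
    d <- sqrt((xy[, 1] - xy[i, 1])^2 + (xy[, 2] - xy[i, 2])^2)
    d[i] <- Inf
    nb <- order(d, seq_len(n))[seq_len(k)]
    for (j in nb) m[cl[i], cl[j]] <- m[cl[i], cl[j]] + 1L
  }
  m
}

# Welch two-sample t by the textbook formulas
oracle_welch <- function(a, b) {
  v1 <- var(a) / length(a); v2 <- var(b) / length(b)
  t <- (mean(a) - mean(b)) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (length(a) - 1) + v2^2 / (length(b) - 1))
  list(t = t, p = 2 * pt(-abs(t), df))
}

# classical pooled-variance two-sample t
oracle_pooled_t <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  sp2 <- ((n1 - 1) * var(a) + (n2 - 1) * var(b)) / (n1 + n2 - 2)
  (mean(a) - mean(b)) / sqrt(sp2 * (1 / n1 + 1 / n2))
}

# Benjamini-Hochberg step-up by explicit sort
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(n)
  out[o] <- adj
  out
}

# polygon area by the shoelace formula (closed matrix input)
oracle_area <- function(poly) {
  v <- poly[-nrow(poly), , drop = FALSE]
  x <- v[, 1]; y <- v[, 2]
  j <- c(seq_len(nrow(v))[-1], 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}
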