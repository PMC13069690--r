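#' Spatial enrichment index
#'
#' For each gene, the SEI is the spatial-weight-weighted mean expression
#' across cells; dividing by the unweighted mean (plus a small \code{epsilon}
#' guarding against zero means) gives the normalized SEI, whose baseline
#' value is 1 under uniform weights. Genes with normalized SEI well above 1
#' are enriched where the weights are high (near the boundary or centroid the
#' weights were derived from).
#'
#' @param expr Gene-by-cell expression matrix.
#' @param weights A \code{weight_vector} (matched by cell id) or numeric
#'   vector aligned with the expression columns; must not be all zero.
#' @param epsilon Stabilizing constant in the denominator; default 1e-6.
#' @return A data.frame with columns \code{gene}, \code{sei}, \code{mu}
#'   (unweighted mean), \code{norm_sei}, \code{n_cells}, sorted by
#'   \code{norm_sei} descending (ties by gene id); \code{epsilon} is attached
#'   as an attribute.
#' @export
compute_sei <- function(expr, weights, epsilon = 1e-6) {
  if (inherits(weights, "weight_vector") ||
      (is.data.frame(weights) && all(c("cell", "weight") %in% names(weights)))) {
    m <- match(colnames(expr), weights$cell)
    if (any(is.na(m))) {
      stop("weights are missing ", sum(is.na(m)), " of the expression cells")
    }
    w <- weights$weight[m]
  } else {
    w <- as.numeric(weights)
    if (length(w) != ncol(expr)) {
      stop("weight length does not match expression cell count")
    }
  }
  if (sum(w) <= 0) stop("weights must have a positive sum")
  em <- as.matrix(expr)
  sei <- as.numeric(em %*% w) / sum(w)
  mu <- rowMeans(em)
  out <- data.frame(gene = rownames(expr),
                    sei = sei,
                    mu = mu,
                    norm_sei = sei / (mu + epsilon),
                    n_cells = ncol(expr),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$norm_sei, out$gene), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "epsilon") <- epsilon
  out
}

#' Spearman correlation between a gene's expression and spatial weights
#'
#' @param expr_gene Numeric expression vector for one gene, aligned with
#'   \code{weights} (or named by cell id when \code{weights} is a
#'   \code{weight_vector}).
#' @param weights A \code{weight_vector} or numeric vector.
#' @param nonzero_only Drop cells with zero expression before ranking
#'   (default TRUE, matching how expression-weight scatter is usually read on
#'   sparse panels).
#' @return A list with \code{rho} (Spearman correlation, average-rank ties),
#'   \code{n} (cells used) and \code{ok} (FALSE when the correlation is
#'   undefined because expression or weights have no variation; \code{rho}
#'   is then \code{NA} rather than an error).
#' @export
correlate_expression_weights <- function(expr_gene, weights,
                                         nonzero_only = TRUE) {
  if (inherits(weights, "weight_vector") ||
      (is.data.frame(weights) && all(c("cell", "weight") %in% names(weights)))) {
    if (!is.null(names(expr_gene))) {
      m <- match(names(expr_gene), weights$cell)
      if (any(is.na(m))) stop("weights are missing some expression cells")
      w <- weights$weight[m]
    } else {
      if (length(expr_gene) != nrow(weights)) {
        stop("expression and weight lengths differ")
      }
      w <- weights$weight
    }
  } else {
    w <- as.numeric(weights)
    if (length(w) != length(expr_gene)) {
      stop("expression and weight lengths differ")
    }
  }
  y <- as.numeric(expr_gene)
  if (nonzero_only) {
    keep <- y != 0
    y <- y[keep]
    w <- w[keep]
  }
  if (length(y) < 3) stop("fewer than 3 usable cells for correlation")
  if (stats::sd(y) == 0 || stats::sd(w) == 0) {
    return(list(rho = NA_real_, n = length(y), ok = FALSE))
  }
  list(rho = stats::cor(y, w, method = "spearman"), n = length(y), ok = TRUE)
}

#' Mean expression across spatial-weight bins
#'
#' Summarises expression along a weight gradient: weights are cut into
#' \code{n_bins} equal-width bins over their range (right-closed, lowest bin
#' left-closed) and each gene's mean expression per bin is reported. Bins
#' with no cells are \code{NA}, not zero.
#'
#' @param expr Gene-by-cell expression matrix.
#' @param weights A \code{weight_vector} or numeric vector aligned with the
#'   expression columns.
#' @param n_bins Number of bins, >= 2 (default 10); 1 is allowed and gives
#'   the overall mean.
#' @return A gene x bin matrix of mean expression; columns labeled by bin
#'   midpoint.
#' @export
binned_expression <- function(expr, weights, n_bins = 10) {
  if (inherits(weights, "weight_vector") ||
      (is.data.frame(weights) && all(c("cell", "weight") %in% names(weights)))) {
    m <- match(colnames(expr), weights$cell)
    if (any(is.na(m))) stop("weights are missing some expression cells")
    w <- weights$weight[m]
  } else {
    w <- as.numeric(weights)
    if (length(w) != ncol(expr)) {
      stop("weight length does not match expression cell count")
    }
  }
  n_bins <- as.integer(n_bins)
  if (n_bins < 1) stop("n_bins must be >= 1")
  rng <- range(w)
  if (rng[1] == rng[2] || n_bins == 1) {
    out <- matrix(rowMeans(as.matrix(expr)), ncol = 1,
                  dimnames = list(rownames(expr), sprintf("%.6g", mean(rng))))
    return(out)
  }
  breaks <- seq(rng[1], rng[2], length.out = n_bins + 1)
  bin <- cut(w, breaks = breaks, include.lowest = TRUE, right = TRUE)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  em <- as.matrix(expr)
  out <- matrix(NA_real_, nrow(em), n_bins,
                dimnames = list(rownames(em), sprintf("%.6g", mids)))
  for (b in seq_len(n_bins)) {
    sel <- which(as.integer(bin) == b)
    if (length(sel) > 0) {
      out[, b] <- rowMeans(em[, sel, drop = FALSE])
    }
  }
  out
}
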