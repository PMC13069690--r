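#' Cluster-to-cluster spatial interaction matrix
#'
#' For every cell, finds its \code{k_neighbors} nearest spatial neighbors
#' (Euclidean distance, self excluded, ties broken by ascending cell index)
#' and tabulates neighbor cluster identities against the focal cell's
#' cluster. Entry (i, j) counts how often cells of cluster i have a cluster-j
#' cell among their k nearest neighbors, so every row i sums to
#' \code{k_neighbors} times the size of cluster i.
#'
#' Neighbors are computed over exactly the cell table passed in; to restrict
#' the analysis to, say, ring-localized cells, pass that subset.
#'
#' @param cells A validated cell table.
#' @param k_neighbors Neighborhood size; default 10. Must be smaller than the
#'   cell count.
#' @return An \code{interaction_matrix} object: list with \code{counts}
#'   (integer matrix with cluster labels as dimnames, rows = focal cluster),
#'   \code{clusters} and \code{k_neighbors}.
#' @export
compute_interaction_matrix <- function(cells, k_neighbors = 10) {
  validate_cell_table(cells)
  n <- nrow(cells)
  if (!is.numeric(k_neighbors) || k_neighbors < 1 || k_neighbors >= n) {
    stop("k_neighbors must satisfy 1 <= k < number of cells (", n, ")")
  }
  k_neighbors <- as.integer(k_neighbors)
  cl <- as.character(cells$cluster)
  labels <- sort(unique(cl))
  nn <- .knn_search(cbind(cells$x, cells$y), k_neighbors)
  focal <- factor(rep(cl, k_neighbors), levels = labels)
  neigh <- factor(cl[as.vector(nn$index)], levels = labels)
  counts <- table(focal, neigh)
  counts <- matrix(as.integer(counts), nrow = length(labels),
                   dimnames = list(labels, labels))
  structure(list(counts = counts, clusters = labels,
                 k_neighbors = k_neighbors),
            class = "interaction_matrix")
}

#' @export
print.interaction_matrix <- function(x, ...) {
  cat("interaction_matrix (k =", x$k_neighbors, "):\n")
  print(x$counts)
  invisible(x)
}

#' Row-scale an interaction matrix
#'
#' Raw neighbor counts are dominated by cluster sizes; row scaling makes
#' enriched associations visible. \code{row_prop} converts each row to
#' proportions of its sum; \code{row_z} standardizes each row to mean 0 and
#' unit standard deviation (constant rows map to all zeros).
#'
#' @param m An \code{interaction_matrix}.
#' @param mode \code{"row_z"} or \code{"row_prop"}.
#' @return The numeric scaled matrix, with the mode in the \code{"mode"}
#'   attribute.
#' @export
scale_interaction_matrix <- function(m, mode = c("row_z", "row_prop")) {
  mode <- match.arg(mode)
  counts <- if (inherits(m, "interaction_matrix")) m$counts else as.matrix(m)
  out <- t(apply(counts, 1, function(r) {
    if (mode == "row_prop") {
      if (sum(r) == 0) rep(0, length(r)) else r / sum(r)
    } else {
      s <- stats::sd(r)
      if (is.na(s) || s == 0) rep(0, length(r)) else (r - mean(r)) / s
    }
  }))
  dimnames(out) <- dimnames(counts)
  attr(out, "mode") <- mode
  out
}

#' Write an interaction matrix (and optionally its scaled form) as TSV
#'
#' @param m An \code{interaction_matrix} or plain matrix.
#' @param path Output path; cluster labels become row/column headers.
#' @return \code{path}, invisibly.
#' @export
write_interaction_matrix <- function(m, path) {
  counts <- if (inherits(m, "interaction_matrix")) m$counts else as.matrix(m)
  df <- data.frame(cluster = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
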