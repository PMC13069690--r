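# run expr with a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  expr
}

#' Configuration for a synthetic tissue
#'
#' Describes a simulated tissue: a planar cell layout with cluster structure,
#' and a log-scale expression matrix containing cluster marker genes,
#' spatial-gradient genes and null genes. The simulator emulates the
#' *modeling* assumptions of the analysis stack (normalized log expression
#' with Gaussian noise and zero-inflation), not the sequencing process, so
#' there is no count sampling.
#'
#' Layouts:
#' \describe{
#'   \item{two_blobs}{two well-separated round clusters (A larger than B);
#'     gradient covariate = normalized distance to the tissue centroid.}
#'   \item{nested_disc}{inner disc (cluster A) surrounded by an annulus
#'     (cluster B); gradient covariate = normalized distance to the disc
#'     center, whose generating boundary is the circle separating the two.}
#'   \item{half_planes}{left/right half clusters split by a vertical line;
#'     gradient covariate = normalized x position.}
#'   \item{zones_1d}{three vertical zones A, B, C (liver-zonation-like);
#'     gradient covariate = normalized x position.}
#' }
#'
#' @param n_cells Number of cells (>= 20); default 400.
#' @param layout One of \code{"two_blobs"}, \code{"nested_disc"},
#'   \code{"half_planes"}, \code{"zones_1d"}.
#' @param domain Bounding box \code{c(xmin, xmax, ymin, ymax)} in abstract
#'   length units; default \code{c(0, 1000, 0, 1000)}.
#' @param n_marker_genes,n_gradient_genes,n_null_genes Gene counts per
#'   category; total must be >= 1.
#' @param baseline Baseline log expression; default 1.
#' @param marker_effect Mean log-scale shift of a marker in its cluster;
#'   default 1.
#' @param gradient_slope Log-scale change of a gradient gene across the full
#'   covariate range; default 2.
#' @param noise_sd Gaussian noise standard deviation on the log scale, > 0;
#'   default 0.5.
#' @param dropout_rate Zero-inflation probability in [0, 1); default 0.1.
#' @param seed RNG seed; default 1.
#' @return A \code{tissue_config} list.
#' @export
synthetic_tissue_config <- function(n_cells = 400,
                                    layout = c("nested_disc", "two_blobs",
                                               "half_planes", "zones_1d"),
                                    domain = c(0, 1000, 0, 1000),
                                    n_marker_genes = 20,
                                    n_gradient_genes = 20,
                                    n_null_genes = 20,
                                    baseline = 1,
                                    marker_effect = 1,
                                    gradient_slope = 2,
                                    noise_sd = 0.5,
                                    dropout_rate = 0.1,
                                    seed = 1) {
  layout <- match.arg(layout)
  if (n_cells < 20) stop("n_cells must be >= 20")
  if (n_marker_genes + n_gradient_genes + n_null_genes < 1) {
    stop("at least one gene required")
  }
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0")
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must be in [0, 1)")
  structure(list(n_cells = as.integer(n_cells), layout = layout,
                 domain = domain,
                 n_marker_genes = as.integer(n_marker_genes),
                 n_gradient_genes = as.integer(n_gradient_genes),
                 n_null_genes = as.integer(n_null_genes),
                 baseline = baseline, marker_effect = marker_effect,
                 gradient_slope = gradient_slope, noise_sd = noise_sd,
                 dropout_rate = dropout_rate, seed = as.integer(seed)),
            class = "tissue_config")
}

#' Small reference fixture: 400 cells x 60 genes
#' @param seed RNG seed; default 1.
#' @return A \code{tissue_config}.
#' @export
small_tissue_config <- function(seed = 1) {
  synthetic_tissue_config(n_cells = 400, layout = "nested_disc",
                          n_marker_genes = 20, n_gradient_genes = 20,
                          n_null_genes = 20, seed = seed)
}

#' Medium fixture: 5000 cells x 300 genes
#' @param seed RNG seed; default 1.
#' @return A \code{tissue_config}.
#' @export
medium_tissue_config <- function(seed = 1) {
  synthetic_tissue_config(n_cells = 5000, layout = "nested_disc",
                          n_marker_genes = 100, n_gradient_genes = 100,
                          n_null_genes = 100, seed = seed)
}

#' Gradient benchmark fixture: 50 gradient genes among 1000
#'
#' 400 cells, 50 gradient genes at signal-to-noise |slope|/noise_sd = 4
#' (slope 2, noise 0.5) among 950 null genes; used for power, sign-recovery
#' and rank-concordance checks.
#'
#' @param seed RNG seed; default 1.
#' @return A \code{tissue_config}.
#' @export
gradient_bench_config <- function(seed = 1) {
  synthetic_tissue_config(n_cells = 400, layout = "nested_disc",
                          n_marker_genes = 0, n_gradient_genes = 50,
                          n_null_genes = 950, gradient_slope = 2,
                          noise_sd = 0.5, seed = seed)
}

#' Pure-null fixture: 1000 null genes, 200 cells
#' @param seed RNG seed; default 1.
#' @return A \code{tissue_config}.
#' @export
null_tissue_config <- function(seed = 1) {
  synthetic_tissue_config(n_cells = 200, layout = "nested_disc",
                          n_marker_genes = 0, n_gradient_genes = 0,
                          n_null_genes = 1000, seed = seed)
}

# circle polygon used as the generating boundary of the nested_disc layout
.circle_poly <- function(center, radius, n = 128) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  .poly_close(cbind(x = center[1] + radius * cos(th),
                    y = center[2] + radius * sin(th)))
}

#' Generate a synthetic tissue with known ground truth
#'
#' Draws cell coordinates per the configured layout, assigns cluster labels,
#' and simulates log-scale expression: marker genes get
#' \code{baseline + marker_effect} in their cluster, gradient genes follow
#' \code{baseline + slope * g} (direction +1) or
#' \code{baseline + slope * (1 - g)} (direction -1) where \code{g} in [0, 1]
#' is the layout's normalized spatial covariate, and null genes sit at
#' baseline. Gaussian noise, zero-inflation at \code{dropout_rate} and
#' clamping at 0 are applied to every gene. Fully reproducible from the
#' config seed.
#'
#' @param config A \code{tissue_config} from
#'   \code{\link{synthetic_tissue_config}}.
#' @return A list with \code{cells} (cell table), \code{expr} (gene x cell
#'   matrix), and \code{truth}: per-gene table (\code{gene},
#'   \code{category}, \code{cluster}, \code{direction}), the per-cell
#'   covariate \code{g}, and the generating \code{geometry} (boundary
#'   polygon for \code{nested_disc}, otherwise \code{NULL}).
#' @export
generate_tissue <- function(config) {
  stopifnot(inherits(config, "tissue_config"))
  .with_seed(config$seed, {
    n <- config$n_cells
    dm <- config$domain
    w <- dm[2] - dm[1]; h <- dm[4] - dm[3]
    ctr <- c(dm[1] + w / 2, dm[3] + h / 2)
    geometry <- NULL
    if (config$layout == "two_blobs") {
      n1 <- round(0.6 * n); n2 <- n - n1
      c1 <- c(dm[1] + 0.3 * w, ctr[2]); c2 <- c(dm[1] + 0.75 * w, ctr[2])
      sdb <- 0.05 * w
      x <- c(stats::rnorm(n1, c1[1], sdb), stats::rnorm(n2, c2[1], sdb))
      y <- c(stats::rnorm(n1, c1[2], sdb), stats::rnorm(n2, c2[2], sdb))
      cl <- rep(c("A", "B"), c(n1, n2))
      g <- normalize_minmax(sqrt((x - ctr[1])^2 + (y - ctr[2])^2))
    } else if (config$layout == "nested_disc") {
      n1 <- round(0.4 * n); n2 <- n - n1
      r1 <- 0.2 * min(w, h); r2 <- 0.45 * min(w, h)
      # uniform-in-area radii
      rad <- c(r1 * sqrt(stats::runif(n1)),
               sqrt(stats::runif(n2, r1^2, r2^2)))
      th <- stats::runif(n, 0, 2 * pi)
      x <- ctr[1] + rad * cos(th)
      y <- ctr[2] + rad * sin(th)
      cl <- rep(c("A", "B"), c(n1, n2))
      g <- normalize_minmax(rad)
      geometry <- .circle_poly(ctr, r1)
    } else if (config$layout == "half_planes") {
      x <- stats::runif(n, dm[1], dm[2])
      y <- stats::runif(n, dm[3], dm[4])
      cl <- ifelse(x < ctr[1], "A", "B")
      g <- normalize_minmax(x)
    } else {                               # zones_1d
      x <- stats::runif(n, dm[1], dm[2])
      y <- stats::runif(n, dm[3], dm[4])
      zone <- cut(x, breaks = dm[1] + w * c(0, 1 / 3, 2 / 3, 1),
                  labels = c("A", "B", "C"), include.lowest = TRUE)
      cl <- as.character(zone)
      g <- normalize_minmax(x)
    }
    cells <- data.frame(cell = sprintf("cell_%05d", seq_len(n)),
                        x = x, y = y, cluster = cl,
                        stringsAsFactors = FALSE)
    # gene truth table
    nm <- config$n_marker_genes; ng <- config$n_gradient_genes
    nn <- config$n_null_genes
    clusters <- sort(unique(cl))
    truth <- data.frame(
      gene = c(if (nm > 0) sprintf("marker_%04d", seq_len(nm)),
               if (ng > 0) sprintf("gradient_%04d", seq_len(ng)),
               if (nn > 0) sprintf("null_%04d", seq_len(nn))),
      category = rep(c("marker", "gradient", "null"), c(nm, ng, nn)),
      cluster = NA_character_,
      direction = NA_integer_,
      stringsAsFactors = FALSE)
    if (nm > 0) {
      truth$cluster[truth$category == "marker"] <-
        rep_len(clusters, nm)
    }
    if (ng > 0) {
      truth$direction[truth$category == "gradient"] <-
        rep_len(c(1L, -1L), ng)
    }
    ngene <- nrow(truth)
    mean_mat <- matrix(config$baseline, ngene, n,
                       dimnames = list(truth$gene, cells$cell))
    for (i in which(truth$category == "marker")) {
      mean_mat[i, cl == truth$cluster[i]] <-
        config$baseline + config$marker_effect
    }
    for (i in which(truth$category == "gradient")) {
      gg <- if (truth$direction[i] > 0) g else 1 - g
      mean_mat[i, ] <- config$baseline + config$gradient_slope * gg
    }
    expr <- mean_mat + matrix(stats::rnorm(ngene * n, 0, config$noise_sd),
                              ngene, n)
    if (config$dropout_rate > 0) {
      drop <- matrix(stats::runif(ngene * n) < config$dropout_rate, ngene, n)
      expr[drop] <- 0
    }
    expr[expr < 0] <- 0
    list(cells = cells, expr = expr,
         truth = list(genes = truth, covariate = g, geometry = geometry,
                      config = config))
  })
}

#' Write a synthetic tissue to disk
#'
#' Writes the standard file set into a directory: \code{coords.tsv},
#' \code{expr.mtx} (+ \code{expr.mtx.genes.txt}, \code{expr.mtx.cells.txt})
#' and \code{truth.tsv}.
#'
#' @param tissue Output of \code{\link{generate_tissue}}.
#' @param dir Output directory (created if missing).
#' @return \code{dir}, invisibly.
#' @export
write_tissue <- function(tissue, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_cell_table(tissue$cells, file.path(dir, "coords.tsv"))
  write_expression(tissue$expr, file.path(dir, "expr.mtx"))
  utils::write.table(tissue$truth$genes, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
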