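#' Natural cubic spline basis for a spatial covariate
#'
#' Wraps \code{splines::ns}: interior knots at equally spaced quantiles of
#' \code{t} (\code{df_spline - 1} of them), boundary knots at the range, and
#' basis functions linear beyond the boundary knots. No intercept column.
#'
#' @param t Numeric covariate (spatial distances or weights).
#' @param df_spline Degrees of freedom (basis columns); default 3.
#' @return An n x \code{df_spline} basis matrix.
#' @export
natural_spline_basis <- function(t, df_spline = 3) {
  if (!is.numeric(t) || any(!is.finite(t))) stop("covariate must be finite numeric")
  df_spline <- as.integer(df_spline)
  if (df_spline < 1) stop("df_spline must be >= 1")
  nu <- length(unique(t))
  if (nu < df_spline + 2) {
    stop("degenerate covariate: only ", nu, " distinct values, need at least ",
         df_spline + 2)
  }
  unclass(splines::ns(t, df = df_spline))
}

#' Orthonormal spatial design from a covariate
#'
#' Builds the design used by spline-based gradient testing: the covariate
#' \code{t} and its natural-spline basis are assembled as \code{[1, t, ns(t)]},
#' the non-intercept block is centered against the constant vector, and a
#' column-pivoted QR keeps the first \code{df_spline} orthonormal directions
#' (rank tolerance 1e-10 relative to the largest R diagonal). Because a
#' natural spline already spans the linear trend, the augmented block is
#' rank-deficient by construction and the QR keeps exactly \code{df_spline}
#' independent directions. The first column is sign-flipped if needed so it
#' correlates positively with \code{t}, making a positive first coefficient
#' mean "expression increases along the covariate".
#'
#' @param t Numeric covariate vector.
#' @param df_spline Spline degrees of freedom; default 3.
#' @return A \code{spatial_design} object: list with \code{t}, \code{df_spline},
#'   \code{X} (raw spline basis), \code{Z} (n x df orthonormal, centered),
#'   \code{sign_flipped}.
#' @export
build_spatial_design <- function(t, df_spline = 3) {
  X <- natural_spline_basis(t, df_spline = df_spline)
  df_spline <- ncol(X)
  B <- cbind(t, X)
  B <- sweep(B, 2, colMeans(B))            # center against the constant vector
  qrB <- qr(B)                             # LINPACK QR pivots near-dependent columns
  dR <- abs(diag(qr.R(qrB)))[seq_len(min(dim(B)))]
  rank <- sum(dR > 1e-10 * max(dR))
  if (rank < df_spline) {
    stop("rank deficiency: centered design has rank ", rank,
         " but df_spline = ", df_spline)
  }
  Z <- qr.Q(qrB)[, seq_len(df_spline), drop = FALSE]
  flipped <- FALSE
  if (stats::cor(Z[, 1], t) < 0) {
    Z[, 1] <- -Z[, 1]
    flipped <- TRUE
  }
  structure(list(t = t, df_spline = df_spline, X = X, Z = Z,
                 sign_flipped = flipped),
            class = "spatial_design")
}

#' Per-gene ordinary least squares fits against a shared design
#'
#' @param expr Gene-by-cell expression matrix (dense or sparse); columns must
#'   align with the design rows.
#' @param design n x p design matrix including an intercept column; must be
#'   full rank with n > p.
#' @return A list with \code{coefficients} (genes x p), \code{sigma2}
#'   (residual variances), \code{df_residual}, \code{stdev_unscaled}
#'   (sqrt of the diagonal of \code{(D'D)^{-1}}), and \code{design}.
#' @export
fit_linear_models <- function(expr, design) {
  design <- as.matrix(design)
  n <- nrow(design)
  p <- ncol(design)
  if (ncol(expr) != n) {
    stop("expression has ", ncol(expr), " cells but design has ", n, " rows")
  }
  qrD <- qr(design)
  if (qrD$rank < p) stop("design matrix is rank deficient (rank ", qrD$rank,
                         " < ", p, " columns)")
  if (n <= p) stop("need more observations than design columns")
  Y <- t(as.matrix(expr))                  # n x genes
  coef <- qr.coef(qrD, Y)
  resid <- qr.resid(qrD, Y)
  df_res <- n - p
  sigma2 <- colSums(resid^2) / df_res
  xtxi <- chol2inv(chol(crossprod(design)))
  list(coefficients = t(coef),
       sigma2 = as.numeric(sigma2),
       df_residual = df_res,
       stdev_unscaled = sqrt(diag(xtxi)),
       design = design)
}

# inverse of the trigamma function by 1D root finding; x is the target value,
# the root for d0/2 is bracketed in [1e-2, 1e4]
.trigamma_inverse <- function(x) {
  lo <- 1e-2; hi <- 1e4
  if (x >= trigamma(lo)) return(lo)
  if (x <= trigamma(hi)) return(hi)
  stats::uniroot(function(y) trigamma(y) - x, c(lo, hi), tol = 1e-10)$root
}

#' Empirical-Bayes moderation of per-gene residual variances
#'
#' Shrinks each gene's residual variance toward a pooled prior, gaining
#' \code{d0} prior degrees of freedom for downstream t/F tests. The prior is
#' fitted by moment matching on log variances: with \code{z = log(s^2)},
#' the mean and excess variance of \code{z - digamma(d/2) + log(d/2)} are
#' matched to the digamma/trigamma moments of a scaled inverse-chi-squared
#' prior. When the log variances show no excess dispersion beyond sampling
#' noise, \code{d0} is infinite and every posterior variance equals the prior
#' variance.
#'
#' @param s2 Per-gene residual variances.
#' @param df Residual degrees of freedom (shared across genes).
#' @param d0 Optional override of the prior degrees of freedom; \code{0}
#'   bypasses moderation (posterior = observed), \code{Inf} forces full
#'   pooling.
#' @return A list with \code{d0}, \code{s02} (prior variance),
#'   \code{s2_post} (posterior variances), \code{df_total} (= d0 + df, capped
#'   at \code{df} when \code{d0 = 0}), and \code{degenerate} (TRUE when all
#'   variances were zero).
#' @export
squeeze_variances <- function(s2, df, d0 = NULL) {
  s2 <- as.numeric(s2)
  if (all(s2 == 0)) {
    return(list(d0 = Inf, s02 = 0, s2_post = rep(0, length(s2)),
                df_total = Inf, degenerate = TRUE))
  }
  if (!is.null(d0)) {
    if (d0 == 0) {
      return(list(d0 = 0, s02 = NA_real_, s2_post = s2, df_total = df,
                  degenerate = FALSE))
    }
    if (is.infinite(d0)) {
      s02 <- mean(s2)
      return(list(d0 = Inf, s02 = s02, s2_post = rep(s02, length(s2)),
                  df_total = Inf, degenerate = FALSE))
    }
  }
  pos <- s2 > 0
  if (sum(pos) < 2) stop("need at least 2 genes with positive variance")
  z <- log(s2[pos])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.null(d0)) {
    if (!is.finite(evar) || evar <= 0) {
      d0 <- Inf
    } else {
      d0 <- 2 * .trigamma_inverse(evar)
    }
  }
  if (is.infinite(d0)) {
    s02 <- exp(emean)
    s2_post <- rep(s02, length(s2))
    df_total <- Inf
  } else {
    s02 <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s02 + df * s2) / (d0 + df)
    df_total <- d0 + df
  }
  list(d0 = d0, s02 = s02, s2_post = s2_post, df_total = df_total,
       degenerate = FALSE)
}

# shared detection-fraction filter; returns logical keep vector
.min_pct_keep <- function(expr_a, expr_b, min_pct) {
  pct_a <- Matrix::rowMeans(expr_a > 0)
  pct_b <- Matrix::rowMeans(expr_b > 0)
  list(pct_a = as.numeric(pct_a), pct_b = as.numeric(pct_b),
       keep = pmax(pct_a, pct_b) >= min_pct)
}

#' Moderated two-group differential expression
#'
#' Fits, per gene, the linear model \code{y = intercept + effect * I(group A)}
#' over the cells of the two groups, moderates the residual variances by
#' empirical Bayes (\code{\link{squeeze_variances}}), and tests the group
#' coefficient with a moderated t on \code{d0 + d} degrees of freedom.
#' Expression is assumed log-scale upstream, so the group coefficient is the
#' log fold change of A over B in the upstream log base (reported unchanged).
#'
#' @param expr Gene-by-cell expression matrix.
#' @param cells_a,cells_b Disjoint cell id vectors, each of length >= 2; all
#'   ids must be expression columns.
#' @param min_pct Genes detected (expression > 0) in less than this fraction
#'   of cells in both groups are excluded before testing; default 0. Excluded
#'   gene ids are attached as the \code{"excluded_genes"} attribute.
#' @param d0 Optional prior-df override passed to
#'   \code{\link{squeeze_variances}} (\code{0} gives the classical t).
#' @return A data.frame (one row per tested gene) with columns \code{gene},
#'   \code{effect} (log fold change), \code{statistic} (moderated t),
#'   \code{p}, \code{adj_p} (Benjamini-Hochberg), \code{pct_a}, \code{pct_b},
#'   sorted by \code{adj_p} then decreasing \code{|effect|}.
#' @export
run_group_de <- function(expr, cells_a, cells_b, min_pct = 0, d0 = NULL) {
  cells_a <- as.character(cells_a)
  cells_b <- as.character(cells_b)
  if (length(intersect(cells_a, cells_b)) > 0) stop("groups overlap")
  if (length(cells_a) < 2 || length(cells_b) < 2) {
    stop("each group needs at least 2 cells")
  }
  missing <- setdiff(c(cells_a, cells_b), colnames(expr))
  if (length(missing) > 0) {
    stop("cell ids absent from expression matrix: ", missing[1],
         if (length(missing) > 1) paste0(" (+", length(missing) - 1, " more)"))
  }
  ea <- expr[, cells_a, drop = FALSE]
  eb <- expr[, cells_b, drop = FALSE]
  det <- .min_pct_keep(ea, eb, min_pct)
  keep <- det$keep
  if (!any(keep)) stop("no genes pass the min_pct filter")
  sub <- cbind(as.matrix(ea), as.matrix(eb))[keep, , drop = FALSE]
  design <- cbind(intercept = 1,
                  group_a = rep(c(1, 0), c(length(cells_a), length(cells_b))))
  fit <- fit_linear_models(sub, design)
  sq <- squeeze_variances(fit$sigma2, fit$df_residual, d0 = d0)
  tstat <- fit$coefficients[, 2] / (fit$stdev_unscaled[2] * sqrt(sq$s2_post))
  p <- 2 * stats::pt(-abs(tstat), df = sq$df_total)
  out <- data.frame(gene = rownames(sub),
                    effect = as.numeric(fit$coefficients[, 2]),
                    statistic = as.numeric(tstat),
                    p = as.numeric(p),
                    adj_p = stats::p.adjust(p, method = "BH"),
                    pct_a = det$pct_a[keep],
                    pct_b = det$pct_b[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(out$adj_p, -abs(out$effect)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded_genes") <- rownames(expr)[!keep]
  attr(out, "d0") <- sq$d0
  out
}

#' One-vs-rest marker detection per cluster
#'
#' Runs \code{\link{run_group_de}} for every cluster against all remaining
#' cells, yielding a marker table per cluster.
#'
#' @param expr Gene-by-cell expression matrix.
#' @param cells Cell table whose \code{cluster} column defines the groups
#'   (>= 2 clusters, each with >= 2 cells).
#' @param min_pct Detection-fraction filter, as in \code{\link{run_group_de}}.
#' @return A named list of DE tables, one per cluster label.
#' @export
run_marker_de <- function(expr, cells, min_pct = 0) {
  validate_cell_table(cells)
  cl <- as.character(cells$cluster)
  labels <- sort(unique(cl))
  if (length(labels) < 2) stop("need at least 2 clusters for marker detection")
  ids <- as.character(cells$cell)
  out <- lapply(labels, function(lab) {
    run_group_de(expr, ids[cl == lab], ids[cl != lab], min_pct = min_pct)
  })
  names(out) <- labels
  out
}

#' Spline-based spatial gradient differential expression
#'
#' Tests, per gene, whether expression varies smoothly along a spatial
#' covariate (distances or decay weights). The covariate is expanded into the
#' orthonormal design of \code{\link{build_spatial_design}}; each gene is fit
#' as \code{y = intercept + Z beta}, variances are moderated, and the
#' \code{df_spline} coefficients are tested jointly with a moderated F on
#' (\code{df_spline}, \code{d0 + d}) degrees of freedom. The first
#' coefficient ("Z1") is reported as the effect and its sign as the trend
#' direction: positive means expression increases with the covariate.
#'
#' @param expr Gene-by-cell expression matrix.
#' @param covariate A \code{weight_vector} (matched to expression columns by
#'   cell id) or a numeric vector aligned with the columns of \code{expr}.
#' @param df_spline Spline degrees of freedom; default 3.
#' @param d0 Optional prior-df override (see \code{\link{squeeze_variances}}).
#' @return A data.frame with columns \code{gene}, \code{effect} (Z1
#'   coefficient), \code{statistic} (moderated F), \code{p}, \code{adj_p},
#'   \code{trend_sign}, plus per-coefficient moderated t columns
#'   \code{t_Z1..t_Zk}; sorted by \code{adj_p} then decreasing
#'   \code{|effect|}.
#' @export
run_spatial_de <- function(expr, covariate, df_spline = 3, d0 = NULL) {
  if (inherits(covariate, "weight_vector") ||
      (is.data.frame(covariate) && all(c("cell", "weight") %in% names(covariate)))) {
    m <- match(colnames(expr), covariate$cell)
    if (any(is.na(m))) {
      stop("covariate is missing ", sum(is.na(m)), " of the expression cells")
    }
    t <- covariate$weight[m]
  } else {
    t <- as.numeric(covariate)
    if (length(t) != ncol(expr)) {
      stop("covariate length ", length(t), " does not match ", ncol(expr),
           " expression cells")
    }
  }
  des <- build_spatial_design(t, df_spline = df_spline)
  k <- des$df_spline
  design <- cbind(intercept = 1, des$Z)
  fit <- fit_linear_models(expr, design)
  sq <- squeeze_variances(fit$sigma2, fit$df_residual, d0 = d0)
  beta <- fit$coefficients[, -1, drop = FALSE]
  denom <- sq$s2_post
  fstat <- rowSums(beta^2) / k / denom
  p <- stats::pf(fstat, df1 = k, df2 = sq$df_total, lower.tail = FALSE)
  tcols <- beta / sqrt(denom)              # Z'Z = I, so unscaled stdev = 1
  colnames(tcols) <- paste0("t_Z", seq_len(k))
  out <- data.frame(gene = rownames(expr),
                    effect = as.numeric(beta[, 1]),
                    statistic = as.numeric(fstat),
                    p = as.numeric(p),
                    adj_p = stats::p.adjust(p, method = "BH"),
                    trend_sign = sign(as.numeric(beta[, 1])),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(tcols))
  out <- out[order(out$adj_p, -abs(out$effect)), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "d0") <- sq$d0
  attr(out, "design") <- des
  out
}

#' Write a DE table as TSV
#'
#' @param de A DE table from \code{\link{run_group_de}} or
#'   \code{\link{run_spatial_de}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_de_table <- function(de, path) {
  utils::write.table(de, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}
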