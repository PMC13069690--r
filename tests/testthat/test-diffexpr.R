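expr_mat <- function(m, genes = NULL, cells = NULL) {
  if (is.null(genes)) genes <- sprintf("g%03d", seq_len(nrow(m)))
  if (is.null(cells)) cells <- sprintf("c%03d", seq_len(ncol(m)))
  dimnames(m) <- list(genes, cells)
  m
}

test_that("natural spline basis has the right shape and tail linearity", {
  t <- seq(0, 1, length.out = 100)
  X <- natural_spline_basis(t, df_spline = 3)
  expect_equal(dim(X), c(100, 3))
  # natural splines are linear beyond the boundary knots: second differences
  # of each basis function evaluated outside [min, max] vanish
  t_out <- c(-3, -2, -1, 2, 3, 4)
  Xo <- unclass(splines::ns(t, df = 3))
  pred <- splines::ns(t, df = 3)
  Xout <- predict(pred, t_out)
  for (j in 1:3) {
    expect_equal(diff(diff(Xout[1:3, j])), 0, tolerance = 1e-10)
    expect_equal(diff(diff(Xout[4:6, j])), 0, tolerance = 1e-10)
  }
  expect_error(natural_spline_basis(rep(1, 50)), "degenerate")
  expect_error(natural_spline_basis(c(0, 1, 0, 1), df_spline = 3), "degenerate")

  X1 <- natural_spline_basis(t, df_spline = 1)
  expect_equal(ncol(X1), 1)
  expect_true(all(diff(X1[, 1]) > 0) || all(diff(X1[, 1]) < 0))
})

test_that("spatial designs are orthonormal, centered, and sign-aligned", {
  set.seed(31)
  for (rep in 1:20) {
    t <- switch(1 + rep %% 3,
                runif(80), rexp(80), sort(rnorm(80)))
    des <- build_spatial_design(t, df_spline = 3)
    Z <- des$Z
    expect_lt(max(abs(crossprod(Z) - diag(3))), 1e-8)
    expect_lt(max(abs(colSums(Z))), 1e-8)
    expect_gt(cor(Z[, 1], t), 0)
  }
})

test_that("the design spans the centered covariate-plus-spline space", {
  t <- seq(0, 1, length.out = 50)
  des <- build_spatial_design(t, df_spline = 3)
  # independent orthonormalization: classical Gram-Schmidt on centered [t, X]
  B <- cbind(t, natural_spline_basis(t, 3))
  B <- sweep(B, 2, colMeans(B))
  G <- matrix(0, nrow(B), 0)
  for (j in seq_len(ncol(B))) {
    v <- B[, j]
    if (ncol(G) > 0) v <- v - G %*% crossprod(G, v)
    if (sqrt(sum(v^2)) > 1e-8) G <- cbind(G, v / sqrt(sum(v^2)))
  }
  expect_equal(ncol(G), 3)
  # projectors agree => spans agree
  P1 <- tcrossprod(des$Z)
  P2 <- tcrossprod(G)
  expect_lt(max(abs(P1 - P2)), 1e-8)
})

test_that("per-gene OLS recovers exact and noisy coefficients", {
  t <- seq(0, 1, length.out = 60)
  des <- build_spatial_design(t, 3)
  D <- cbind(1, des$Z)
  y_exact <- 3 * des$Z[, 1]
  set.seed(5)
  noise <- matrix(rnorm(60 * 200, sd = 0.7), 200, 60)
  expr <- expr_mat(rbind(y_exact, noise))
  fit <- fit_linear_models(expr, D)
  expect_equal(unname(fit$coefficients[1, 2]), 3, tolerance = 1e-10)
  expect_equal(fit$sigma2[1], 0, tolerance = 1e-18)
  expect_equal(fit$df_residual, 60 - 4)
  # pure-noise genes: mean residual variance near the truth, coefs near 0
  expect_lt(abs(mean(fit$sigma2[-1]) - 0.49), 3 * 0.49 * sqrt(2 / 56 / 200))
  expect_lt(max(abs(colMeans(fit$coefficients[-1, -1]))), 3 * 0.7 / sqrt(200))

  expect_error(fit_linear_models(expr, cbind(D, D[, 2])), "rank deficient")
})

test_that("variance squeezing hits its limits and matches limma", {
  # zero dispersion of the log variances: infinite prior df, full pooling
  # (the digamma bias correction places the pooled value slightly above the
  # shared observed variance, exactly as limma does)
  s2 <- rep(0.8, 50)
  sq <- squeeze_variances(s2, df = 10)
  expect_equal(sq$d0, Inf)
  expect_equal(sq$s2_post, rep(sq$s02, 50), tolerance = 1e-12)
  expect_equal(sq$s02, 0.8 * exp(log(5) - digamma(5)), tolerance = 1e-12)

  set.seed(8)
  s2r <- 0.5 * rchisq(400, 15) / 15 * (4 / rchisq(400, 4))
  sq0 <- squeeze_variances(s2r, df = 15, d0 = 0)
  expect_identical(sq0$s2_post, s2r)

  skip_if_not_installed("limma")
  ours <- squeeze_variances(s2r, df = 15)
  ref <- limma::squeezeVar(s2r, df = 15)
  expect_equal(ours$d0, ref$df.prior, tolerance = 0.02 * ref$df.prior)
  expect_equal(ours$s02, ref$var.prior, tolerance = 0.02 * ref$var.prior)
  expect_equal(ours$s2_post, ref$var.post, tolerance = 0.02)

  degen <- squeeze_variances(rep(0, 5), df = 3)
  expect_true(degen$degenerate)
  expect_equal(degen$s02, 0)
})

test_that("the prior is recovered from scaled inverse-chi-squared truth", {
  d0_true <- 4; s02_true <- 1; d <- 20
  d0_hat <- s02_hat <- numeric(20)
  for (r in 1:20) {
    set.seed(100 + r)
    sigma2 <- d0_true * s02_true / rchisq(1000, d0_true)
    s2 <- sigma2 * rchisq(1000, d) / d
    sq <- squeeze_variances(s2, df = d)
    d0_hat[r] <- sq$d0
    s02_hat[r] <- sq$s02
  }
  expect_lt(abs(mean(d0_hat) - d0_true), 0.5 * d0_true)
  expect_lt(abs(mean(s02_hat) - s02_true), 0.2 * s02_true)
})

test_that("moderated t with d0 = 0 equals the classical pooled t", {
  set.seed(12)
  n <- 50
  expr <- expr_mat(matrix(rnorm(100 * n), 100, n))
  a <- colnames(expr)[1:25]
  b <- colnames(expr)[26:50]
  de <- run_group_de(expr, a, b, d0 = 0)
  de <- de[order(de$gene), ]
  t_ref <- apply(expr, 1, function(y) oracle_pooled_t(y[1:25], y[26:50]))
  expect_equal(de$statistic, unname(t_ref[order(names(t_ref))]),
               tolerance = 1e-8)
})

test_that("group DE recovers planted shifts and controls the null", {
  set.seed(1)
  n <- 200
  expr <- expr_mat(matrix(abs(rnorm(1000 * n)), 1000, n))
  a <- colnames(expr)[1:100]
  b <- colnames(expr)[101:200]
  de_null <- run_group_de(expr, a, b)
  expect_lte(mean(de_null$adj_p < 0.05), 0.05)

  # gene with group means differing by exactly 2 and near-zero noise
  y <- c(rep(3, 100), rep(1, 100)) + rnorm(n, sd = 1e-4)
  expr2 <- expr_mat(rbind(expr, planted = y),
                    genes = c(rownames(expr), "planted"))
  de2 <- run_group_de(expr2, a, b)
  row <- de2[de2$gene == "planted", ]
  expect_equal(row$effect, 2, tolerance = 1e-3)
  expect_lt(row$adj_p, 1e-10)
  expect_equal(de2$gene[1], "planted")          # sorted by adj_p

  # identical groups (same values, new ids): effect exactly 0
  dup <- expr[, a]
  colnames(dup) <- paste0("dup_", seq_len(ncol(dup)))
  expr3 <- cbind(expr[, a], dup)
  de3 <- run_group_de(expr3, a, colnames(dup))
  expect_equal(max(abs(de3$effect)), 0, tolerance = 1e-12)

  expect_error(run_group_de(expr, a, a), "overlap")
  expect_error(run_group_de(expr, a[1], b), "2 cells")
})

test_that("min_pct filtering excludes undetected genes and flags them", {
  set.seed(3)
  m <- matrix(runif(40, 0.5, 2), 4, 10)
  m[1, ] <- 0
  m[1, 1] <- 0.3                                 # detected in 10% of cells
  expr <- expr_mat(m)
  de <- run_group_de(expr, colnames(expr)[1:5], colnames(expr)[6:10],
                     min_pct = 0.25)
  expect_false("g001" %in% de$gene)
  expect_equal(attr(de, "excluded_genes"), "g001")
})

test_that("one-vs-rest markers are symmetric for 2 clusters and found for 3", {
  set.seed(6)
  cells <- random_cells(90, n_clusters = 2, seed = 6)
  expr <- expr_mat(matrix(abs(rnorm(30 * 90)), 30, 90),
                   cells = cells$cell)
  res <- run_marker_de(expr, cells)
  expect_named(res, c("A", "B"))
  a <- res$A[order(res$A$gene), ]
  b <- res$B[order(res$B$gene), ]
  expect_equal(a$effect, -b$effect, tolerance = 1e-12)

  # synthetic 3-cluster tissue with planted markers: 5 markers per cluster
  tis <- generate_tissue(synthetic_tissue_config(
    n_cells = 300, layout = "zones_1d", n_marker_genes = 15,
    n_gradient_genes = 0, n_null_genes = 30, marker_effect = 1.5, seed = 9))
  res3 <- run_marker_de(tis$expr, tis$cells)
  truth <- tis$truth$genes
  for (cl in names(res3)) {
    planted <- truth$gene[truth$category == "marker" &
                            !is.na(truth$cluster) & truth$cluster == cl]
    top10 <- utils::head(res3[[cl]]$gene[res3[[cl]]$effect > 0], 10)
    expect_true(all(planted %in% top10))
  }

  solo <- cells; solo$cluster <- "only"
  expect_error(run_marker_de(expr, solo), "2 clusters")
})

test_that("spatial DE detects planted linear trends with correct signs", {
  set.seed(1)
  n <- 300
  t <- runif(n)
  up <- 2 * t + rnorm(n, sd = sqrt(0.1))
  down <- -2 * t + 3 + rnorm(n, sd = sqrt(0.1))   # kept positive
  flat <- rnorm(n, mean = 1, sd = sqrt(0.1))
  expr <- expr_mat(rbind(up = up, down = down, flat = abs(flat)),
                   genes = c("up", "down", "flat"))
  de <- run_spatial_de(expr, t)
  de <- de[match(c("up", "down", "flat"), de$gene), ]
  expect_equal(de$trend_sign[1:2], c(1, -1))
  expect_lt(max(de$adj_p[1:2]), 0.05)
  expect_lt(abs(de$effect[3]), abs(de$effect[1]))
})

test_that("spatial DE statistics are invariant to affine covariate rescaling", {
  set.seed(44)
  n <- 120
  t <- runif(n)
  expr <- expr_mat(matrix(abs(rnorm(40 * n, mean = 1)), 40, n))
  de1 <- run_spatial_de(expr, t)
  de2 <- run_spatial_de(expr, 100 * t + 7)
  expect_equal(de1$statistic, de2$statistic, tolerance = 1e-8)
  expect_equal(de1$p, de2$p, tolerance = 1e-8)
  expect_equal(de1$trend_sign, de2$trend_sign)
})

test_that("BH adjustment equals the brute-force step-up", {
  set.seed(17)
  p <- runif(500)^1.7
  expect_equal(p.adjust(p, "BH"), oracle_bh(p), tolerance = 1e-14)
  de_p <- c(0.001, 0.01, 0.02, 0.5, 0.5, 1)
  expect_equal(p.adjust(de_p, "BH"), oracle_bh(de_p), tolerance = 1e-14)
})
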