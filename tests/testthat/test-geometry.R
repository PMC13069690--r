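make_cells <- function(xy, cluster = "a") {
  data.frame(cell = sprintf("c%03d", seq_len(nrow(xy))),
             x = xy[, 1], y = xy[, 2], cluster = cluster,
             stringsAsFactors = FALSE)
}

test_that("mean kNN outlier flagging matches hand-enumerated distances", {
  cells <- make_cells(cbind(c(0, 1, 2, 10), 0))
  rep1 <- remove_spatial_outliers(cells, k_outlier = 1, tau = 2)
  expect_equal(rep1$mean_knn_dist, c(1, 1, 1, 8))
  expect_equal(rep1$keep, c(TRUE, TRUE, TRUE, FALSE))

  # 3 equally spaced collinear points, k = 2: endpoints average (1+2)/2 = 1.5
  cells3 <- make_cells(cbind(c(0, 1, 2), 0))
  rep2 <- remove_spatial_outliers(cells3, k_outlier = 2, tau = 1.2)
  expect_equal(rep2$mean_knn_dist, c(1.5, 1, 1.5))
  expect_equal(rep2$keep, c(FALSE, TRUE, FALSE))

  expect_true(all(remove_spatial_outliers(cells, k_outlier = 2, tau = Inf)$keep))
  expect_error(remove_spatial_outliers(cells, k_outlier = 4, tau = 1), "k_outlier")
  expect_error(remove_spatial_outliers(cells, k_outlier = 1, tau = -1), "tau")
})

test_that("mean kNN distances agree with the brute-force oracle", {
  for (seed in 1:3) {
    cells <- random_cells(150, seed = seed)
    for (k in c(1, 5, 10)) {
      rep <- remove_spatial_outliers(cells, k_outlier = k, tau = Inf)
      expect_equal(rep$mean_knn_dist,
                   oracle_mean_knn(cbind(cells$x, cells$y), k),
                   tolerance = 1e-12)
    }
  }
})

test_that("subregion detection separates blobs and flags noise", {
  set.seed(7)
  xy <- rbind(cbind(rnorm(50, 0, 1), rnorm(50, 0, 1)),
              cbind(rnorm(50, 100, 1), rnorm(50, 0, 1)))
  lab <- detect_subregions(xy, "dbscan", eps = 5)
  expect_equal(sort(unique(lab)), c(1, 2))
  expect_true(all(lab[1:50] == lab[1]) && all(lab[51:100] == lab[51]))

  expect_equal(detect_subregions(xy[1:50, ], "kmeans", n_centers = 1),
               rep(1L, 50))
  expect_error(detect_subregions(xy, "dbscan", eps = 1e-6), "noise")
})

test_that("concave hull handles convex input, concave input, and degenerates", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  h <- concave_hull(square, concavity = 2)
  expect_equal(oracle_area(h), 1)
  expect_equal(nrow(h), 5)                      # closed

  # C-shape: the concave hull should dig into the opening
  set.seed(11)
  th <- runif(400, pi / 3, 2 * pi - pi / 3)
  r <- runif(400, 2, 3)
  cshape <- cbind(r * cos(th), r * sin(th))
  hc <- concave_hull(cshape, concavity = 1)
  chull_poly <- cshape[c(rev(chull(cshape)), rev(chull(cshape))[1]), ]
  expect_lt(oracle_area(hc), oracle_area(chull_poly))
  expect_true(all(sp::point.in.polygon(cshape[, 1], cshape[, 2],
                                       hc[, 1], hc[, 2]) > 0))
  # convex hull recovered in the infinite-concavity limit
  hinf <- concave_hull(cshape, concavity = Inf)
  expect_equal(oracle_area(hinf), oracle_area(chull_poly), tolerance = 1e-12)

  expect_error(concave_hull(rbind(c(0, 0), c(1, 1))), "degenerate")
  expect_error(concave_hull(rbind(c(0, 0), c(1, 1), c(2, 2))), "degenerate")
})

test_that("hull containment holds on random point sets", {
  for (seed in 1:5) {
    set.seed(seed)
    xy <- cbind(runif(200), runif(200))
    h <- concave_hull(xy, concavity = 2)
    expect_true(all(sp::point.in.polygon(xy[, 1], xy[, 2],
                                         h[, 1], h[, 2]) > 0))
    expect_gt(oracle_area(h), 0)
  }
})

test_that("get_boundary composes the pipeline and orders regions by area", {
  tis <- generate_tissue(synthetic_tissue_config(
    n_cells = 400, layout = "two_blobs", n_marker_genes = 1,
    n_gradient_genes = 0, n_null_genes = 0, seed = 3))
  # blob A is the larger blob; a single compact blob gives one region
  bs_b <- get_boundary(tis$cells, "B", tau = 200, eps = 60)
  expect_equal(length(bs_b$polygons), 1)

  # both blobs under one label: two regions, region 1 the larger
  cells2 <- tis$cells
  cells2$cluster <- "all"
  bs2 <- get_boundary(cells2, "all", tau = 500, eps = 60)
  expect_equal(length(bs2$polygons), 2)
  areas <- vapply(bs2$polygons, oracle_area, 0)
  expect_true(areas[1] >= areas[2])
  expect_equal(bs2$params$eps, 60)

  expect_error(get_boundary(tis$cells, "nope", tau = 1, eps = 1), "unknown cluster")
})

test_that("ring buffer area matches the Minkowski-sum formula for a square", {
  sq <- rbind(c(0, 0), c(2, 0), c(2, 2), c(0, 2), c(0, 0))
  ring <- build_ring_region(sq, dist = 1)
  # square side s buffered by r: area s^2 + 4 s r + pi r^2
  expect_equal(oracle_area(ring$outer), 12 + pi, tolerance = 0.01 * (12 + pi))
  ring_area <- oracle_area(ring$outer) - oracle_area(ring$inner)
  expect_equal(ring_area, 8 + pi, tolerance = 0.01 * (8 + pi))

  tiny <- build_ring_region(sq, dist = 1e-6)
  expect_lt(oracle_area(tiny$outer) - oracle_area(tiny$inner), 1e-4)
  expect_error(build_ring_region(sq, dist = -1), "dist")
})

test_that("cells_inside is boundary-inclusive and rings partition the outer set", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  cells <- make_cells(rbind(c(0.5, 0.5), c(2, 2), c(0, 0.5)))
  inside <- cells_inside(cells, sq)
  expect_equal(inside$cell, c("c001", "c003"))  # edge point included

  sq2 <- rbind(c(-1, -1), c(1, -1), c(1, 1), c(-1, 1), c(-1, -1))
  ring <- build_ring_region(sq2, dist = 1)
  probe <- make_cells(rbind(c(0, 0), c(1.5, 0)))
  in_ring <- cells_inside(probe, ring)
  expect_equal(in_ring$cell, "c002")            # center excluded, annulus kept

  # partition: inner + ring = outer, disjointly
  cells_many <- random_cells(300, seed = 5)
  cells_many$x <- cells_many$x / 20 - 2.5       # spread across the ring
  cells_many$y <- cells_many$y / 20 - 2.5
  s_in <- cells_inside(cells_many, ring$inner)
  s_ring <- cells_inside(cells_many, ring)
  s_out <- cells_inside(cells_many, ring$outer)
  expect_equal(sort(c(s_in$cell, s_ring$cell)), sort(s_out$cell))
  expect_length(intersect(s_in$cell, s_ring$cell), 0)
})

test_that("larger tau and larger dist never shrink the selections", {
  cells <- random_cells(120, seed = 9)
  r1 <- remove_spatial_outliers(cells, 5, tau = 8)
  r2 <- remove_spatial_outliers(cells, 5, tau = 16)
  expect_true(all(r1$cell[r1$keep] %in% r2$cell[r2$keep]))

  sq <- rbind(c(40, 40), c(60, 40), c(60, 60), c(40, 60), c(40, 40))
  ring_small <- build_ring_region(sq, dist = 5)
  ring_big <- build_ring_region(sq, dist = 15)
  c_small <- cells_inside(cells, ring_small)
  c_big <- cells_inside(cells, ring_big)
  expect_true(all(c_small$cell %in% c_big$cell))
})

test_that("composition tables and the per-ring Welch comparison behave", {
  sub <- make_cells(cbind(1:4, 1), cluster = c("a", "a", "a", "b"))
  tab <- stats_cells_inside(sub)
  expect_equal(tab$proportion, c(0.75, 0.25))
  expect_equal(tab$cluster, c("a", "b"))
  expect_equal(sum(tab$proportion), 1, tolerance = 1e-12)

  one <- stats_cells_inside(make_cells(cbind(1:3, 1), cluster = "z"))
  expect_equal(one$proportion, 1)
  tie <- stats_cells_inside(make_cells(cbind(1:4, 1),
                                       cluster = c("b", "b", "a", "a")))
  expect_equal(tie$cluster, c("a", "b"))        # tie broken by label
  expect_error(stats_cells_inside(sub[0, ]), "empty")

  comp <- function(p) data.frame(cluster = "T", count = 1, proportion = p)
  same <- list(comp(0.4), comp(0.4), comp(0.4))
  res_same <- compare_compositions(same, same)
  expect_equal(res_same$p, 1)

  a <- list(comp(0.9), comp(0.89), comp(0.91))
  b <- list(comp(0.1), comp(0.11), comp(0.09))
  res <- compare_compositions(a, b)
  expect_lt(res$p, 0.01)
  orc <- oracle_welch(c(0.9, 0.89, 0.91), c(0.1, 0.11, 0.09))
  expect_equal(res$t, orc$t, tolerance = 1e-12)
  expect_equal(res$p, orc$p, tolerance = 1e-12)

  # a cluster absent from a ring counts as proportion 0
  mixed_a <- list(data.frame(cluster = c("T", "U"), count = c(1, 1),
                             proportion = c(0.5, 0.5)),
                  comp(0.5))
  res_mix <- compare_compositions(mixed_a, list(comp(0.5), comp(0.5)))
  expect_true("U" %in% res_mix$cluster)
  expect_equal(res_mix$mean_a[res_mix$cluster == "U"], 0.25)

  expect_error(compare_compositions(list(comp(0.5)), a), "2 rings")
})

test_that("anchor splitting cuts the perimeter into length-conserving edges", {
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  edges2 <- split_boundary_by_anchors(sq, rbind(c(0, 0), c(1, 1)))
  expect_length(edges2, 2)
  lens <- vapply(edges2, function(e) sum(sqrt(rowSums(diff(e$polyline)^2))), 0)
  expect_equal(lens, c(2, 2))

  edges4 <- split_boundary_by_anchors(sq, rbind(c(0, 0), c(1, 0),
                                                c(1, 1), c(0, 1)))
  expect_length(edges4, 4)
  expect_equal(vapply(edges4, function(e)
    sum(sqrt(rowSums(diff(e$polyline)^2))), 0), rep(1, 4))

  expect_error(split_boundary_by_anchors(sq, rbind(c(0, 0), c(0.01, 0.01))),
               "ambiguous")

  # edge lengths always reconstruct the perimeter
  set.seed(21)
  xy <- cbind(runif(100), runif(100))
  h <- concave_hull(xy, 2)
  perim <- sum(sqrt(rowSums(diff(h)^2)))
  ed <- split_boundary_by_anchors(h, xy[1:3, ])
  total <- sum(vapply(ed, function(e)
    sum(sqrt(rowSums(diff(e$polyline)^2))), 0))
  expect_equal(total, perim, tolerance = 1e-9 * perim)
})

test_that("boundary geometries survive a GeoJSON round trip", {
  tis <- small_tissue()
  bs <- get_boundary(tis$cells, "A", tau = 200, eps = 120)
  tmp <- withr::local_tempfile(fileext = ".geojson")
  write_geojson(bs, tmp)
  back <- read_geojson(tmp)
  expect_s3_class(back, "boundary_set")
  expect_equal(back$polygons[[1]], bs$polygons[[1]], ignore_attr = TRUE)

  ring <- build_ring_region(bs, dist = 50)
  write_geojson(ring, tmp)
  ring_back <- read_geojson(tmp)
  expect_s3_class(ring_back, "ring_region")
  expect_equal(ring_back$outer, ring$outer, ignore_attr = TRUE)
})
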