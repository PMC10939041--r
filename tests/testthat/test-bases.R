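test_that("B-spline bases form a partition of unity with the documented
           column count", {
  x <- runif(200, -3, 5)
  bd <- bspline_design(x, n_knots = 20L, degree = 3L)
  expect_equal(ncol(bd$B), 22L)          # (20 - 1) + 3
  expect_equal(rowSums(bd$B), rep(1, 200), tolerance = 1e-12)
  # boundary points included
  bd2 <- bspline_design(c(0, 0.3, 1), n_knots = 5L, degree = 3L,
                        xrange = c(0, 1))
  expect_equal(rowSums(bd2$B), rep(1, 3), tolerance = 1e-12)
  expect_error(bspline_design(rep(1, 5)), "constant")
})

test_that("degree-0 bases reduce to indicator bins", {
  B <- bspline_design(c(0, 0.49, 0.5, 1), n_knots = 3L, degree = 0L,
                      xrange = c(0, 1))$B
  expect_equal(B, rbind(c(1, 0), c(1, 0), c(0, 1), c(0, 1)),
               ignore_attr = TRUE)
})

test_that("difference penalties match hand computation and annihilate
           their polynomial nullspace", {
  expect_equal(diff_penalty(3L, 1L),
               rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)))
  K2 <- diff_penalty(8L, 2L)
  expect_equal(as.numeric(K2 %*% (1:8)), rep(0, 8L))   # linear sequences
  expect_equal(rowSums(diff_penalty(6L, 1L)), rep(0, 6L))
  expect_equal(rowSums(K2), rep(0, 8L))
  ev <- eigen(K2, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  expect_equal(sum(ev > 1e-8), 6L)                      # rank p - order
})

test_that("MRF penalty is the graph Laplacian", {
  g2 <- zone_graph(c("A", "B"), rbind(c("A", "B")))
  expect_equal(mrf_penalty(g2), rbind(c(1, -1), c(-1, 1)),
               ignore_attr = TRUE)
  K3 <- mrf_penalty(path_graph(3L))
  expect_equal(K3, rbind(c(1, -1, 0), c(-1, 2, -1), c(0, -1, 1)),
               ignore_attr = TRUE)
  # K %*% 1 = 0 on any graph
  g <- make_lattice_zones(3L, 3L)
  expect_equal(as.numeric(mrf_penalty(g) %*% rep(1, 9L)), rep(0, 9L))
})

test_that("path-graph MRF penalty equals the first-order random-walk
           penalty exactly", {
  for (p in c(3L, 5L, 9L)) {
    expect_equal(unname(mrf_penalty(path_graph(p))), diff_penalty(p, 1L))
  }
})

test_that("MRF quadratic form equals the edge-wise sum of squared
           differences", {
  g <- make_lattice_zones(3L, 4L)
  K <- mrf_penalty(g)
  withr::with_seed(11, {
    for (r in 1:5) {
      b <- rnorm(length(g$zones))
      names(b) <- g$zones
      edge_sum <- sum(apply(g$edges, 1L, function(e) (b[e[1]] - b[e[2]])^2))
      expect_equal(as.numeric(t(b) %*% K %*% b), edge_sum,
                   tolerance = 1e-10)
    }
  })
})

test_that("tensor products have p*q columns and constants in the penalty
           nullspace", {
  g <- make_lattice_zones(4L, 4L)
  td <- tensor_design(g$centroids$lon, g$centroids$lat, n_knots = 8L)
  expect_equal(td$p, 10L)                       # (8 - 1) + 3 per margin
  expect_equal(ncol(td$B), 100L)
  expect_equal(as.numeric(td$K %*% rep(1, 100L)), rep(0, 100L),
               tolerance = 1e-10)
  expect_error(tensor_design(rep(1, 4), 1:4), "degenerate")
})

test_that("iid blocks are zone incidence with identity penalty", {
  g <- zone_graph(c("A", "B"), rbind(c("A", "B")))
  ib <- iid_block(c("A", "A", "B"), g)
  expect_equal(as.matrix(ib$X), rbind(c(1, 0), c(1, 0), c(0, 1)),
               ignore_attr = TRUE)
  expect_equal(ib$K, diag(2L))
})

test_that("constraint absorption drops one column, keeps the penalty PSD,
           and tracks the nullspace", {
  x <- runif(100)
  bd <- bspline_design(x, n_knots = 10L)
  bl <- ordstar:::new_term_block("s(x)", "pspline", bd$B,
                                 diff_penalty(ncol(bd$B), 2L))
  expect_equal(bl$null_dim, 2L)
  blc <- absorb_constraint(bl)
  expect_equal(ncol(blc$X), ncol(bd$B) - 1L)
  expect_equal(blc$null_dim, 1L)                # linear trend retained
  ev <- eigen(blc$K, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  # rank + nullspace = columns
  expect_equal(sum(ev > 1e-8 * max(ev)) + blc$null_dim, ncol(blc$X))
  # idempotent
  expect_identical(absorb_constraint(blc), blc)
})

test_that("constrained tensor penalty on a connected grid has an empty
           nullspace (constant removed)", {
  g <- make_lattice_zones(4L, 4L)
  td <- tensor_design(g$centroids$lon, g$centroids$lat, n_knots = 5L)
  bl <- ordstar:::new_term_block("tp", "tensor", td$B, td$K)
  blc <- absorb_constraint(bl, cvec = colSums(td$B))
  expect_equal(blc$null_dim, 0L)
})
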