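test_that("margin-of-error solves the simplex projection exactly", {
  V <- cbind(c(1, 0), c(0, 1))
  expect_equal(as.numeric(margin_of_error(c(1, 0), V)), 0)
  expect_equal(as.numeric(margin_of_error(c(0.5, 0.5), V)), 0)
  # off-simplex point: orthogonal projection of (0.8, 0.8) onto the segment
  m <- margin_of_error(c(0.8, 0.8), V)
  expect_equal(as.numeric(m), 0.6 / sqrt(2), tolerance = 1e-12)
  expect_equal(attr(m, "alpha"), c(0.5, 0.5), tolerance = 1e-12)
  # interior point of a triangle
  b <- fix_basis()
  ctr <- rowMeans(b$normalized)
  expect_equal(as.numeric(margin_of_error(ctr, b$normalized)), 0)
  expect_error(margin_of_error(c(1, 2), matrix(numeric(0), 2, 0)),
               "at least one vertex")
})

test_that("the exact margin agrees with brute-force simplex-grid search", {
  withr::with_seed(101, {
    for (rep in 1:25) {
      Tdim <- sample(3:6, 1)
      J <- sample(2:3, 1)
      V <- matrix(stats::runif(Tdim * J), Tdim)
      x <- stats::runif(Tdim)
      exact <- as.numeric(margin_of_error(x, V))
      grid <- grid_margin(x, V, step = 1e-3)
      expect_gte(grid, exact - 1e-9)
      expect_lt(grid - exact, 1e-3)
    }
  })
})

test_that("exhaustive vertex search recovers the true compartment curves", {
  b <- fix_basis()
  centers <- fix_centers(b)
  sol <- enumerate_vertex_sets(centers, 3)
  expect_equal(sol$vertex_cluster_index, 1:3)
  expect_equal(sol$total_margin, 0)
  expect_equal(sol$candidate_count, choose(10, 3))
  expect_lt(perm_matched_error(t(sol$vertices), b$normalized), 1e-6)
  expect_equal(sol$total_margin,
               sum(sol$per_center_margin[-sol$vertex_cluster_index]))
  # interior (mixed) centers have zero margin only at the vertices
  expect_true(all(sol$per_center_margin[1:3] == 0))
})

test_that("M = J leaves a single vacuous subset with zero margin", {
  centers <- fix_centers(n_mix = 0)
  sol <- enumerate_vertex_sets(centers, 3)
  expect_equal(sol$candidate_count, 1)
  expect_equal(sol$total_margin, 0)
  expect_error(enumerate_vertex_sets(centers, 4), "2 <= J <= M")
})

test_that("the subset minimizer matches brute-force enumeration", {
  withr::with_seed(33, {
    centers <- matrix(stats::runif(18), 6, 3)
    sol <- enumerate_vertex_sets(centers, 3)
    combos <- utils::combn(6, 3)
    objs <- apply(combos, 2, function(S)
      sum(vapply(setdiff(1:6, S), function(m)
        grid_margin(centers[m, ], t(centers[S, ]), step = 5e-4),
        numeric(1))))
    expect_equal(sol$vertex_cluster_index, combos[, which.min(objs)])
    expect_equal(sol$total_margin, min(objs), tolerance = 1e-2)
  })
})

test_that("the optimal total margin is non-increasing in J", {
  withr::with_seed(55, {
    centers <- matrix(stats::runif(80), 10, 8)
    margins <- vapply(2:6, function(J)
      enumerate_vertex_sets(centers, J)$total_margin, numeric(1))
    expect_true(all(diff(margins) <= 1e-10))
  })
})

test_that("the selected vertex set maximizes source dominance on pure pixels", {
  b <- fix_basis()
  centers <- fix_centers(b)
  sol <- enumerate_vertex_sets(centers, 3)
  V <- t(sol$vertices)
  combos <- utils::combn(nrow(centers), 3)
  for (j in 1:3) {
    alpha_sel <- attr(margin_of_error(b$normalized[, j], V), "alpha")
    expect_equal(max(alpha_sel), 1, tolerance = 1e-9)  # one-hot at truth
    for (ci in sample(ncol(combos), 8)) {
      S <- combos[, ci]
      if (identical(S, sol$vertex_cluster_index)) next
      alpha_other <- attr(margin_of_error(b$normalized[, j],
                                          t(centers[S, , drop = FALSE])),
                          "alpha")
      expect_lte(max(alpha_other), max(alpha_sel) + 1e-9)
    }
  }
})

test_that("convexity projection preserves planar vertex geometry", {
  withr::with_seed(8, {
    # a triangle living in a 2-D affine subspace of 10-dim curve space
    B <- qr.Q(qr(matrix(stats::rnorm(20), 10, 2)))
    tri2 <- rbind(c(0, 0), c(3, 0), c(1, 2))
    V <- tri2 %*% t(B) + 0.5
    P <- convexity_projection(V, V)
    expect_equal(as.numeric(dist(P)), as.numeric(dist(tri2)),
                 tolerance = 1e-9)
    # interior points project inside the projected hull
    w <- c(0.2, 0.3, 0.5)
    p_int <- convexity_projection(matrix(w %*% V, 1), V)
    expect_lt(as.numeric(margin_of_error(as.numeric(p_int), t(P))), 1e-9)
  })
  expect_warning(convexity_projection(matrix(1:4, 2), matrix(1:4, 2)),
                 "first two")
})
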