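# Two tight groups of near-identical normalized 2-frame pixels, as a
# dynamic series; used for the exemplar-recovery checks.
two_group_series <- function(jitter = 0.002, n = 5, seed = 21) {
  withr::with_seed(seed, {
    a <- 0.2 + stats::rnorm(n, 0, jitter)
    b <- 0.8 + stats::rnorm(n, 0, jitter)
    vals <- cbind(rbind(a, 1 - a), rbind(b, 1 - b))
    vals <- sweep(vals, 2, colSums(vals), "/")
    dynamic_series(vals, frame_interval = 1, normalized = TRUE)
  })
}

test_that("similarities are negative squared distances with symmetric off-diagonal", {
  vals <- cbind(c(0.2, 0.8), c(0.5, 0.5), c(0.3, 0.7))
  s <- dynamic_series(vals, frame_interval = 1, normalized = TRUE)
  S <- similarity_matrix(s, preference = -1)
  expect_equal(S[1, 2], -(0.3^2 + 0.3^2))
  expect_equal(S[1, 3], -(0.1^2 + 0.1^2))
  expect_equal(S[2, 3], -(0.2^2 + 0.2^2))
  expect_equal(S[lower.tri(S)], t(S)[lower.tri(S)])
  expect_equal(diag(S), rep(-1, 3))
  # identical pixels have the maximal similarity of zero
  s2 <- dynamic_series(cbind(c(0.4, 0.6), c(0.4, 0.6)), frame_interval = 1,
                       normalized = TRUE)
  expect_equal(similarity_matrix(s2, preference = -1)[1, 2], 0)
  raw <- dynamic_series(vals * 3, frame_interval = 1)
  expect_error(similarity_matrix(raw), "normalize")
})

test_that("affinity propagation recovers trivial and two-group structure", {
  one <- affinity_propagation(matrix(-0.5, 1, 1))
  expect_equal(one$exemplar_index, 1L)
  expect_equal(one$assignment, 1L)

  s <- two_group_series()
  S <- similarity_matrix(s)
  cl <- affinity_propagation(S, series = s)
  expect_true(cl$converged)
  expect_equal(length(cl$exemplar_index), 2L)
  expect_equal(sort(unique(cl$assignment[1:5])),
               sort(unique(cl$assignment))[1])
  expect_equal(length(unique(cl$assignment[6:10])), 1L)
  expect_false(cl$assignment[1] == cl$assignment[6])
  # exemplars are actual data points; centers rows sum to one
  expect_true(all(cl$exemplar_index %in% 1:10))
  expect_equal(rowSums(cl$centers), c(1, 1))
  expect_equal(cl$sizes, c(5L, 5L))

  # a weaker damping factor finds the same partition here
  cl05 <- affinity_propagation(S, series = s, damping = 0.5)
  expect_equal(length(cl05$exemplar_index), 2L)
  expect_equal(cl05$assignment[1:5], rep(cl05$assignment[1], 5))
  expect_equal(cl05$assignment[6:10], rep(cl05$assignment[6], 5))
})

test_that("termination requires a stable exemplar set for the full window", {
  s <- two_group_series()
  S <- similarity_matrix(s)
  short <- affinity_propagation(S, convergence_window = 5)
  long <- affinity_propagation(S, convergence_window = 15)
  expect_true(short$converged && long$converged)
  expect_gte(short$n_iter, 5)
  expect_gte(long$n_iter, short$n_iter + 10)
  expect_equal(short$exemplar_index, long$exemplar_index)
})

test_that("EM refinement is a fixed point on well-separated exact clusters", {
  s <- two_group_series(jitter = 1e-4)
  cl <- affinity_propagation(similarity_matrix(s), series = s)
  ref <- em_refine(s, cl)
  expect_lt(max(abs(ref$centers - cl$centers)), 1e-6)
  ll <- attr(ref, "loglik")
  expect_true(all(diff(ll) >= -1e-8 * abs(ll[-length(ll)])))
})

# Noisy draws around three known normalized prototypes; EM should pull the
# member-mean centers toward the prototypes.
noisy_three_cluster <- function(seed) {
  withr::with_seed(seed, {
    proto <- rbind(c(0.5, 0.3, 0.15, 0.05),
                   c(0.1, 0.2, 0.3, 0.4),
                   c(0.25, 0.25, 0.25, 0.25))
    X <- proto[rep(1:3, each = 30), ] + matrix(stats::rnorm(360, 0, 0.04), 90)
    X <- pmax(X, 1e-6)
    X <- X / rowSums(X)
    list(series = dynamic_series(t(X), frame_interval = 1, normalized = TRUE),
         proto = proto)
  })
}

test_that("EM refinement moves centers toward the true component means", {
  dist_to_truth <- function(centers, proto)
    mean(apply(centers, 1, function(v)
      sqrt(min(colSums((t(proto) - v)^2)))))
  deltas <- vapply(1:20, function(seed) {
    d <- noisy_three_cluster(seed)
    cl <- affinity_propagation(similarity_matrix(d$series), series = d$series)
    if (length(cl$exemplar_index) < 2) return(c(0, 0))
    ref <- em_refine(d$series, cl)
    ex_curves <- t(d$series$values)[cl$exemplar_index, , drop = FALSE]
    c(dist_to_truth(ex_curves, d$proto) - dist_to_truth(ref$centers, d$proto),
      dist_to_truth(cl$centers, d$proto) - dist_to_truth(ref$centers, d$proto))
  }, numeric(2))
  # refined centers denoise the raw exemplar curves (single noisy pixels) ...
  expect_gt(mean(deltas[1, ]), 0)
  # ... and are on average no worse than the hard member means
  expect_gt(mean(deltas[2, ]), -0.002)
})

test_that("EM refinement agrees with an independent mixture implementation", {
  skip_if_not_installed("mclust")
  d <- noisy_three_cluster(42)
  cl <- affinity_propagation(similarity_matrix(d$series), series = d$series)
  ref <- em_refine(d$series, cl, tol = 1e-10, max_iter = 500)
  X <- t(d$series$values)
  M <- length(cl$exemplar_index)
  s2 <- mean(vapply(seq_len(M), function(m)
    mean(rowSums(sweep(X[cl$assignment == m, , drop = FALSE], 2,
                       cl$centers[m, ])^2)), numeric(1))) / ncol(X)
  mc <- mclust::emEII(data = X, parameters = list(
    pro = cl$sizes / sum(cl$sizes), mean = t(cl$centers),
    variance = list(modelName = "EII", d = ncol(X), G = M, sigmasq = s2)),
    control = mclust::emControl(tol = 1e-10, itmax = 500))
  mc_centers <- t(mc$parameters$mean)
  mc_centers <- mc_centers / rowSums(mc_centers)
  # same fixed point up to renormalization and row order (empty clusters may
  # have been dropped by the refinement, so match centers by nearest)
  nearest <- function(A, B) max(apply(A, 1, function(v)
    sqrt(min(rowSums(sweep(B, 2, v)^2)))))
  expect_lt(nearest(ref$centers, mc_centers), 5e-3)
})

test_that("the clustering wrapper returns a data-driven number of clusters", {
  st <- generate_synthetic_study(synthetic_config(snr_db = 30, seed = 2024))
  pre <- preprocess(st$series)
  cl <- cluster_series(pre$series)
  M <- nrow(cl$centers)
  expect_gte(M, 3)
  expect_true(all(abs(rowSums(cl$centers) - 1) < 1e-6))
  expect_equal(sum(cl$sizes), n_pixels(pre$series))
  expect_true(all(cl$assignment %in% seq_len(M)))
})
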