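#' Pairwise similarity matrix for affinity propagation
#'
#' The similarity of pixel i to candidate exemplar m is the negative squared
#' Euclidean distance between their normalized time-courses,
#' `s(i, m) = -||x_i - x_m||^2`; identical curves have the maximal similarity
#' of zero. The diagonal holds the exemplar preference, which controls how
#' many clusters emerge: the default is the median of the off-diagonal
#' similarities.
#'
#' @param series a sum-normalized [dynamic_series()].
#' @param preference `"median"` (default) or a numeric value placed on the
#'   diagonal.
#' @param preference_scale multiplier applied when `preference = "median"`:
#'   similarities are negative, so values above 1 push the preference lower
#'   and yield fewer clusters. The default 3 keeps the data-driven cluster
#'   count in the low-teens operating range the vertex search is designed
#'   for on dense pixel sets; 1 reproduces the plain reference default.
#' @return an N x N similarity matrix.
#' @export
similarity_matrix <- function(series, preference = "median",
                              preference_scale = 3) {
  if (!inherits(series, "dynamic_series")) stop("series must be a dynamic_series")
  if (!series$normalized)
    stop("similarities are defined on sum-normalized series; run normalize_sum()")
  X <- t(series$values)                     # N x T, rows are pixels
  sq <- rowSums(X^2)
  S <- -(outer(sq, sq, "+") - 2 * tcrossprod(X))
  S <- pmin(S, 0)                           # clip numerical positives
  pref <- if (identical(preference, "median")) {
    preference_scale * stats::median(S[upper.tri(S) | lower.tri(S)])
  } else as.numeric(preference)
  diag(S) <- pref
  S
}

#' Affinity propagation clustering
#'
#' Initialization-free exemplar-based clustering by message passing.
#' Responsibilities are updated as
#' `r(i,m) <- s(i,m) - max_{m' != m} (a(i,m') + s(i,m'))`, letting all
#' candidate exemplars compete for ownership of each data point, and
#' availabilities as
#' `a(i,m) <- min(0, r(m,m) + sum_{i' not in (i,m)} max(0, r(i',m)))` with
#' self-availability `a(m,m) <- sum_{i' != m} max(0, r(i',m))`, collecting
#' evidence from data points that support a good exemplar. Messages are
#' damped (`new = damping * old + (1 - damping) * computed`). Exemplars are
#' the points with `a(m,m) + r(m,m) > 0`; iteration stops when the exemplar
#' set is unchanged for `convergence_window` consecutive iterations.
#'
#' @param similarities square similarity matrix, e.g. [similarity_matrix()].
#' @param series optional [dynamic_series()]; when supplied, cluster centers
#'   are computed as re-normalized member means.
#' @param damping damping factor in `[0.5, 1)`.
#' @param max_iter iteration cap; non-convergence returns the best-so-far
#'   result with a warning and `converged = FALSE`.
#' @param convergence_window consecutive stable iterations required to
#'   declare convergence (default 10).
#' @return an object of class `cluster_set`: `centers` (M x T, or `NULL`
#'   without `series`), `assignment`, `exemplar_index`, `sizes`, `converged`,
#'   `n_iter`.
#' @export
affinity_propagation <- function(similarities, series = NULL, damping = 0.9,
                                 max_iter = 1000, convergence_window = 10) {
  S <- as.matrix(similarities)
  N <- nrow(S)
  if (ncol(S) != N) stop("similarities must be square")
  if (damping < 0.5 || damping >= 1) stop("damping must lie in [0.5, 1)")
  if (N == 1L) {
    return(.cluster_set(exemplars = 1L, assignment = 1L, series = series,
                        converged = TRUE, n_iter = 0L))
  }
  # degenerate inputs (duplicated points, symmetric similarities) make the
  # message passing oscillate; break the symmetry with infinitesimal
  # deterministic jitter, as reference implementations do
  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  set.seed(571L)
  S <- S + (.Machine$double.eps * abs(S) + 1e-300) *
    matrix(stats::rnorm(N * N), N)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  A <- matrix(0, N, N)
  R <- matrix(0, N, N)
  idx <- seq_len(N)
  exemplars_prev <- integer(0)
  stable <- 0L
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # responsibilities
    AS <- A + S
    top <- max.col(AS, ties.method = "first")
    mx1 <- AS[cbind(idx, top)]
    AS[cbind(idx, top)] <- -Inf
    mx2 <- AS[cbind(idx, max.col(AS, ties.method = "first"))]
    Rnew <- S - mx1
    Rnew[cbind(idx, top)] <- S[cbind(idx, top)] - mx2
    R <- damping * R + (1 - damping) * Rnew
    # availabilities
    Rp <- pmax(R, 0)
    diag(Rp) <- diag(R)
    cs <- colSums(Rp)
    Anew <- matrix(cs, N, N, byrow = TRUE) - Rp
    dA <- diag(Anew)
    Anew <- pmin(Anew, 0)
    diag(Anew) <- dA
    A <- damping * A + (1 - damping) * Anew
    exemplars <- which(diag(A) + diag(R) > 0)
    if (length(exemplars) && identical(exemplars, exemplars_prev)) {
      stable <- stable + 1L
      if (stable >= convergence_window) { converged <- TRUE; break }
    } else stable <- 0L
    exemplars_prev <- exemplars
  }
  if (!length(exemplars_prev)) {
    warning("affinity propagation found no exemplars; returning the point ",
            "of maximal self-evidence as a single cluster")
    exemplars_prev <- which.max(diag(A) + diag(R))
  }
  if (!converged)
    warning("affinity propagation did not converge within max_iter; ",
            "returning best-so-far exemplars")
  exemplars <- exemplars_prev
  # final medoid refinement, as in the reference implementations: each
  # cluster's exemplar becomes the member maximizing the within-cluster
  # similarity sum, and points are then reassigned
  cl <- max.col(S[, exemplars, drop = FALSE], ties.method = "first")
  cl[exemplars] <- seq_along(exemplars)
  for (k in seq_along(exemplars)) {
    members <- which(cl == k)
    sums <- colSums(S[members, members, drop = FALSE])
    exemplars[k] <- members[which.max(sums)]
  }
  exemplars <- sort(exemplars)
  assignment <- max.col(S[, exemplars, drop = FALSE], ties.method = "first")
  assignment[exemplars] <- seq_along(exemplars)
  .cluster_set(exemplars = exemplars, assignment = assignment,
               series = series, converged = converged, n_iter = iter)
}

# Assemble a cluster_set from exemplar ids and an assignment into 1..M.
.cluster_set <- function(exemplars, assignment, series, converged, n_iter,
                         centers = NULL) {
  M <- length(exemplars)
  sizes <- tabulate(assignment, nbins = M)
  if (is.null(centers) && !is.null(series)) {
    X <- t(series$values)
    centers <- matrix(0, M, ncol(X))
    for (m in seq_len(M))
      centers[m, ] <- colMeans(X[assignment == m, , drop = FALSE])
    centers <- centers / rowSums(centers)
  }
  structure(list(centers = centers, assignment = assignment,
                 exemplar_index = exemplars, sizes = sizes,
                 converged = converged, n_iter = n_iter),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> M = %d clusters over %d pixels (%s after %d iterations)\n",
              length(x$exemplar_index), length(x$assignment),
              if (isTRUE(x$converged)) "converged" else "not converged",
              x$n_iter))
  invisible(x)
}

#' Expectation-maximization refinement of cluster centers
#'
#' Refines an affinity-propagation solution with a Gaussian-mixture EM pass:
#' component means are initialized at the cluster centers, a single shared
#' isotropic covariance is used, and mixing weights start proportional to
#' cluster sizes. The log-likelihood is non-decreasing across iterations; the
#' refined centers (re-normalized to unit sum) and hard maximum-posterior
#' assignments are returned. The pass denoises centers that member-mean
#' averaging alone leaves noisy. Deterministic: EM from a fixed
#' initialization involves no randomness (`seed` is accepted for interface
#' symmetry with the other pipeline stages).
#'
#' @param series the sum-normalized [dynamic_series()] that was clustered.
#' @param init a `cluster_set` with `M >= 2` from [affinity_propagation()].
#' @param seed unused; kept so pipeline stages share a calling convention.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return a refined `cluster_set`; the log-likelihood trace is attached as
#'   attribute `loglik`. Clusters left without members by the hard
#'   assignment are dropped.
#' @export
em_refine <- function(series, init, seed = NULL, max_iter = 100, tol = 1e-6) {
  if (!inherits(init, "cluster_set") || length(init$exemplar_index) < 2)
    stop("init must be a cluster_set with at least 2 clusters")
  X <- t(series$values)                     # N x T
  N <- nrow(X); Tn <- ncol(X)
  mu <- init$centers
  M <- nrow(mu)
  pro <- init$sizes / sum(init$sizes)
  sigma2 <- mean(vapply(seq_len(M), function(m) {
    mean(rowSums(sweep(X[init$assignment == m, , drop = FALSE], 2,
                       mu[m, ])^2))
  }, numeric(1))) / Tn
  floor_s2 <- 1e-12 * mean(X^2)
  if (!is.finite(sigma2) || sigma2 <= floor_s2) {
    warning("near-singular shared covariance; ridge-regularized")
    sigma2 <- max(sigma2, floor_s2, 1e-12)
  }
  loglik <- numeric(0)
  for (it in seq_len(max_iter)) {
    d2 <- outer(rowSums(X^2), rowSums(mu^2), "+") - 2 * tcrossprod(X, mu)
    logdens <- -d2 / (2 * sigma2) - Tn / 2 * log(2 * pi * sigma2)
    lw <- sweep(logdens, 2, log(pro), "+")
    mx <- apply(lw, 1, max)
    ll <- sum(mx + log(rowSums(exp(lw - mx))))
    loglik <- c(loglik, ll)
    if (it > 1 && ll - loglik[it - 1] < tol * abs(loglik[it - 1]) + tol) break
    gamma <- exp(lw - mx)
    gamma <- gamma / rowSums(gamma)
    nk <- colSums(gamma)
    pro <- nk / N
    mu <- sweep(crossprod(gamma, X), 1, nk, "/")
    d2 <- outer(rowSums(X^2), rowSums(mu^2), "+") - 2 * tcrossprod(X, mu)
    sigma2 <- max(sum(gamma * d2) / (N * Tn), floor_s2, 1e-12)
  }
  d2 <- outer(rowSums(X^2), rowSums(mu^2), "+") - 2 * tcrossprod(X, mu)
  lw <- sweep(-d2 / (2 * sigma2), 2, log(pro), "+")
  assignment <- max.col(lw, ties.method = "first")
  keep <- sort(unique(assignment))
  if (length(keep) < M)
    assignment <- match(assignment, keep)
  mu <- mu[keep, , drop = FALSE]
  mu <- pmax(mu, 0)
  mu <- mu / rowSums(mu)
  out <- .cluster_set(exemplars = init$exemplar_index[keep],
                      assignment = assignment, series = NULL,
                      converged = init$converged, n_iter = init$n_iter,
                      centers = mu)
  attr(out, "loglik") <- loglik
  out
}

#' Cluster normalized pixel time-courses
#'
#' The clustering stage of the deconvolution pipeline: builds the similarity
#' matrix, runs affinity propagation (the number of clusters M is
#' data-driven, never user-fixed), and optionally refines the centers with
#' the Gaussian-mixture EM pass.
#'
#' @param series a sum-normalized [dynamic_series()].
#' @param damping,preference,preference_scale,max_iter,convergence_window
#'   see [affinity_propagation()] and [similarity_matrix()].
#' @param refine run [em_refine()] after affinity propagation (default TRUE).
#' @param seed passed through to [em_refine()].
#' @return a `cluster_set`.
#' @export
cluster_series <- function(series, damping = 0.9, preference = "median",
                           preference_scale = 3, max_iter = 1000,
                           convergence_window = 10, refine = TRUE,
                           seed = NULL) {
  S <- similarity_matrix(series, preference, preference_scale)
  cl <- affinity_propagation(S, series = series, damping = damping,
                             max_iter = max_iter,
                             convergence_window = convergence_window)
  if (refine && length(cl$exemplar_index) >= 2)
    cl <- em_refine(series, cl, seed = seed)
  cl
}
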