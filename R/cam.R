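#' Margin-of-error of a point to a convex hull
#'
#' The Euclidean distance between a time-course and the convex hull of a
#' candidate vertex set: the minimum over convex weights `alpha` (alpha >= 0,
#' sum(alpha) = 1) of `||point - vertices %*% alpha||`. Zero exactly when the
#' point lies inside the hull. The quadratic program is solved exactly by
#' enumerating the faces of the simplex: for each non-empty vertex subset the
#' equality-constrained least-squares solution is computed in closed form
#' (KKT system) and the best feasible face is taken. The projection of the
#' optimum always lies on a face with non-negative weights, so the
#' enumeration attains the global minimum; it is practical for the small
#' vertex counts (J <= ~8) the method operates with.
#'
#' @param point numeric T-vector.
#' @param vertices T x J matrix of candidate vertex curves.
#' @return non-negative scalar margin; the minimizing weights are attached as
#'   attribute `alpha`.
#' @export
margin_of_error <- function(point, vertices) {
  V <- as.matrix(vertices)
  x <- as.numeric(point)
  if (ncol(V) < 1L) stop("vertex set must contain at least one vertex")
  if (nrow(V) != length(x)) stop("point and vertices must share dimension T")
  if (!all(is.finite(V)) || !all(is.finite(x))) stop("inputs must be finite")
  p <- .project_convex_hull(x, V)
  structure(p$margin, alpha = p$alpha)
}

# Exact projection of x onto the convex hull of the columns of V by face
# enumeration. Returns margin and full-length alpha.
.project_convex_hull <- function(x, V) {
  J <- ncol(V)
  G <- crossprod(V)
  g <- as.numeric(crossprod(V, x))
  xx <- sum(x^2)
  best <- list(m2 = Inf, alpha = NULL)
  for (k in seq_len(J)) {
    combos <- utils::combn(J, k)
    for (ci in seq_len(ncol(combos))) {
      S <- combos[, ci]
      K <- rbind(cbind(G[S, S, drop = FALSE], 1), c(rep(1, k), 0))
      rhs <- c(g[S], 1)
      sol <- tryCatch(solve(K, rhs), error = function(e) NULL)
      if (is.null(sol)) sol <- as.numeric(MASS::ginv(K) %*% rhs)
      a <- sol[seq_len(k)]
      if (all(a >= -1e-10)) {
        m2 <- xx - 2 * sum(a * g[S]) + sum(a * (G[S, S, drop = FALSE] %*% a))
        if (m2 < 1e-14 * xx) m2 <- 0
        if (m2 < best$m2) {
          alpha <- numeric(J); alpha[S] <- pmax(a, 0)
          best <- list(m2 = m2, alpha = alpha / sum(alpha))
        }
      }
    }
  }
  list(margin = sqrt(max(best$m2, 0)), alpha = best$alpha)
}

# Precompute, from M cluster-center curves (rows of `centers`), the squared
# projection residual of every center onto the affine hull of every center
# subset ("face") of size <= j_max, with infeasible faces (negative weights)
# set to Inf. Works entirely in Gram-matrix space, so the cost is independent
# of T. The margin of center m to the convex hull of a vertex subset V is
# then min over faces S of V of the stored residual -- the classic
# active-face characterization of simplex projection.
.face_residuals <- function(centers, j_max) {
  C <- as.matrix(centers)
  M <- nrow(C)
  G <- tcrossprod(C)
  dG <- diag(G)
  pow2 <- 2^(seq_len(M) - 1)
  n_faces <- sum(vapply(seq_len(j_max), function(k) choose(M, k), numeric(1)))
  if (n_faces > 2e6)
    stop("too many cluster centers (M = ", M, ") for exhaustive vertex ",
         "search up to J = ", j_max, "; lower the affinity-propagation ",
         "preference to reduce M")
  R <- matrix(Inf, n_faces, M)
  keys <- numeric(n_faces)
  row <- 0L
  for (k in seq_len(j_max)) {
    combos <- utils::combn(M, k)
    ones <- rep(1, k)
    for (ci in seq_len(ncol(combos))) {
      S <- combos[, ci]
      row <- row + 1L
      keys[row] <- sum(pow2[S])
      GSS <- G[S, S, drop = FALSE]
      K <- rbind(cbind(GSS, 1), c(ones, 0))
      rhs <- rbind(G[S, , drop = FALSE], 1)
      A <- tryCatch(solve(K, rhs), error = function(e) MASS::ginv(K) %*% rhs)
      a <- A[seq_len(k), , drop = FALSE]
      feas <- colSums(a < -1e-9) == 0
      r2 <- dG - 2 * colSums(a * G[S, , drop = FALSE]) + colSums(a * (GSS %*% a))
      # squared residuals below the floating-point cancellation floor of the
      # Gram-space formula are exact zeros (points inside the hull)
      r2[r2 < 1e-14 * dG] <- 0
      r2 <- pmax(r2, 0)
      r2[!feas] <- Inf
      R[row, ] <- r2
    }
  }
  ord <- order(keys)
  list(R = R[ord, , drop = FALSE], keys = keys[ord], pow2 = pow2, M = M,
       j_max = j_max)
}

# Non-empty subsets of positions 1..J as a 0/1 pattern matrix (rows = faces).
.face_patterns <- function(J) {
  P <- as.matrix(expand.grid(rep(list(0:1), J)))[-1, , drop = FALSE]
  storage.mode(P) <- "numeric"
  unname(P)
}

#' Exhaustive search for the simplex vertices among cluster centers
#'
#' The convex-hull-to-data fitting criterion of convex analysis of mixtures:
#' every one of the `choose(M, J)` subsets of J cluster centers is evaluated
#' as a candidate vertex set, the margin-of-error of each remaining
#' "exterior" center to the subset's convex hull is computed, and the subset
#' whose summed exterior margin is minimal is returned. Under the pure-pixel
#' condition (at least one pixel per compartment whose signal is exclusively
#' enriched in that compartment) the noise-free minimizer is the set of true
#' compartment time-activity curves with zero total margin. Ties are broken
#' toward the lexicographically smallest index tuple.
#'
#' @param clusters a `cluster_set` with centers, or an M x T matrix of
#'   center curves.
#' @param J number of vertices (compartments) to select, `2 <= J <= M`.
#' @param face_cache optional precomputed result of the internal face table
#'   (reused across candidate J by [select_num_compartments()]).
#' @return an object of class `vertex_solution`: `vertex_cluster_index`
#'   (sorted), `total_margin`, `per_center_margin` (zero at the vertices),
#'   `candidate_count = choose(M, J)`, and `vertices` (J x T curves).
#' @export
enumerate_vertex_sets <- function(clusters, J, face_cache = NULL) {
  centers <- if (inherits(clusters, "cluster_set")) clusters$centers
             else as.matrix(clusters)
  M <- nrow(centers)
  J <- as.integer(J)
  if (J < 2 || J > M) stop("J must satisfy 2 <= J <= M")
  if (choose(M, J) > 2e6)
    stop("choose(M, J) too large for exhaustive search; reduce the cluster ",
         "count via the affinity-propagation preference")
  fc <- face_cache %||% .face_residuals(centers, J)
  if (fc$j_max < J) fc <- .face_residuals(centers, J)
  combos <- utils::combn(M, J)
  P <- .face_patterns(J)
  best_obj <- Inf
  best <- NULL
  all_idx <- seq_len(M)
  for (ci in seq_len(ncol(combos))) {
    S <- combos[, ci]
    rows <- findInterval(as.numeric(P %*% fc$pow2[S]), fc$keys)
    ext <- all_idx[-S]
    sub <- fc$R[rows, ext, drop = FALSE]
    m2 <- sub[1L, ]
    for (r in seq_len(nrow(sub))[-1L]) m2 <- pmin(m2, sub[r, ])
    obj <- sum(sqrt(m2))
    if (obj < best_obj) {
      best_obj <- obj
      best <- list(S = S, ext = ext, m2 = m2)
    }
  }
  per_center <- numeric(M)
  per_center[best$ext] <- sqrt(best$m2)
  structure(list(vertex_cluster_index = best$S,
                 total_margin = best_obj,
                 per_center_margin = per_center,
                 candidate_count = ncol(combos),
                 vertices = centers[best$S, , drop = FALSE]),
            class = "vertex_solution")
}

#' @export
print.vertex_solution <- function(x, ...) {
  cat(sprintf("<vertex_solution> J = %d vertices (clusters %s), total margin %.4g over %d candidate subsets\n",
              length(x$vertex_cluster_index),
              paste(x$vertex_cluster_index, collapse = ","),
              x$total_margin, x$candidate_count))
  invisible(x)
}

#' Convexity-preserving 2-D projection of the scatter simplex
#'
#' Projects time-courses onto the principal plane of the selected vertex
#' set: the 2-D affine plane through the vertex centroid that minimizes the
#' summed squared projection residuals of the vertices. For three vertices
#' spanning a plane this is the exact plane of the triangle, so vertex
#' geometry (and hence convex combinations) is preserved; it is the
#' projection used for scatter-simplex plots.
#'
#' @param x a [dynamic_series()], `cluster_set`, or points matrix (rows =
#'   curves).
#' @param vertices a `vertex_solution`, or J x T matrix of vertex curves.
#' @return n x 2 matrix of coordinates.
#' @export
convexity_projection <- function(x, vertices) {
  pts <- if (inherits(x, "dynamic_series")) t(x$values)
         else if (inherits(x, "cluster_set")) x$centers
         else as.matrix(x)
  V <- if (inherits(vertices, "vertex_solution")) vertices$vertices
       else as.matrix(vertices)
  if (nrow(V) < 3) {
    warning("fewer than 3 vertices; falling back to the first two coordinates")
    return(pts[, 1:2, drop = FALSE])
  }
  ctr <- colMeans(V)
  B <- sweep(V, 2, ctr)
  U <- svd(t(B), nu = 2)$u
  sweep(pts, 2, ctr) %*% U
}
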