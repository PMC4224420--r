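#' Minimum description length of a clustered compartment model
#'
#' Total code length of the model "every cluster center is its best convex
#' reconstruction from the J selected vertex curves, plus i.i.d. Gaussian
#' noise": the negative maximized Gaussian log-likelihood of the M x T
#' center reconstruction residuals (noise variance at its MLE), plus the
#' parameter-encoding penalty `(P/2) log(M*T)` with
#' `P = J*T + M*(J-1) + 1` freely adjustable parameters (J vertex curves,
#' M mixing-weight vectors on the (J-1)-simplex, one noise variance).
#' Richer vertex sets fit at least as well, so the likelihood term is
#' non-increasing in J while the penalty grows; the code length balances the
#' two.
#'
#' @param clusters a `cluster_set` (or M x T center matrix).
#' @param solution the fitted [enumerate_vertex_sets()] result for this J.
#' @param J number of vertices of `solution`.
#' @param size_weighted weight each center's residual by its cluster size
#'   (off by default; the unweighted form treats centers as the modeled
#'   observations).
#' @return finite scalar code length (smaller is better).
#' @export
code_length <- function(clusters, solution, J,
                        size_weighted = FALSE) {
  centers <- if (inherits(clusters, "cluster_set")) clusters$centers
             else as.matrix(clusters)
  M <- nrow(centers); Tn <- ncol(centers)
  J <- as.integer(J)
  if (length(solution$per_center_margin) != M)
    stop("solution does not match the cluster set")
  r2 <- solution$per_center_margin^2
  w <- if (size_weighted && inherits(clusters, "cluster_set"))
    clusters$sizes / mean(clusters$sizes) else rep(1, M)
  sse <- sum(w * r2)
  n_obs <- M * Tn
  sigma2 <- sse / n_obs
  if (sigma2 < 1e-12) {
    warning("degenerate (zero) residual variance; floored at 1e-12")
    sigma2 <- 1e-12
  }
  nll <- n_obs / 2 * (log(2 * pi * sigma2) + 1)
  P <- J * Tn + M * (J - 1) + 1
  nll + P / 2 * log(n_obs)
}

#' Detect the number of vascular compartments by MDL
#'
#' Runs the exhaustive vertex search for every candidate compartment count J
#' and evaluates the description code length of each fitted model; the most
#' probable J is the minimizer (ties broken toward smaller J, i.e.
#' parsimony). This is the model-selection step that makes the deconvolution
#' fully unsupervised.
#'
#' @param clusters a `cluster_set` from [cluster_series()].
#' @param j_min,j_max candidate range (defaults 2..6); `j_max` is clipped to
#'   the number of clusters M.
#' @param size_weighted see [code_length()].
#' @return an object of class `model_selection_result`: `candidates`,
#'   `code_length`, `chosen_J`, and `fit_per_J` (the `vertex_solution` per
#'   candidate).
#' @export
select_num_compartments <- function(clusters, j_min = 2, j_max = 6,
                                    size_weighted = FALSE) {
  centers <- if (inherits(clusters, "cluster_set")) clusters$centers
             else as.matrix(clusters)
  M <- nrow(centers)
  j_min <- as.integer(j_min); j_max <- as.integer(min(j_max, M))
  if (j_min > j_max) stop("j_min must not exceed j_max (after clipping to M)")
  candidates <- j_min:j_max
  fc <- .face_residuals(centers, j_max)
  fits <- lapply(candidates, function(J)
    enumerate_vertex_sets(centers, J, face_cache = fc))
  cl <- mapply(function(fit, J) code_length(clusters, fit, J, size_weighted),
               fits, candidates)
  chosen <- candidates[which.min(cl)]
  structure(list(candidates = candidates, code_length = as.numeric(cl),
                 chosen_J = chosen,
                 fit_per_J = stats::setNames(fits, paste0("J", candidates))),
            class = "model_selection_result")
}

#' @export
print.model_selection_result <- function(x, ...) {
  cat("<model_selection_result>\n")
  print(data.frame(J = x$candidates, code_length = x$code_length,
                   chosen = x$candidates == x$chosen_J))
  invisible(x)
}
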