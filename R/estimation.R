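#' Identify the plasma-input vertex
#'
#' Among the selected compartment curves, the plasma input function is the
#' vertex of fastest tracer enhancement: the column reaching its peak most
#' rapidly. Peak-time ties are broken by the steeper initial upslope (mean
#' slope from the first frame to the peak).
#'
#' @param curves T x J matrix of compartment curves (J >= 2).
#' @param times optional timestamps (defaults to frame index).
#' @return the plasma column index.
#' @export
identify_plasma_vertex <- function(curves, times = NULL) {
  curves <- as.matrix(curves)
  if (ncol(curves) < 2) stop("need at least two compartment curves")
  times <- times %||% seq_len(nrow(curves))
  if (all(apply(curves, 2, function(x) diff(range(x))) < 1e-12))
    stop("all compartment curves are flat; plasma vertex is ambiguous")
  peak <- apply(curves, 2, which.max)
  cand <- which(peak == min(peak))
  if (length(cand) == 1L) return(cand)
  if (min(peak) == 1L) {
    # peaks at the very first frame carry no upslope; the plasma input is
    # then the curve of highest (fastest-washout) normalized peak
    return(cand[which.max(curves[1L, cand])])
  }
  upslope <- vapply(cand, function(j) {
    p <- peak[j]
    (curves[p, j] - curves[1L, j]) / (times[p] - times[1L])
  }, numeric(1))
  cand[which.max(upslope)]
}

#' Lower-triangular Toeplitz matrix of the plasma input
#'
#' The sampled-system convolution operator: a lower-triangular Toeplitz
#' matrix whose first column is the plasma curve scaled by the frame
#' interval, so that `matrix %*% h` discretizes the causal convolution
#' `C_p (*) h` with the same left-rectangle quadrature as
#' [solve_compartment()]. Requires uniform frame spacing.
#'
#' @param cp a [plasma_input()] sampled on a uniform time grid.
#' @return T x T lower-triangular matrix.
#' @export
toeplitz_input_matrix <- function(cp) {
  if (!inherits(cp, "plasma_input")) stop("cp must be a plasma_input")
  dt <- diff(cp$times)
  if (diff(range(dt)) > 1e-8 * mean(dt))
    stop("the Toeplitz construction requires uniform frame spacing")
  Tm <- stats::toeplitz(cp$concentration * dt[1])
  Tm[upper.tri(Tm)] <- 0
  Tm
}

#' Fit flux rate and transfer constant of one vertex curve
#'
#' Estimates the tissue-compartment parameters from a vertex time-activity
#' curve by deconvolution against the plasma input: minimizes
#' `|| y - Toeplitz(Cp) %*% (ktrans * exp(-kep * t)) ||` over
#' `ktrans >= 0, kep >= 0`. The 1-D profile over kep is searched on a log
#' grid and refined by golden-section minimization; at each kep the optimal
#' non-negative ktrans is closed-form. Because the curves are
#' sum-normalized, ktrans is in relative units while kep is an absolute
#' rate in /min.
#'
#' @param vertex_curve T-vector, the (normalized) tissue vertex curve.
#' @param cp the [plasma_input()] identified by [identify_plasma_vertex()].
#' @param kep_range search bracket in /min (default `c(1e-3, 20)`, covering
#'   physiologic dynamic-contrast values).
#' @param n_grid log-grid size before refinement.
#' @return list with `ktrans` (relative), `kep` (/min), `fit_residual`, and
#'   `reliable` (`FALSE` when the vertex is indistinguishable from the
#'   plasma input, which leaves kep unidentifiable).
#' @export
fit_flux_rate <- function(vertex_curve, cp, kep_range = c(1e-3, 20),
                          n_grid = 200) {
  y <- as.numeric(vertex_curve)
  if (length(y) != length(cp$times))
    stop("vertex curve and plasma input must share the time grid")
  Tm <- toeplitz_input_matrix(cp)
  tau <- cp$times - cp$times[1]
  profile <- function(lk) {
    g <- as.numeric(Tm %*% exp(-exp(lk) * tau))
    gg <- sum(g^2)
    kt <- if (gg > 0) max(0, sum(y * g) / gg) else 0
    sum((y - kt * g)^2)
  }
  lgrid <- seq(log(kep_range[1]), log(kep_range[2]), length.out = n_grid)
  vals <- vapply(lgrid, profile, numeric(1))
  i <- which.min(vals)
  lo <- lgrid[max(1, i - 1)]; hi <- lgrid[min(n_grid, i + 1)]
  opt <- stats::optimize(profile, c(lo, hi), tol = 1e-9)
  kep <- exp(opt$minimum)
  g <- as.numeric(Tm %*% exp(-kep * tau))
  ktrans <- max(0, sum(y * g) / sum(g^2))
  reliable <- TRUE
  if (stats::sd(y) > 0 && stats::sd(cp$concentration) > 0 &&
      stats::cor(y, cp$concentration) > 0.999) {
    warning("vertex curve is nearly proportional to the plasma input; ",
            "kep estimate flagged unreliable")
    reliable <- FALSE
  }
  list(ktrans = ktrans, kep = kep,
       fit_residual = sqrt(sum((y - ktrans * g)^2)), reliable = reliable)
}

#' Per-pixel local transfer-constant maps by non-negative least squares
#'
#' Unmixes every pixel time-course against the compartment basis:
#' `min_{w >= 0} || x_i - A %*% w ||`. The tissue columns of `w` are the
#' local volume transfer constants K_\{i,j\} and the plasma column is the
#' local plasma volume v_\{p,i\} (relative units). When the series carries
#' the per-pixel sums recorded by [normalize_sum()], the weights are
#' rescaled by them, which restores proportionality of each map column to
#' the underlying local transfer constants up to a single global
#' per-compartment scale.
#'
#' @param series a sum-normalized [dynamic_series()].
#' @param basis a [compartment_basis()] with a `plasma_index`.
#' @return an object of class `transfer_maps`: `ktrans_local`
#'   (N x (J-1)), `vp_local` (length N), `residual` (per-pixel residual norm
#'   on the normalized scale), `partial_volume_flag` (at purity threshold
#'   0.8), `weights` (full N x J), and the basis.
#' @export
fit_local_transfer_maps <- function(series, basis) {
  if (!inherits(basis, "compartment_basis")) stop("basis must be a compartment_basis")
  if (is.null(basis$plasma_index))
    stop("basis must identify its plasma column; see identify_plasma_vertex()")
  A <- basis$curves
  if (kappa(A) > 1e8)
    stop("ill-conditioned compartment basis (condition number > 1e8); ",
         "reduce the number of compartments J")
  X <- series$values
  N <- ncol(X); J <- ncol(A)
  W <- matrix(0, N, J)
  resid <- numeric(N)
  for (i in seq_len(N)) {
    if (all(X[, i] == 0)) next
    fit <- pracma::lsqnonneg(A, X[, i])
    W[i, ] <- fit$x
    resid[i] <- sqrt(max(fit$resid.norm, 0))
  }
  share <- W / pmax(rowSums(W), .Machine$double.eps)
  pv <- apply(share, 1, max) < 0.8
  if (!is.null(series$column_scale)) W <- W * series$column_scale
  structure(list(ktrans_local = W[, -basis$plasma_index, drop = FALSE],
                 vp_local = W[, basis$plasma_index],
                 residual = resid, partial_volume_flag = pv,
                 weights = W, basis = basis),
            class = "transfer_maps")
}

#' Fraction of partial-volume pixels
#'
#' A pixel is pure when its largest unmixing weight holds at least
#' `purity_threshold` of its total weight; the partial-volume fraction is
#' one minus the proportion of pure pixels. Zero-weight pixels are excluded
#' from the denominator with a warning.
#'
#' @param maps a `transfer_maps` from [fit_local_transfer_maps()].
#' @param purity_threshold weight share defining purity (default 0.8).
#' @return fraction in `[0, 1]`.
#' @export
partial_volume_fraction <- function(maps, purity_threshold = 0.8) {
  W <- maps$weights
  tot <- rowSums(W)
  if (any(tot == 0)) {
    warning("excluding ", sum(tot == 0), " zero-weight pixel(s)")
    W <- W[tot > 0, , drop = FALSE]
    tot <- tot[tot > 0]
  }
  share <- W / tot
  1 - mean(apply(share, 1, max) >= purity_threshold)
}

#' Compare fitted studies across timepoints
#'
#' Longitudinal comparison of per-compartment pharmacokinetics (e.g. before,
#' during and after therapy). Tissue compartments are matched across
#' timepoints by descending flux rate constant -- the fast-flow pool of one
#' timepoint is compared with the fast-flow pool of the next -- so the
#' matching is invariant to how each study's basis columns happen to be
#' ordered. Reported per compartment and timepoint: kep, relative K^trans,
#' and their percent deltas versus the previous timepoint, plus each study's
#' partial-volume fraction.
#'
#' @param results named list (>= 2) of fitted study bundles as returned by
#'   [deconvolve_series()], or any list whose elements carry a `pk`
#'   data.frame with columns `ktrans` and `kep` (and optionally
#'   `partial_volume_fraction`).
#' @return an object of class `longitudinal_comparison` with a tidy `table`
#'   data.frame; compartments of a timepoint with a differing J are left
#'   unmatched (`NA` deltas) rather than failing.
#' @export
longitudinal_compare <- function(results) {
  if (length(results) < 2) stop("need at least two fitted studies")
  labels <- names(results) %||% paste0("t", seq_along(results))
  labels[labels == ""] <- paste0("t", which(labels == ""))
  ordered <- lapply(results, function(r) {
    pk <- r$pk
    pk[order(-pk$kep), , drop = FALSE]
  })
  js <- vapply(ordered, nrow, integer(1))
  if (length(unique(js)) > 1)
    message("timepoints differ in compartment count; unmatched slots are NA")
  jmax <- max(js)
  rows <- list()
  for (ti in seq_along(ordered)) {
    for (ci in seq_len(jmax)) {
      cur <- if (ci <= js[ti]) ordered[[ti]][ci, ] else NULL
      prev <- if (ti > 1 && ci <= js[ti - 1]) ordered[[ti - 1]][ci, ] else NULL
      rows[[length(rows) + 1L]] <- data.frame(
        timepoint = labels[ti],
        pool_rank = ci,
        kep = if (!is.null(cur)) cur$kep else NA_real_,
        ktrans_rel = if (!is.null(cur)) cur$ktrans else NA_real_,
        delta_kep_pct = if (!is.null(cur) && !is.null(prev))
          100 * (cur$kep - prev$kep) / prev$kep else NA_real_,
        delta_ktrans_pct = if (!is.null(cur) && !is.null(prev))
          100 * (cur$ktrans - prev$ktrans) / prev$ktrans else NA_real_,
        partial_volume_fraction =
          results[[ti]]$partial_volume_fraction %||% NA_real_)
    }
  }
  structure(list(table = do.call(rbind, rows), timepoint_labels = labels),
            class = "longitudinal_comparison")
}

#' @export
print.longitudinal_comparison <- function(x, ...) {
  cat("<longitudinal_comparison> pools matched by descending kep\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}
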