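#' Impulse response of a tissue compartment
#'
#' The two-compartment kinetic model gives each tissue compartment the
#' exponential impulse response `exp(-kep * t)`: tracer entering the
#' interstitial space washes back to plasma at the flux rate constant k_ep.
#'
#' @param kep flux rate constant in /min, `>= 0`.
#' @param times sample times in minutes, non-negative and increasing.
#' @return numeric vector `exp(-kep * times)`, values in `(0, 1]`.
#' @export
tissue_impulse_response <- function(kep, times) {
  if (length(kep) != 1L || !is.finite(kep) || kep < 0)
    stop("kep must be a single non-negative rate (/min)")
  times <- as.numeric(times)
  if (any(times < 0) || any(diff(times) < 0))
    stop("times must be non-negative and increasing")
  exp(-kep * times)
}

# Causal discrete convolution of an input curve with an impulse response,
# left-rectangle quadrature: y_n = sum_{k <= n} cp_k h(t_n - t_k) dt_k with
# dt_k = t_{k+1} - t_k (last step repeated). Exact for impulse inputs.
.convolve_causal <- function(times, cp, impulse) {
  T <- length(times)
  dt <- diff(times)
  dt <- c(dt, dt[length(dt)])
  lag <- outer(times, times, "-")      # lag[n, k] = t_n - t_k
  H <- impulse(pmax(lag, 0))
  H[lag < 0] <- 0
  as.numeric(H %*% (cp * dt))
}

#' Solve the two-compartment kinetics for one tissue type
#'
#' Solves the first-order kinetic equation
#' \deqn{dC_e/dt = K^{trans} C_p(t) - k_{ep} C_e(t)}
#' whose solution is the causal convolution
#' \eqn{C_e(t) = K^{trans} (C_p \ast e^{-k_{ep} t})}. The convolution is
#' discretized with left-rectangle quadrature on the acquisition grid, which
#' is causal and exact for impulse inputs.
#'
#' @param cp a [plasma_input()].
#' @param ktrans volume transfer constant (/min), `>= 0`.
#' @param kep flux rate constant (/min), `>= 0`.
#' @return non-negative tissue concentration curve, same length as `cp$times`.
#' @export
solve_compartment <- function(cp, ktrans, kep) {
  if (!inherits(cp, "plasma_input")) stop("cp must be a plasma_input")
  if (length(ktrans) != 1L || !is.finite(ktrans) || ktrans < 0)
    stop("ktrans must be a single non-negative rate (/min)")
  if (length(kep) != 1L || !is.finite(kep) || kep < 0)
    stop("kep must be a single non-negative rate (/min)")
  ktrans * .convolve_causal(cp$times, cp$concentration,
                            function(t) exp(-kep * t))
}

#' Population plasma-input (arterial input function) model
#'
#' A standard multi-exponential bolus model for the plasma tracer
#' concentration: after the bolus onset `t0` the curve is
#' \eqn{C_p(t) = \sum_i a_i e^{-m_i (t - t_0)}}, optionally multiplied by a
#' smooth uptake ramp \eqn{1 - e^{-s (t - t_0)}} (sharpness `s`; the default
#' `Inf` gives an instantaneous onset). The curve is zero before onset and
#' peaks before any tissue curve convolved from it, which is what lets the
#' vertex of fastest tracer enhancement be identified as the plasma input.
#'
#' @param times sample times in minutes.
#' @param aif_params list with `amplitudes` (non-negative, same length as
#'   `decays`), `decays` (positive rates /min), `onset` (bolus arrival, min)
#'   and `sharpness` (uptake ramp rate /min, `Inf` = step onset).
#' @return a [plasma_input()].
#' @export
population_aif <- function(times,
                           aif_params = list(amplitudes = c(6, 1),
                                             decays = c(3, 0.15),
                                             onset = 0, sharpness = Inf)) {
  a <- as.numeric(aif_params$amplitudes)
  m <- as.numeric(aif_params$decays)
  t0 <- aif_params$onset %||% 0
  s <- aif_params$sharpness %||% Inf
  if (length(a) != length(m))
    stop("amplitudes and decays must have the same length")
  if (any(a < 0) || any(m <= 0) || s <= 0)
    stop("AIF amplitudes must be >= 0 and decay/sharpness rates > 0")
  tau <- pmax(as.numeric(times) - t0, 0)
  conc <- rowSums(exp(-outer(tau, m)) * rep(a, each = length(tau)))
  if (is.finite(s)) conc <- conc * (1 - exp(-s * tau))
  conc[as.numeric(times) < t0] <- 0
  plasma_input(times, conc)
}

#' Compartment basis: the mixing matrix of the pixel model
#'
#' Columns are the J compartment time-activity curves (sum-normalized when
#' they come from normalized cluster centers); one column is the plasma
#' input. Every pixel time-course is a non-negative linear combination of
#' these columns.
#'
#' @param curves T x J matrix, one compartment curve per column.
#' @param plasma_index column holding the plasma input function.
#' @param source_vertex optional cluster index each column was taken from.
#' @param normalized whether columns are expected to sum to one.
#' @return an object of class `compartment_basis`.
#' @export
compartment_basis <- function(curves, plasma_index = NULL,
                              source_vertex = NULL, normalized = TRUE) {
  curves <- as.matrix(curves)
  if (min(curves) < -1e-9) stop("compartment curves must be non-negative")
  if (normalized) {
    cs <- colSums(curves)
    if (any(abs(cs - 1) > 1e-6))
      stop("normalized basis columns must sum to 1 (+- 1e-6)")
  }
  if (qr(curves)$rank < ncol(curves))
    warning("compartment curves are not linearly independent; ",
            "the mixture model is unidentifiable")
  if (!is.null(plasma_index) &&
      (plasma_index < 1 || plasma_index > ncol(curves)))
    stop("plasma_index out of range")
  structure(list(curves = curves, plasma_index = plasma_index,
                 source_vertex = source_vertex),
            class = "compartment_basis")
}

#' Mix compartment curves into pixel time-courses
#'
#' Implements the pixel-mixture model: the time-course of pixel i is
#' \eqn{x_i(t) = \sum_j K_{i,j} C_j(t) + v_{p,i} C_p(t)}, i.e. a non-negative
#' linear combination of the compartment curves with the local volume
#' transfer constants (and local plasma volume) as weights.
#'
#' @param basis a [compartment_basis()] or a T x J curve matrix.
#' @param weights N x J non-negative weight matrix (rows = pixels); the
#'   column order must match the basis columns.
#' @param times optional timestamps for the resulting series.
#' @param ... passed to [dynamic_series()] (e.g. `shape`, `mask`).
#' @return a [dynamic_series()] with `values = curves %*% t(weights)`.
#' @export
mix_pixels <- function(basis, weights, times = NULL, ...) {
  curves <- if (inherits(basis, "compartment_basis")) basis$curves
            else as.matrix(basis)
  weights <- as.matrix(weights)
  if (ncol(weights) != ncol(curves))
    stop("weights must have one column per compartment curve")
  if (min(weights) < 0)
    stop("local volume transfer constants (weights) must be non-negative")
  dynamic_series(curves %*% t(weights), times = times, ...)
}
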