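#' Construct a dynamic imaging series
#'
#' A dynamic series is the central data container of the package: a
#' time-by-pixel matrix of tracer concentrations (each row is one acquisition
#' frame, each column one retained pixel), together with the acquisition
#' timestamps in minutes, the spatial grid the pixels came from, and an
#' optional boolean mask recording which grid positions the columns map to.
#'
#' @param values numeric T x N matrix of non-negative tracer concentrations;
#'   rows are frames, columns are pixels.
#' @param times acquisition timestamps in minutes, strictly increasing, one per
#'   frame. When `NULL`, uniform spacing `frame_interval` starting at 0 is used.
#' @param frame_interval frame spacing in minutes used when `times` is absent.
#'   The default, 0.5 min, corresponds to a typical dynamic protocol of one
#'   scan every 30 seconds.
#' @param shape optional integer vector of 2-D/3-D grid dimensions; the grid
#'   must hold at least N pixels.
#' @param mask optional logical array (matching `shape` when both are given)
#'   with exactly N `TRUE` cells, identifying the grid positions of the
#'   retained columns.
#' @param normalized logical; `TRUE` after sum normalization (every column
#'   sums to one).
#' @param pixel_index integer positions of the retained columns in the
#'   original grid; defaults to `which(mask)` or `1:N`.
#' @param column_scale optional per-pixel temporal sums recorded by
#'   [normalize_sum()] so that absolute weight scales can be restored later.
#'
#' @return an object of class `dynamic_series`.
#' @seealso [normalize_sum()], [read_series()], [generate_synthetic_study()]
#' @export
dynamic_series <- function(values, times = NULL, frame_interval = 0.5,
                           shape = NULL, mask = NULL, normalized = FALSE,
                           pixel_index = NULL, column_scale = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 2L)
    stop("a dynamic series needs at least two time frames (T >= 2)")
  if (!all(is.finite(values)))
    stop("all tracer concentrations must be finite")
  if (min(values) < -1e-12)
    stop("tracer concentrations must be non-negative")
  values[values < 0] <- 0
  if (is.null(times))
    times <- (seq_len(nrow(values)) - 1) * frame_interval
  times <- as.numeric(times)
  if (length(times) != nrow(values))
    stop("length(times) must equal the number of frames")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("timestamps must be finite and strictly increasing")
  if (!is.null(shape)) {
    shape <- as.integer(shape)
    if (prod(shape) < ncol(values))
      stop("prod(shape) must be at least the number of pixels")
  }
  if (!is.null(mask)) {
    storage.mode(mask) <- "logical"
    if (sum(mask) != ncol(values))
      stop("mask must select exactly N = ncol(values) pixels")
    if (!is.null(shape) && !identical(as.integer(dim(mask) %||% length(mask)),
                                      shape))
      stop("mask dimensions do not match shape")
  }
  if (is.null(pixel_index))
    pixel_index <- if (!is.null(mask)) which(mask) else seq_len(ncol(values))
  if (anyDuplicated(pixel_index))
    stop("pixel_index must be injective")
  out <- structure(
    list(times = times, values = values, shape = shape, mask = mask,
         normalized = isTRUE(normalized), pixel_index = as.integer(pixel_index),
         column_scale = column_scale),
    class = "dynamic_series")
  if (out$normalized) {
    cs <- colSums(values)
    if (any(abs(cs - 1) > 1e-9))
      stop("normalized series must have columns summing to 1 (+- 1e-9)")
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Number of frames / pixels of a dynamic series
#' @param series a [dynamic_series()]
#' @return integer count.
#' @export
n_frames <- function(series) nrow(series$values)

#' @rdname n_frames
#' @export
n_pixels <- function(series) ncol(series$values)

#' @export
print.dynamic_series <- function(x, ...) {
  cat(sprintf("<dynamic_series> %d frames x %d pixels, t = %.3g..%.3g min%s\n",
              n_frames(x), n_pixels(x), min(x$times), max(x$times),
              if (x$normalized) " (sum-normalized)" else ""))
  if (!is.null(x$shape))
    cat("  grid:", paste(x$shape, collapse = " x "), "\n")
  invisible(x)
}

#' Plasma input function (AIF)
#'
#' The tracer concentration in plasma, \eqn{C_p(t)}: the driving input of the
#' two-compartment kinetic model.
#'
#' @param times timestamps in minutes, strictly increasing.
#' @param concentration non-negative plasma tracer concentration, one value
#'   per timestamp.
#' @return an object of class `plasma_input`.
#' @export
plasma_input <- function(times, concentration) {
  times <- as.numeric(times)
  concentration <- as.numeric(concentration)
  if (length(times) != length(concentration))
    stop("times and concentration must have the same length")
  if (any(!is.finite(times)) || any(diff(times) <= 0))
    stop("timestamps must be finite and strictly increasing")
  if (any(!is.finite(concentration)) || min(concentration) < -1e-12)
    stop("plasma concentrations must be finite and non-negative")
  concentration[concentration < 0] <- 0
  structure(list(times = times, concentration = concentration),
            class = "plasma_input")
}

#' @export
print.plasma_input <- function(x, ...) {
  cat(sprintf("<plasma_input> %d samples, peak %.4g at t = %.3g min\n",
              length(x$times), max(x$concentration),
              x$times[which.max(x$concentration)]))
  invisible(x)
}

#' Per-compartment pharmacokinetic parameters
#'
#' Holds the tissue-compartment parameters of the two-compartment model:
#' the unidirectional volume transfer constant K^trans (/min; relative units
#' when estimated from sum-normalized curves), the flux rate constant k_ep
#' (/min) governing washout, and the plasma volume fraction v_p.
#'
#' @param ktrans volume transfer constants, one per tissue compartment (/min).
#' @param kep flux rate constants, one per tissue compartment (/min).
#' @param vp plasma volume fraction in `[0, 1]` (a single typical value).
#' @return an object of class `pk_parameters`.
#' @export
pk_parameters <- function(ktrans, kep, vp = 0) {
  ktrans <- as.numeric(ktrans); kep <- as.numeric(kep)
  if (length(ktrans) != length(kep))
    stop("ktrans and kep must have one entry per tissue compartment")
  if (any(ktrans < 0) || any(kep < 0))
    stop("pharmacokinetic rate constants must be non-negative")
  if (vp < 0 || vp > 1) stop("vp must lie in [0, 1]")
  structure(list(ktrans = ktrans, kep = kep, vp = vp), class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("<pk_parameters>\n")
  print(data.frame(compartment = seq_along(x$ktrans),
                   ktrans = x$ktrans, kep = x$kep))
  cat("  vp:", x$vp, "\n")
  invisible(x)
}
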