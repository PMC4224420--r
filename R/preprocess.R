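#' Restrict a dynamic series to a masked region
#'
#' Keeps only the pixels inside a boolean region-of-interest mask (e.g. a
#' tumour outline), preserving frame order. The mask is given on the series'
#' spatial grid and is matched against the positions the current columns map
#' to, so masking an already-masked series composes correctly.
#'
#' @param series a [dynamic_series()] carrying a `shape`.
#' @param mask logical array on the grid (same dimensions as `series$shape`).
#' @return the masked [dynamic_series()].
#' @export
apply_mask <- function(series, mask) {
  if (!inherits(series, "dynamic_series")) stop("series must be a dynamic_series")
  storage.mode(mask) <- "logical"
  shape <- series$shape %||% dim(mask)
  if (!is.null(series$shape) &&
      !identical(as.integer(dim(mask) %||% length(mask)), as.integer(shape)))
    stop("mask dimensions do not match the series grid")
  keep <- mask[series$pixel_index]
  if (!any(keep)) stop("mask selects zero pixels of the series")
  new_mask <- array(FALSE, shape)
  new_mask[series$pixel_index[keep]] <- TRUE
  dynamic_series(series$values[, keep, drop = FALSE], times = series$times,
                 shape = shape, mask = new_mask,
                 normalized = series$normalized,
                 pixel_index = series$pixel_index[keep],
                 column_scale = series$column_scale[keep])
}

#' Remove initial pre-uptake frames
#'
#' Drops the first `k` frames of the series: these precede sufficient onsite
#' tracer uptake (typically the four initial images of a dynamic protocol)
#' and carry no kinetic information.
#'
#' @param series a [dynamic_series()].
#' @param k number of initial frames to remove (default 4); must leave at
#'   least one frame.
#' @return the shortened [dynamic_series()].
#' @export
drop_initial_frames <- function(series, k = 4) {
  if (!inherits(series, "dynamic_series")) stop("series must be a dynamic_series")
  k <- as.integer(k)
  if (k < 0 || k >= n_frames(series))
    stop("k must satisfy 0 <= k < number of frames")
  if (k == 0L) return(series)
  keep <- (k + 1L):n_frames(series)
  if (length(keep) < 2L)
    warning("single-frame series after frame removal; downstream steps need T >= 2")
  dynamic_series(series$values[keep, , drop = FALSE],
                 times = series$times[keep], shape = series$shape,
                 mask = series$mask, normalized = FALSE,
                 pixel_index = series$pixel_index,
                 column_scale = series$column_scale)
}

#' Preprocessing report
#'
#' Bookkeeping of the uninformative-pixel filter: how many pixels failed the
#' temporal-mean rule, how many the temporal-variation rule (pixels failing
#' both are counted once, under the mean rule), and the mapping from retained
#' columns back to original grid positions.
#' @param n_frames_removed,n_pixels_in,n_pixels_removed_low_mean,n_pixels_removed_low_variation,n_pixels_out,retained_index report fields.
#' @return an object of class `preprocess_report`.
#' @export
preprocess_report <- function(n_frames_removed, n_pixels_in,
                              n_pixels_removed_low_mean,
                              n_pixels_removed_low_variation,
                              n_pixels_out, retained_index) {
  stopifnot(n_pixels_out == n_pixels_in - n_pixels_removed_low_mean -
              n_pixels_removed_low_variation,
            !anyDuplicated(retained_index))
  structure(list(n_frames_removed = n_frames_removed,
                 n_pixels_in = n_pixels_in,
                 n_pixels_removed_low_mean = n_pixels_removed_low_mean,
                 n_pixels_removed_low_variation = n_pixels_removed_low_variation,
                 n_pixels_out = n_pixels_out,
                 retained_index = retained_index),
            class = "preprocess_report")
}

#' @export
print.preprocess_report <- function(x, ...) {
  cat(sprintf(paste0("<preprocess_report> %d -> %d pixels ",
                     "(%d low mean, %d low variation), %d frames removed\n"),
              x$n_pixels_in, x$n_pixels_out, x$n_pixels_removed_low_mean,
              x$n_pixels_removed_low_variation, x$n_frames_removed))
  invisible(x)
}

#' Filter uninformative pixels
#'
#' Removes pixels whose temporal average signal is lower than `mean_frac`
#' (default 5%) of the maximum temporal average over pixels, or whose
#' temporal dynamic variation is lower than `var_frac` (default 5%) of the
#' maximum variation over pixels. Variation is measured as the temporal
#' standard deviation by default; `var_stat = "range"` uses the
#' peak-to-trough range instead. Each threshold is relative to the maximum of
#' its own statistic, making both rules scale-free.
#'
#' @param series a [dynamic_series()] (not yet normalized).
#' @param mean_frac,var_frac thresholds as fractions of the per-statistic
#'   maximum over pixels.
#' @param var_stat `"sd"` (default) or `"range"`.
#' @param n_frames_removed frames already removed upstream, recorded in the
#'   report.
#' @return list with `series` (filtered) and `report` (a
#'   [preprocess_report()]).
#' @export
filter_uninformative_pixels <- function(series, mean_frac = 0.05,
                                        var_frac = 0.05,
                                        var_stat = c("sd", "range"),
                                        n_frames_removed = 0L) {
  if (!inherits(series, "dynamic_series")) stop("series must be a dynamic_series")
  var_stat <- match.arg(var_stat)
  x <- series$values
  mu <- colMeans(x)
  v <- if (var_stat == "sd") apply(x, 2, stats::sd)
       else apply(x, 2, function(col) diff(range(col)))
  low_mean <- mu < mean_frac * max(mu)
  low_var <- v < var_frac * max(v)
  keep <- !(low_mean | low_var)
  if (!any(keep))
    stop("all pixels were removed as uninformative; lower the thresholds")
  out <- dynamic_series(x[, keep, drop = FALSE], times = series$times,
                        shape = series$shape,
                        mask = if (is.null(series$mask)) NULL else {
                          m <- series$mask; m[series$pixel_index[!keep]] <- FALSE; m
                        },
                        normalized = series$normalized,
                        pixel_index = series$pixel_index[keep],
                        column_scale = series$column_scale[keep])
  report <- preprocess_report(
    n_frames_removed = as.integer(n_frames_removed),
    n_pixels_in = n_pixels(series),
    n_pixels_removed_low_mean = sum(low_mean),
    n_pixels_removed_low_variation = sum(low_var & !low_mean),
    n_pixels_out = sum(keep),
    retained_index = series$pixel_index[keep])
  list(series = out, report = report)
}

#' Sum-normalize pixel time-courses
#'
#' Divides every pixel time-course by its temporal sum so that each column
#' sums to one. This focuses the analysis on the shape of the
#' pharmacokinetics rather than the absolute tracer concentration and places
#' every pixel on the unit simplex, the geometry exploited by convex analysis
#' of mixtures. The per-pixel sums are stored in `column_scale` so absolute
#' weight scales can be restored when fitting transfer-constant maps.
#' Normalizing an already-normalized series is a no-op.
#'
#' @param series a [dynamic_series()] whose columns all have positive sums.
#' @return the normalized [dynamic_series()].
#' @export
normalize_sum <- function(series) {
  if (!inherits(series, "dynamic_series")) stop("series must be a dynamic_series")
  if (series$normalized) return(series)
  cs <- colSums(series$values)
  if (any(cs <= 0))
    stop("zero-sum pixel time-course; run filter_uninformative_pixels() first")
  dynamic_series(sweep(series$values, 2, cs, "/"), times = series$times,
                 shape = series$shape, mask = series$mask, normalized = TRUE,
                 pixel_index = series$pixel_index, column_scale = cs)
}

#' Full preprocessing pipeline
#'
#' Applies the fixed preprocessing order: region mask, removal of the initial
#' pre-uptake frames, elimination of uninformative pixels, and sum
#' normalization.
#'
#' @param series a [dynamic_series()].
#' @param mask optional region-of-interest mask, see [apply_mask()].
#' @param drop_frames initial frames to remove (default 4).
#' @param mean_frac,var_frac,var_stat see [filter_uninformative_pixels()].
#' @return list with `series` (preprocessed, normalized) and `report`.
#' @export
preprocess <- function(series, mask = NULL, drop_frames = 4,
                       mean_frac = 0.05, var_frac = 0.05, var_stat = "sd") {
  if (!is.null(mask)) series <- apply_mask(series, mask)
  series <- drop_initial_frames(series, drop_frames)
  filtered <- filter_uninformative_pixels(series, mean_frac, var_frac,
                                          var_stat = var_stat,
                                          n_frames_removed = drop_frames)
  list(series = normalize_sum(filtered$series), report = filtered$report)
}
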