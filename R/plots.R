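#' Scatter-simplex plot
#'
#' Projects the normalized pixel time-courses and the cluster centers onto
#' the convexity-preserving plane of the selected vertices
#' ([convexity_projection()]) and draws the candidate simplex: interior
#' (partial-volume) pixels fall inside the polygon whose corners are the
#' compartment vertices.
#'
#' @param fit a `dce_fit` bundle from [deconvolve_series()], or a
#'   `cluster_set` together with `solution`.
#' @param solution a `vertex_solution` when `fit` is a `cluster_set`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the projected pixel coordinates.
#' @export
plot_scatter_simplex <- function(fit, solution = NULL, ...) {
  if (inherits(fit, "dce_fit")) {
    series <- fit$series; clusters <- fit$clusters; solution <- fit$solution
  } else {
    series <- NULL; clusters <- fit
    if (is.null(solution)) stop("supply a vertex_solution")
  }
  pts <- if (!is.null(series)) convexity_projection(series, solution)
         else convexity_projection(clusters, solution)
  cent <- convexity_projection(clusters, solution)
  vert <- cent[solution$vertex_cluster_index, , drop = FALSE]
  graphics::plot(pts, pch = 16, cex = 0.4, col = "grey60",
                 xlab = "projection 1", ylab = "projection 2",
                 main = "Scatter simplex of normalized pixel time-courses",
                 ...)
  hull <- grDevices::chull(vert)
  graphics::polygon(vert[hull, 1], vert[hull, 2], border = "firebrick",
                    lwd = 2)
  graphics::points(cent, pch = 4, col = "steelblue", lwd = 2)
  graphics::points(vert, pch = 17, col = "firebrick", cex = 1.4)
  invisible(pts)
}

#' MDL model-selection curve
#'
#' Description code length against the candidate number of compartments;
#' the chosen J is the minimum.
#'
#' @param ms a `model_selection_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot_mdl_curve <- function(ms, ...) {
  graphics::plot(ms$candidates, ms$code_length, type = "b", pch = 16,
                 xlab = "number of compartments J",
                 ylab = "description code length", ...)
  graphics::abline(v = ms$chosen_J, lty = 2, col = "firebrick")
  invisible(ms)
}

#' Write per-compartment transfer-constant maps as grayscale PNG images
#'
#' Renders every column of the local transfer-constant maps (and the plasma
#' volume map) back onto the spatial grid.
#'
#' @param maps a `transfer_maps`.
#' @param series the preprocessed [dynamic_series()] the maps were fitted on
#'   (supplies grid shape and pixel positions).
#' @param dir output directory.
#' @return the written file paths, invisibly.
#' @export
write_map_images <- function(maps, series, dir) {
  if (is.null(series$shape) || length(series$shape) != 2)
    stop("map images need a 2-D grid shape on the series")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  W <- cbind(maps$ktrans_local, vp = maps$vp_local)
  labs <- c(paste0("ktrans_local", seq_len(ncol(maps$ktrans_local))),
            "vp_local")
  paths <- character(0)
  for (j in seq_len(ncol(W))) {
    img <- matrix(0, series$shape[1], series$shape[2])
    img[series$pixel_index] <- W[, j]
    path <- file.path(dir, paste0(labs[j], ".png"))
    grDevices::png(path, 480, 480)
    graphics::image(t(img[nrow(img):1, ]), col = grDevices::gray.colors(256),
                    axes = FALSE, main = labs[j], useRaster = TRUE)
    grDevices::dev.off()
    paths <- c(paths, path)
  }
  invisible(paths)
}
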