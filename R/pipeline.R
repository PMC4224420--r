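#' Deconvolve a dynamic series into vascular compartments
#'
#' The full unsupervised analysis on an in-memory series: preprocessing
#' (mask, initial-frame removal, uninformative-pixel filter, sum
#' normalization), affinity-propagation + EM clustering, exhaustive
#' simplex-vertex identification, MDL detection of the compartment count
#' (unless `j` is fixed), plasma-vertex identification, per-compartment
#' flux-rate / transfer-constant estimation, and per-pixel non-negative
#' least-squares transfer-constant maps.
#'
#' @param series a raw [dynamic_series()].
#' @param mask optional region-of-interest mask.
#' @param j fixed compartment count; `NULL` (default) selects J by MDL.
#' @param j_min,j_max MDL candidate range.
#' @param drop_frames,mean_frac,var_frac preprocessing settings, see
#'   [preprocess()].
#' @param damping,preference,preference_scale clustering settings, see
#'   [cluster_series()].
#' @param refine run the EM refinement pass (default TRUE).
#' @param seed passed to the clustering stage.
#' @return a bundle (class `dce_fit`) with elements `series` (preprocessed),
#'   `report`, `clusters`, `model_selection` (`NULL` when `j` was fixed),
#'   `solution`, `basis`, `pk` (per-tissue-compartment data.frame with
#'   `ktrans`, `kep`, `fit_residual`, `reliable`), `maps`,
#'   `partial_volume_fraction` and `chosen_J`.
#' @export
deconvolve_series <- function(series, mask = NULL, j = NULL,
                              j_min = 2, j_max = 6, drop_frames = 4,
                              mean_frac = 0.05, var_frac = 0.05,
                              damping = 0.9, preference = "median",
                              preference_scale = 3,
                              refine = TRUE, seed = NULL) {
  pre <- preprocess(series, mask = mask, drop_frames = drop_frames,
                    mean_frac = mean_frac, var_frac = var_frac)
  clusters <- cluster_series(pre$series, damping = damping,
                             preference = preference,
                             preference_scale = preference_scale,
                             refine = refine, seed = seed)
  ms <- NULL
  if (is.null(j)) {
    ms <- select_num_compartments(clusters, j_min = j_min, j_max = j_max)
    j <- ms$chosen_J
    solution <- ms$fit_per_J[[paste0("J", j)]]
  } else {
    solution <- enumerate_vertex_sets(clusters, j)
  }
  curves <- t(solution$vertices)                 # T x J, columns sum to 1
  plasma <- identify_plasma_vertex(curves, pre$series$times)
  basis <- compartment_basis(curves, plasma_index = plasma,
                             source_vertex = solution$vertex_cluster_index)
  cp <- plasma_input(pre$series$times, curves[, plasma])
  tissue <- setdiff(seq_len(j), plasma)
  pk <- do.call(rbind, lapply(seq_along(tissue), function(k) {
    fit <- fit_flux_rate(curves[, tissue[k]], cp)
    data.frame(compartment = k, basis_column = tissue[k],
               ktrans = fit$ktrans, kep = fit$kep,
               fit_residual = fit$fit_residual, reliable = fit$reliable)
  }))
  maps <- fit_local_transfer_maps(pre$series, basis)
  structure(list(series = pre$series, report = pre$report,
                 clusters = clusters, model_selection = ms,
                 solution = solution, basis = basis, pk = pk,
                 maps = maps,
                 partial_volume_fraction = partial_volume_fraction(maps),
                 chosen_J = j, seed = seed),
            class = "dce_fit")
}

#' @export
print.dce_fit <- function(x, ...) {
  cat(sprintf("<dce_fit> J = %d compartments from M = %d clusters (total margin %.4g)\n",
              x$chosen_J, nrow(x$clusters$centers), x$solution$total_margin))
  print(x$pk, row.names = FALSE)
  cat(sprintf("  partial-volume fraction: %.3f\n", x$partial_volume_fraction))
  invisible(x)
}

#' Run the pipeline on a file and write the result bundle
#'
#' Thin driver around [read_series()] and [deconvolve_series()] that writes
#' every result table to `out_dir`: the MDL curve, basis curves, the
#' pharmacokinetic parameter table, the per-pixel transfer-constant maps,
#' the vertex solution, the preprocessing report, a scatter-simplex plot,
#' and a run manifest recording the seed, package version and a hash of the
#' configuration. Outputs are a pure function of the input and seed.
#'
#' @param input path to a series file, or a [dynamic_series()].
#' @param out_dir output directory (created if needed).
#' @param seed integer seed recorded in the manifest and used by the
#'   stochastic stages.
#' @param write_plots write PNG diagnostics (default TRUE).
#' @param ... further arguments to [deconvolve_series()] and
#'   [read_series()] (`frame_interval`, `transpose`, `j`, thresholds, ...).
#' @return the [deconvolve_series()] bundle, invisibly.
#' @export
run_pipeline <- function(input, out_dir, seed = 1, write_plots = TRUE, ...) {
  args <- list(...)
  read_args <- args[names(args) %in% c("format", "frame_interval", "times",
                                       "transpose", "shape")]
  fit_args <- args[!names(args) %in% names(read_args)]
  series <- if (inherits(input, "dynamic_series")) input
            else do.call(read_series, c(list(path = input), read_args))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- do.call(deconvolve_series,
                 c(list(series = series, seed = seed), fit_args))
  ok <- FALSE
  on.exit(if (!ok) unlink(file.path(out_dir, .pipeline_outputs), force = TRUE))

  if (!is.null(fit$model_selection))
    data.table::fwrite(data.table::data.table(
      J = fit$model_selection$candidates,
      code_length = fit$model_selection$code_length),
      file.path(out_dir, "mdl_curve.csv"))
  basis_dt <- data.table::as.data.table(fit$basis$curves)
  names(basis_dt) <- paste0("compartment", seq_len(ncol(fit$basis$curves)))
  basis_dt <- cbind(data.table::data.table(time = fit$series$times), basis_dt)
  data.table::fwrite(basis_dt, file.path(out_dir, "basis_curves.csv"))
  data.table::fwrite(fit$pk, file.path(out_dir, "pk_parameters.csv"))
  maps_dt <- data.table::data.table(pixel_index = fit$series$pixel_index)
  kt <- fit$maps$ktrans_local
  colnames(kt) <- paste0("ktrans_local", seq_len(ncol(kt)))
  maps_dt <- cbind(maps_dt, data.table::as.data.table(kt),
                   data.table::data.table(vp_local = fit$maps$vp_local,
                                          residual = fit$maps$residual))
  data.table::fwrite(maps_dt, file.path(out_dir, "transfer_maps.csv"))
  jsonlite::write_json(
    list(vertex_cluster_index = fit$solution$vertex_cluster_index,
         total_margin = fit$solution$total_margin,
         per_center_margin = fit$solution$per_center_margin,
         candidate_count = fit$solution$candidate_count),
    file.path(out_dir, "vertex_solution.json"), auto_unbox = TRUE, digits = NA)
  write_report(fit$report, file.path(out_dir, "preprocess_report.json"))
  if (write_plots) {
    grDevices::png(file.path(out_dir, "scatter_simplex.png"), 720, 720)
    plot_scatter_simplex(fit)
    grDevices::dev.off()
    if (!is.null(fit$model_selection)) {
      grDevices::png(file.path(out_dir, "mdl_curve.png"), 720, 480)
      plot_mdl_curve(fit$model_selection)
      grDevices::dev.off()
    }
  }
  cfg <- c(list(seed = seed), fit_args)
  tmp <- tempfile(); jsonlite::write_json(cfg, tmp, auto_unbox = TRUE,
                                          force = TRUE)
  manifest <- list(seed = seed,
                   package_version = as.character(utils::packageVersion("camdce")),
                   r_version = as.character(getRversion()),
                   config_hash = unname(tools::md5sum(tmp)),
                   chosen_J = fit$chosen_J,
                   n_clusters = nrow(fit$clusters$centers),
                   total_margin = fit$solution$total_margin,
                   partial_volume_fraction = fit$partial_volume_fraction)
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  ok <- TRUE
  invisible(fit)
}

.pipeline_outputs <- c("mdl_curve.csv", "basis_curves.csv",
                       "pk_parameters.csv", "transfer_maps.csv",
                       "vertex_solution.json", "preprocess_report.json",
                       "scatter_simplex.png", "mdl_curve.png",
                       "manifest.json")
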