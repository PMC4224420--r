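#' Configuration of a synthetic dynamic study
#'
#' Describes one synthetic validation study: a J-compartment model (J-1
#' tissue pools plus one plasma input), customized per-compartment local
#' volume transfer constant maps on a rectangular grid with designated
#' pure-pixel patches, and additive Gaussian noise at a given SNR.
#'
#' The default geometry emulates the rim/core vascular heterogeneity of an
#' angiogenic tumour: a fast-washout pool concentrated on a peripheral rim,
#' a slow pool in the core, and a heterogeneous plasma volume fraction. Every
#' compartment (including plasma) owns a rectangular patch of pure-volume
#' pixels, the identifiability condition for convex analysis of mixtures.
#'
#' @param J total number of compartments including the plasma input
#'   (default 3: two tissue pools + plasma).
#' @param pk [pk_parameters()] for the `J - 1` tissue compartments. The
#'   default pairs a fast pool (kep = 1.5/min) with a 10x slower pool
#'   (kep = 0.15/min).
#' @param aif_params plasma-input model parameters, see [population_aif()].
#'   The default bolus arrives at 1.8 min -- so the four initial frames of a
#'   0.5-min protocol are pre-contrast -- and rises with a smooth uptake
#'   ramp (sharpness 6/min), the standard population-AIF shape.
#' @param grid 2-D pixel grid dimensions.
#' @param map_spec geometry of the transfer-constant maps: `pure_patch`
#'   (side of the square pure-pixel region per compartment), `band_width`
#'   (radial width of each tissue pool's Gaussian profile), `vp_base` and
#'   `vp_peak` (plasma volume fraction range).
#' @param n_frames,frame_interval temporal sampling (default 19 frames every
#'   0.5 min, so that dropping the four pre-contrast frames leaves 15).
#' @param snr_db signal-to-noise ratio of the additive Gaussian noise in dB,
#'   defined as `10*log10(mean(signal^2)/noise variance)`; `Inf` = noise-free.
#' @param n_replicates number of replicated noisy datasets.
#' @param seed integer seed making the study reproducible.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(J = 3,
                             pk = pk_parameters(ktrans = c(0.25, 0.08),
                                                kep = c(1.5, 0.15)),
                             aif_params = list(amplitudes = c(6, 1),
                                               decays = c(3, 0.15),
                                               onset = 1.8, sharpness = 6),
                             grid = c(20, 20),
                             map_spec = list(pure_patch = 3, band_width = 0.22,
                                             vp_base = 0.02, vp_peak = 0.08),
                             n_frames = 19, frame_interval = 0.5,
                             snr_db = 30, n_replicates = 1, seed = 1) {
  if (J < 2) stop("J must be at least 2 (one tissue pool + plasma)")
  if (!inherits(pk, "pk_parameters")) stop("pk must be pk_parameters()")
  if (length(pk$kep) != J - 1)
    stop("pk must describe exactly J - 1 tissue compartments")
  if (anyDuplicated(pk$kep))
    stop("tissue kep values must be distinct for an identifiable study")
  if (length(grid) != 2 || any(grid < 4))
    stop("grid must give two dimensions of at least 4 pixels")
  if (is.na(snr_db)) stop("snr_db must be finite or Inf")
  if (J * map_spec$pure_patch > grid[2])
    stop("grid too narrow to place one pure-pixel patch per compartment")
  structure(list(J = J, pk = pk, aif_params = aif_params, grid = as.integer(grid),
                 map_spec = map_spec, n_frames = as.integer(n_frames),
                 frame_interval = frame_interval, snr_db = snr_db,
                 n_replicates = as.integer(n_replicates), seed = as.integer(seed)),
            class = "synthetic_config")
}

# Ground-truth transfer-constant maps on the grid: smooth radial profiles
# (rim for the fastest pool, core for the slowest) plus one square pure patch
# per compartment. Returns N x J weights, plasma column last.
.truth_maps <- function(config) {
  nr <- config$grid[1]; nc <- config$grid[2]
  Jt <- config$J - 1
  rc <- (nr + 1) / 2; cc <- (nc + 1) / 2
  ix <- matrix(seq_len(nr), nr, nc)        # row index per pixel
  jx <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  d <- sqrt(((ix - rc) / (nr / 2))^2 + ((jx - cc) / (nc / 2))^2)
  d <- pmin(as.numeric(d), 1)
  bw <- config$map_spec$band_width
  # tissue pool j centred on radius c_j: fastest pool outermost (rim),
  # slowest innermost (core); kep sorted descending onto radii descending
  ord <- order(config$pk$kep, decreasing = TRUE)
  radii <- if (Jt == 1) 0.75 else seq(0.8, 0, length.out = Jt)
  W <- matrix(0, nr * nc, config$J)
  for (k in seq_len(Jt)) {
    j <- ord[k]
    W[, j] <- config$pk$ktrans[j] * exp(-((d - radii[k]) / bw)^2)
  }
  W[, config$J] <- config$map_spec$vp_base +
    (config$map_spec$vp_peak - config$map_spec$vp_base) *
    exp(-((d - 0.75) / 0.3)^2)
  # pure patches: compartment j owns a pure_patch^2 square along the top edge
  p <- config$map_spec$pure_patch
  pure <- vector("list", config$J)
  scales <- c(config$pk$ktrans, config$map_spec$vp_peak)
  for (j in seq_len(config$J)) {
    rows <- 2:(1 + p)
    cols <- ((j - 1) * p + 1):(j * p)
    idx <- as.integer(outer(rows, (cols - 1) * nr, "+"))  # column-major ids
    W[idx, ] <- 0
    W[idx, j] <- scales[j]
    pure[[j]] <- idx
  }
  list(weights = W, pure_pixel_index = pure)
}

#' Generate a synthetic dynamic study with ground truth
#'
#' Builds the compartment time-activity curves from the plasma-input model
#' and the two-compartment kinetics (unit-amplitude convolution per tissue
#' pool), multiplies them with the customized local volume transfer constant
#' maps of [synthetic_config()], and adds i.i.d. Gaussian noise at the
#' requested SNR (clipped at zero). The generator is a pure function of the
#' configuration: the same seed reproduces the study bitwise.
#'
#' @param config a [synthetic_config()].
#' @param replicate which noise replicate to generate (1..`n_replicates`);
#'   replicates share the ground-truth maps and curves and differ only in
#'   the noise draw.
#' @return a list with `series` (a [dynamic_series()]) and `truth`, where
#'   `truth` holds `basis` (T x J unnormalized compartment curves, plasma
#'   last), `basis_normalized`, `maps` (N x J true local weights), `aif`,
#'   `pure_pixel_index` (per compartment) and `partial_volume_fraction`
#'   (designed fraction of mixed pixels at purity threshold 0.8).
#' @export
generate_synthetic_study <- function(config = synthetic_config(),
                                     replicate = 1) {
  if (!inherits(config, "synthetic_config"))
    stop("config must be a synthetic_config()")
  if (replicate < 1 || replicate > config$n_replicates)
    stop("replicate out of range 1..n_replicates")
  times <- (seq_len(config$n_frames) - 1) * config$frame_interval
  aif <- population_aif(times, config$aif_params)
  Jt <- config$J - 1
  curves <- matrix(0, config$n_frames, config$J)
  for (j in seq_len(Jt))
    curves[, j] <- solve_compartment(aif, 1, config$pk$kep[j])
  curves[, config$J] <- aif$concentration
  tm <- .truth_maps(config)
  signal <- curves %*% t(tm$weights)

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed + 100003L * (replicate - 1L))
  values <- signal
  if (is.finite(config$snr_db)) {
    sd_noise <- sqrt(mean(signal^2) / 10^(config$snr_db / 10))
    values <- pmax(signal + matrix(stats::rnorm(length(signal), 0, sd_noise),
                                   nrow(signal)), 0)
  }

  bn <- sweep(curves, 2, colSums(curves), "/")
  share <- tm$weights * rep(colSums(curves), each = nrow(tm$weights))
  share <- share / rowSums(share)
  pvf <- 1 - mean(apply(share, 1, max) >= 0.8)
  series <- dynamic_series(values, times = times, shape = config$grid,
                           mask = array(TRUE, config$grid))
  truth <- list(basis = curves, basis_normalized = bn, maps = tm$weights,
                aif = aif, pure_pixel_index = tm$pure_pixel_index,
                plasma_index = config$J,
                partial_volume_fraction = pvf, config = config)
  list(series = series, truth = truth)
}
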