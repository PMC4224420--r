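# Shared fixtures: small analytic curves, constructed cluster sets, and the
# brute-force margin oracle used to cross-check the exact QP solver.

fix_times <- function(T = 15, dt = 0.5, start = 0) start + (seq_len(T) - 1) * dt

fix_aif <- function(times, onset = 0.5, sharpness = 6) {
  population_aif(times, list(amplitudes = c(6, 1), decays = c(3, 0.15),
                             onset = onset, sharpness = sharpness))
}

# True compartment curves (tissue pools first, plasma last), unnormalized
# and sum-normalized, on a shared time grid.
fix_basis <- function(times = fix_times(), kep = c(1.5, 0.15), onset = 0.5) {
  aif <- fix_aif(times, onset)
  curves <- vapply(kep, function(k) solve_compartment(aif, 1, k),
                   numeric(length(times)))
  curves <- cbind(curves, aif$concentration)
  list(curves = curves,
       normalized = sweep(curves, 2, colSums(curves), "/"),
       aif = aif, kep = kep, plasma = ncol(curves))
}

# Noise-free cluster set: the J true normalized curves plus strict convex
# combinations of them, as an M x T center matrix (truth in rows 1..J).
fix_centers <- function(basis = fix_basis(), n_mix = 7, seed = 7) {
  if (n_mix == 0) return(t(basis$normalized))
  withr::with_seed(seed, {
    J <- ncol(basis$normalized)
    mix <- matrix(stats::runif(n_mix * J, 0.1, 1), n_mix)
    mix <- mix / rowSums(mix)
    rbind(t(basis$normalized), mix %*% t(basis$normalized))
  })
}

# Brute-force margin oracle: minimize ||x - V alpha|| over the simplex grid
# with step `step`, for J <= 3 (vectorized over the grid).
grid_margin <- function(point, vertices, step = 1e-3) {
  V <- as.matrix(vertices)
  J <- ncol(V)
  stopifnot(J <= 3)
  a1 <- seq(0, 1, by = step)
  A <- switch(J,
    matrix(1, 1, 1),
    rbind(a1, 1 - a1),
    {
      g <- expand.grid(a1 = a1, a2 = a1)
      g <- g[g$a1 + g$a2 <= 1 + 1e-12, ]
      rbind(g$a1, g$a2, pmax(1 - g$a1 - g$a2, 0))
    })
  R <- V %*% A - as.numeric(point)
  sqrt(min(colSums(R^2)))
}

# Max absolute error between two curve sets after optimal column matching.
perm_matched_error <- function(est, truth) {
  J <- ncol(truth)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], p)
    out
  }
  min(vapply(perms(seq_len(J)), function(p)
    max(abs(est[, p, drop = FALSE] - truth)), numeric(1)))
}

# One default synthetic study fitted end-to-end, computed lazily and shared
# across tests in a file.
.fixture_env <- new.env(parent = emptyenv())
fix_default_fit <- function() {
  if (is.null(.fixture_env$fit)) {
    st <- generate_synthetic_study(synthetic_config(snr_db = 30, seed = 2024))
    .fixture_env$study <- st
    .fixture_env$fit <- deconvolve_series(st$series)
  }
  list(study = .fixture_env$study, fit = .fixture_env$fit)
}
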