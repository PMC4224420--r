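test_that("the plasma vertex is the curve of fastest enhancement", {
  b <- fix_basis()
  expect_equal(identify_plasma_vertex(b$normalized), b$plasma)
  # explicit peak frames 2 and 7
  two <- cbind(c(0, 1, 0.8, 0.6, 0.5, 0.4, 0.3, 0.2),
               c(0, 0.1, 0.2, 0.4, 0.6, 0.8, 1, 0.9))
  expect_equal(identify_plasma_vertex(two), 1L)
  # peak-frame tie broken by the steeper initial upslope
  tie <- cbind(c(0.1, 0.2, 1, 0.5, 0.3), c(0.8, 0.9, 1, 0.7, 0.6))
  expect_equal(identify_plasma_vertex(tie), 1L)
  flat <- cbind(rep(0.2, 5), rep(0.2, 5))
  expect_error(identify_plasma_vertex(flat), "ambiguous")
})

test_that("the Toeplitz operator discretizes the causal convolution", {
  tms <- fix_times(8, 1)
  delta <- plasma_input(tms, c(1, rep(0, 7)))
  Tm <- toeplitz_input_matrix(delta)
  h <- exp(-0.6 * tms)
  expect_equal(as.numeric(Tm %*% h), h, tolerance = 1e-14)
  expect_true(all(Tm[upper.tri(Tm)] == 0))

  cp <- fix_aif(fix_times(15, 0.5), onset = 0.5)
  Tm2 <- toeplitz_input_matrix(cp)
  tau <- cp$times - cp$times[1]
  expect_equal(as.numeric(Tm2 %*% exp(-1.1 * tau)),
               solve_compartment(cp, 1, 1.1), tolerance = 1e-12)
  expect_error(toeplitz_input_matrix(plasma_input(c(0, 1, 3), c(1, 1, 1))),
               "uniform")
})

test_that("flux-rate fitting recovers noise-free parameters to optimizer tolerance", {
  tms <- fix_times(15, 0.5)
  cp <- fix_aif(tms, onset = 0.5)
  for (pars in list(c(0.2, 0.6), c(0.9, 2.0), c(0.05, 0.12))) {
    y <- solve_compartment(cp, pars[1], pars[2])
    fit <- fit_flux_rate(y, cp)
    expect_lt(abs(fit$kep - pars[2]) / pars[2], 1e-4)
    expect_lt(abs(fit$ktrans - pars[1]) / pars[1], 1e-4)
    expect_true(fit$reliable)
  }
  # scale invariance: a sum-normalized curve gives the same kep
  y <- solve_compartment(cp, 0.3, 0.8)
  fitn <- fit_flux_rate(y / sum(y), cp)
  expect_lt(abs(fitn$kep - 0.8) / 0.8, 1e-4)
})

test_that("the kep -> 0 limit reproduces the running integral of the input", {
  tms <- fix_times(15, 0.5)
  cp <- fix_aif(tms, onset = 0.5)
  y <- solve_compartment(cp, 0.4, 0)
  fit <- fit_flux_rate(y, cp)
  expect_lt(fit$kep, 0.02)  # pushed to the slow end of the search range
  Tm <- toeplitz_input_matrix(cp)
  fitted <- fit$ktrans * as.numeric(Tm %*% exp(-fit$kep * (tms - tms[1])))
  expect_lt(max(abs(fitted - y)) / max(y), 0.01)
})

test_that("a plasma-proportional vertex is flagged unidentifiable", {
  tms <- fix_times(15, 0.5)
  cp <- fix_aif(tms, onset = 0.5)
  expect_warning(fit <- fit_flux_rate(0.2 * cp$concentration, cp),
                 "unreliable")
  expect_false(fit$reliable)
})

test_that("grid fitting matches the two-stage deconvolution oracle", {
  # oracle: unconstrained NNLS deconvolution of the impulse response,
  # then a log-linear fit of its exponential decay
  tms <- fix_times(18, 0.5)
  cp <- fix_aif(tms, onset = 0.5)
  Tm <- toeplitz_input_matrix(cp)
  for (pars in list(c(0.2, 0.6), c(0.5, 1.4))) {
    y <- solve_compartment(cp, pars[1], pars[2])
    h <- pracma::lsqnonneg(Tm, y)$x
    use <- which(h > max(h) * 1e-3)
    lf <- stats::lm(log(h[use]) ~ tms[use])
    kep_oracle <- -unname(stats::coef(lf)[2])
    fit <- fit_flux_rate(y, cp)
    expect_lt(abs(fit$kep - kep_oracle) / kep_oracle, 0.02)
  }
})

test_that("per-pixel NNLS unmixing is exact on constructed pixels", {
  b <- fix_basis()
  basis <- compartment_basis(b$normalized, plasma_index = b$plasma)
  # pure pixels: one-hot weights on the matching column
  series <- dynamic_series(b$normalized, times = fix_times(),
                           normalized = TRUE)
  maps <- fit_local_transfer_maps(series, basis)
  expect_equal(unname(maps$weights), diag(3), tolerance = 1e-9)
  expect_false(any(maps$partial_volume_flag))
  expect_equal(maps$vp_local, c(0, 0, 1), tolerance = 1e-9)

  # an all-zero pixel yields all-zero weights
  z <- dynamic_series(cbind(b$normalized, 0), times = fix_times())
  maps0 <- fit_local_transfer_maps(z, basis)
  expect_equal(maps0$weights[4, ], rep(0, 3))

  # J = 2 toy system against exhaustive search over the weight simplex
  A <- cbind(c(0.7, 0.2, 0.1), c(0.1, 0.3, 0.6))
  w_true <- c(0.35, 0.65)
  x <- A %*% w_true
  toy <- dynamic_series(cbind(x), frame_interval = 1)
  basis2 <- compartment_basis(A, plasma_index = 2, normalized = FALSE)
  m2 <- fit_local_transfer_maps(toy, basis2)
  a1 <- seq(0, 1, by = 1e-4)
  resid <- colSums((as.numeric(x) - A %*% rbind(a1, 1 - a1))^2)
  w_grid <- c(a1[which.min(resid)], 1 - a1[which.min(resid)])
  expect_equal(unname(m2$weights[1, ]), w_grid, tolerance = 1e-4)
})

test_that("an ill-conditioned basis is rejected", {
  u <- c(0.5, 0.3, 0.2)
  A <- cbind(u, u * (1 + 1e-12))
  expect_error(
    fit_local_transfer_maps(
      dynamic_series(cbind(u), frame_interval = 1),
      suppressWarnings(compartment_basis(A, plasma_index = 2,
                                         normalized = FALSE))),
    "ill-conditioned")
})

test_that("partial-volume bookkeeping counts mixed pixels", {
  b <- fix_basis()
  basis <- compartment_basis(b$normalized, plasma_index = b$plasma)
  pure <- dynamic_series(b$normalized[, c(1, 1, 2, 3)], times = fix_times(),
                         normalized = FALSE)
  maps_pure <- fit_local_transfer_maps(pure, basis)
  expect_equal(partial_volume_fraction(maps_pure), 0)

  half <- 0.5 * b$normalized[, 1] + 0.5 * b$normalized[, 2]
  mixed <- dynamic_series(cbind(half, half), times = fix_times())
  maps_mixed <- fit_local_transfer_maps(mixed, basis)
  expect_equal(partial_volume_fraction(maps_mixed), 1)
  # threshold at 0.5 declares the equal mixture pure again
  expect_equal(partial_volume_fraction(maps_mixed, purity_threshold = 0.5), 0)
})

test_that("the measured partial-volume fraction matches the generator design", {
  st <- generate_synthetic_study(synthetic_config(snr_db = Inf, seed = 17))
  pre <- preprocess(st$series)
  win <- st$truth$basis[-(1:4), ]
  basis <- compartment_basis(sweep(win, 2, colSums(win), "/"),
                             plasma_index = st$truth$plasma_index)
  maps <- fit_local_transfer_maps(pre$series, basis)
  expect_lt(abs(partial_volume_fraction(maps) -
                  st$truth$partial_volume_fraction), 0.05)
})

test_that("longitudinal comparison matches pools by flux rate", {
  mk <- function(kep, ktrans, pvf = 0.4)
    list(pk = data.frame(ktrans = ktrans, kep = kep),
         partial_volume_fraction = pvf)
  same <- longitudinal_compare(list(base = mk(c(1.5, 0.2), c(0.3, 0.1)),
                                    interim = mk(c(1.5, 0.2), c(0.3, 0.1))))
  d <- same$table[same$table$timepoint == "interim", ]
  expect_equal(d$delta_kep_pct, c(0, 0))
  expect_equal(d$delta_ktrans_pct, c(0, 0))

  # compartment labels are invariant to column permutation of either basis
  swapped <- longitudinal_compare(list(base = mk(c(0.2, 1.5), c(0.1, 0.3)),
                                       interim = mk(c(1.5, 0.2), c(0.3, 0.1))))
  d2 <- swapped$table[swapped$table$timepoint == "interim", ]
  expect_equal(d2$delta_kep_pct, c(0, 0))

  # a fast pool whose kep halves is reported as a -50% delta
  ther <- longitudinal_compare(list(base = mk(c(1.5, 0.2), c(0.3, 0.1)),
                                    post = mk(c(0.75, 0.2), c(0.3, 0.1))))
  d3 <- ther$table[ther$table$timepoint == "post", ]
  expect_equal(d3$delta_kep_pct[1], -50)
  expect_error(longitudinal_compare(list(mk(1, 1))), "at least two")
})

test_that("a simulated therapy response is recovered end to end", {
  fast_halved <- synthetic_config(
    pk = pk_parameters(ktrans = c(0.25, 0.08), kep = c(0.75, 0.15)),
    snr_db = 40, seed = 301)
  base <- generate_synthetic_study(synthetic_config(snr_db = 40, seed = 300))
  post <- generate_synthetic_study(fast_halved)
  fit_base <- deconvolve_series(base$series, j = 3)
  fit_post <- deconvolve_series(post$series, j = 3)
  cmp <- longitudinal_compare(list(base = fit_base, post = fit_post))
  fast_delta <- cmp$table[cmp$table$timepoint == "post" &
                            cmp$table$pool_rank == 1, "delta_kep_pct"]
  expect_lt(abs(fast_delta - (-50)), 5)
})
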