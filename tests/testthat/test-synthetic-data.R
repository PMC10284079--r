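test_that("phantom generation is seeded and structurally correct", {
  t1 <- make_cell_phantom(48, 48, n_cells = 5, radius_range = c(3, 6),
                          seed = 9)
  t2 <- make_cell_phantom(48, 48, n_cells = 5, radius_range = c(3, 6),
                          seed = 9)
  expect_identical(t1, t2)
  expect_equal(nrow(t1$cells), 5)
  expect_equal(length(unique(t1$labels[t1$labels > 0])), 5)
  expect_true(all(t1$maps$tau1 <= t1$maps$tau2))
  expect_true(all(t1$maps$alpha1 >= 0 & t1$maps$alpha1 <= 1))
  # empty phantom is background only
  t0 <- make_cell_phantom(16, 16, n_cells = 0, seed = 1)
  expect_true(all(t0$labels == 0))
})

test_that("simulated histograms are seeded and conserve photons in expectation", {
  cfg <- sim_config(rows = 12, cols = 12, screamer_fraction = 0,
                    dead_fraction = 0, skew_max_bins = 0,
                    skew_jitter_bins = 0)
  truth <- make_cell_phantom(12, 12, n_cells = 1, photons_per_pixel = 800,
                             radius_range = c(2, 3), seed = 3)
  a <- simulate_histogram(truth, cfg, seed = 5)
  b <- simulate_histogram(truth, cfg, seed = 5)
  expect_identical(a$hist$counts, b$hist$counts)

  # zero signal, zero DCR -> all-zero histogram
  cfg0 <- sim_config(rows = 8, cols = 8, dcr_median_cps = 0,
                     screamer_fraction = 0, dead_fraction = 0)
  tr0 <- make_cell_phantom(8, 8, n_cells = 0, bg_photons = 0)
  expect_equal(sum(simulate_histogram(tr0, cfg0, seed = 1)$hist$counts), 0)

  # mean total counts = signal + DCR x T, within central-limit error
  set.seed(6)
  expected_total <- sum(truth$maps$signal_photons) +
    sum(a$dcr_cps) * cfg$integration_s
  totals <- replicate(60, sum(simulate_histogram(truth, cfg,
                                                 sensor = a$sensor)$hist$counts))
  z <- (mean(totals) - expected_total) / (sd(totals) / sqrt(length(totals)))
  expect_lt(abs(z), 4)
})

test_that("injected sensor artifacts are recoverable from the simulation", {
  cfg <- sim_config(rows = 16, cols = 16)
  truth <- make_cell_phantom(16, 16, n_cells = 1, photons_per_pixel = 3000,
                             seed = 2)
  sim <- simulate_histogram(truth, cfg, seed = 8)
  # injected lags on bright pixels are recovered when referenced against the
  # unshifted expected curve of the same decay
  ax <- sim$hist$axis
  irf <- gaussian_irf(cfg$irf_fwhm_ps, ax, cfg$irf_t0_ns)
  bright <- which(truth$maps$signal_photons > 500 &
                    unclass(sim$status) == "ok", arr.ind = TRUE)
  px <- bright[1, ]
  ref <- model_decay(truth$maps$alpha1[px[1], px[2]],
                     truth$maps$tau1[px[1], px[2]],
                     truth$maps$tau2[px[1], px[2]],
                     amplitude = truth$maps$signal_photons[px[1], px[2]],
                     offset = 0, irf = irf, axis = ax)
  sk <- estimate_skew_map(sim$hist, ref, max_lag = 75)
  expect_equal(sk$lag[px[1], px[2]], sim$skew$lag[px[1], px[2]])
})

test_that("photon streams match histogram simulation in distribution", {
  cfg <- sim_config(rows = 8, cols = 8, screamer_fraction = 0,
                    dead_fraction = 0)
  truth <- make_cell_phantom(8, 8, n_cells = 0, bg_photons = 300, seed = 4)
  st <- simulate_photon_stream(truth, cfg, seed = 11)
  st2 <- simulate_photon_stream(truth, cfg, seed = 11)
  expect_identical(st$stream$events, st2$stream$events)

  h <- histogram_from_stream(st$stream,
                             make_time_axis(cfg$rep_rate_hz,
                                            cfg$bin_width_ps))
  expect_equal(sum(h$counts), nrow(st$stream$events))

  # totals from streams and from direct histograms share a distribution
  set.seed(12)
  tot_s <- replicate(25, nrow(simulate_photon_stream(truth, cfg,
                                                     sensor = st$sensor)$stream$events))
  tot_h <- replicate(25, sum(simulate_histogram(truth, cfg,
                                                sensor = st$sensor)$hist$counts))
  expect_gt(suppressWarnings(ks.test(tot_s, tot_h)$p.value), 0.01)

  # zero-rate config gives an empty stream
  cfg0 <- sim_config(rows = 4, cols = 4, dcr_median_cps = 0,
                     screamer_fraction = 0, dead_fraction = 0)
  tr0 <- make_cell_phantom(4, 4, n_cells = 0, bg_photons = 0)
  expect_equal(nrow(simulate_photon_stream(tr0, cfg0, seed = 1)$stream$events),
               0L)
})

test_that("CMOS rendering is consistent with the coarse photon map", {
  truth <- make_cell_phantom(96, 96, n_cells = 3, radius_range = c(14, 18),
                             seed = 13)
  im <- simulate_cmos_image(truth, K = 2, noise = FALSE)
  expect_equal(dim(im$values), c(192, 192))
  # block-averaging the fine image correlates with the coarse signal map
  # (boundary pixels differ slightly: area vs centre sampling)
  blocks <- array(im$values, dim = c(2, 96, 2, 96))
  coarse <- apply(blocks, c(2, 4), mean) * 4 # undo the 1/K^2 scaling
  expect_gt(cor(as.vector(coarse), as.vector(truth$maps$signal_photons)),
            0.99)
  # noise-free constant truth renders constant
  flat <- make_cell_phantom(8, 8, n_cells = 0, bg_photons = 100)
  imf <- simulate_cmos_image(flat, K = 2, noise = FALSE)
  expect_equal(length(unique(as.vector(imf$values))), 1)
})

test_that("time courses follow the configured response directions", {
  cfg <- sim_config(rows = 16, cols = 16, screamer_fraction = 0,
                    dead_fraction = 0)
  truth <- make_cell_phantom(16, 16, n_cells = 1, photons_per_pixel = 1000,
                             seed = 14)
  tc <- timecourse_config(n_frames = 5, alpha1_delta = 0.15,
                          intensity_rel_rise = 0.6)
  run <- simulate_timecourse(truth, tc, cfg, seed = 15)
  expect_length(run$frames, 5)
  expect_equal(run$times_min, c(0, 3, 6, 9, 12))
  # per-frame truth: alpha1 never decreases, tau_m never increases,
  # photons never decrease
  a1 <- vapply(run$truths, function(t) mean(t$maps$alpha1), numeric(1))
  tm <- vapply(run$truths, function(t) mean(truth_tau_m(t)), numeric(1))
  ph <- vapply(run$truths, function(t) sum(t$maps$signal_photons), numeric(1))
  expect_true(all(diff(a1) >= 0))
  expect_true(all(diff(tm) <= 0))
  expect_true(all(diff(ph) >= 0))
  # simulated total intensity rises accordingly
  tot <- vapply(run$frames, function(h) sum(h$counts), numeric(1))
  expect_gt(cor(run$times_min, tot), 0.9)

  # flat curves give statistically identical frames
  tcf <- timecourse_config(n_frames = 4, alpha1_delta = 0,
                           intensity_rel_rise = 0)
  runf <- simulate_timecourse(truth, tcf, cfg, seed = 16)
  totf <- vapply(runf$frames, function(h) sum(h$counts), numeric(1))
  expect_lt(diff(range(totf)) / mean(totf), 0.05)
})

test_that("IRF acquisitions yield the configured pulse width and DCR", {
  cfg <- sim_config(rows = 24, cols = 24)
  acq <- simulate_irf_acquisition(cfg, photons_per_pixel = 3000, seed = 17)
  # skew-correct with the true lags, then measure on ok pixels
  corr <- apply_skew_correction(acq$hist, acq$skew)
  irf <- measure_irf(corr, acq$status)
  expect_equal(irf$fwhm_ps, cfg$irf_fwhm_ps, tolerance = 41.1 / 380)
  # the tail recovers the per-pixel DCR medians
  d <- estimate_dcr_map(acq$hist, 2)
  ok <- unclass(acq$status) == "ok"
  expect_equal(median(d$dcr[ok]), median(acq$dcr_cps[ok]), tolerance = 0.1)

  # with no skew, correction changes nothing
  cfg0 <- sim_config(rows = 8, cols = 8, skew_max_bins = 0,
                     skew_jitter_bins = 0)
  acq0 <- simulate_irf_acquisition(cfg0, seed = 18)
  expect_equal(apply_skew_correction(acq0$hist, acq0$skew)$counts,
               acq0$hist$counts)
})

test_that("dead pixels never fire and screamers run hot", {
  cfg <- sim_config(rows = 20, cols = 20, dead_fraction = 0.05,
                    screamer_fraction = 0.15)
  truth <- make_cell_phantom(20, 20, n_cells = 1, seed = 19)
  sim <- simulate_histogram(truth, cfg, seed = 20)
  st <- unclass(sim$status)
  totals <- apply(sim$hist$counts, c(1, 2), sum)
  expect_true(all(totals[st == "dark-dead"] == 0))
  expect_gt(median(sim$dcr_cps[st == "screamer"]),
            10 * median(sim$dcr_cps[st == "ok"]))
})
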