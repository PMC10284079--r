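test_that("gaussian IRF is normalized with the requested width", {
  ax <- default_axis()
  irf <- gaussian_irf(380, ax, t0_ns = 2)
  expect_equal(sum(irf$curve), 1)
  # 380 ps at 41.1 ps bins is ~9.2 bins wide
  expect_equal(measure_fwhm(irf$curve) * ax$bin_width_ps, 380,
               tolerance = 41.1 / 380)
  # sub-bin FWHM degenerates to an impulse
  expect_warning(irf0 <- gaussian_irf(10, ax, 2), "single-bin")
  expect_equal(sum(irf0$curve > 0), 1)
  expect_equal(which.max(irf0$curve) - 1, round(2e3 / 41.1))
})

test_that("measured IRF recovers width and rejects the dark offset", {
  ax <- default_axis()
  set.seed(21)
  pulse <- gaussian_irf(380, ax, 2)$curve * 2e5
  h <- decay_histogram(array(rpois(486, pulse), dim = c(1, 1, 486)), ax, 10)
  irf <- measure_irf(h)
  expect_equal(irf$fwhm_ps, 380, tolerance = 41.1 / 380)

  # a uniform offset of 5 counts/bin is removed and leaves the FWHM intact
  h5 <- decay_histogram(array(rpois(486, pulse + 5), dim = c(1, 1, 486)),
                        ax, 10)
  irf5 <- measure_irf(h5)
  expect_equal(irf5$fwhm_ps, irf$fwhm_ps, tolerance = 0.05)

  # an impulse passes through unchanged up to normalization
  imp <- array(0, dim = c(1, 1, 486)); imp[1, 1, 50] <- 1000
  irf_i <- measure_irf(decay_histogram(imp, ax, 10))
  expect_equal(which.max(irf_i$curve), 50)
  expect_equal(sum(irf_i$curve), 1)

  h0 <- decay_histogram(array(0, dim = c(1, 1, 486)), ax, 10)
  expect_error(measure_irf(h0), "no counts")
})

test_that("the periodic decay model conserves flux for any parameters", {
  ax <- default_axis()
  irf <- gaussian_irf(380, ax, 1)
  set.seed(22)
  for (i in 1:20) {
    a1 <- runif(1); t1 <- runif(1, 0.05, 9); t2 <- runif(1, t1, 10)
    amp <- runif(1, 10, 1e6); off <- runif(1, 0, 20)
    m <- model_decay(a1, t1, t2, amplitude = amp, offset = off, irf = irf,
                     axis = ax)
    expect_equal(sum(m - off), amp, tolerance = 1e-9)
  }
  expect_error(model_decay(1, -1, NULL, 100, 0, irf, ax), "positive")
})

test_that("delta-IRF mono model matches the wrapped exponential closed form", {
  ax <- default_axis()
  delta <- suppressWarnings(gaussian_irf(1e-6, ax, 0))
  m <- model_decay(1, 1.0, NULL, amplitude = 1000, offset = 0, irf = delta,
                   axis = ax)
  # successive-bin ratio is exp(-dt/tau)
  expect_equal(m[10] / m[9], exp(-ax$bin_width_ps / 1e3 / 1.0),
               tolerance = 1e-9)
  # wrap-around factor at bin 0: 1 / (1 - exp(-Tp/tau)) for tau = 3 ns
  m3 <- model_decay(1, 3, NULL, amplitude = 1, offset = 0, irf = delta,
                    axis = ax)
  dt <- ax$bin_width_ps / 1e3
  # bin-0 value exceeds the infinite-tail (unwrapped) discrete exponential
  # by the geometric wrap factor 1 / (1 - exp(-Tp/tau)), ~1.0013 at 3 ns
  k_unwrapped <- 1 - exp(-dt / 3) # unit-sum geometric on [0, Inf)
  expect_equal(m3[1] / k_unwrapped, 1 / (1 - exp(-486 * dt / 3)),
               tolerance = 1e-9)
})

test_that("mean lifetime is the amplitude-weighted mixture", {
  expect_equal(mean_lifetime(1, 1.7, 0, 3), 1.7)
  expect_equal(mean_lifetime(0.5, 1, 0.5, 3), 2)
  expect_error(mean_lifetime(0.6, 1, 0.6, 3), "sum to 1")
  # increasing the short fraction strictly decreases tau_m
  a <- seq(0.1, 0.9, 0.1)
  tm <- mean_lifetime(a, 0.4, 1 - a, 2.5)
  expect_true(all(diff(tm) < 0))
  expect_true(all(tm >= 0.4 & tm <= 2.5))
})

test_that("intensity integrates the decay above the dark level", {
  expect_equal(intensity_from_decay(rep(0, 100)), 0)
  expect_equal(intensity_from_decay(rep(3, 100), offset = 3), 0)
  set.seed(23)
  ax <- default_axis()
  y <- rpois(486, reference_shape(ax, photons = 3000)) + rpois(486, 2)
  est <- intensity_from_decay(y, offset = 2)
  expect_equal(est, 3000, tolerance = 4 * sqrt(3000 + 2 * 486) / 3000)
})

test_that("spatial binning sums clipped neighborhoods", {
  h <- uniform_hist(6, 6, per_bin = 1)
  expect_equal(bin_spatial(h, 0)$counts, h$counts)
  b1 <- bin_spatial(h, 1)
  expect_equal(b1$counts[3, 3, 1], 9) # interior 3x3
  expect_equal(b1$counts[1, 1, 1], 4) # corner neighborhood is truncated
  expect_equal(b1$counts[1, 3, 1], 6) # edge
  # bad pixels contribute nothing
  st <- matrix("ok", 6, 6); st[2, 2] <- "screamer"
  class(st) <- c("pixel_status", class(st))
  expect_equal(bin_spatial(h, 1, st)$counts[3, 3, 1], 8)
})

test_that("noiseless fits recover generating parameters to 1e-6", {
  ax <- default_axis()
  irf <- gaussian_irf(380, ax, 1)
  y_mono <- model_decay(1, 1.0, NULL, 1e5, 0, irf, ax)
  f <- fit_pixel(y_mono, irf, ax, model = "mono")
  expect_lt(abs(f$tau_m - 1.0), 1e-6)
  expect_true(f$converged)

  y_bi <- model_decay(0.7, 0.4, 2.5, 5e4, 2, irf, ax)
  fb <- fit_pixel(y_bi, irf, ax, model = "bi", offset = 2)
  expect_lt(abs(fb$params$alpha1 - 0.7), 1e-5)
  expect_lt(abs(fb$params$tau1 - 0.4) / 0.4, 1e-5)
  expect_lt(abs(fb$params$tau2 - 2.5) / 2.5, 1e-5)
  expect_lt(abs(fb$tau_m - mean_lifetime(0.7, 0.4, 0.3, 2.5)) / fb$tau_m,
            1e-6)
  expect_true(fb$params$tau1 <= fb$params$tau2)
})

test_that("biexponential recovery at 3000 photons is unbiased and tight", {
  ax <- default_axis()
  irf <- gaussian_irf(380, ax, 1)
  truth_tm <- mean_lifetime(0.7, 0.4, 0.3, 2.5) # = 1.03 ns
  expected <- model_decay(0.7, 0.4, 2.5, 3000, 1, irf, ax)
  set.seed(31)
  tm <- replicate(120, {
    y <- rpois(ax$n_bins, expected)
    fit_pixel(y, irf, ax, model = "bi", offset = 1)$tau_m
  })
  expect_lt(abs(mean(tm) - truth_tm) / truth_tm, 0.02) # bias < 2%
  expect_lt(sd(tm) / truth_tm, 0.05)                   # SD < 5%
  # per-replicate tau_m within 5% on average (recovery example)
  expect_lt(mean(abs(tm - truth_tm) / truth_tm), 0.05)
})

test_that("reduced chi-square sits near 1 on well-specified Poisson data", {
  ax <- default_axis()
  irf <- gaussian_irf(380, ax, 1)
  expected <- model_decay(1, 2.5, NULL, 2e5, 10, irf, ax)
  set.seed(32)
  chi2 <- replicate(40, {
    y <- rpois(ax$n_bins, expected)
    fit_pixel(y, irf, ax, model = "mono", offset = 10)$chi2_reduced
  })
  expect_equal(mean(chi2), 1, tolerance = 0.2)
})

test_that("decays below the photon threshold yield sentinel results", {
  ax <- default_axis()
  irf <- gaussian_irf(380, ax, 1)
  y <- rpois(ax$n_bins, model_decay(1, 2, NULL, 100, 0, irf, ax))
  f <- fit_pixel(y, irf, ax, model = "mono", min_photons = 500)
  expect_false(f$was_fitted)
  expect_true(is.na(f$tau_m))
  expect_false(f$converged)
})

test_that("fit_image recovers a two-region phantom and orders the regions", {
  ax <- default_axis()
  cfg <- sim_config(rows = 16, cols = 16, screamer_fraction = 0,
                    dead_fraction = 0, skew_max_bins = 10,
                    skew_jitter_bins = 0)
  truth <- make_cell_phantom(16, 16, n_cells = 0, bg_photons = 3000,
                             bg_params = list(alpha1 = 0.7, tau1 = 0.4,
                                              tau2 = 2.5), seed = 1)
  # two vertical halves with tau_m 0.8 vs 1.2 via alpha1
  # tau_m = a*0.4 + (1-a)*2.5 -> a = (2.5 - tau_m)/2.1
  truth$maps$alpha1[, 1:8] <- (2.5 - 0.8) / 2.1
  truth$maps$alpha1[, 9:16] <- (2.5 - 1.2) / 2.1
  sim <- simulate_histogram(truth, cfg, seed = 2)
  irfacq <- simulate_irf_acquisition(cfg, sensor = sim$sensor, seed = 3)
  calib <- calibrate_sensor(sim$hist, irf_hist = irfacq$hist,
                            screamer_quantile = 1)
  img <- fit_image(sim$hist, calib, model = "bi", b = 0, min_photons = 500)
  left <- mean(img$maps$tau_m[, 1:8], na.rm = TRUE)
  right <- mean(img$maps$tau_m[, 9:16], na.rm = TRUE)
  expect_lt(left, right)
  expect_equal(left, 0.8, tolerance = 0.1)
  expect_equal(right, 1.2, tolerance = 0.1)

  # binning reduces map variance on the same frame
  img_b1 <- fit_image(sim$hist, calib, model = "bi", b = 1,
                      min_photons = 500)
  v0 <- var(as.vector(img$maps$tau_m[, 1:8]), na.rm = TRUE)
  v1 <- var(as.vector(img_b1$maps$tau_m[, 1:8]), na.rm = TRUE)
  expect_lt(v1, v0)
})

test_that("an all-dark frame yields only sentinel pixels", {
  cfg <- sim_config(rows = 8, cols = 8, screamer_fraction = 0,
                    dead_fraction = 0)
  truth <- make_cell_phantom(8, 8, n_cells = 0, bg_photons = 0)
  sim <- simulate_histogram(truth, cfg, seed = 4)
  calib <- calibrate_sensor(sim$hist, screamer_quantile = 1,
                            dead_count_threshold = -1)
  img <- fit_image(sim$hist, calib, min_photons = 500)
  expect_true(all(is.na(img$maps$tau_m)))
})

test_that("tidy and glance expose fit results as tibbles", {
  ax <- default_axis()
  irf <- gaussian_irf(380, ax, 1)
  f <- fit_pixel(model_decay(0.7, 0.4, 2.5, 5e4, 0, irf, ax), irf, ax)
  td <- tidy(f)
  expect_s3_class(td, "tbl_df")
  expect_equal(td$estimate[td$term == "alpha1"], 0.7, tolerance = 1e-4)
  gl <- glance(f)
  expect_equal(nrow(gl), 1)
  expect_true(gl$converged)
})
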