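# Shared fixtures for the suite: small axes, streams and simulated sensors.

default_axis <- function() make_time_axis(50e6, 41.1)

# a deterministic little photon stream on an r x c sensor
tiny_stream <- function(n = 100, rows = 8, cols = 8, n_bins = 486,
                        seed = 1) {
  set.seed(seed)
  photon_stream(
    data.frame(row = sample(0:(rows - 1), n, TRUE),
               col = sample(0:(cols - 1), n, TRUE),
               tdc_code = sample(0:(n_bins - 1), n, TRUE)),
    rows = rows, cols = cols, rep_rate_hz = 50e6, bin_width_ps = 41.1,
    integration_s = 10)
}

# uniform-count histogram: every pixel has `per_bin` counts in every bin
uniform_hist <- function(rows = 10, cols = 10, per_bin = 2,
                         axis = default_axis(), integration_s = 10) {
  decay_histogram(array(per_bin, dim = c(rows, cols, axis$n_bins)),
                  axis, integration_s)
}

# histogram in which each pixel holds a given 1D decay
hist_from_decays <- function(decays, axis = default_axis(),
                             integration_s = 10) {
  # decays: npix x n_bins matrix, filled into a square-ish sensor
  npix <- nrow(decays)
  rows <- npix
  decay_histogram(array(decays, dim = c(rows, 1, ncol(decays))),
                  axis, integration_s)
}

# a clean coumarin-like reference decay shape (expected counts)
reference_shape <- function(axis = default_axis(), tau = 2.5,
                            photons = 5000, t0_ns = 1) {
  irf <- gaussian_irf(380, axis, t0_ns)
  model_decay(1, tau, NULL, amplitude = photons, offset = 0, irf = irf,
              axis = axis)
}

circshift_right <- function(x, l) {
  n <- length(x)
  l <- l %% n
  if (l == 0) return(x)
  c(x[(n - l + 1):n], x[1:(n - l)])
}

# small fully simulated sensor with calibration ground truth
small_sim <- function(rows = 32, cols = 32, n_cells = 3, photons = 3000,
                      seed = 7, sim_seed = 42, radius_range = c(3, 6), ...) {
  cfg <- sim_config(rows = rows, cols = cols, ...)
  truth <- make_cell_phantom(rows, cols, n_cells = n_cells,
                             photons_per_pixel = photons,
                             radius_range = radius_range, seed = seed)
  sim <- simulate_histogram(truth, cfg, seed = sim_seed)
  list(cfg = cfg, truth = truth, sim = sim)
}
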