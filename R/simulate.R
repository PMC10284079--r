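#' Simulator configuration
#'
#' Sensor and acquisition settings of the emulated SPAD light-sheet system.
#' Defaults describe the device this package targets: a 192x128 array with
#' 41.1 ps TDC bins at 50 MHz excitation, a 380 ps FWHM IRF, 10 s
#' integration, log-normal per-pixel dark count rates with median 34 cps, a
#' smooth left-right timing-skew gradient of up to 60 bins with small
#' per-pixel jitter, and 15% high-DCR "screamer" pixels.
#'
#' @param rows,cols Sensor dimensions in pixels.
#' @param bin_width_ps TDC bin width (ps).
#' @param rep_rate_hz Laser repetition rate (Hz).
#' @param irf_fwhm_ps IRF full width at half maximum (ps).
#' @param irf_t0_ns IRF peak position on the axis (ns).
#' @param integration_s Integration time per frame (s).
#' @param dcr_median_cps Median of the log-normal DCR distribution (cps).
#' @param dcr_sdlog Log-scale SD of the DCR distribution.
#' @param skew_max_bins Maximum lag of the skew gradient (bins).
#' @param skew_jitter_bins SD of integer per-pixel lag jitter (bins).
#' @param screamer_fraction Fraction of screamer pixels.
#' @param screamer_dcr_multiplier DCR multiplier applied to screamers.
#' @param dead_fraction Fraction of pixels that never fire.
#' @return A `sim_config`.
#' @export
sim_config <- function(rows = 192, cols = 128, bin_width_ps = 41.1,
                       rep_rate_hz = 50e6, irf_fwhm_ps = 380, irf_t0_ns = 1,
                       integration_s = 10, dcr_median_cps = 34,
                       dcr_sdlog = 0.7, skew_max_bins = 60,
                       skew_jitter_bins = 2, screamer_fraction = 0.15,
                       screamer_dcr_multiplier = 100, dead_fraction = 0.005) {
  cfg <- list(rows = as.integer(rows), cols = as.integer(cols),
              bin_width_ps = bin_width_ps, rep_rate_hz = rep_rate_hz,
              irf_fwhm_ps = irf_fwhm_ps, irf_t0_ns = irf_t0_ns,
              integration_s = integration_s, dcr_median_cps = dcr_median_cps,
              dcr_sdlog = dcr_sdlog, skew_max_bins = as.integer(skew_max_bins),
              skew_jitter_bins = skew_jitter_bins,
              screamer_fraction = screamer_fraction,
              screamer_dcr_multiplier = screamer_dcr_multiplier,
              dead_fraction = dead_fraction)
  with(cfg, stopifnot(rows > 0, cols > 0, bin_width_ps > 0, rep_rate_hz > 0,
                      irf_fwhm_ps > 0, integration_s > 0,
                      dcr_median_cps >= 0,
                      screamer_fraction >= 0, screamer_fraction <= 1,
                      dead_fraction >= 0, dead_fraction <= 1))
  structure(cfg, class = "sim_config")
}

sim_axis <- function(cfg) make_time_axis(cfg$rep_rate_hz, cfg$bin_width_ps)

#' Generate a ground-truth cell phantom
#'
#' Places elliptical "cells" with per-cell biexponential NAD(P)H decay
#' parameters drawn from literature-typical ranges on a dim biexponential
#' background, producing the per-pixel parameter and photon maps that drive
#' the simulator and the label map used as segmentation ground truth. Cell
#' geometry is kept on the object so the companion CMOS image can be
#' rendered with sub-pixel boundaries.
#'
#' @param rows,cols Phantom (SPAD) grid size.
#' @param n_cells Number of cells to place.
#' @param param_ranges Named list of `c(min, max)` ranges for `alpha1`,
#'   `tau1` (ns) and `tau2` (ns).
#' @param photons_per_pixel Expected signal photons per cell pixel over the
#'   integration (detection efficiency — fill factor, PDE — is absorbed into
#'   this budget).
#' @param bg_photons Expected background photons per pixel.
#' @param bg_params Background decay parameters (`alpha1`, `tau1`, `tau2`).
#' @param radius_range Cell semi-axis range in pixels.
#' @param seed Optional RNG seed for reproducibility.
#' @param max_tries Placement rejection attempts per cell before giving up
#'   with a warning.
#' @return A `ground_truth`: maps `alpha1`, `tau1`, `tau2`,
#'   `signal_photons`; `labels`; `cells` tibble; `shape`.
#' @export
make_cell_phantom <- function(rows = 64, cols = 64, n_cells = 5,
                              param_ranges = list(alpha1 = c(0.6, 0.85),
                                                  tau1 = c(0.3, 0.5),
                                                  tau2 = c(2.0, 3.0)),
                              photons_per_pixel = 3000, bg_photons = 50,
                              bg_params = list(alpha1 = 0.7, tau1 = 0.4,
                                               tau2 = 2.5),
                              radius_range = c(4, 9), seed = NULL,
                              max_tries = 200) {
  if (!is.null(seed)) set.seed(seed)
  if (n_cells < 0) stop("`n_cells` must be non-negative", call. = FALSE)
  # cells must fit inside the frame with a margin
  max_r <- (min(rows, cols) - 3) / 2
  radius_range <- pmin(radius_range, max_r)
  cells <- tibble::tibble(label = integer(), cy = numeric(), cx = numeric(),
                          a = numeric(), b = numeric(), theta = numeric(),
                          alpha1 = numeric(), tau1 = numeric(),
                          tau2 = numeric(), brightness = numeric())
  placed <- 0
  while (placed < n_cells) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      a <- stats::runif(1, radius_range[1], radius_range[2])
      b <- stats::runif(1, radius_range[1], radius_range[2])
      r <- max(a, b)
      cy <- stats::runif(1, r, rows - 1 - r)
      cx <- stats::runif(1, r, cols - 1 - r)
      if (nrow(cells) == 0 ||
          all(sqrt((cells$cy - cy)^2 + (cells$cx - cx)^2) >
              pmax(cells$a, cells$b) + r + 1)) {
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      warning("could not place all cells without overlap; phantom has ",
              placed, " cells")
      break
    }
    placed <- placed + 1
    cells <- dplyr::bind_rows(cells, tibble::tibble(
      label = placed, cy = cy, cx = cx, a = a, b = b,
      theta = stats::runif(1, 0, pi),
      alpha1 = stats::runif(1, param_ranges$alpha1[1], param_ranges$alpha1[2]),
      tau1 = stats::runif(1, param_ranges$tau1[1], param_ranges$tau1[2]),
      tau2 = stats::runif(1, param_ranges$tau2[1], param_ranges$tau2[2]),
      brightness = stats::runif(1, 0.8, 1.2)))
  }
  labels <- render_labels(cells, rows, cols, K = 1)
  maps <- list(
    alpha1 = matrix(bg_params$alpha1, rows, cols),
    tau1 = matrix(bg_params$tau1, rows, cols),
    tau2 = matrix(bg_params$tau2, rows, cols),
    signal_photons = matrix(bg_photons, rows, cols))
  for (i in seq_len(nrow(cells))) {
    sel <- labels == cells$label[i]
    maps$alpha1[sel] <- cells$alpha1[i]
    maps$tau1[sel] <- cells$tau1[i]
    maps$tau2[sel] <- cells$tau2[i]
    maps$signal_photons[sel] <- photons_per_pixel * cells$brightness[i]
  }
  structure(list(maps = maps, labels = labels, cells = cells,
                 shape = as.integer(c(rows, cols)), bg_photons = bg_photons,
                 photons_per_pixel = photons_per_pixel),
            class = "ground_truth")
}

# rasterize cell ellipses on a K-times-finer grid (labels, later wins)
render_labels <- function(cells, rows, cols, K = 1) {
  lab <- matrix(0L, rows * K, cols * K)
  if (nrow(cells) == 0) return(lab)
  yy <- ((seq_len(rows * K) - 0.5) / K) - 0.5 # SPAD pixel-center units
  xx <- ((seq_len(cols * K) - 0.5) / K) - 0.5
  Y <- matrix(yy, rows * K, cols * K)
  X <- matrix(xx, rows * K, cols * K, byrow = TRUE)
  for (i in seq_len(nrow(cells))) {
    dy <- Y - cells$cy[i]; dx <- X - cells$cx[i]
    u <- dy * cos(cells$theta[i]) + dx * sin(cells$theta[i])
    v <- -dy * sin(cells$theta[i]) + dx * cos(cells$theta[i])
    inside <- (u / cells$a[i])^2 + (v / cells$b[i])^2 <= 1
    lab[inside] <- cells$label[i]
  }
  lab
}

#' True mean-lifetime map of a phantom
#'
#' @param truth A `ground_truth`.
#' @return Matrix of `tau_m` in ns.
#' @export
truth_tau_m <- function(truth) {
  stopifnot(inherits(truth, "ground_truth"))
  with(truth$maps, mean_lifetime(alpha1, tau1, 1 - alpha1, tau2))
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %dx%d, %d cells, %g photons/cell pixel\n",
              x$shape[1], x$shape[2], nrow(x$cells), x$photons_per_pixel))
  invisible(x)
}

# draw the fixed sensor state: per-pixel DCR, status, integer skew lags
draw_sensor_state <- function(cfg) {
  npix <- cfg$rows * cfg$cols
  dcr <- stats::rlnorm(npix, meanlog = log(cfg$dcr_median_cps),
                       sdlog = cfg$dcr_sdlog)
  status <- rep("ok", npix)
  n_scr <- round(cfg$screamer_fraction * npix)
  if (n_scr > 0) {
    scr <- sample.int(npix, n_scr)
    dcr[scr] <- dcr[scr] * cfg$screamer_dcr_multiplier
    status[scr] <- "screamer"
  }
  n_dead <- round(cfg$dead_fraction * npix)
  if (n_dead > 0) {
    dead <- sample(which(status == "ok"), n_dead)
    dcr[dead] <- 0
    status[dead] <- "dark-dead"
  }
  grad <- (col(matrix(0, cfg$rows, cfg$cols)) - 1) / max(cfg$cols - 1, 1)
  lag <- round(cfg$skew_max_bins * grad +
                 stats::rnorm(npix, 0, cfg$skew_jitter_bins))
  lag <- pmin(pmax(lag, 0), cfg$skew_max_bins)
  st <- matrix(status, cfg$rows, cfg$cols)
  class(st) <- c("pixel_status", class(st))
  list(dcr_cps = matrix(dcr, cfg$rows, cfg$cols),
       status = st,
       skew = structure(list(lag = matrix(as.integer(lag), cfg$rows,
                                          cfg$cols),
                             degenerate = matrix(FALSE, cfg$rows, cfg$cols),
                             max_lag = cfg$skew_max_bins + 15L),
                        class = "skew_map"))
}

# expected per-pixel curves -> Poisson counts -> per-pixel right-shift by lag
simulate_counts <- function(expected, lag, rows, cols, n_bins) {
  X <- matrix(stats::rpois(length(expected), expected),
              nrow = rows * cols, ncol = n_bins)
  lag <- as.vector(lag) %% n_bins
  for (l in unique(lag)) {
    if (l == 0) next
    sel <- lag == l
    X[sel, ] <- X[sel, c((n_bins - l + 1):n_bins, 1:(n_bins - l)),
                  drop = FALSE]
  }
  array(X, dim = c(rows, cols, n_bins))
}

# expected signal+dark curve matrix (pixels x bins) for a phantom
expected_curves <- function(truth, cfg, sensor, axis, irf) {
  n <- axis$n_bins
  npix <- cfg$rows * cfg$cols
  f_irf <- stats::fft(irf$curve)
  bw_ns <- axis$bin_width_ps / 1e3
  # one curve per distinct parameter triple (cells share params, so this
  # stays cheap even at full sensor size)
  key <- paste(truth$maps$alpha1, truth$maps$tau1, truth$maps$tau2)
  photons <- as.vector(truth$maps$signal_photons)
  photons[as.vector(unclass(sensor$status)) == "dark-dead"] <- 0
  E <- matrix(0, npix, n)
  for (k in unique(key)) {
    sel <- key == k
    i <- which(sel)[1]
    curve <- model_decay_fft(truth$maps$alpha1[i], truth$maps$tau1[i],
                             truth$maps$tau2[i], 1, 0, f_irf, n, bw_ns)
    E[sel, ] <- photons[sel] %o% curve
  }
  dark <- as.vector(sensor$dcr_cps) * cfg$integration_s / n
  E + dark
}

#' Simulate a SPAD acquisition of a phantom
#'
#' Forward model: per pixel, the expected curve is the periodic
#' reconvolution model of the pixel's decay parameters (Gaussian IRF) plus a
#' uniform dark level from the pixel's DCR; counts are independent Poisson
#' per bin; each pixel decay is then circularly delayed by the pixel's
#' timing lag. Screamer pixels receive inflated DCR, dead pixels produce no
#' counts. The injected sensor maps are returned as ground truth for
#' calibration-recovery tests.
#'
#' @param truth A `ground_truth` whose shape matches `cfg`.
#' @param cfg A `sim_config`.
#' @param seed Optional RNG seed.
#' @param sensor Optional sensor state from a previous call (to hold DCR,
#'   skew and status fixed across frames of a time course).
#' @return List with `hist` (`decay_histogram`), `skew` (`skew_map`),
#'   `dcr_cps` (matrix), `status` (`pixel_status`), `sensor` (reusable
#'   state).
#' @export
simulate_histogram <- function(truth, cfg, seed = NULL, sensor = NULL) {
  stopifnot(inherits(truth, "ground_truth"), inherits(cfg, "sim_config"))
  if (!all(truth$shape == c(cfg$rows, cfg$cols)))
    stop("phantom and sim_config shapes differ", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  axis <- sim_axis(cfg)
  irf <- gaussian_irf(cfg$irf_fwhm_ps, axis, cfg$irf_t0_ns)
  if (is.null(sensor)) sensor <- draw_sensor_state(cfg)
  E <- expected_curves(truth, cfg, sensor, axis, irf)
  counts <- simulate_counts(E, sensor$skew$lag, cfg$rows, cfg$cols,
                            axis$n_bins)
  hist <- decay_histogram(counts, axis, cfg$integration_s,
                          provenance = "simulated")
  list(hist = hist, skew = sensor$skew, dcr_cps = sensor$dcr_cps,
       status = sensor$status, sensor = sensor)
}

#' Simulate a raw photon stream
#'
#' One Poisson draw of the same forward model as [simulate_histogram()],
#' expanded into per-photon events in shuffled order, so histogramming the
#' stream reproduces a draw from the histogram distribution.
#'
#' @inheritParams simulate_histogram
#' @return List with `stream` (`photon_stream`) plus the injected sensor
#'   maps as in [simulate_histogram()].
#' @export
simulate_photon_stream <- function(truth, cfg, seed = NULL, sensor = NULL) {
  sim <- simulate_histogram(truth, cfg, seed = seed, sensor = sensor)
  d <- dim(sim$hist$counts)
  nz <- which(sim$hist$counts > 0)
  cnt <- sim$hist$counts[nz]
  idx <- rep(nz - 1L, cnt)
  row <- idx %% d[1]
  col <- (idx %/% d[1]) %% d[2]
  bin <- idx %/% (d[1] * d[2])
  ord <- sample.int(length(idx))
  stream <- photon_stream(
    tibble::tibble(row = row[ord], col = col[ord], tdc_code = bin[ord]),
    rows = d[1], cols = d[2], rep_rate_hz = cfg$rep_rate_hz,
    bin_width_ps = cfg$bin_width_ps, integration_s = cfg$integration_s)
  list(stream = stream, skew = sim$skew, dcr_cps = sim$dcr_cps,
       status = sim$status, sensor = sim$sensor)
}

#' Simulate the companion CMOS intensity image
#'
#' Renders the phantom's photon map on a `K`-times-finer grid using the
#' stored sub-pixel cell geometry, with optional Poisson shot noise. The
#' `"mcherry"` channel lights up labeled cells only (uniform per cell), as a
#' stand-in for a cytoplasmic label used to build cell masks.
#'
#' @param truth A `ground_truth`.
#' @param K Integer fineness factor per axis (default 2, i.e. 4x pixels).
#' @param photon_scale Overall brightness scale of the fine image.
#' @param channel `"nadh-intensity"` or `"mcherry"`.
#' @param noise Add Poisson shot noise (default `TRUE`).
#' @param seed Optional RNG seed.
#' @return An `intensity_image` on the fine grid.
#' @export
simulate_cmos_image <- function(truth, K = 2, photon_scale = 1,
                                channel = c("nadh-intensity", "mcherry"),
                                noise = TRUE, seed = NULL) {
  stopifnot(inherits(truth, "ground_truth"))
  channel <- match.arg(channel)
  if (K < 1 || K != round(K)) stop("`K` must be a positive integer",
                                   call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  lab_fine <- render_labels(truth$cells, truth$shape[1], truth$shape[2], K)
  if (channel == "nadh-intensity") {
    expected <- matrix(truth$bg_photons, nrow(lab_fine), ncol(lab_fine))
    for (i in seq_len(nrow(truth$cells))) {
      sel <- lab_fine == truth$cells$label[i]
      expected[sel] <- truth$photons_per_pixel * truth$cells$brightness[i]
    }
  } else {
    expected <- matrix(0, nrow(lab_fine), ncol(lab_fine))
    for (i in seq_len(nrow(truth$cells))) {
      sel <- lab_fine == truth$cells$label[i]
      expected[sel] <- 1000 * truth$cells$brightness[i]
    }
  }
  expected <- expected * photon_scale / K^2
  vals <- if (noise) {
    matrix(stats::rpois(length(expected), expected), nrow(expected))
  } else expected
  intensity_image(vals, channel = channel)
}

#' Time-course configuration
#'
#' Piecewise-linear response curves emulating a cyanide-type metabolic
#' perturbation: the free-NAD(P)H fraction `alpha1` ramps up (so the mean
#' lifetime ramps down) and the fluorescence intensity ramps up, from the
#' baseline at frame 0 to the configured endpoint at the final frame.
#'
#' @param n_frames Number of frames (>= 1).
#' @param frame_interval_min Minutes between frames.
#' @param alpha1_delta Total additive rise of `alpha1` (default 0.12).
#' @param intensity_rel_rise Total relative rise of signal photons (default
#'   0.5).
#' @return A `timecourse_config`.
#' @export
timecourse_config <- function(n_frames = 7, frame_interval_min = 3,
                              alpha1_delta = 0.12,
                              intensity_rel_rise = 0.5) {
  stopifnot(n_frames >= 1, frame_interval_min > 0)
  structure(list(n_frames = as.integer(n_frames),
                 frame_interval_min = frame_interval_min,
                 alpha1_delta = alpha1_delta,
                 intensity_rel_rise = intensity_rel_rise),
            class = "timecourse_config")
}

#' Simulate a metabolic perturbation time course
#'
#' Frame 0 is the baseline phantom; subsequent frames follow the
#' [timecourse_config()] response curves and are simulated with the sensor
#' state (DCR, skew, status) held fixed across frames, as on a real camera.
#'
#' @param truth Baseline `ground_truth`.
#' @param tc A `timecourse_config`.
#' @param cfg A `sim_config`.
#' @param seed Optional RNG seed.
#' @return List with `frames` (list of `decay_histogram`), `truths`
#'   (per-frame `ground_truth`), `times_min`, `sensor` state.
#' @export
simulate_timecourse <- function(truth, tc, cfg, seed = NULL) {
  stopifnot(inherits(tc, "timecourse_config"))
  if (!is.null(seed)) set.seed(seed)
  sensor <- draw_sensor_state(cfg)
  ramp <- if (tc$n_frames == 1) 0 else
    (seq_len(tc$n_frames) - 1) / (tc$n_frames - 1)
  frames <- vector("list", tc$n_frames)
  truths <- vector("list", tc$n_frames)
  for (i in seq_len(tc$n_frames)) {
    ti <- truth
    ti$maps$alpha1 <- pmin(ti$maps$alpha1 + tc$alpha1_delta * ramp[i], 0.98)
    ti$maps$signal_photons <-
      ti$maps$signal_photons * (1 + tc$intensity_rel_rise * ramp[i])
    truths[[i]] <- ti
    frames[[i]] <- simulate_histogram(ti, cfg, sensor = sensor)$hist
  }
  list(frames = frames, truths = truths,
       times_min = (seq_len(tc$n_frames) - 1) * tc$frame_interval_min,
       sensor = sensor)
}

#' Simulate an IRF acquisition
#'
#' Every pixel sees the attenuated laser pulse (a Gaussian of the configured
#' IRF width) plus its dark level, delayed by its timing lag — the input for
#' IRF measurement, tail-based DCR estimation and skew calibration.
#'
#' @param cfg A `sim_config`.
#' @param photons_per_pixel Expected pulse photons per pixel.
#' @param seed Optional RNG seed.
#' @param sensor Optional fixed sensor state.
#' @return As [simulate_histogram()].
#' @export
simulate_irf_acquisition <- function(cfg, photons_per_pixel = 2000,
                                     seed = NULL, sensor = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(seed)
  axis <- sim_axis(cfg)
  irf <- gaussian_irf(cfg$irf_fwhm_ps, axis, cfg$irf_t0_ns)
  if (is.null(sensor)) sensor <- draw_sensor_state(cfg)
  npix <- cfg$rows * cfg$cols
  photons <- rep(photons_per_pixel, npix)
  photons[as.vector(unclass(sensor$status)) == "dark-dead"] <- 0
  E <- photons %o% irf$curve +
    as.vector(sensor$dcr_cps) * cfg$integration_s / axis$n_bins
  counts <- simulate_counts(E, sensor$skew$lag, cfg$rows, cfg$cols,
                            axis$n_bins)
  hist <- decay_histogram(counts, axis, cfg$integration_s,
                          provenance = "simulated_irf")
  list(hist = hist, skew = sensor$skew, dcr_cps = sensor$dcr_cps,
       status = sensor$status, sensor = sensor)
}
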