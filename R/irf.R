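#' Measure the FWHM of a discrete curve
#'
#' Full width at half maximum with linear interpolation between bins.
#'
#' @param curve Non-negative numeric vector.
#' @param bin_width_ps Bin width (ps); with the default 1 the width is in bins.
#' @return FWHM in the units of `bin_width_ps`.
#' @export
measure_fwhm <- function(curve, bin_width_ps = 1) {
  if (all(curve <= 0)) stop("curve has no positive values", call. = FALSE)
  pk <- which.max(curve)
  half <- curve[pk] / 2
  # walk left
  i <- pk
  while (i > 1 && curve[i - 1] >= half) i <- i - 1
  left <- if (i == 1 || curve[i] == half) i else {
    i - (curve[i] - half) / (curve[i] - curve[i - 1])
  }
  j <- pk
  n <- length(curve)
  while (j < n && curve[j + 1] >= half) j <- j + 1
  right <- if (j == n || curve[j] == half) j else {
    j + (curve[j] - half) / (curve[j] - curve[j + 1])
  }
  (right - left) * bin_width_ps
}

new_irf <- function(curve, fwhm_ps, t0_bin) {
  s <- sum(curve)
  if (s <= 0) stop("IRF curve must have positive total", call. = FALSE)
  structure(list(curve = curve / s, fwhm_ps = fwhm_ps,
                 t0_bin = as.integer(t0_bin)), class = "irf")
}

#' Gaussian model IRF
#'
#' Discretized Gaussian instrument response on a time axis, unit sum, for
#' simulation or for fitting when no measured IRF is available. The device
#' emulated here has a 380 ps FWHM.
#'
#' @param fwhm_ps Full width at half maximum (ps).
#' @param axis A `time_axis`.
#' @param t0_ns Peak position on the axis (ns).
#' @return An `irf` object (`curve`, `fwhm_ps`, `t0_bin`).
#' @export
gaussian_irf <- function(fwhm_ps = 380, axis, t0_ns = 1) {
  stopifnot(inherits(axis, "time_axis"))
  if (fwhm_ps <= 0) stop("`fwhm_ps` must be positive", call. = FALSE)
  if (t0_ns < 0 || t0_ns > axis$period_ns)
    stop("`t0_ns` must lie within the axis", call. = FALSE)
  t_ps <- axis_times(axis, "ps")
  t0_ps <- t0_ns * 1e3
  if (fwhm_ps < axis$bin_width_ps) {
    warning("IRF FWHM below one TDC bin; using a single-bin impulse")
    curve <- numeric(axis$n_bins)
    curve[which.min(abs(t_ps - t0_ps))] <- 1
    return(new_irf(curve, fwhm_ps, which.min(abs(t_ps - t0_ps)) - 1L))
  }
  sigma <- fwhm_ps / (2 * sqrt(2 * log(2)))
  curve <- exp(-0.5 * ((t_ps - t0_ps) / sigma)^2)
  new_irf(curve, fwhm_ps, which.max(curve) - 1L)
}

#' Measure the IRF from an IRF acquisition
#'
#' Aggregates the decays of ok pixels (the acquisition should image an
#' attenuated fraction of the excitation pulses), subtracts the tail-estimated
#' dark offset, clips negatives and normalizes to unit sum. The empirical
#' FWHM of the result is reported on the object.
#'
#' @param irf_hist A `decay_histogram` from an IRF acquisition (skew-correct
#'   it first for a sharp aggregate).
#' @param status Optional `pixel_status`; only ok pixels are aggregated.
#' @param tail_ns Tail window used to estimate the offset (ns).
#' @return An `irf` object with empirical `fwhm_ps`.
#' @export
measure_irf <- function(irf_hist, status = NULL, tail_ns = 2) {
  stopifnot(inherits(irf_hist, "decay_histogram"))
  d <- dim(irf_hist$counts)
  ok <- if (is.null(status)) matrix(TRUE, d[1], d[2]) else ok_pixels(status)
  if (!any(ok)) stop("no ok pixels in IRF acquisition", call. = FALSE)
  agg <- aggregate_decay(irf_hist, ok)
  if (all(agg == 0)) stop("IRF acquisition contains no counts", call. = FALSE)
  bw_ns <- irf_hist$axis$bin_width_ps / 1e3
  tail_bins <- max(1L, floor(tail_ns / bw_ns))
  n <- length(agg)
  offset <- mean(agg[(n - tail_bins + 1):n])
  curve <- pmax(agg - offset, 0)
  if (all(curve == 0)) stop("IRF acquisition is offset only", call. = FALSE)
  fwhm <- measure_fwhm(curve, irf_hist$axis$bin_width_ps)
  new_irf(curve, fwhm, which.max(curve) - 1L)
}

#' @export
print.irf <- function(x, ...) {
  cat(sprintf("<irf> %d bins, FWHM %.3g ps, peak at bin %d\n",
              length(x$curve), x$fwhm_ps, x$t0_bin))
  invisible(x)
}
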