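#' Expected decay under the periodic reconvolution model
#'
#' Forward model for iterative reconvolution fitting. The fluorescence
#' impulse response is a mixture of exponentials; at a finite laser period
#' the tails of previous pulses wrap around, which for an exponential has the
#' closed geometric-series form `e^(-t/tau) / (1 - e^(-Tp/tau))` on one
#' period. Discretized on the time axis and normalized to unit sum, the
#' kernel is circularly convolved with the unit-sum IRF, scaled by the photon
#' amplitude, and the uniform dark offset is added. By construction
#' `sum(expected - offset) == amplitude` exactly for every parameter choice
#' (flux conservation under wrap-around).
#'
#' @param alpha1 Fractional amplitude of the first component (`alpha2 = 1 -
#'   alpha1`).
#' @param tau1,tau2 Lifetimes in ns (`tau2` may be `NULL` for a
#'   mono-exponential, equivalent to `alpha1 = 1`).
#' @param amplitude Total signal photons in the curve.
#' @param offset Uniform dark level, counts per bin.
#' @param irf An `irf` object on the same axis.
#' @param axis A `time_axis`.
#' @return Numeric vector of expected counts per bin.
#' @export
model_decay <- function(alpha1, tau1, tau2 = NULL, amplitude, offset = 0,
                        irf, axis) {
  stopifnot(inherits(irf, "irf"), inherits(axis, "time_axis"))
  if (length(irf$curve) != axis$n_bins)
    stop("IRF and axis disagree on bin count", call. = FALSE)
  model_decay_fft(alpha1, tau1, tau2, amplitude, offset,
                  stats::fft(irf$curve), axis$n_bins,
                  axis$bin_width_ps / 1e3)
}

# internal: forward model with a precomputed FFT of the IRF
model_decay_fft <- function(alpha1, tau1, tau2, amplitude, offset,
                            f_irf, n_bins, bw_ns) {
  if (tau1 <= 0 || (!is.null(tau2) && tau2 <= 0))
    stop("lifetimes must be positive", call. = FALSE)
  if (is.null(tau2)) {
    if (abs(alpha1 - 1) > 1e-12)
      stop("mono-exponential model requires alpha1 = 1", call. = FALSE)
  } else if (alpha1 < 0 || alpha1 > 1) {
    stop("alpha1 must lie in [0, 1]", call. = FALSE)
  }
  tb <- (seq_len(n_bins) - 1) * bw_ns
  kern <- function(tau) {
    k <- exp(-tb / tau)
    k / sum(k) # unit sum == wrapped kernel normalized over one period
  }
  k <- if (is.null(tau2)) kern(tau1) else {
    alpha1 * kern(tau1) + (1 - alpha1) * kern(tau2)
  }
  conv <- Re(stats::fft(stats::fft(k) * f_irf, inverse = TRUE)) / n_bins
  amplitude * conv + offset
}

#' Amplitude-weighted mean fluorescence lifetime
#'
#' `tau_m = alpha1 * tau1 + alpha2 * tau2`, the standard summary of
#' biexponential NAD(P)H decays (short free component, long bound component).
#'
#' @param alpha1,alpha2 Fractional amplitudes; must sum to 1.
#' @param tau1,tau2 Lifetimes (ns).
#' @return Mean lifetime in ns (vectorized).
#' @export
mean_lifetime <- function(alpha1, tau1, alpha2, tau2) {
  if (any(abs(alpha1 + alpha2 - 1) > 1e-8))
    stop("fractional amplitudes must sum to 1", call. = FALSE)
  alpha1 * tau1 + alpha2 * tau2
}

#' Integrated signal photons of a decay
#'
#' Total counts minus the dark contribution (`n_bins * offset`), floored at
#' zero — the per-pixel fluorescence intensity used for photon thresholds and
#' intensity maps.
#'
#' @param decay Numeric counts per bin.
#' @param offset Dark level, counts per bin.
#' @return Photon count (scalar).
#' @export
intensity_from_decay <- function(decay, offset = 0) {
  max(sum(decay) - length(decay) * offset, 0)
}
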