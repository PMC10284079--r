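#' Estimate per-pixel dark count rates from decay tails
#'
#' Dark counts are uncorrelated with the laser sync, so they form a uniform
#' offset across the time axis. The last `tail_ns` of each pixel decay —
#' where the fluorescence has decayed away — estimates that per-bin offset,
#' and a per-bin level `b` over an axis of `n` bins acquired for `T` seconds
#' implies a rate `b * n / T` counts per second.
#'
#' @param hist A `decay_histogram` (a dark or long-tail acquisition).
#' @param tail_ns Width of the tail window in ns (default 2).
#' @return A `dcr_map`: list with matrices `dcr` (cps) and `offset_per_bin`
#'   (counts/bin, the fixed offset handed to the fitter), plus `tail_bins`.
#' @export
estimate_dcr_map <- function(hist, tail_ns = 2) {
  stopifnot(inherits(hist, "decay_histogram"))
  bw_ns <- hist$axis$bin_width_ps / 1e3
  tail_bins <- floor(tail_ns / bw_ns)
  if (tail_bins < 1)
    stop("tail window spans zero bins; increase `tail_ns`", call. = FALSE)
  n <- hist$axis$n_bins
  if (tail_bins >= n)
    stop("tail window must be shorter than the time axis", call. = FALSE)
  tail_idx <- (n - tail_bins + 1):n
  d <- dim(hist$counts)
  tail_counts <- hist$counts[, , tail_idx, drop = FALSE]
  offset <- apply(tail_counts, c(1, 2), sum) / tail_bins
  dcr <- offset * n / hist$meta$integration_s
  structure(list(dcr = dcr, offset_per_bin = offset,
                 tail_bins = as.integer(tail_bins)),
            class = "dcr_map")
}

#' Classify screamer and dead SPAD pixels
#'
#' SPAD arrays carry a population of "screamer" pixels with pathologically
#' high dark count rates (around 15% for the device emulated here) and
#' occasional pixels that never fire. Screamers are flagged by a quantile
#' threshold on the DCR distribution — the criterion is device-specific and
#' deliberately configurable — and dead pixels by their total counts under
#' illumination.
#'
#' @param dcr_map A `dcr_map` from [estimate_dcr_map()].
#' @param hist The illuminated `decay_histogram` used for dead-pixel counts.
#' @param screamer_quantile Pixels with DCR strictly above this quantile of
#'   the DCR distribution are screamers (default 0.85, i.e. top 15%).
#' @param dead_count_threshold Pixels with total counts at or below this are
#'   dark-dead (default 0).
#' @return A `pixel_status` character matrix with entries `"ok"`,
#'   `"screamer"`, `"dark-dead"`.
#' @export
detect_bad_pixels <- function(dcr_map, hist, screamer_quantile = 0.85,
                              dead_count_threshold = 0) {
  stopifnot(inherits(dcr_map, "dcr_map"), inherits(hist, "decay_histogram"))
  totals <- apply(hist$counts, c(1, 2), sum)
  if (!identical(dim(totals), dim(dcr_map$dcr)))
    stop("dcr map and histogram shapes differ", call. = FALSE)
  status <- matrix("ok", nrow(totals), ncol(totals))
  cut <- stats::quantile(dcr_map$dcr, screamer_quantile, names = FALSE)
  status[dcr_map$dcr > cut] <- "screamer"
  status[totals <= dead_count_threshold] <- "dark-dead"
  class(status) <- c("pixel_status", class(status))
  status
}

ok_pixels <- function(status) unclass(status) == "ok"

#' Estimate the inter-pixel timing skew map
#'
#' Per-pixel TDC chains carry fixed timing offsets of up to tens of bins
#' across the array. Each pixel's lag relative to a reference decay is the
#' arg-max over lags in `[-max_lag, max_lag]` of the Pearson-normalized
#' circular cross-correlation between the pixel decay and the reference
#' (mean-subtracted, unit-norm, so the uniform dark offset drops out). Ties
#' break toward the smallest magnitude lag; constant decays get lag 0 and a
#' degenerate flag.
#'
#' @param hist A `decay_histogram`.
#' @param reference Numeric reference decay of length `n_bins` (see
#'   [make_reference_decay()]).
#' @param max_lag Lag search half-range in bins (default 75).
#' @param status Optional `pixel_status`; non-ok pixels get lag 0 and the
#'   degenerate flag.
#' @return A `skew_map`: list with integer matrix `lag` and logical matrix
#'   `degenerate`.
#' @export
estimate_skew_map <- function(hist, reference, max_lag = 75, status = NULL) {
  stopifnot(inherits(hist, "decay_histogram"))
  d <- dim(hist$counts)
  n <- d[3]
  if (length(reference) != n)
    stop("reference decay length must equal the number of time bins",
         call. = FALSE)
  if (max_lag < 0 || max_lag >= n / 2)
    stop("`max_lag` must be in [0, n_bins/2)", call. = FALSE)
  npix <- d[1] * d[2]
  X <- matrix(hist$counts, nrow = npix, ncol = n)
  bad <- rep(FALSE, npix)
  if (!is.null(status)) bad <- !as.vector(ok_pixels(status))

  r <- reference - mean(reference)
  rn <- sqrt(sum(r^2))
  if (rn == 0) stop("reference decay is constant", call. = FALSE)
  fr <- stats::fft(r / rn)

  # candidate lags ordered by |lag| so which.max tie-breaks to smallest
  lag_seq <- seq(-max_lag, max_lag)
  lag_seq <- lag_seq[order(abs(lag_seq), lag_seq)]
  idx <- (lag_seq %% n) + 1L

  lag <- integer(npix)
  degen <- logical(npix)
  chunk <- 4096L
  for (s in seq(1L, npix, by = chunk)) {
    e <- min(s + chunk - 1L, npix)
    Xi <- X[s:e, , drop = FALSE]
    mu <- rowMeans(Xi)
    Xi <- Xi - mu
    nrm <- sqrt(rowSums(Xi^2))
    z <- nrm == 0
    nrm[z] <- 1
    Xi <- Xi / nrm
    # C[l] = sum_b x[(b+l) mod n] * r[b] = IFFT(FFT(x) * Conj(FFT(r)))
    FX <- stats::mvfft(t(Xi))
    C <- Re(stats::mvfft(FX * Conj(fr), inverse = TRUE)) / n
    Csub <- C[idx, , drop = FALSE]
    pick <- apply(Csub, 2, which.max)
    li <- lag_seq[pick]
    li[z] <- 0L
    lag[s:e] <- li
    degen[s:e] <- z
  }
  lag[bad] <- 0L
  degen[bad] <- TRUE
  structure(list(lag = matrix(as.integer(lag), d[1], d[2]),
                 degenerate = matrix(degen, d[1], d[2]),
                 max_lag = as.integer(max_lag)),
            class = "skew_map")
}

#' Correct timing skew by circular shifts
#'
#' Each pixel decay is circularly shifted by minus its lag so that all pixels
#' share a common rise time; per-pixel total counts are exactly conserved, so
#' aggregation and binning after correction no longer broaden the decay.
#'
#' @param hist A `decay_histogram`.
#' @param skew A `skew_map` of matching shape.
#' @return A corrected `decay_histogram`.
#' @export
apply_skew_correction <- function(hist, skew) {
  stopifnot(inherits(hist, "decay_histogram"), inherits(skew, "skew_map"))
  d <- dim(hist$counts)
  if (!identical(dim(skew$lag), d[1:2]))
    stop("skew map shape must equal sensor shape", call. = FALSE)
  n <- d[3]
  npix <- d[1] * d[2]
  X <- matrix(hist$counts, nrow = npix, ncol = n)
  lag <- as.vector(skew$lag) %% n
  for (l in unique(lag)) {
    if (l == 0) next
    sel <- lag == l
    # shift left by l (inverse of a right shift by l)
    X[sel, ] <- X[sel, c((l + 1):n, 1:l), drop = FALSE]
  }
  out <- hist
  out$counts <- array(X, dim = d)
  out$meta$provenance <- paste0(hist$meta$provenance, "+skew_corrected")
  out
}

#' Build a reference decay for skew estimation
#'
#' @param hist A `decay_histogram` of a bright, uniform sample (e.g. a
#'   fluorescence standard).
#' @param status Optional `pixel_status`; only ok pixels are considered.
#' @param method `"max-pixel"` (brightest ok pixel, default) or
#'   `"central-block"` (aggregate of the central `block`-square of ok pixels).
#' @param block Side of the central block for `"central-block"`.
#' @return Numeric decay of length `n_bins`.
#' @export
make_reference_decay <- function(hist, status = NULL,
                                 method = c("max-pixel", "central-block"),
                                 block = 16) {
  stopifnot(inherits(hist, "decay_histogram"))
  method <- match.arg(method)
  d <- dim(hist$counts)
  ok <- if (is.null(status)) matrix(TRUE, d[1], d[2]) else ok_pixels(status)
  if (!any(ok)) stop("no ok pixels to build a reference from", call. = FALSE)
  if (method == "max-pixel") {
    totals <- apply(hist$counts, c(1, 2), sum)
    totals[!ok] <- -Inf
    w <- which(totals == max(totals), arr.ind = TRUE)[1, ]
    as.numeric(hist$counts[w[1], w[2], ])
  } else {
    half <- floor(block / 2)
    rc <- floor(d[1] / 2); cc <- floor(d[2] / 2)
    rsel <- max(1, rc - half + 1):min(d[1], rc + half)
    csel <- max(1, cc - half + 1):min(d[2], cc + half)
    m <- matrix(FALSE, d[1], d[2])
    m[rsel, csel] <- TRUE
    m <- m & ok
    if (!any(m)) stop("no ok pixels in the central block", call. = FALSE)
    aggregate_decay(hist, m)
  }
}

#' Bundle sensor calibration state
#'
#' @param dcr_map A `dcr_map`.
#' @param skew_map A `skew_map`.
#' @param status A `pixel_status` matrix.
#' @param reference_decay Numeric reference decay.
#' @param irf An [irf] object (see [gaussian_irf()] / [measure_irf()]).
#' @param axis The shared `time_axis`.
#' @return A `calibration_bundle`.
#' @export
calibration_bundle <- function(dcr_map, skew_map, status, reference_decay,
                               irf, axis) {
  stopifnot(inherits(dcr_map, "dcr_map"), inherits(skew_map, "skew_map"),
            inherits(irf, "irf"), inherits(axis, "time_axis"))
  if (!identical(dim(dcr_map$dcr), dim(skew_map$lag)) ||
      !identical(dim(dcr_map$dcr), dim(unclass(status))))
    stop("calibration components disagree on sensor shape", call. = FALSE)
  if (length(reference_decay) != axis$n_bins ||
      length(irf$curve) != axis$n_bins)
    stop("calibration components disagree on the time axis", call. = FALSE)
  structure(list(dcr_map = dcr_map, skew_map = skew_map, status = status,
                 reference_decay = reference_decay, irf = irf, axis = axis),
            class = "calibration_bundle")
}

#' Run the full calibration chain on an acquisition
#'
#' Convenience wrapper: DCR from tails, bad-pixel classification, reference
#' decay, skew map, and IRF (measured from `irf_hist` when given, otherwise a
#' Gaussian model IRF positioned at the reference rise).
#'
#' @param hist A bright calibration acquisition (`decay_histogram`).
#' @param irf_hist Optional IRF acquisition (`decay_histogram`).
#' @param tail_ns Tail window for DCR estimation (ns).
#' @param screamer_quantile,dead_count_threshold See [detect_bad_pixels()].
#' @param max_lag See [estimate_skew_map()].
#' @param irf_fwhm_ps FWHM of the model IRF when no `irf_hist` is supplied.
#' @return A `calibration_bundle`.
#' @export
calibrate_sensor <- function(hist, irf_hist = NULL, tail_ns = 2,
                             screamer_quantile = 0.85,
                             dead_count_threshold = 0, max_lag = 75,
                             irf_fwhm_ps = 380) {
  dcr <- estimate_dcr_map(hist, tail_ns)
  status <- detect_bad_pixels(dcr, hist, screamer_quantile,
                              dead_count_threshold)
  ref <- make_reference_decay(hist, status)
  skew <- estimate_skew_map(hist, ref, max_lag, status)
  irf <- if (!is.null(irf_hist)) {
    ih <- apply_skew_correction(irf_hist, skew)
    measure_irf(ih, status, tail_ns = tail_ns)
  } else {
    t0 <- (which.max(ref) - 1) * hist$axis$bin_width_ps / 1e3
    gaussian_irf(irf_fwhm_ps, hist$axis, t0_ns = t0)
  }
  calibration_bundle(dcr, skew, status, ref, irf, hist$axis)
}

status_codes <- c("ok" = 0L, "screamer" = 1L, "dark-dead" = 2L)

#' Persist / load a calibration bundle
#'
#' Maps are stored in one HDF5 file (`dcr`, `offset_per_bin`, `lag`,
#' `status` as integer codes 0=ok/1=screamer/2=dark-dead, `reference`,
#' `irf`), scalars and provenance in a JSON sidecar (`<path>.json`).
#'
#' @param calib A `calibration_bundle`.
#' @param path HDF5 file path; the sidecar is `<path>.json`.
#' @return `path` invisibly (write); a `calibration_bundle` (read).
#' @export
write_calibration <- function(calib, path) {
  stopifnot(inherits(calib, "calibration_bundle"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  rhdf5::h5write(calib$dcr_map$dcr, path, "dcr")
  rhdf5::h5write(calib$dcr_map$offset_per_bin, path, "offset_per_bin")
  rhdf5::h5write(calib$skew_map$lag, path, "lag")
  st <- matrix(status_codes[unclass(calib$status)], nrow(calib$skew_map$lag))
  rhdf5::h5write(st, path, "status")
  rhdf5::h5write(calib$reference_decay, path, "reference")
  rhdf5::h5write(calib$irf$curve, path, "irf")
  side <- list(
    bin_width_ps = calib$axis$bin_width_ps,
    rep_rate_hz = 1e9 / calib$axis$period_ns,
    tail_bins = calib$dcr_map$tail_bins,
    max_lag = calib$skew_map$max_lag,
    irf_fwhm_ps = calib$irf$fwhm_ps,
    irf_t0_bin = calib$irf$t0_bin,
    schema_version = "1")
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  axis <- make_time_axis(side$rep_rate_hz, side$bin_width_ps)
  dcr <- structure(list(dcr = rhdf5::h5read(path, "dcr"),
                        offset_per_bin = rhdf5::h5read(path, "offset_per_bin"),
                        tail_bins = as.integer(side$tail_bins)),
                   class = "dcr_map")
  lag <- rhdf5::h5read(path, "lag")
  storage.mode(lag) <- "integer"
  skew <- structure(list(lag = lag,
                         degenerate = matrix(FALSE, nrow(lag), ncol(lag)),
                         max_lag = as.integer(side$max_lag)),
                    class = "skew_map")
  stc <- rhdf5::h5read(path, "status")
  status <- matrix(names(status_codes)[stc + 1L], nrow(stc))
  class(status) <- c("pixel_status", class(status))
  curve <- as.numeric(rhdf5::h5read(path, "irf"))
  irf <- structure(list(curve = curve, fwhm_ps = side$irf_fwhm_ps,
                        t0_bin = side$irf_t0_bin), class = "irf")
  calibration_bundle(dcr, skew, status,
                     as.numeric(rhdf5::h5read(path, "reference")), irf, axis)
}

#' Export calibration maps as TIFF for inspection
#'
#' @param calib A `calibration_bundle`.
#' @param dir Output directory.
#' @return Character vector of file paths, invisibly.
#' @export
export_calibration_tiff <- function(calib, dir) {
  stopifnot(inherits(calib, "calibration_bundle"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  norm01 <- function(m) {
    rng <- range(m, finite = TRUE)
    if (diff(rng) == 0) return(m * 0)
    (m - rng[1]) / diff(rng)
  }
  paths <- c(dcr = file.path(dir, "dcr.tif"),
             lag = file.path(dir, "lag.tif"),
             status = file.path(dir, "status.tif"))
  tiff::writeTIFF(norm01(calib$dcr_map$dcr), paths["dcr"], bits.per.sample = 32)
  tiff::writeTIFF(norm01(calib$skew_map$lag), paths["lag"], bits.per.sample = 32)
  st <- matrix(status_codes[unclass(calib$status)], nrow(calib$skew_map$lag))
  tiff::writeTIFF(st / 2, paths["status"], bits.per.sample = 32)
  invisible(paths)
}
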