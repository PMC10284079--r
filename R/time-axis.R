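#' Construct a TCSPC time axis
#'
#' A time axis discretizes one laser period into TDC bins. The number of bins
#' is the largest whole number of bins that fits in the period, so
#' `n_bins * bin_width_ps` never exceeds the period. For the 50 MHz / 41.1 ps
#' configuration of a per-pixel-TDC SPAD camera this yields a 20 ns axis of
#' 486 bins.
#'
#' @param rep_rate_hz Laser repetition rate in Hz (sets the period).
#' @param bin_width_ps TDC bin width in picoseconds.
#' @return A `time_axis` object with fields `bin_width_ps`, `n_bins` and
#'   `period_ns`.
#' @examples
#' make_time_axis(50e6, 41.1) # 486 bins over 20 ns
#' @export
make_time_axis <- function(rep_rate_hz, bin_width_ps) {
  if (!is.numeric(rep_rate_hz) || length(rep_rate_hz) != 1 || rep_rate_hz <= 0)
    stop("`rep_rate_hz` must be a single positive number", call. = FALSE)
  if (!is.numeric(bin_width_ps) || length(bin_width_ps) != 1 || bin_width_ps <= 0)
    stop("`bin_width_ps` must be a single positive number", call. = FALSE)
  period_ps <- 1e12 / rep_rate_hz
  n_bins <- floor(period_ps / bin_width_ps)
  if (n_bins < 1)
    stop("bin width exceeds the laser period; no bins fit", call. = FALSE)
  structure(
    list(bin_width_ps = bin_width_ps, n_bins = as.integer(n_bins),
         period_ns = period_ps / 1e3),
    class = "time_axis"
  )
}

#' Bin start times of a time axis
#'
#' @param axis A `time_axis`.
#' @param unit `"ns"` (default) or `"ps"`.
#' @return Numeric vector of length `n_bins`; bin 0 starts at the laser sync
#'   edge.
#' @export
axis_times <- function(axis, unit = c("ns", "ps")) {
  stopifnot(inherits(axis, "time_axis"))
  unit <- match.arg(unit)
  t_ps <- (seq_len(axis$n_bins) - 1) * axis$bin_width_ps
  if (unit == "ns") t_ps / 1e3 else t_ps
}

#' @export
print.time_axis <- function(x, ...) {
  cat(sprintf("<time_axis> %d bins of %.4g ps over a %.4g ns period\n",
              x$n_bins, x$bin_width_ps, x$period_ns))
  invisible(x)
}
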