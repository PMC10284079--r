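#' Decay histograms
#'
#' The central working object: a 3D array of photon counts indexed
#' (row, col, time bin) together with its [make_time_axis()] axis and the
#' integration time. Constructed from photon streams with
#' [histogram_from_stream()] or simulated with [simulate_histogram()].
#'
#' @param counts Non-negative integer array, dim = c(rows, cols, n_bins).
#' @param axis A `time_axis` whose `n_bins` matches `dim(counts)[3]`.
#' @param integration_s Integration time (s).
#' @param provenance Optional character tag recording origin.
#' @param n_discarded Events dropped because their TDC code fell beyond the
#'   axis (bookkeeping from histogramming).
#' @return A `decay_histogram`.
#' @export
decay_histogram <- function(counts, axis, integration_s,
                            provenance = "unspecified", n_discarded = 0L) {
  stopifnot(inherits(axis, "time_axis"))
  if (length(dim(counts)) != 3)
    stop("`counts` must be a 3D (row, col, bin) array", call. = FALSE)
  if (dim(counts)[3] != axis$n_bins)
    stop("third dimension of `counts` must equal axis$n_bins", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  integration_s <- as.numeric(integration_s)[1]
  if (integration_s <= 0) stop("`integration_s` must be positive", call. = FALSE)
  structure(
    list(counts = counts, axis = axis,
         meta = list(integration_s = integration_s, provenance = provenance,
                     n_discarded = as.integer(n_discarded))),
    class = "decay_histogram"
  )
}

#' @export
print.decay_histogram <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf(
    "<decay_histogram> %dx%d pixels x %d bins, %.4g total counts (%g s, %s)\n",
    d[1], d[2], d[3], sum(x$counts), x$meta$integration_s, x$meta$provenance))
  invisible(x)
}

hist_shape <- function(hist) dim(hist$counts)[1:2]

#' Histogram a photon stream onto a time axis
#'
#' Converts per-photon events into a 3D decay histogram. TDC codes beyond the
#' axis (the TDC range of the camera exceeds the laser period) are discarded
#' by default and their number recorded; set `fold = TRUE` to wrap them
#' modulo the period instead.
#'
#' @param stream A `photon_stream`.
#' @param axis A `time_axis`; its bin width must match the stream metadata.
#' @param fold Wrap out-of-range TDC codes modulo `n_bins` instead of
#'   dropping them (default `FALSE`).
#' @return A `decay_histogram`; `$meta$n_discarded` counts dropped events.
#' @export
histogram_from_stream <- function(stream, axis, fold = FALSE) {
  stopifnot(inherits(stream, "photon_stream"), inherits(axis, "time_axis"))
  if (abs(stream$meta$bin_width_ps - axis$bin_width_ps) > 1e-9)
    stop("axis bin width does not match stream metadata", call. = FALSE)
  rows <- stream$meta$rows; cols <- stream$meta$cols
  ev <- stream$events
  n_disc <- 0L
  if (nrow(ev) > 0) {
    if (any(ev$row < 0L | ev$row >= rows | ev$col < 0L | ev$col >= cols))
      stop("event pixel coordinates outside sensor shape", call. = FALSE)
    if (fold) {
      ev$tdc_code <- ev$tdc_code %% axis$n_bins
    } else {
      keep <- ev$tdc_code < axis$n_bins
      n_disc <- sum(!keep)
      ev <- ev[keep, , drop = FALSE]
    }
  }
  n_cells <- rows * cols * axis$n_bins
  idx <- ev$row + rows * (ev$col + cols * ev$tdc_code) + 1L
  counts <- array(tabulate(idx, nbins = n_cells),
                  dim = c(rows, cols, axis$n_bins))
  decay_histogram(counts, axis, stream$meta$integration_s,
                  provenance = "histogram_from_stream", n_discarded = n_disc)
}

#' Aggregate pixel decays into a single decay curve
#'
#' Sums the decay histograms of a set of pixels (e.g. all good pixels of the
#' array) into one 1D decay, as used for whole-sensor lifetime fits of
#' fluorescence standards.
#'
#' @param hist A `decay_histogram`.
#' @param mask Logical matrix of sensor shape selecting pixels; `NULL` selects
#'   all pixels.
#' @return Numeric vector of counts per time bin.
#' @export
aggregate_decay <- function(hist, mask = NULL) {
  stopifnot(inherits(hist, "decay_histogram"))
  d <- dim(hist$counts)
  if (is.null(mask)) mask <- matrix(TRUE, d[1], d[2])
  if (!identical(dim(mask), d[1:2]))
    stop("mask shape must equal sensor shape", call. = FALSE)
  mask <- mask & !is.na(mask)
  if (!any(mask)) stop("mask selects no pixels", call. = FALSE)
  m <- matrix(hist$counts, nrow = d[1] * d[2], ncol = d[3])
  colSums(m[as.vector(mask), , drop = FALSE])
}

#' Write / read a decay histogram (HDF5)
#'
#' Persists `/histogram` (rows x cols x bins, unsigned 32-bit) with the same
#' root attributes as the photon-stream dialect.
#'
#' @param hist A `decay_histogram`.
#' @param path File path.
#' @return `path` invisibly (write); a `decay_histogram` (read).
#' @export
write_decay_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "decay_histogram"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  cnt <- hist$counts
  storage.mode(cnt) <- "integer"
  rhdf5::h5createDataset(path, "histogram", dims = dim(cnt),
                         H5type = "H5T_STD_U32LE")
  rhdf5::h5write(cnt, path, "histogram")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(dim(cnt)[1], fid, "rows")
  rhdf5::h5writeAttribute(dim(cnt)[2], fid, "cols")
  rhdf5::h5writeAttribute(hist$axis$bin_width_ps, fid, "bin_width_ps")
  rhdf5::h5writeAttribute(1e9 / hist$axis$period_ns, fid, "rep_rate_hz")
  rhdf5::h5writeAttribute(hist$meta$integration_s, fid, "integration_s")
  rhdf5::h5writeAttribute("1", fid, "schema_version")
  invisible(path)
}

#' @rdname write_decay_histogram
#' @export
read_decay_histogram <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  at <- rhdf5::h5readAttributes(path, "/")
  missing <- setdiff(stream_attrs, names(at))
  if (length(missing) > 0)
    stop("histogram file is missing attribute(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  counts <- rhdf5::h5read(path, "histogram")
  axis <- make_time_axis(as.numeric(at$rep_rate_hz), as.numeric(at$bin_width_ps))
  decay_histogram(counts, axis, at$integration_s, provenance = "file")
}
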