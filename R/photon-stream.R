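#' Photon event streams
#'
#' A photon stream is the raw product of a TCSPC SPAD acquisition: one record
#' per detected photon carrying the pixel coordinates and the TDC time code.
#' Events are kept unsorted, in a tibble with 0-based integer columns `row`,
#' `col` and `tdc_code`, plus sensor/acquisition metadata.
#'
#' @param events Data frame with integer columns `row`, `col`, `tdc_code`
#'   (0-based pixel indices and TDC bin codes).
#' @param rows,cols Sensor dimensions in pixels.
#' @param rep_rate_hz Laser repetition rate (Hz).
#' @param bin_width_ps TDC bin width (ps).
#' @param integration_s Integration time of the acquisition (s).
#' @return A `photon_stream` object.
#' @export
photon_stream <- function(events, rows, cols, rep_rate_hz, bin_width_ps,
                          integration_s) {
  events <- tibble::as_tibble(events)
  if (nrow(events) == 0 && !all(c("row", "col", "tdc_code") %in% names(events)))
    events <- tibble::tibble(row = integer(), col = integer(),
                             tdc_code = integer())
  req <- c("row", "col", "tdc_code")
  if (!all(req %in% names(events)))
    stop("`events` must have columns row, col, tdc_code", call. = FALSE)
  events <- events[req]
  events[] <- lapply(events, function(v) as.integer(as.vector(v)))
  rows <- as.integer(rows)[1]; cols <- as.integer(cols)[1]
  rep_rate_hz <- as.numeric(rep_rate_hz)[1]
  bin_width_ps <- as.numeric(bin_width_ps)[1]
  integration_s <- as.numeric(integration_s)[1]
  if (integration_s <= 0)
    stop("`integration_s` must be positive", call. = FALSE)
  if (nrow(events) > 0) {
    if (any(events$row < 0L) || any(events$row >= rows) ||
        any(events$col < 0L) || any(events$col >= cols))
      stop("event pixel coordinates fall outside the sensor", call. = FALSE)
    if (any(events$tdc_code < 0L))
      stop("negative TDC codes are invalid", call. = FALSE)
  }
  structure(
    list(events = events,
         meta = list(rows = as.integer(rows), cols = as.integer(cols),
                     rep_rate_hz = rep_rate_hz, bin_width_ps = bin_width_ps,
                     integration_s = integration_s)),
    class = "photon_stream"
  )
}

#' @export
print.photon_stream <- function(x, ...) {
  cat(sprintf(
    "<photon_stream> %d events on a %dx%d sensor (%.3g MHz, %.4g ps bins, %g s)\n",
    nrow(x$events), x$meta$rows, x$meta$cols, x$meta$rep_rate_hz / 1e6,
    x$meta$bin_width_ps, x$meta$integration_s))
  invisible(x)
}

stream_attrs <- c("rows", "cols", "bin_width_ps", "rep_rate_hz",
                  "integration_s", "schema_version")

#' Write a photon stream to HDF5
#'
#' Persists the stream in a simple HDF5 dialect: a dataset `/photons` of shape
#' N x 3 (unsigned 16-bit; columns row, col, tdc_code) and root attributes
#' `rows`, `cols`, `bin_width_ps`, `rep_rate_hz`, `integration_s`,
#' `schema_version`.
#'
#' @param stream A `photon_stream`.
#' @param path Output file path (overwritten if present).
#' @return `path`, invisibly.
#' @export
write_photon_stream <- function(stream, path) {
  stopifnot(inherits(stream, "photon_stream"))
  if (file.exists(path)) unlink(path)
  rhdf5::h5createFile(path)
  ev <- as.matrix(stream$events[c("row", "col", "tdc_code")])
  storage.mode(ev) <- "integer"
  rhdf5::h5createDataset(path, "photons", dims = dim(ev), H5type = "H5T_STD_U16LE")
  if (nrow(ev) > 0) rhdf5::h5write(ev, path, "photons")
  fid <- rhdf5::H5Fopen(path)
  on.exit(rhdf5::H5Fclose(fid), add = TRUE)
  rhdf5::h5writeAttribute(stream$meta$rows, fid, "rows")
  rhdf5::h5writeAttribute(stream$meta$cols, fid, "cols")
  rhdf5::h5writeAttribute(stream$meta$bin_width_ps, fid, "bin_width_ps")
  rhdf5::h5writeAttribute(stream$meta$rep_rate_hz, fid, "rep_rate_hz")
  rhdf5::h5writeAttribute(stream$meta$integration_s, fid, "integration_s")
  rhdf5::h5writeAttribute("1", fid, "schema_version")
  invisible(path)
}

#' Read a photon stream from HDF5
#'
#' @param path File written by [write_photon_stream()] (or conforming to the
#'   same dialect).
#' @return A `photon_stream`.
#' @export
read_photon_stream <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  objs <- rhdf5::h5ls(path)
  if (!"photons" %in% objs$name)
    stop("photon-stream file is missing dataset '/photons'", call. = FALSE)
  at <- rhdf5::h5readAttributes(path, "/")
  missing <- setdiff(stream_attrs, names(at))
  if (length(missing) > 0)
    stop("photon-stream file is missing attribute(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  ev <- rhdf5::h5read(path, "photons")
  if (length(ev) == 0) ev <- matrix(integer(), ncol = 3)
  storage.mode(ev) <- "integer"
  photon_stream(
    tibble::tibble(row = ev[, 1], col = ev[, 2], tdc_code = ev[, 3]),
    rows = at$rows, cols = at$cols, rep_rate_hz = at$rep_rate_hz,
    bin_width_ps = at$bin_width_ps, integration_s = at$integration_s
  )
}
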