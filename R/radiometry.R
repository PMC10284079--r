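#' Detector specification for count-rate budgets
#'
#' Describes a TCSPC detection system for acquisition-speed comparisons: a
#' laser-scanning microscope reads its single timing channel sequentially
#' across image pixels, while a SPAD array with per-pixel TDCs counts on all
#' pixels simultaneously.
#'
#' @param n_pixels Image pixel count (the 192x128 array is ~25,000; nominal
#'   rounded values are accepted for table-style outputs).
#' @param per_pixel_max_rate Saturation count rate of one timing channel
#'   (cps).
#' @param dead_time_ns Detector dead time (ns).
#' @param mode `"sequential"` (laser scanning) or `"simultaneous"` (array).
#' @return A `detector_spec`.
#' @export
detector_spec <- function(n_pixels, per_pixel_max_rate, dead_time_ns,
                          mode = c("sequential", "simultaneous")) {
  mode <- match.arg(mode)
  n_pixels <- as.numeric(n_pixels)
  per_pixel_max_rate <- as.numeric(per_pixel_max_rate)
  dead_time_ns <- as.numeric(dead_time_ns)
  if (any(is.na(c(n_pixels, per_pixel_max_rate, dead_time_ns))))
    stop("detector spec fields must be numeric", call. = FALSE)
  if (n_pixels <= 0 || per_pixel_max_rate <= 0 || dead_time_ns <= 0)
    stop("detector spec fields must be positive", call. = FALSE)
  structure(list(n_pixels = n_pixels, per_pixel_max_rate = per_pixel_max_rate,
                 dead_time_ns = dead_time_ns, mode = mode),
            class = "detector_spec")
}

#' Maximum system count rate
#'
#' Simultaneous detectors saturate at `n_pixels * per_pixel_max_rate`;
#' a sequential system is capped by its single channel.
#'
#' @param spec A `detector_spec`.
#' @return Count rate in cps.
#' @export
system_max_rate <- function(spec) {
  stopifnot(inherits(spec, "detector_spec"))
  if (spec$mode == "simultaneous") spec$n_pixels * spec$per_pixel_max_rate
  else spec$per_pixel_max_rate
}

#' Effective per-image-pixel count rate
#'
#' A sequential system divides its channel across the image pixels; a
#' simultaneous array devotes a full channel to each.
#'
#' @param spec A `detector_spec`.
#' @return Count rate in cps per image pixel.
#' @export
effective_pixel_rate <- function(spec) {
  stopifnot(inherits(spec, "detector_spec"))
  if (spec$mode == "sequential") spec$per_pixel_max_rate / spec$n_pixels
  else spec$per_pixel_max_rate
}

#' Acquisition speed advantage of one detector over another
#'
#' Ratio of maximum system count rates; it scales with the number of array
#' pixels for a simultaneous system.
#'
#' @param a,b `detector_spec`s (advantage of `a` over `b`).
#' @return Dimensionless ratio.
#' @export
speed_advantage <- function(a, b) {
  rb <- system_max_rate(b)
  if (rb == 0) stop("denominator system rate is zero", call. = FALSE)
  system_max_rate(a) / rb
}

um2_to_cm2 <- 1e-8

#' Peak irradiance of a focused spot
#'
#' Top-hat convention over a circular spot of the given diameter (the
#' convention under which a 5 mW, 1 um diffraction-limited two-photon spot
#' gives ~640,000 W/cm2).
#'
#' @param power_w Average power at the sample (W).
#' @param diameter_um Spot diameter (um).
#' @param convention `"tophat"` (default) or `"gaussian"` (peak of a Gaussian
#'   with 1/e2 diameter `diameter_um`, `2P/(pi w0^2)`).
#' @return Irradiance in W/cm2.
#' @export
peak_irradiance_spot <- function(power_w, diameter_um,
                                 convention = c("tophat", "gaussian")) {
  convention <- match.arg(convention)
  if (power_w <= 0 || diameter_um <= 0)
    stop("power and diameter must be positive", call. = FALSE)
  r_cm2 <- (diameter_um / 2)^2 * um2_to_cm2
  if (convention == "tophat") power_w / (pi * r_cm2)
  else 2 * power_w / (pi * r_cm2)
}

#' Peak irradiance of a light sheet
#'
#' Gaussian-sheet convention by default: the waist thickness is the full
#' 1/e2 thickness (`w0 = thickness/2`) and the peak is
#' `2P / (pi * w0 * width)`; a 0.4 mW, 200 um x 9 um sheet gives ~28 W/cm2.
#' The `"tophat"` option divides power by the geometric area.
#'
#' @param power_w Average power at the sample (W).
#' @param width_um Sheet width (um).
#' @param waist_thickness_um Sheet waist thickness (um, full 1/e2).
#' @param convention `"gaussian"` (default) or `"tophat"`.
#' @return Irradiance in W/cm2.
#' @export
peak_irradiance_sheet <- function(power_w, width_um, waist_thickness_um,
                                  convention = c("gaussian", "tophat")) {
  convention <- match.arg(convention)
  if (power_w <= 0 || width_um <= 0 || waist_thickness_um <= 0)
    stop("power and sheet dimensions must be positive", call. = FALSE)
  if (convention == "gaussian") {
    w0_cm <- waist_thickness_um / 2 * 1e-4
    2 * power_w / (pi * w0_cm * width_um * 1e-4)
  } else {
    power_w / (width_um * waist_thickness_um * um2_to_cm2)
  }
}

#' Light dose
#'
#' @param irradiance_w_cm2 Irradiance (W/cm2).
#' @param time_s Exposure time (s).
#' @return Dose in J/cm2.
#' @export
light_dose <- function(irradiance_w_cm2, time_s) {
  if (irradiance_w_cm2 < 0 || time_s < 0)
    stop("irradiance and time must be non-negative", call. = FALSE)
  irradiance_w_cm2 * time_s
}

#' Effective count rate from a photon budget
#'
#' @param photons_per_pixel Photons collected per image pixel.
#' @param integration_time_s Total integration time (s).
#' @return Effective rate in cps.
#' @export
photons_budget <- function(photons_per_pixel, integration_time_s) {
  if (photons_per_pixel < 0 || integration_time_s <= 0)
    stop("photon count must be non-negative and time positive", call. = FALSE)
  photons_per_pixel / integration_time_s
}

#' Side-by-side count-rate budget of two detection systems
#'
#' @param a,b `detector_spec`s.
#' @param names Column labels for the two systems.
#' @return A tibble with one row per quantity (pixel count, dead time, max
#'   pixel/system rate, effective pixel rate, speed advantage of `a` over
#'   `b`).
#' @export
budget_table <- function(a, b, names = c("system_a", "system_b")) {
  stopifnot(inherits(a, "detector_spec"), inherits(b, "detector_spec"))
  q <- function(s) c(s$n_pixels, s$dead_time_ns, s$per_pixel_max_rate,
                     system_max_rate(s), effective_pixel_rate(s))
  out <- tibble::tibble(
    quantity = c("image_pixel_count", "dead_time_ns", "max_pixel_rate_cps",
                 "max_system_rate_cps", "effective_pixel_rate_cps"),
    !!names[1] := q(a),
    !!names[2] := q(b)
  )
  dplyr::bind_rows(out, tibble::tibble(
    quantity = "speed_advantage_a_over_b",
    !!names[1] := speed_advantage(a, b),
    !!names[2] := NA_real_))
}
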