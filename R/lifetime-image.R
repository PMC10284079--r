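new_lifetime_image <- function(maps, converged, fitted_mask, provenance,
                               axis) {
  structure(list(maps = maps, converged = converged,
                 fitted_mask = fitted_mask, provenance = provenance,
                 axis = axis),
            class = "lifetime_image")
}

#' @export
print.lifetime_image <- function(x, ...) {
  d <- dim(x$maps$tau_m)
  nf <- sum(!is.na(x$maps$tau_m))
  cat(sprintf(
    "<lifetime_image> %dx%d pixels, %d fitted (%s model, b=%d, >=%g photons)\n",
    d[1], d[2], nf, x$provenance$model, x$provenance$b,
    x$provenance$min_photons))
  if (nf > 0)
    cat(sprintf("  tau_m: median %.3f ns  alpha1: median %.3f\n",
                stats::median(x$maps$tau_m, na.rm = TRUE),
                stats::median(x$maps$alpha1, na.rm = TRUE)))
  invisible(x)
}

#' Tidy a lifetime image into a per-pixel tibble
#'
#' One row per pixel with 0-based `row`/`col` and the fitted parameter maps;
#' unfitted pixels carry `NA`.
#'
#' @param x A `lifetime_image`.
#' @param drop_unfitted Drop sentinel pixels (default `FALSE`).
#' @param ... Unused.
#' @return A tibble with columns `row`, `col`, `tau_m`, `alpha1`, `tau1`,
#'   `tau2`, `intensity`, `chi2_reduced`, `converged`.
#' @export
tidy.lifetime_image <- function(x, drop_unfitted = FALSE, ...) {
  d <- dim(x$maps$tau_m)
  out <- tibble::tibble(
    row = rep(0:(d[1] - 1), times = d[2]),
    col = rep(0:(d[2] - 1), each = d[1]),
    tau_m = as.vector(x$maps$tau_m),
    alpha1 = as.vector(x$maps$alpha1),
    tau1 = as.vector(x$maps$tau1),
    tau2 = as.vector(x$maps$tau2),
    intensity = as.vector(x$maps$intensity),
    chi2_reduced = as.vector(x$maps$chi2_reduced),
    converged = as.vector(x$converged)
  )
  if (drop_unfitted) out <- out[!is.na(out$tau_m), ]
  out
}

#' One-row summary of a lifetime image
#'
#' @param x A `lifetime_image`.
#' @param ... Unused.
#' @return A one-row tibble: fitted pixel count and fraction, medians of
#'   `tau_m`/`alpha1`, mean intensity, median reduced chi-square.
#' @export
glance.lifetime_image <- function(x, ...) {
  tm <- x$maps$tau_m
  tibble::tibble(
    n_pixels = length(tm),
    n_fitted = sum(!is.na(tm)),
    frac_fitted = mean(!is.na(tm)),
    tau_m_median = stats::median(tm, na.rm = TRUE),
    alpha1_median = stats::median(x$maps$alpha1, na.rm = TRUE),
    intensity_mean = mean(x$maps$intensity, na.rm = TRUE),
    chi2_reduced_median = stats::median(x$maps$chi2_reduced, na.rm = TRUE)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a single-decay fit
#'
#' @param x A `flim_fit` from [fit_pixel()].
#' @param ... Unused.
#' @return Tibble of parameter estimates (term, estimate).
#' @export
tidy.flim_fit <- function(x, ...) {
  p <- x$params
  tibble::tibble(
    term = c("alpha1", "tau1", "alpha2", "tau2", "amplitude", "offset"),
    estimate = c(p$alpha1, p$tau1, p$alpha2, p$tau2, p$amplitude, p$offset)
  )
}

#' @rdname tidy.flim_fit
#' @export
glance.flim_fit <- function(x, ...) {
  tibble::tibble(tau_m = x$tau_m, chi2_reduced = x$chi2_reduced,
                 n_photons = x$n_photons, converged = x$converged,
                 model = x$model)
}

#' Export lifetime maps as multi-page 32-bit TIFF
#'
#' Pages tau_m, alpha1, tau1, tau2, intensity, chi2_reduced. Each page is
#' normalized by its maximum (TIFF float samples live in `[0, 1]`); the
#' per-page scales, page order and provenance go in the JSON sidecar
#' `<path>.json`. `NA` sentinels are written as 0.
#'
#' @param img A `lifetime_image`.
#' @param path Output TIFF path.
#' @return `path` invisibly.
#' @export
write_lifetime_tiff <- function(img, path) {
  stopifnot(inherits(img, "lifetime_image"))
  pages <- c("tau_m", "alpha1", "tau1", "tau2", "intensity", "chi2_reduced")
  scales <- vapply(pages, function(nm) {
    mx <- suppressWarnings(max(img$maps[[nm]], na.rm = TRUE))
    if (!is.finite(mx) || mx <= 0) 1 else mx
  }, numeric(1))
  li <- lapply(pages, function(nm) {
    m <- img$maps[[nm]] / scales[[nm]]
    m[is.na(m)] <- 0
    m
  })
  tiff::writeTIFF(li, path, bits.per.sample = 32, reduce = FALSE)
  side <- c(img$provenance,
            list(pages = pages, page_scales = as.list(scales),
                 n_fitted = sum(!is.na(img$maps$tau_m)),
                 bin_width_ps = img$axis$bin_width_ps))
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Plot a lifetime image map
#'
#' @param object A `lifetime_image`.
#' @param map Which map to show (default `"tau_m"`).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lifetime_image <- function(object, map = "tau_m", ...) {
  df <- tidy.lifetime_image(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data[[map]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey20") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = map,
                  title = sprintf("%s (%s model)", map,
                                  object$provenance$model))
}

#' Plot a fitted decay with its reconvolution model
#'
#' @param object A `flim_fit` with data attached.
#' @param bin_width_ps Bin width for the time axis (ps).
#' @param ... Unused.
#' @return A ggplot of counts and fitted curve on a log count scale.
#' @export
autoplot.flim_fit <- function(object, bin_width_ps = 41.1, ...) {
  if (!object$was_fitted || is.null(object$data))
    stop("fit carries no data to plot", call. = FALSE)
  t_ns <- (seq_along(object$data) - 1) * bin_width_ps / 1e3
  df <- tibble::tibble(t = t_ns, counts = object$data,
                       fitted = object$expected)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$counts), size = 0.4,
                        alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), colour = "red") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (ns)", y = "counts / bin",
                  title = sprintf("tau_m = %.3f ns", object$tau_m))
}
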