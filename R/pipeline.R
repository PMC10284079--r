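#' Linear trend test for time-course summaries
#'
#' Simple linear regression of a per-frame summary (e.g. the mean `tau_m` of
#' masked fitted pixels) against acquisition time; significance is the
#' F-test of the regression with `(1, n - 2)` degrees of freedom, which for
#' simple regression equals the squared t-statistic of the slope.
#'
#' @param values Per-frame summary values.
#' @param times Frame times (same length, non-constant).
#' @param summary_used Label recording which summary the values are
#'   (default `"mean"`).
#' @return A `trend_result` with `slope`, `F_statistic`, `p_value`,
#'   `n_frames`, `summary_used`.
#' @export
linear_trend_test <- function(values, times, summary_used = "mean") {
  if (length(values) != length(times))
    stop("`values` and `times` must have equal length", call. = FALSE)
  keep <- is.finite(values) & is.finite(times)
  values <- values[keep]; times <- times[keep]
  n <- length(values)
  if (n < 3) stop("need at least 3 frames for a trend test", call. = FALSE)
  if (stats::var(times) == 0)
    stop("`times` must not be constant", call. = FALSE)
  fit <- stats::lm(values ~ times)
  slope <- unname(stats::coef(fit)[2])
  ssr <- sum((stats::fitted(fit) - mean(values))^2)
  sse <- sum(stats::residuals(fit)^2)
  if (sse <= .Machine$double.eps * max(sum(values^2), 1)) {
    # residual variance numerically zero
    if (abs(ssr) <= .Machine$double.eps * max(sum(values^2), 1)) {
      f <- 0; p <- 1 # constant response
    } else {
      f <- Inf; p <- 0 # exact non-constant line
    }
  } else {
    f <- ssr / (sse / (n - 2))
    p <- stats::pf(f, 1, n - 2, lower.tail = FALSE)
  }
  structure(list(slope = slope, F_statistic = f, p_value = p,
                 n_frames = n, summary_used = summary_used),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf(
    "<trend_result> slope %.4g per unit time, F = %.4g, p = %.4g (%d frames, %s)\n",
    x$slope, x$F_statistic, x$p_value, x$n_frames, x$summary_used))
  invisible(x)
}

#' @rdname linear_trend_test
#' @param x A `trend_result`.
#' @param ... Unused.
#' @export
glance.trend_result <- function(x, ...) {
  tibble::tibble(slope = x$slope, F_statistic = x$F_statistic,
                 p_value = x$p_value, n_frames = x$n_frames,
                 summary_used = x$summary_used)
}

#' Pipeline configuration
#'
#' Configuration for [run_pipeline()]. Either supply `histogram_files`
#' (HDF5 decay histograms of successive frames) or a `sim` block describing
#' a synthetic acquisition to generate.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Master seed; stage sub-seeds are derived from it.
#' @param model,b,min_photons,weights Fitting options, see [fit_image()].
#' @param K CMOS/SPAD grid ratio for fusion and masks.
#' @param mask_threshold Intensity threshold for the cell mask channel.
#' @param sim Named list passed to the simulator: `rows`, `cols`, `n_cells`,
#'   `photons_per_pixel`, `n_frames`, `frame_interval_min`, plus any
#'   [sim_config()] override.
#' @param histogram_files Optional character vector of existing frame files.
#' @param calibration_file Optional existing calibration bundle (HDF5 path
#'   from [write_calibration()]).
#' @return A `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1, model = "bi", b = 1,
                            min_photons = 500, weights = "poisson", K = 2,
                            mask_threshold = 100,
                            sim = list(rows = 48, cols = 48, n_cells = 4,
                                       photons_per_pixel = 3000,
                                       n_frames = 5, frame_interval_min = 3),
                            histogram_files = NULL,
                            calibration_file = NULL) {
  structure(list(out_dir = out_dir, seed = seed, model = model, b = b,
                 min_photons = min_photons, weights = weights, K = K,
                 mask_threshold = mask_threshold, sim = sim,
                 histogram_files = histogram_files,
                 calibration_file = calibration_file),
            class = "pipeline_config")
}

#' Run the end-to-end processing pipeline
#'
#' Orchestrates simulate (optional) -> calibrate -> skew-correct/bin/fit ->
#' fuse -> per-cell stats -> time-course trend test, writing all artifacts
#' and a run manifest under `cfg$out_dir`. Given the same inputs and seed
#' the outputs are identical.
#'
#' @param cfg A `pipeline_config`.
#' @return Invisibly, a list with `frames` (lifetime images), `calibration`,
#'   `cell_stats` tibble, `trends` tibble and `manifest` path.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!dir.exists(cfg$out_dir)) dir.create(cfg$out_dir, recursive = TRUE)
  stages <- character()
  t_start <- Sys.time()
  if (!is.null(cfg$calibration_file) && !file.exists(cfg$calibration_file))
    stop("calibration file not found: ", cfg$calibration_file, call. = FALSE)
  if (!is.null(cfg$histogram_files)) {
    miss <- cfg$histogram_files[!file.exists(cfg$histogram_files)]
    if (length(miss) > 0)
      stop("histogram file not found: ", miss[1], call. = FALSE)
  }
  set.seed(cfg$seed)

  # -- acquire -------------------------------------------------------------
  nadh_img <- NULL; mch_img <- NULL; times_min <- NULL
  if (is.null(cfg$histogram_files)) {
    s <- cfg$sim
    scfg_args <- s[setdiff(names(s), c("n_cells", "photons_per_pixel",
                                       "n_frames", "frame_interval_min",
                                       "radius_range"))]
    scfg <- do.call(sim_config, scfg_args)
    truth <- make_cell_phantom(
      rows = scfg$rows, cols = scfg$cols,
      n_cells = s$n_cells %||% 4,
      photons_per_pixel = s$photons_per_pixel %||% 3000,
      radius_range = s$radius_range %||% c(4, 9),
      seed = cfg$seed + 1)
    tc <- timecourse_config(n_frames = s$n_frames %||% 5,
                            frame_interval_min = s$frame_interval_min %||% 3)
    sim <- simulate_timecourse(truth, tc, scfg, seed = cfg$seed + 2)
    frames_hist <- sim$frames
    times_min <- sim$times_min
    irf_acq <- simulate_irf_acquisition(scfg, sensor = sim$sensor)
    nadh_img <- simulate_cmos_image(truth, K = cfg$K, seed = cfg$seed + 3)
    mch_img <- simulate_cmos_image(truth, K = cfg$K, channel = "mcherry",
                                   seed = cfg$seed + 4)
    write_intensity_tiff(nadh_img, file.path(cfg$out_dir, "cmos_nadh.tif"))
    write_intensity_tiff(mch_img, file.path(cfg$out_dir, "cmos_mcherry.tif"))
    stages <- c(stages, "simulate")
  } else {
    frames_hist <- lapply(cfg$histogram_files, read_decay_histogram)
    times_min <- seq_along(frames_hist) - 1
  }

  # -- calibrate -----------------------------------------------------------
  calib <- if (!is.null(cfg$calibration_file)) {
    read_calibration(cfg$calibration_file)
  } else if (is.null(cfg$histogram_files)) {
    calibrate_sensor(frames_hist[[1]], irf_hist = irf_acq$hist)
  } else {
    calibrate_sensor(frames_hist[[1]])
  }
  write_calibration(calib, file.path(cfg$out_dir, "calibration.h5"))
  stages <- c(stages, "calibrate")

  # -- fit -----------------------------------------------------------------
  frames <- vector("list", length(frames_hist))
  for (i in seq_along(frames_hist)) {
    frames[[i]] <- fit_image(frames_hist[[i]], calib, model = cfg$model,
                             b = cfg$b, min_photons = cfg$min_photons,
                             weights = cfg$weights)
    write_lifetime_tiff(frames[[i]],
                        file.path(cfg$out_dir,
                                  sprintf("lifetime_frame%02d.tif", i - 1)))
  }
  stages <- c(stages, "fit")

  # -- fuse + stats --------------------------------------------------------
  cell_stats <- NULL
  mask_c <- NULL
  if (!is.null(mch_img)) {
    fused <- upscale_lifetime(frames[[1]], nadh_img)
    fused_tau <- fused$maps$tau_m
    fused_tau[is.na(fused_tau)] <- 0
    tiff::writeTIFF(fused_tau / max(fused_tau, 1e-12),
                    file.path(cfg$out_dir, "fused_tau_m.tif"),
                    bits.per.sample = 32)
    mask_f <- threshold_mask(mch_img, cfg$mask_threshold)
    mask_c <- mask_to_spad_grid(mask_f, cfg$K)
    write_mask_tiff(mask_c, file.path(cfg$out_dir, "cell_mask.tif"))
    cell_stats <- purrr::map_dfr(seq_along(frames), function(i) {
      dplyr::mutate(masked_stats(frames[[i]], mask_c),
                    frame = i - 1L, time_min = times_min[i],
                    .before = 1)
    })
    utils::write.csv(cell_stats, file.path(cfg$out_dir, "cell_stats.csv"),
                     row.names = FALSE)
    stages <- c(stages, "fuse", "stats")
  }

  # -- trend ---------------------------------------------------------------
  trends <- NULL
  if (length(frames) >= 3) {
    sel_mask <- if (!is.null(mask_c)) mask_c$mask else NULL
    summarize_frame <- function(img, map) {
      m <- img$maps[[map]]
      if (!is.null(sel_mask)) m <- m[sel_mask]
      mean(m, na.rm = TRUE)
    }
    trends <- purrr::map_dfr(
      c("tau_m", "alpha1", "intensity"),
      function(map) {
        v <- vapply(frames, summarize_frame, numeric(1), map = map)
        tr <- linear_trend_test(v, times_min)
        dplyr::mutate(glance(tr), response = map, .before = 1)
      })
    utils::write.csv(trends, file.path(cfg$out_dir, "trend.csv"),
                     row.names = FALSE)
    stages <- c(stages, "trend")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("spadflim")),
    seed = cfg$seed,
    model = cfg$model, b = cfg$b, min_photons = cfg$min_photons,
    weights = cfg$weights, K = cfg$K,
    n_frames = length(frames),
    stages = stages,
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  manifest_path <- file.path(cfg$out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(list(frames = frames, calibration = calib,
                 cell_stats = cell_stats, trends = trends,
                 manifest = manifest_path))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot a time-course trend
#'
#' @param values Per-frame summary values.
#' @param times Frame times.
#' @param response Axis label.
#' @return A ggplot with the fitted regression line.
#' @export
plot_trend <- function(values, times, response = "summary") {
  df <- tibble::tibble(time = times, value = values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "red") +
    ggplot2::labs(x = "time (min)", y = response)
}
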