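#' Intensity images on the fine (CMOS) grid
#'
#' The light-sheet system pairs the SPAD array with a higher-resolution CMOS
#' intensity camera imaging the same field of view; by default the CMOS grid
#' is 2x finer per axis (4x the pixel count).
#'
#' @param values Non-negative numeric matrix.
#' @param channel One of `"nadh-intensity"`, `"mcherry"`, `"brightfield"`.
#' @return An `intensity_image`.
#' @export
intensity_image <- function(values,
                            channel = c("nadh-intensity", "mcherry",
                                        "brightfield")) {
  channel <- match.arg(channel)
  if (!is.matrix(values) || any(values < 0, na.rm = TRUE))
    stop("`values` must be a non-negative matrix", call. = FALSE)
  structure(list(values = values, channel = channel),
            class = "intensity_image")
}

#' @export
print.intensity_image <- function(x, ...) {
  cat(sprintf("<intensity_image> %dx%d (%s)\n", nrow(x$values),
              ncol(x$values), x$channel))
  invisible(x)
}

#' Write / read an intensity image as TIFF
#'
#' Values are stored as 32-bit float normalized by their maximum; the scale
#' and channel go in a JSON sidecar so the round trip restores photon units.
#'
#' @param img An `intensity_image`.
#' @param path TIFF path; sidecar is `<path>.json`.
#' @return `path` invisibly (write); an `intensity_image` (read).
#' @export
write_intensity_tiff <- function(img, path) {
  stopifnot(inherits(img, "intensity_image"))
  s <- max(img$values, 1e-12)
  tiff::writeTIFF(img$values / s, path, bits.per.sample = 32)
  jsonlite::write_json(list(scale = s, channel = img$channel),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_intensity_tiff
#' @export
read_intensity_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  v <- tiff::readTIFF(path)
  if (length(dim(v)) == 3) v <- v[, , 1]
  intensity_image(v * side$scale, channel = side$channel)
}

upscale_factor <- function(fine_dim, coarse_dim) {
  K <- fine_dim / coarse_dim
  if (any(K != round(K)) || length(unique(K)) != 1)
    stop("intensity grid must be the same integer multiple of the SPAD grid ",
         "on both axes", call. = FALSE)
  as.integer(K[1])
}

bilinear_upscale <- function(m, K) {
  if (K == 1) return(m)
  EBImage::resize(m, w = nrow(m) * K, h = ncol(m) * K, filter = "bilinear")
}

#' Fuse a lifetime image with the fine-grid intensity image
#'
#' Interpolates each lifetime parameter map bilinearly to the CMOS grid and
#' supplies a display weight map (the intensity normalized to `[0, 1]`). The
#' weighting is for display compositing only — lifetime values themselves are
#' never altered by intensity; brightness is modulated, not tau.
#'
#' @param img A `lifetime_image`.
#' @param intensity An `intensity_image` whose grid is an integer multiple
#'   of the SPAD grid.
#' @return A list with `maps` (upscaled parameter matrices), `weight`
#'   (normalized intensity), and `K`.
#' @export
upscale_lifetime <- function(img, intensity) {
  stopifnot(inherits(img, "lifetime_image"),
            inherits(intensity, "intensity_image"))
  K <- upscale_factor(dim(intensity$values), dim(img$maps$tau_m))
  maps <- lapply(img$maps, bilinear_upscale, K = K)
  mx <- max(intensity$values, na.rm = TRUE)
  weight <- if (mx > 0) intensity$values / mx else intensity$values
  list(maps = maps, weight = weight, K = K)
}

# 8-connected component labeling (column-major seed order), BFS flood fill
label_components_8 <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  offs <- cbind(dr = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dc = c(-1, 0, 1, -1, 1, -1, 0, 1))
  seeds <- which(mask)
  for (s in seeds) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    stack <- s
    lab[s] <- nxt
    while (length(stack) > 0) {
      cur <- stack[length(stack)]
      stack <- stack[-length(stack)]
      r <- ((cur - 1L) %% nr) + 1L
      cl <- ((cur - 1L) %/% nr) + 1L
      rr <- r + offs[, 1]; cc <- cl + offs[, 2]
      keep <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
      nb <- (cc[keep] - 1L) * nr + rr[keep]
      nb <- nb[mask[nb] & lab[nb] == 0L]
      if (length(nb) > 0) {
        lab[nb] <- nxt
        stack <- c(stack, nb)
      }
    }
  }
  lab
}

#' Threshold an intensity image into a labeled cell mask
#'
#' Binary threshold (strictly above), 8-connected component labeling, and
#' removal of components below `min_size` pixels; surviving labels are
#' renumbered contiguously from 1.
#'
#' @param intensity An `intensity_image` (typically the mCherry channel).
#' @param threshold Intensity threshold (same units as the image).
#' @param min_size Minimum component size in pixels (default 4).
#' @return A `cell_mask`: list with logical `mask` and integer `labels`.
#' @export
threshold_mask <- function(intensity, threshold, min_size = 4) {
  stopifnot(inherits(intensity, "intensity_image"))
  if (threshold < 0) stop("`threshold` must be non-negative", call. = FALSE)
  m <- intensity$values > threshold
  m[is.na(m)] <- FALSE
  lab <- label_components_8(m)
  if (max(lab) > 0) {
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    keep <- which(sizes >= min_size)
    relab <- integer(max(lab))
    relab[keep] <- seq_along(keep)
    lab[lab > 0] <- relab[lab[lab > 0]]
  }
  structure(list(mask = lab > 0, labels = lab), class = "cell_mask")
}

#' @export
print.cell_mask <- function(x, ...) {
  cat(sprintf("<cell_mask> %dx%d, %d components, %d masked pixels\n",
              nrow(x$labels), ncol(x$labels), max(x$labels), sum(x$mask)))
  invisible(x)
}

#' Downsample a fine-grid cell mask to the SPAD grid
#'
#' A SPAD pixel is masked when at least `frac` of its `K x K` fine sub-pixels
#' are masked (the boundary case counts as masked); its label is the majority
#' label among its masked sub-pixels, ties toward the smallest label.
#'
#' @param mask A `cell_mask` on the fine grid.
#' @param K Integer upscale factor between the grids.
#' @param frac Masked sub-pixel fraction required (default 0.5).
#' @return A `cell_mask` on the coarse grid.
#' @export
mask_to_spad_grid <- function(mask, K, frac = 0.5) {
  stopifnot(inherits(mask, "cell_mask"))
  K <- as.integer(K)
  nr <- nrow(mask$labels); nc <- ncol(mask$labels)
  if (nr %% K != 0 || nc %% K != 0)
    stop("fine grid is not a K multiple of a coarse grid", call. = FALSE)
  cr <- nr %/% K; cc <- nc %/% K
  # per-block masked fraction via dimension folding
  a <- array(mask$mask, dim = c(K, cr, K, cc))
  fracs <- apply(a, c(2, 4), sum) / K^2
  coarse_mask <- fracs >= frac
  lab <- matrix(0L, cr, cc)
  for (i in which(coarse_mask)) {
    r <- ((i - 1L) %% cr) + 1L
    cl <- ((i - 1L) %/% cr) + 1L
    block <- mask$labels[((r - 1L) * K + 1L):(r * K),
                         ((cl - 1L) * K + 1L):(cl * K)]
    block <- block[block > 0]
    tab <- tabulate(block)
    lab[i] <- which.max(tab) # ties -> smallest label
  }
  structure(list(mask = coarse_mask, labels = lab), class = "cell_mask")
}

#' Write a labeled mask as 16-bit TIFF
#'
#' @param mask A `cell_mask`.
#' @param path TIFF path.
#' @return `path` invisibly.
#' @export
write_mask_tiff <- function(mask, path) {
  stopifnot(inherits(mask, "cell_mask"))
  tiff::writeTIFF(mask$labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Per-cell statistics of a masked lifetime image
#'
#' Statistics are computed over fitted (non-sentinel) pixels only; labels
#' whose pixels are all unfitted are reported with `n_pixels = 0` and `NA`
#' statistics. Centroids are 0-based pixel coordinates over the label's
#' masked pixels.
#'
#' @param img A `lifetime_image`.
#' @param mask A `cell_mask` on the same (SPAD) grid.
#' @return A tibble with columns `label`, `n_pixels`, `tau_m_mean`,
#'   `tau_m_median`, `alpha1_mean`, `intensity_mean`, `centroid_row`,
#'   `centroid_col`.
#' @export
masked_stats <- function(img, mask) {
  stopifnot(inherits(img, "lifetime_image"), inherits(mask, "cell_mask"))
  if (!identical(dim(mask$labels), dim(img$maps$tau_m)))
    stop("mask and lifetime image grids differ", call. = FALSE)
  n_lab <- max(mask$labels)
  rows0 <- row(mask$labels) - 1
  cols0 <- col(mask$labels) - 1
  purrr::map_dfr(seq_len(n_lab), function(l) {
    sel <- mask$labels == l
    fitted <- sel & !is.na(img$maps$tau_m)
    if (!any(fitted)) {
      return(tibble::tibble(label = l, n_pixels = 0L, tau_m_mean = NA_real_,
                            tau_m_median = NA_real_, alpha1_mean = NA_real_,
                            intensity_mean = NA_real_,
                            centroid_row = mean(rows0[sel]),
                            centroid_col = mean(cols0[sel])))
    }
    tibble::tibble(
      label = l,
      n_pixels = sum(fitted),
      tau_m_mean = mean(img$maps$tau_m[fitted]),
      tau_m_median = stats::median(img$maps$tau_m[fitted]),
      alpha1_mean = mean(img$maps$alpha1[fitted]),
      intensity_mean = mean(img$maps$intensity[fitted]),
      centroid_row = mean(rows0[sel]),
      centroid_col = mean(cols0[sel])
    )
  })
}
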