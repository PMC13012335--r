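# Per-pixel lifetime estimation on wide-field FLIM cubes and the
# image-level summaries (lifetime histograms, intensity-weighted renders).

#' Wide-field FLIM cube
#'
#' A 3-D photon-count array (`rows x cols x time bins`) with its time axis
#' and a per-pixel validity mask. Masked (invalid) pixels — e.g. a sensor's
#' defective region — never contribute to fits or summaries.
#'
#' @param counts Non-negative integer array, `rows x cols x n_bins`.
#' @param axis A `time_axis` with `n_bins == dim(counts)[3]`.
#' @param valid_mask Logical `rows x cols` matrix; default all valid.
#' @return An object of class `flim_cube`.
#' @export
flim_cube <- function(counts, axis, valid_mask = NULL) {
  stopifnot(is.array(counts), length(dim(counts)) == 3,
            inherits(axis, "time_axis"))
  if (dim(counts)[3] != axis$n_bins) {
    stop("flim_cube: third dimension must equal axis$n_bins")
  }
  if (any(counts < 0)) stop("flim_cube: counts must be non-negative")
  nr <- dim(counts)[1]; nc <- dim(counts)[2]
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nr, nc)
  stopifnot(is.logical(valid_mask), all(dim(valid_mask) == c(nr, nc)))
  structure(list(counts = counts, axis = axis, valid_mask = valid_mask),
            class = "flim_cube")
}

#' @export
print.flim_cube <- function(x, ...) {
  d <- dim(x$counts)
  cat(sprintf("<flim_cube> %d x %d pixels x %d bins (%.3g ns/bin), %d invalid px\n",
              d[1], d[2], d[3], x$axis$bin_width, sum(!x$valid_mask)))
  invisible(x)
}

#' Per-pixel lifetime fitting of a FLIM cube
#'
#' Fits every valid pixel's decay independently — by default a tail fit
#' between 90% and 20% of that pixel's own peak, matching per-pixel
#' wide-field processing; reconvolution mode is available when an IRF is
#' supplied. Pixels that are masked, have fewer than `min_photons` total
#' counts, or whose fit fails are left undefined (`NA`).
#'
#' @param cube A `flim_cube`.
#' @param mode `"tail"` (default) or `"reconvolution"`.
#' @param min_photons Minimum total counts for a pixel to be fitted
#'   (default 100).
#' @param irf `instrument_response`, required for reconvolution mode.
#' @param ... Passed to [fit_tail()] or [fit_reconvolution()].
#' @return A `lifetime_image`: list of matrices `tau_map` (ns), `intensity_map`
#'   (total counts) and `chi2_map`.
#' @export
fit_cube <- function(cube, mode = c("tail", "reconvolution"),
                     min_photons = 100, irf = NULL, ...) {
  stopifnot(inherits(cube, "flim_cube"))
  mode <- match.arg(mode)
  if (mode == "reconvolution" && is.null(irf)) {
    stop("fit_cube: reconvolution mode requires an IRF")
  }
  nr <- dim(cube$counts)[1]; nc <- dim(cube$counts)[2]
  tau_map <- matrix(NA_real_, nr, nc)
  chi2_map <- matrix(NA_real_, nr, nc)
  intensity_map <- apply(cube$counts, c(1, 2), sum)
  fit_one <- function(counts) {
    d <- decay_histogram(counts, cube$axis)
    if (mode == "tail") fit_tail(d, ...) else fit_reconvolution(d, irf, ...)
  }
  n_defined <- 0L
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!cube$valid_mask[i, j] || intensity_map[i, j] < min_photons) next
      fit <- tryCatch(fit_one(cube$counts[i, j, ]), error = function(e) NULL)
      if (!is.null(fit) && isTRUE(fit$converged) && is.finite(fit$tau)) {
        tau_map[i, j] <- fit$tau
        chi2_map[i, j] <- fit$chi2_reduced
        n_defined <- n_defined + 1L
      }
    }
  }
  if (n_defined == 0L) {
    warning("fit_cube: no pixel produced a defined lifetime")
  }
  structure(list(tau_map = tau_map, intensity_map = intensity_map,
                 chi2_map = chi2_map),
            class = "lifetime_image")
}

#' @export
print.lifetime_image <- function(x, ...) {
  ok <- is.finite(x$tau_map)
  cat(sprintf("<lifetime_image> %d x %d px, %d defined; tau %.3g-%.3g ns\n",
              nrow(x$tau_map), ncol(x$tau_map), sum(ok),
              if (any(ok)) min(x$tau_map[ok]) else NA,
              if (any(ok)) max(x$tau_map[ok]) else NA))
  invisible(x)
}

#' Lifetime histogram of a fitted image
#'
#' Mean, standard deviation and a binned histogram of per-pixel lifetimes
#' over defined pixels, optionally weighting each pixel by its intensity
#' (total counts). Unweighted statistics use the sample SD; weighted
#' statistics use the intensity-weighted mean and the weighted population
#' SD.
#'
#' @param image A `lifetime_image`.
#' @param weights `"none"` (default) or `"intensity"`.
#' @param bin_width Histogram bin width in ns (default 0.05).
#' @return List with `mean`, `sd`, `n` and a data.frame `histogram`
#'   (`tau_mid`, `weight`).
#' @export
lifetime_histogram <- function(image, weights = c("none", "intensity"),
                               bin_width = 0.05) {
  stopifnot(inherits(image, "lifetime_image"), bin_width > 0)
  weights <- match.arg(weights)
  ok <- is.finite(image$tau_map)
  if (!any(ok)) stop("lifetime_histogram: no defined pixels")
  tau <- image$tau_map[ok]
  if (weights == "none") {
    m <- mean(tau)
    s <- if (length(tau) > 1) stats::sd(tau) else 0
    w <- rep(1, length(tau))
  } else {
    w <- image$intensity_map[ok]
    if (sum(w) <= 0) stop("lifetime_histogram: zero total intensity")
    m <- sum(w * tau) / sum(w)
    s <- sqrt(sum(w * (tau - m)^2) / sum(w))
  }
  breaks <- seq(floor(min(tau) / bin_width) * bin_width,
                ceiling(max(tau) / bin_width + 1e-12) * bin_width + bin_width,
                by = bin_width)
  bin <- findInterval(tau, breaks, rightmost.closed = TRUE)
  hist <- data.frame(
    tau_mid = breaks[seq_len(length(breaks) - 1)] + bin_width / 2,
    weight = as.numeric(tapply(w, factor(bin, levels = seq_len(length(breaks) - 1)),
                               sum, default = 0))
  )
  list(mean = m, sd = s, n = length(tau), histogram = hist)
}

#' Render a lifetime image with intensity-scaled brightness
#'
#' Standard FLIM display: pixel hue encodes the lifetime over `tau_range`
#' (blue = short through red = long) and pixel brightness encodes intensity,
#' normalized to the 99th percentile of the intensity map (so the render is
#' invariant to an overall intensity scale). Undefined pixels are black.
#'
#' @param image A `lifetime_image`.
#' @param tau_range `c(min, max)` lifetime range in ns for the hue scale.
#' @return A `rows x cols x 3` RGB array in [0, 1].
#' @export
render_intensity_weighted <- function(image, tau_range) {
  stopifnot(inherits(image, "lifetime_image"),
            length(tau_range) == 2)
  if (!(tau_range[1] < tau_range[2])) {
    stop("render_intensity_weighted: tau_range must satisfy min < max")
  }
  frac <- (image$tau_map - tau_range[1]) / diff(tau_range)
  frac[!is.finite(frac)] <- 0
  frac <- pmin(pmax(frac, 0), 1)
  p99 <- stats::quantile(image$intensity_map, 0.99, names = FALSE)
  bright <- if (p99 > 0) pmin(image$intensity_map / p99, 1) else
    matrix(0, nrow(image$intensity_map), ncol(image$intensity_map))
  bright[!is.finite(image$tau_map)] <- 0
  # hue 2/3 (blue) for short lifetimes down to 0 (red) for long
  hue <- (1 - frac) * (2 / 3)
  cols <- grDevices::hsv(h = as.vector(hue), s = 1, v = as.vector(bright))
  rgb <- grDevices::col2rgb(cols) / 255
  out <- array(0, dim = c(nrow(image$tau_map), ncol(image$tau_map), 3))
  out[, , 1] <- matrix(rgb[1, ], nrow(image$tau_map))
  out[, , 2] <- matrix(rgb[2, ], nrow(image$tau_map))
  out[, , 3] <- matrix(rgb[3, ], nrow(image$tau_map))
  out
}
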