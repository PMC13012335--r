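# Bar-target contrast measurement on intensity images (fluorescent
# USAF-style resolution readout).

#' Extract a line profile from an intensity image
#'
#' Samples the image along the straight line from `line_start` to
#' `line_end` (row, col coordinates, 1-based) at unit-pixel spacing,
#' averaging `width_px` parallel samples taken perpendicular to the line at
#' each position. Off-grid positions are read by bilinear interpolation.
#'
#' @param intensity_map Numeric matrix of pixel intensities.
#' @param line_start,line_end Numeric `c(row, col)` endpoints, inside the
#'   image.
#' @param width_px Number of parallel samples to average (>= 1).
#' @param bar_period_px Optional known bar period in pixels, attached to
#'   the profile for [bar_contrast()].
#' @return A `bar_profile`: list with `values`, `positions` (px along the
#'   line) and `bar_period_px`.
#' @export
extract_profile <- function(intensity_map, line_start, line_end,
                            width_px = 1, bar_period_px = NULL) {
  stopifnot(is.matrix(intensity_map), length(line_start) == 2,
            length(line_end) == 2, width_px >= 1)
  nr <- nrow(intensity_map); nc <- ncol(intensity_map)
  inside <- function(p) p[1] >= 1 && p[1] <= nr && p[2] >= 1 && p[2] <= nc
  if (!inside(line_start) || !inside(line_end)) {
    stop("extract_profile: line endpoints must lie inside the image")
  }
  d <- c(line_end[1] - line_start[1], line_end[2] - line_start[2])
  len <- sqrt(sum(d^2))
  if (len == 0) stop("extract_profile: degenerate line")
  u <- d / len                     # along-line unit vector
  v <- c(-u[2], u[1])              # perpendicular
  n_steps <- floor(len) + 1
  offsets <- seq_len(width_px) - (width_px + 1) / 2
  bilinear <- function(r, cc) {
    r <- min(max(r, 1), nr); cc <- min(max(cc, 1), nc)
    r0 <- floor(r); c0 <- floor(cc)
    r1 <- min(r0 + 1, nr); c1 <- min(c0 + 1, nc)
    fr <- r - r0; fc <- cc - c0
    (1 - fr) * (1 - fc) * intensity_map[r0, c0] +
      (1 - fr) * fc * intensity_map[r0, c1] +
      fr * (1 - fc) * intensity_map[r1, c0] +
      fr * fc * intensity_map[r1, c1]
  }
  pos <- seq(0, by = 1, length.out = n_steps)
  values <- vapply(pos, function(s) {
    pt <- c(line_start[1] + s * u[1], line_start[2] + s * u[2])
    mean(vapply(offsets, function(o) {
      bilinear(pt[1] + o * v[1], pt[2] + o * v[2])
    }, numeric(1)))
  }, numeric(1))
  structure(list(values = values, positions = pos,
                 bar_period_px = bar_period_px),
            class = "bar_profile")
}

#' Michelson contrast of a bar-target profile
#'
#' The conventional USAF bar readout: the profile is partitioned into
#' half-period windows using the known bar period; the bright-bar level is
#' the mean of per-window maxima over bright windows and the dark-bar level
#' the mean of per-window minima over dark windows, and the contrast is
#' `100 * (I_max - I_min) / (I_max + I_min)` percent. Invariant under any
#' positive scaling of the profile, and in [0, 100] for non-negative
#' profiles.
#'
#' @param profile A `bar_profile` (or numeric vector).
#' @param bar_period_px Full bar period in pixels; taken from the profile
#'   if attached.
#' @return Contrast in percent.
#' @export
bar_contrast <- function(profile, bar_period_px = NULL) {
  if (inherits(profile, "bar_profile")) {
    if (is.null(bar_period_px)) bar_period_px <- profile$bar_period_px
    values <- profile$values
  } else {
    values <- as.numeric(profile)
  }
  if (is.null(bar_period_px)) stop("bar_contrast: bar_period_px is required")
  if (any(values < 0)) stop("bar_contrast: profile must be non-negative")
  half <- bar_period_px / 2
  if (length(values) < bar_period_px) {
    stop("bar_contrast: profile shorter than one full bar pair")
  }
  # half-period windows; classify each as bright or dark by its mean level
  n_win <- floor(length(values) / half)
  win_stats <- t(vapply(seq_len(n_win), function(w) {
    idx <- (floor((w - 1) * half) + 1):min(floor(w * half), length(values))
    c(mean(values[idx]), max(values[idx]), min(values[idx]))
  }, numeric(3)))
  med <- stats::median(win_stats[, 1])
  bright <- win_stats[, 1] >= med
  if (all(bright) || !any(bright)) {
    # flat profile: no modulation
    i_max <- max(values); i_min <- min(values)
  } else {
    i_max <- mean(win_stats[bright, 2])
    i_min <- mean(win_stats[!bright, 3])
  }
  if (i_max + i_min == 0) stop("bar_contrast: zero total intensity")
  100 * (i_max - i_min) / (i_max + i_min)
}
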