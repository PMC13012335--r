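#' Time axis for TCSPC histograms
#'
#' Defines the binning of a time-correlated single-photon counting (TCSPC)
#' measurement: the bin width, the number of bins and the excitation
#' repetition period. All times are in nanoseconds. Bin *centers* are used
#' throughout: bin `i` (0-based) is centered at `(i + 0.5) * bin_width`.
#'
#' @param bin_width Width of one time bin in ns (e.g. 0.37 for the
#'   micro-camera, ~0.0122 for a bench TDC).
#' @param n_bins Number of time bins (>= 4).
#' @param period Repetition period in ns (50 ns for 20 MHz excitation).
#'   Must satisfy `n_bins * bin_width <= period` (within rounding).
#' @return An object of class `time_axis` with fields `bin_width`, `n_bins`,
#'   `period`.
#' @examples
#' ax <- time_axis(bin_width = 0.37, n_bins = 50, period = 50)
#' head(bin_centers(ax))
#' @export
time_axis <- function(bin_width, n_bins, period) {
  stopifnot(is.numeric(bin_width), length(bin_width) == 1L, bin_width > 0,
            is.numeric(n_bins), length(n_bins) == 1L,
            is.numeric(period), length(period) == 1L, period > 0)
  n_bins <- as.integer(n_bins)
  if (n_bins < 4L) stop("time_axis: n_bins must be >= 4")
  if (n_bins * bin_width > period * (1 + 1e-9)) {
    stop("time_axis: n_bins * bin_width exceeds the repetition period")
  }
  structure(list(bin_width = bin_width, n_bins = n_bins, period = period),
            class = "time_axis")
}

#' @rdname time_axis
#' @param axis A `time_axis`.
#' @export
bin_centers <- function(axis) {
  stopifnot(inherits(axis, "time_axis"))
  (seq_len(axis$n_bins) - 0.5) * axis$bin_width
}

#' Default bench and micro-camera time axes
#'
#' The bench TCSPC system runs at 20 MHz (50 ns period); its histograms are
#' binned to 1024 channels (~48.8 ps), the resolution at which a 1 s,
#' 1e5-photon acquisition still puts enough counts in each fitted channel
#' for stable Poisson-weighted fitting. The wide-field SPAD micro-camera
#' histograms photons into 50 bins of 370 ps at the same repetition rate.
#'
#' @return A `time_axis`.
#' @export
bench_axis <- function() time_axis(bin_width = 50 / 1024, n_bins = 1024, period = 50)

#' @rdname bench_axis
#' @export
camera_axis <- function() time_axis(bin_width = 0.37, n_bins = 50, period = 50)

same_axis <- function(a, b, tol = 1e-9) {
  inherits(a, "time_axis") && inherits(b, "time_axis") &&
    a$n_bins == b$n_bins &&
    abs(a$bin_width - b$bin_width) <= tol * a$bin_width &&
    abs(a$period - b$period) <= tol * a$period
}

#' @export
print.time_axis <- function(x, ...) {
  cat(sprintf("<time_axis> %d bins x %.4g ns (span %.4g ns), period %.4g ns\n",
              x$n_bins, x$bin_width, x$n_bins * x$bin_width, x$period))
  invisible(x)
}

#' TCSPC decay histogram
#'
#' A histogram of detected photon arrival times relative to the excitation
#' pulse, together with acquisition metadata.
#'
#' @param counts Non-negative photon counts, one per bin. Measured and
#'   simulated histograms are integers; real-valued expectations are also
#'   accepted so noise-free model curves can be fitted directly.
#' @param axis The `time_axis` the counts were histogrammed on.
#' @param acquisition_time Acquisition time in seconds (default 1, the bulk
#'   protocol).
#' @param excitation_power Optional excitation power in mW (used for the
#'   relative-intensity proxy).
#' @return An object of class `decay_histogram`.
#' @export
decay_histogram <- function(counts, axis, acquisition_time = 1,
                            excitation_power = NULL) {
  stopifnot(inherits(axis, "time_axis"), is.numeric(counts))
  if (length(counts) != axis$n_bins) {
    stop("decay_histogram: length(counts) must equal axis$n_bins")
  }
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("decay_histogram: counts must be finite and non-negative")
  }
  structure(list(counts = as.numeric(counts), axis = axis,
                 acquisition_time = acquisition_time,
                 excitation_power = excitation_power),
            class = "decay_histogram")
}

#' @export
print.decay_histogram <- function(x, ...) {
  cat(sprintf("<decay_histogram> %d bins, %s photons, %.3g s acquisition\n",
              x$axis$n_bins, format(sum(x$counts), big.mark = ","),
              x$acquisition_time))
  invisible(x)
}

#' Instrument response function (IRF)
#'
#' The system's measured temporal response to the excitation pulse itself
#' (e.g. laser light scattered off a frosted slide). Weights are normalized
#' to sum to 1 and must share the bin grid of any decay they are used to
#' reconvolve.
#'
#' @param weights Non-negative response per bin; normalized internally.
#' @param axis The `time_axis` (same grid as the associated decay).
#' @return An object of class `instrument_response`.
#' @export
instrument_response <- function(weights, axis) {
  stopifnot(inherits(axis, "time_axis"), is.numeric(weights))
  if (length(weights) != axis$n_bins) {
    stop("instrument_response: length(weights) must equal axis$n_bins")
  }
  if (any(weights < 0)) stop("instrument_response: weights must be non-negative")
  s <- sum(weights)
  if (s <= 0) stop("instrument_response: weights must have positive mass")
  structure(list(weights = weights / s, axis = axis),
            class = "instrument_response")
}

#' A delta-function IRF (unit mass in one bin)
#'
#' Convenience constructor for an idealized instantaneous response, useful
#' when the excitation pulse is much shorter than a bin.
#'
#' @param axis A `time_axis`.
#' @param bin 1-based bin index carrying the unit mass (default 1).
#' @return An `instrument_response`.
#' @export
delta_irf <- function(axis, bin = 1L) {
  w <- numeric(axis$n_bins)
  w[bin] <- 1
  instrument_response(w, axis)
}

#' Monoexponential decay model parameters
#'
#' @param tau Fluorescence lifetime in ns (> 0).
#' @param amplitude Expected total signal photons recorded over the axis.
#' @param background Expected uniform background counts per bin (>= 0).
#' @param shift IRF time offset in bins; may be fractional.
#' @return An object of class `decay_params`.
#' @export
decay_params <- function(tau, amplitude, background = 0, shift = 0) {
  stopifnot(is.numeric(tau), tau > 0, amplitude >= 0, background >= 0)
  structure(list(tau = tau, amplitude = amplitude, background = background,
                 shift = shift),
            class = "decay_params")
}

#' Monoexponential emission kernel under periodic excitation
#'
#' Per-bin emission probabilities for a monoexponential emitter excited by a
#' pulse train. Because excitation repeats every `period`, photons excited by
#' earlier pulses that decay into the current observation window wrap around:
#' the steady-state probability at bin center `t` is proportional to
#' `exp(-t / tau) / (1 - exp(-period / tau))`. The result is normalized to
#' sum to 1 over the axis bins.
#'
#' For a pure monoexponential the wrap factor is constant across bins, so it
#' cancels in the normalization whenever the axis spans the full period; it
#' is retained explicitly so that the unnormalized model matches a
#' multi-pulse superposition.
#'
#' @param tau Lifetime in ns (> 0).
#' @param axis A `time_axis`.
#' @return Numeric vector of per-bin probabilities summing to 1.
#' @export
monoexp_kernel <- function(tau, axis) {
  stopifnot(inherits(axis, "time_axis"))
  if (!is.numeric(tau) || length(tau) != 1L || !is.finite(tau) || tau <= 0) {
    stop("monoexp_kernel: tau must be a positive finite number")
  }
  t <- bin_centers(axis)
  # exp(-t/tau) can underflow for tau << t; work relative to the first bin
  w <- exp(-(t - t[1]) / tau) / (1 - exp(-axis$period / tau))
  w / sum(w)
}

#' Periodic (circular) convolution of a decay kernel with an IRF
#'
#' Circular discrete convolution of a per-bin kernel with the IRF over the
#' repetition period, with an optional fractional-bin IRF shift implemented
#' by linear interpolation between adjacent whole-bin circular shifts. The
#' output sums to the kernel's sum and is clamped non-negative against
#' floating-point jitter.
#'
#' @param kernel Per-bin probabilities (or any non-negative vector).
#' @param irf An `instrument_response` on the same grid.
#' @param shift IRF offset in bins; whole-bin shifts are exact.
#' @return Numeric vector, same length as `kernel`.
#' @export
convolve_periodic <- function(kernel, irf, shift = 0) {
  stopifnot(inherits(irf, "instrument_response"))
  n <- length(kernel)
  if (n != irf$axis$n_bins) {
    stop("convolve_periodic: kernel and IRF are on different grids")
  }
  w <- shift_irf_weights(irf$weights, shift)
  y <- Re(stats::fft(stats::fft(kernel) * stats::fft(w), inverse = TRUE)) / n
  y <- pmax(y, 0)
  s <- sum(y)
  if (s > 0) y <- y * (sum(kernel) / s)
  y
}

# circular shift by a possibly fractional number of bins
shift_irf_weights <- function(w, shift) {
  if (shift == 0) return(w)
  n <- length(w)
  k <- floor(shift)
  f <- shift - k
  rot <- function(x, m) {
    m <- ((m %% n) + n) %% n
    if (m == 0) x else c(x[(n - m + 1):n], x[1:(n - m)])
  }
  if (f == 0) rot(w, k) else (1 - f) * rot(w, k) + f * rot(w, k + 1)
}

#' Expected per-bin counts for a monoexponential decay measurement
#'
#' Composes the emission kernel, the periodic IRF convolution, the signal
#' amplitude and a uniform background:
#' `mu_i = amplitude * (kernel (*) IRF)_i + background`. The signal part sums
#' exactly to `amplitude`.
#'
#' @param params A `decay_params`.
#' @param irf An `instrument_response`.
#' @param axis A `time_axis` matching the IRF grid.
#' @return Numeric vector of expected counts per bin.
#' @export
expected_counts <- function(params, irf, axis) {
  stopifnot(inherits(params, "decay_params"), inherits(axis, "time_axis"))
  if (!same_axis(axis, irf$axis)) {
    stop("expected_counts: axis and IRF grid differ")
  }
  if (params$amplitude == 0) {
    return(rep(params$background, axis$n_bins))
  }
  k <- monoexp_kernel(params$tau, axis)
  params$amplitude * convolve_periodic(k, irf, params$shift) + params$background
}
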