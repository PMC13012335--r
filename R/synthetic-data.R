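# Seeded generators for every input the pipeline consumes: IRFs, noisy
# decays, re-emission cascades, FLIM cubes and photostability series.

# Run code with a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Reference library of solid lifetime standards
#'
#' Lifetimes and relative intensities of the four dyed-epoxy standards used
#' as defaults by the generators: purple 0.80 ns / 0.24 AU, yellow
#' 2.43 ns / 2.48 AU, magenta 2.56 ns / 0.50 AU, orange 3.61 ns / 2.29 AU.
#'
#' @return A data.frame with columns `name`, `tau` (ns) and
#'   `relative_intensity` (AU).
#' @examples
#' phantom_specs()
#' @export
phantom_specs <- function() {
  data.frame(
    name = c("purple", "yellow", "magenta", "orange"),
    tau = c(0.80, 2.43, 2.56, 3.61),
    relative_intensity = c(0.24, 2.48, 0.50, 2.29),
    stringsAsFactors = FALSE
  )
}

#' Simulate an instrument response function
#'
#' Generates a single-peaked (Gaussian) IRF on the given axis, emulating the
#' excitation pulse scattered off a frosted slide. Optional center jitter
#' emulates trigger drift; with `jitter_sd = 0` the result is deterministic
#' regardless of seed.
#'
#' @param axis A `time_axis`.
#' @param fwhm Full width at half maximum in ns; must lie in (0, period/4).
#' @param center Peak position in ns (default 5% of the axis span).
#' @param jitter_sd Standard deviation (ns) of a random center offset.
#' @param seed Optional integer seed (used only when `jitter_sd > 0`).
#' @return An `instrument_response`.
#' @export
simulate_irf <- function(axis, fwhm = 0.25, center = NULL, jitter_sd = 0,
                         seed = NULL) {
  stopifnot(inherits(axis, "time_axis"))
  if (fwhm <= 0 || fwhm >= axis$period / 4) {
    stop("simulate_irf: fwhm must lie in (0, period/4)")
  }
  if (is.null(center)) center <- 0.05 * axis$n_bins * axis$bin_width
  if (jitter_sd > 0) {
    center <- center + with_seed(seed, stats::rnorm(1, 0, jitter_sd))
  }
  sigma <- fwhm / (2 * sqrt(2 * log(2)))
  w <- stats::dnorm(bin_centers(axis), mean = center, sd = sigma)
  if (sum(w) <= 0) stop("simulate_irf: IRF has no mass on the axis")
  instrument_response(w, axis)
}

#' Simulate a noisy TCSPC decay histogram
#'
#' Draws independent Poisson counts per bin with means given by
#' [expected_counts()]. Defaults emulate the bulk acquisition protocol:
#' the laser power is adjusted to 1e5 counts per second and photons are
#' collected for one second.
#'
#' @param params A `decay_params` (use `amplitude = 1e5` for the bulk
#'   protocol).
#' @param irf An `instrument_response`.
#' @param axis A `time_axis`.
#' @param seed Optional integer seed; a fixed seed gives a bit-identical
#'   histogram.
#' @param acquisition_time Seconds, stored as metadata.
#' @param excitation_power Optional mW, stored as metadata.
#' @return A `decay_histogram`.
#' @export
simulate_decay <- function(params, irf, axis, seed = NULL,
                           acquisition_time = 1, excitation_power = NULL) {
  mu <- expected_counts(params, irf, axis)
  counts <- with_seed(seed, stats::rpois(axis$n_bins, mu))
  decay_histogram(counts, axis, acquisition_time = acquisition_time,
                  excitation_power = excitation_power)
}

#' Re-emission cascade parameters
#'
#' In a bulk (non-confocal) measurement at high dye density, emitted photons
#' can be reabsorbed by neighbouring fluorophores and re-emitted before
#' detection, delaying arrival and inflating the apparent lifetime. The
#' cascade is modeled as a geometric number of re-emission generations:
#' with probability `p` a photon is reabsorbed and re-emitted once more.
#'
#' @param p Per-generation reabsorption/re-emission probability in [0, 1).
#' @param max_generations Truncation order of the cascade (default 30; tail
#'   mass < 1e-8 for p <= 0.6).
#' @return An object of class `reemission_params`.
#' @export
reemission_params <- function(p, max_generations = 30L) {
  if (!is.numeric(p) || p < 0 || p >= 1) {
    stop("reemission_params: p must lie in [0, 1)")
  }
  stopifnot(max_generations >= 1)
  structure(list(p = p, max_generations = as.integer(max_generations)),
            class = "reemission_params")
}

#' Apparent emission kernel under a reabsorption/re-emission cascade
#'
#' A photon detected after `n` re-emission generations has arrival time
#' distributed as the sum of `n + 1` independent exponential delays, i.e. an
#' Erlang(n + 1, rate 1/tau) density. The detected arrival-time density is
#' the geometric mixture `sum_n (1 - p) p^n Erlang(n + 1)`, whose
#' (untruncated) mean is `tau / (1 - p)`. Probabilities are sampled at bin
#' centers and renormalized. With `p = 0` (confocal spatial filtering
#' rejects secondary emission) this reduces to [monoexp_kernel()].
#'
#' @param tau Intrinsic lifetime in ns.
#' @param reem A `reemission_params`.
#' @param axis A `time_axis`; for mean-arrival checks use a span much longer
#'   than `tau / (1 - p)`.
#' @return Per-bin probabilities summing to 1.
#' @export
simulate_reemission_decay <- function(tau, reem, axis) {
  stopifnot(inherits(reem, "reemission_params"), inherits(axis, "time_axis"))
  if (tau <= 0) stop("simulate_reemission_decay: tau must be positive")
  if (reem$p == 0) return(monoexp_kernel(tau, axis))
  t <- bin_centers(axis)
  dens <- numeric(axis$n_bins)
  for (n in 0:reem$max_generations) {
    dens <- dens + (1 - reem$p) * reem$p^n *
      stats::dgamma(t, shape = n + 1, rate = 1 / tau)
  }
  dens / sum(dens)
}

#' Phantom layouts for simulated FLIM images
#'
#' `make_quadrant_layout()` assigns one phantom spec to each image quadrant
#' (top-left, top-right, bottom-left, bottom-right in the order of `specs`),
#' emulating the quadrant standard used for multi-lifetime imaging.
#' `make_bar_target_layout()` emulates a chrome USAF-style bar target glued
#' onto a fluorescent slide: opaque bars emit nothing, the slide between
#' them emits with the background spec's intensity; an optional Gaussian
#' blur of the bar mask emulates optical resolution loss.
#'
#' @param size Integer `c(rows, cols)` of the image.
#' @param specs A data.frame of 4 rows with columns `name`, `tau`,
#'   `relative_intensity` (default [phantom_specs()]).
#' @return A `phantom_layout`: list of matrices `tau` (ns) and
#'   `intensity` (AU), plus a `name` matrix of labels.
#' @export
make_quadrant_layout <- function(size = c(128L, 120L), specs = phantom_specs()) {
  stopifnot(length(size) == 2, nrow(specs) == 4)
  nr <- as.integer(size[1]); nc <- as.integer(size[2])
  if (nr < 4L || nc < 4L) stop("make_quadrant_layout: image too small for quadrants")
  tau <- matrix(NA_real_, nr, nc)
  intensity <- matrix(NA_real_, nr, nc)
  name <- matrix(NA_character_, nr, nc)
  top <- seq_len(nr %/% 2); bottom <- (nr %/% 2 + 1):nr
  left <- seq_len(nc %/% 2); right <- (nc %/% 2 + 1):nc
  quads <- list(list(top, left), list(top, right),
                list(bottom, left), list(bottom, right))
  for (q in 1:4) {
    rows <- quads[[q]][[1]]; cols <- quads[[q]][[2]]
    tau[rows, cols] <- specs$tau[q]
    intensity[rows, cols] <- specs$relative_intensity[q]
    name[rows, cols] <- specs$name[q]
  }
  structure(list(tau = tau, intensity = intensity, name = name),
            class = "phantom_layout")
}

#' @rdname make_quadrant_layout
#' @param bar_period_px Full bar period in pixels (bright + dark), >= 2.
#' @param blur_sigma_px Gaussian blur sigma (pixels) applied to the bar
#'   mask; 0 gives a binary mask.
#' @param background A single-row phantom spec for the fluorescent slide.
#' @export
make_bar_target_layout <- function(size = c(64L, 64L), bar_period_px = 8,
                                   blur_sigma_px = 0,
                                   background = phantom_specs()[4, ]) {
  stopifnot(length(size) == 2, nrow(background) == 1)
  nr <- as.integer(size[1]); nc <- as.integer(size[2])
  if (bar_period_px < 2) stop("make_bar_target_layout: bar_period_px must be >= 2")
  if (nc < 2 * bar_period_px) {
    stop("make_bar_target_layout: image narrower than two bar periods")
  }
  # square wave along columns: first half-period opaque (0), second bright (1)
  col_phase <- ((seq_len(nc) - 1) %% bar_period_px) / bar_period_px
  mask <- as.numeric(col_phase >= 0.5)
  if (blur_sigma_px > 0) mask <- gaussian_blur_1d(mask, blur_sigma_px)
  tau <- matrix(background$tau, nr, nc)
  intensity <- matrix(rep(background$relative_intensity * mask, each = nr), nr, nc)
  name <- matrix(background$name, nr, nc)
  structure(list(tau = tau, intensity = intensity, name = name,
                 bar_period_px = bar_period_px),
            class = "phantom_layout")
}

# circular 1-D Gaussian blur (profiles are periodic bar patterns)
gaussian_blur_1d <- function(x, sigma) {
  n <- length(x)
  half <- min(n %/% 2, ceiling(4 * sigma))
  k <- stats::dnorm(-half:half, sd = sigma)
  k <- k / sum(k)
  kf <- numeric(n)
  idx <- ((-half:half) %% n) + 1
  for (i in seq_along(k)) kf[idx[i]] <- kf[idx[i]] + k[i]
  Re(stats::fft(stats::fft(x) * stats::fft(kf), inverse = TRUE)) / n
}

#' Simulate a wide-field FLIM cube
#'
#' Draws an independent Poisson decay realization for every pixel of a
#' phantom layout, emulating the SPAD micro-camera (default geometry
#' 128 x 120 pixels, 50 bins of 370 ps). The expected photon count of a
#' pixel is `photons_per_pixel * intensity`, so brighter phantom materials
#' yield brighter pixels. Pixels under `defect_mask` are flagged invalid,
#' emulating the sensor's defective region.
#'
#' @param layout A `phantom_layout`.
#' @param axis A `time_axis` (default [camera_axis()]).
#' @param photons_per_pixel Expected photons for a pixel of unit intensity.
#' @param irf An `instrument_response` (default a delta IRF, appropriate
#'   when the pulse is much shorter than a camera bin).
#' @param seed Optional integer seed.
#' @param defect_mask Optional logical matrix, TRUE = defective pixel.
#' @return A `flim_cube`.
#' @export
simulate_flim_cube <- function(layout, axis = camera_axis(),
                               photons_per_pixel = 1000, irf = NULL,
                               seed = NULL, defect_mask = NULL) {
  stopifnot(inherits(layout, "phantom_layout"))
  nr <- nrow(layout$tau); nc <- ncol(layout$tau)
  if (nr == 0 || nc == 0) stop("simulate_flim_cube: empty layout")
  if (photons_per_pixel < 0) stop("simulate_flim_cube: photons_per_pixel must be >= 0")
  if (is.null(irf)) irf <- delta_irf(axis)
  photons <- photons_per_pixel * layout$intensity
  counts <- array(0, dim = c(nr, nc, axis$n_bins))
  with_seed(seed, {
    for (tau in unique(as.vector(layout$tau))) {
      sel <- which(layout$tau == tau)
      if (length(sel) == 0) next
      model <- convolve_periodic(monoexp_kernel(tau, axis), irf)
      lambda <- outer(photons[sel], model)     # pixels x bins
      draws <- stats::rpois(length(lambda), lambda)
      for (b in seq_len(axis$n_bins)) {
        plane <- counts[, , b]
        plane[sel] <- draws[(b - 1) * length(sel) + seq_along(sel)]
        counts[, , b] <- plane
      }
    }
  })
  valid <- matrix(TRUE, nr, nc)
  if (!is.null(defect_mask)) {
    stopifnot(is.logical(defect_mask), all(dim(defect_mask) == c(nr, nc)))
    valid[defect_mask] <- FALSE
  }
  flim_cube(counts, axis, valid_mask = valid)
}

#' Map dye quantity to a re-emission probability
#'
#' Higher dye loading increases the chance that an emitted photon is
#' reabsorbed before leaving the material. A saturating map is used:
#' `p(m) = p_max * m / (m + m_half)`. The mapping is illustrative (the
#' mechanism, not a calibrated curve).
#'
#' @param quantity_mg Dye quantity in mg.
#' @param p_max Asymptotic re-emission probability (default 0.3).
#' @param m_half Quantity at half-saturation in mg (default 320).
#' @return Re-emission probability in [0, p_max).
#' @export
dye_quantity_to_p <- function(quantity_mg, p_max = 0.3, m_half = 320) {
  stopifnot(all(quantity_mg >= 0), p_max >= 0, p_max < 1, m_half > 0)
  p_max * quantity_mg / (quantity_mg + m_half)
}

#' Simulate a photostability dose series
#'
#' Emulates the UV-ageing protocol: a phantom slide sits under a 365 nm LED
#' (irradiance ~1.35 mW/cm^2) for 10 h; every hour three lifetime
#' measurements and one intensity measurement are taken. The underlying
#' trends are `lifetime(D) = tau0 * (1 + lifetime_drift_per_dose * D)` and
#' `intensity(D) = intensity0 * exp(-bleach_rate * D)` with multiplicative
#' Gaussian measurement noise. Defaults (zero drift, zero bleaching) model a
#' photostable dye whose apparent variation is measurement noise only.
#'
#' @param tau0 Initial lifetime (ns).
#' @param intensity0 Initial relative intensity (AU).
#' @param hours Measurement time points in hours, increasing from 0.
#' @param irradiance Irradiance in mW/cm^2 (default 1.35).
#' @param lifetime_drift_per_dose Fractional lifetime change per J/cm^2.
#' @param bleach_rate Intensity decay rate per J/cm^2.
#' @param n_lifetime,n_intensity Replicates per time point (defaults 3, 1).
#' @param noise_cv_lifetime,noise_cv_intensity Measurement noise as a
#'   coefficient of variation (defaults 0.5% and 2%, matching the replicate
#'   repeatability of the bulk system).
#' @param seed Optional integer seed.
#' @return A long-form data.frame with columns `time_h`, `dose`
#'   (J/cm^2), `quantity` ("lifetime" or "intensity"), `replicate`, `value`.
#' @export
simulate_photostability_series <- function(tau0, intensity0, hours = 0:10,
                                           irradiance = 1.35,
                                           lifetime_drift_per_dose = 0,
                                           bleach_rate = 0,
                                           n_lifetime = 3, n_intensity = 1,
                                           noise_cv_lifetime = 0.005,
                                           noise_cv_intensity = 0.02,
                                           seed = NULL) {
  if (any(hours < 0)) stop("simulate_photostability_series: hours must be >= 0")
  if (is.unsorted(hours, strictly = TRUE)) {
    stop("simulate_photostability_series: hours must be strictly increasing")
  }
  dose <- cumulative_dose(irradiance, hours)
  with_seed(seed, {
    rows <- lapply(seq_along(hours), function(i) {
      lt <- tau0 * (1 + lifetime_drift_per_dose * dose[i]) *
        (1 + stats::rnorm(n_lifetime, 0, noise_cv_lifetime))
      it <- intensity0 * exp(-bleach_rate * dose[i]) *
        (1 + stats::rnorm(n_intensity, 0, noise_cv_intensity))
      data.frame(
        time_h = hours[i], dose = dose[i],
        quantity = rep(c("lifetime", "intensity"), c(n_lifetime, n_intensity)),
        replicate = c(seq_len(n_lifetime), seq_len(n_intensity)),
        value = c(lt, it), stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}
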