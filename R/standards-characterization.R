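# QC statistics for solid lifetime standards: replicate summaries,
# fabrication repeatability, photostability dose metrics, relative
# intensity and the dye-quantity (reabsorption) comparison.

#' Replicate summary statistics (mean, SD, CV%)
#'
#' Summarizes a long-form replicate table per group: mean, sample standard
#' deviation (n - 1 denominator) and coefficient of variation
#' `CV% = 100 * SD / mean`. This is the repeatability metric used to
#' characterize each standard from three slides measured three times each.
#' Rounding happens only at presentation, never inside the computation.
#'
#' @param table A data.frame with a numeric `value_col` and one or more
#'   grouping columns.
#' @param value_col Name of the value column (default `"value"`).
#' @param group_cols Names of grouping columns (default: all other columns).
#' @return A data.frame with the group columns plus `n`, `mean`, `sd`,
#'   `cv_pct`. `cv_pct` is `NA` where the mean is zero (CV undefined).
#' @examples
#' tab <- data.frame(material = "purple", value = c(0.79, 0.80, 0.81))
#' summarize_replicates(tab)
#' @export
summarize_replicates <- function(table, value_col = "value",
                                 group_cols = NULL) {
  stopifnot(is.data.frame(table), value_col %in% names(table))
  if (is.null(group_cols)) group_cols <- setdiff(names(table), value_col)
  if (length(group_cols) == 0) {
    table$.group <- "all"; group_cols <- ".group"
  }
  v <- table[[value_col]]
  if (!all(is.finite(v))) stop("summarize_replicates: values must be finite")
  key <- interaction(table[group_cols], drop = TRUE, lex.order = TRUE)
  pieces <- split(seq_len(nrow(table)), key)
  rows <- lapply(pieces, function(ii) {
    if (length(ii) < 2) {
      stop("summarize_replicates: need >= 2 values per group for an SD")
    }
    x <- v[ii]
    m <- mean(x); s <- stats::sd(x)
    out <- table[ii[1], group_cols, drop = FALSE]
    out$n <- length(x); out$mean <- m; out$sd <- s
    out$cv_pct <- if (m == 0) NA_real_ else 100 * s / m
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res[setdiff(names(res), ".group")]
}

#' Relative fluorescence intensity from required excitation power
#'
#' The relative brightness of a standard is estimated as the inverse of the
#' excitation laser power required to reach a fixed detector count rate
#' (1e5 cps in the bulk protocol): a brighter material needs less power.
#' This is a proxy, not a radiometric measurement.
#'
#' @param power_required Excitation power in mW (> 0); vectorized.
#' @param k Normalization constant (default 1 mW, giving dimensionless AU).
#' @return Relative intensity in AU.
#' @export
relative_intensity <- function(power_required, k = 1) {
  if (any(!is.finite(power_required)) || any(power_required <= 0)) {
    stop("relative_intensity: power must be positive")
  }
  k / power_required
}

#' Cumulative UV dose from irradiance and exposure time
#'
#' `dose [J/cm^2] = irradiance [mW/cm^2] * 1e-3 * hours * 3600`. Linear and
#' exactly additive over partitioned exposure intervals.
#'
#' @param irradiance Irradiance in mW/cm^2 (>= 0).
#' @param hours Exposure time in hours (>= 0); vectorized.
#' @return Dose in J/cm^2.
#' @examples
#' cumulative_dose(1.35, 10)  # 48.6 J/cm^2 after the full 10 h exposure
#' @export
cumulative_dose <- function(irradiance, hours) {
  if (any(irradiance < 0) || any(hours < 0)) {
    stop("cumulative_dose: irradiance and hours must be non-negative")
  }
  irradiance * 1e-3 * hours * 3600
}

#' Photostability dose metrics
#'
#' For each measured quantity of a photostability series, reports the
#' minimum and maximum of the per-time-point means and the maximum
#' variation `change% = 100 * (max - min) / min` (the spread between the
#' lowest and highest values recorded over the exposure), computed on
#' unrounded values. Individual time points can be excluded to probe
#' outliers (e.g. a single anomalous intensity reading).
#'
#' @param series Long-form data.frame with columns `time_h`, `dose`,
#'   `quantity`, `value` (as produced by
#'   [simulate_photostability_series()]).
#' @param exclude_points Optional vector of `time_h` values to drop before
#'   summarizing.
#' @param denominator `"min"` (default) or `"max"` for the change% basis.
#' @return A data.frame with columns `quantity`, `min`, `max`, `change_pct`
#'   (`NA` when the denominator is zero).
#' @export
photostability_metrics <- function(series, exclude_points = NULL,
                                   denominator = c("min", "max")) {
  stopifnot(is.data.frame(series),
            all(c("time_h", "quantity", "value") %in% names(series)))
  denominator <- match.arg(denominator)
  if (!is.null(exclude_points)) {
    series <- series[!series$time_h %in% exclude_points, , drop = FALSE]
  }
  if (length(unique(series$time_h)) < 2) {
    stop("photostability_metrics: need >= 2 time points after exclusions")
  }
  rows <- lapply(split(series, series$quantity), function(s) {
    per_point <- tapply(s$value, s$time_h, mean)
    lo <- min(per_point); hi <- max(per_point)
    den <- if (denominator == "min") lo else hi
    data.frame(quantity = s$quantity[1], min = lo, max = hi,
               change_pct = if (den == 0) NA_real_ else 100 * (hi - lo) / den,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Cross-batch fabrication repeatability
#'
#' Summarizes each fabrication batch (mean, SD, CV%) and reports the
#' between-batch range of means (max - min), the descriptive measure of
#' fabrication reproducibility. No hypothesis test is performed.
#'
#' @param tables A list of >= 2 long-form replicate tables, one per batch,
#'   each with a numeric `value` column.
#' @param value_col Name of the value column (default `"value"`).
#' @return List with `per_batch` (data.frame: `batch`, `n`, `mean`, `sd`,
#'   `cv_pct`) and `between_batch_range` (max - min of batch means).
#' @export
compare_fabrications <- function(tables, value_col = "value") {
  if (!is.list(tables) || length(tables) < 2) {
    stop("compare_fabrications: need >= 2 batches")
  }
  per <- lapply(seq_along(tables), function(b) {
    tab <- tables[[b]]
    stopifnot(is.data.frame(tab), value_col %in% names(tab))
    tab <- tab[value_col]
    tab$.batch <- b
    s <- summarize_replicates(tab, value_col, group_cols = ".batch")
    names(s)[names(s) == ".batch"] <- "batch"
    s
  })
  per <- do.call(rbind, per)
  rownames(per) <- NULL
  list(per_batch = per,
       between_batch_range = max(per$mean) - min(per$mean))
}

#' Dye-quantity trend report (bulk vs confocal lifetimes)
#'
#' Characterizes how lifetime and intensity change with dye loading:
#' intensity rises with quantity as expected, but the bulk (non-confocal)
#' lifetime also rises because secondary photons from reabsorption and
#' re-emission lengthen the detected decay, while a confocal system's
#' spatial filtering rejects that secondary emission and its lifetime stays
#' flat. Reports monotonicity/flatness flags and the per-pair deltas
#' between successive quantities; quantities are sorted internally and
#' duplicate quantities averaged.
#'
#' @param measurements Data.frame with columns `quantity_mg`, `tau_bulk`,
#'   `tau_confocal`, `intensity` (>= 3 distinct quantities).
#' @param flat_tol Relative tolerance band for the "flat" flags (default
#'   0.05, i.e. +/-5% around the mean).
#' @return List with flags `intensity_increasing`, `tau_bulk_increasing`,
#'   `tau_bulk_flat`, `tau_confocal_flat`, a data.frame `deltas` of
#'   successive differences and the sorted per-quantity `means`.
#' @export
dye_quantity_trend <- function(measurements, flat_tol = 0.05) {
  need <- c("quantity_mg", "tau_bulk", "tau_confocal", "intensity")
  stopifnot(is.data.frame(measurements), all(need %in% names(measurements)))
  m <- measurements[need]
  m <- stats::aggregate(m[-1], by = list(quantity_mg = m$quantity_mg), mean)
  m <- m[order(m$quantity_mg), ]
  if (nrow(m) < 3) stop("dye_quantity_trend: need >= 3 distinct quantities")
  d <- data.frame(
    from_mg = m$quantity_mg[-nrow(m)], to_mg = m$quantity_mg[-1],
    d_tau_bulk = diff(m$tau_bulk), d_tau_confocal = diff(m$tau_confocal),
    d_intensity = diff(m$intensity)
  )
  flat <- function(x) all(abs(x - mean(x)) <= flat_tol * mean(x))
  list(
    intensity_increasing = all(d$d_intensity > 0),
    tau_bulk_increasing = all(d$d_tau_bulk > 0),
    tau_bulk_flat = flat(m$tau_bulk),
    tau_confocal_flat = flat(m$tau_confocal),
    deltas = d,
    means = m
  )
}
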