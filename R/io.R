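# File formats: two-column decay text, multi-page TIFF cubes with a JSON
# sidecar, float TIFF maps, long-form CSV tables and YAML run configs.
# Time unit in all files is nanoseconds; doses J/cm^2; powers mW.
# Text formats use '.' as decimal separator and are locale-independent.

decay_header <- function(axis, acquisition_time = NULL, power = NULL,
                         kind = "decay") {
  c(sprintf("# kind: %s", kind),
    sprintf("# bin_width_ns: %.12g", axis$bin_width),
    sprintf("# n_bins: %d", axis$n_bins),
    sprintf("# period_ns: %.12g", axis$period),
    if (!is.null(acquisition_time))
      sprintf("# acquisition_time_s: %.12g", acquisition_time),
    if (!is.null(power)) sprintf("# excitation_power_mw: %.12g", power),
    "time_ns\tcounts")
}

#' Read and write TCSPC decay histograms and IRFs as text
#'
#' Two-column tab-separated text (`time_ns`, `counts`) with a commented
#' metadata header carrying the bin width, bin count, repetition period and
#' (for decays) acquisition time and excitation power. Writing then reading
#' reproduces counts and metadata exactly. Parsers validate rather than
#' coerce: negative counts and a header period inconsistent with
#' `n_bins * bin_width` are errors that name the offending row/field.
#'
#' @param decay A `decay_histogram`.
#' @param path File path.
#' @return `write_decay()`/`write_irf()` return `path` invisibly;
#'   `read_decay()` returns a `decay_histogram`, `read_irf()` an
#'   `instrument_response`.
#' @export
write_decay <- function(decay, path) {
  stopifnot(inherits(decay, "decay_histogram"))
  hdr <- decay_header(decay$axis, decay$acquisition_time,
                      decay$excitation_power, "decay")
  body <- sprintf("%.12g\t%.12g", bin_centers(decay$axis), decay$counts)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' @rdname write_decay
#' @param irf An `instrument_response`.
#' @export
write_irf <- function(irf, path) {
  stopifnot(inherits(irf, "instrument_response"))
  hdr <- decay_header(irf$axis, kind = "irf")
  body <- sprintf("%.12g\t%.17g", bin_centers(irf$axis), irf$weights)
  writeLines(c(hdr, body), path)
  invisible(path)
}

parse_decay_file <- function(path) {
  lines <- readLines(path)
  hdr_idx <- grep("^# ", lines)
  meta <- list()
  for (h in lines[hdr_idx]) {
    kv <- strsplit(sub("^# ", "", h), ": ", fixed = TRUE)[[1]]
    meta[[kv[1]]] <- kv[2]
  }
  for (f in c("bin_width_ns", "n_bins", "period_ns")) {
    if (is.null(meta[[f]])) stop(sprintf("decay file %s: missing header field '%s'", path, f))
  }
  bw <- as.numeric(meta$bin_width_ns)
  nb <- as.integer(meta$n_bins)
  period <- as.numeric(meta$period_ns)
  if (nb * bw > period * (1 + 1e-9)) {
    stop(sprintf("decay file %s: header period %.6g ns inconsistent with %d bins x %.6g ns",
                 path, period, nb, bw))
  }
  body_start <- max(hdr_idx) + 2  # skip the column-name line
  body <- lines[body_start:length(lines)]
  vals <- strsplit(body, "\t", fixed = TRUE)
  counts <- numeric(length(body))
  for (i in seq_along(vals)) {
    if (length(vals[[i]]) != 2 || is.na(suppressWarnings(as.numeric(vals[[i]][2])))) {
      stop(sprintf("decay file %s: malformed row at line %d", path, body_start + i - 1))
    }
    counts[i] <- as.numeric(vals[[i]][2])
    if (counts[i] < 0) {
      stop(sprintf("decay file %s: negative count at line %d", path, body_start + i - 1))
    }
  }
  if (length(counts) != nb) {
    stop(sprintf("decay file %s: %d rows but header says %d bins", path, length(counts), nb))
  }
  list(axis = time_axis(bw, nb, period), counts = counts, meta = meta)
}

#' @rdname write_decay
#' @export
read_decay <- function(path) {
  p <- parse_decay_file(path)
  decay_histogram(
    p$counts, p$axis,
    acquisition_time = if (!is.null(p$meta$acquisition_time_s))
      as.numeric(p$meta$acquisition_time_s) else 1,
    excitation_power = if (!is.null(p$meta$excitation_power_mw))
      as.numeric(p$meta$excitation_power_mw) else NULL)
}

#' @rdname write_decay
#' @export
read_irf <- function(path) {
  p <- parse_decay_file(path)
  instrument_response(p$counts, p$axis)
}

# 32-bit TIFF samples are stored as unsigned integers scaled to [0, 1];
# dividing integer counts by (2^32 - 1) makes the round trip exact.
TIFF_SCALE <- 2^32 - 1

#' Read and write FLIM cubes as multi-page TIFF with a JSON sidecar
#'
#' The cube is written as one 32-bit TIFF page per time bin, with a JSON
#' sidecar (`<path>.json`) carrying the time axis and the validity mask.
#' Integer photon counts below 2^32 round-trip exactly. Reading without
#' the sidecar is an error that names the expected sidecar path.
#'
#' @param cube A `flim_cube`.
#' @param path TIFF file path; the sidecar is `<path>.json`.
#' @return `write_cube()` returns `path` invisibly; `read_cube()` a
#'   `flim_cube`.
#' @export
write_cube <- function(cube, path) {
  stopifnot(inherits(cube, "flim_cube"))
  pages <- lapply(seq_len(cube$axis$n_bins), function(b) {
    cube$counts[, , b] / TIFF_SCALE
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 32, compression = "none")
  sidecar <- list(
    bin_width_ns = cube$axis$bin_width,
    n_bins = cube$axis$n_bins,
    period_ns = cube$axis$period,
    n_rows = dim(cube$counts)[1],
    n_cols = dim(cube$counts)[2],
    valid_mask = cube$valid_mask
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_cube
#' @export
read_cube <- function(path) {
  sidecar_path <- paste0(path, ".json")
  if (!file.exists(sidecar_path)) {
    stop(sprintf("read_cube: sidecar %s not found; cubes must be written with write_cube()",
                 sidecar_path))
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$n_bins) {
    stop(sprintf("read_cube: %d TIFF pages but sidecar says %d bins",
                 length(pages), meta$n_bins))
  }
  counts <- array(0, dim = c(meta$n_rows, meta$n_cols, meta$n_bins))
  for (b in seq_along(pages)) counts[, , b] <- round(pages[[b]] * TIFF_SCALE)
  axis <- time_axis(meta$bin_width_ns, meta$n_bins, meta$period_ns)
  flim_cube(counts, axis, valid_mask = matrix(as.logical(meta$valid_mask),
                                              meta$n_rows, meta$n_cols))
}

#' Write a lifetime/intensity map as 32-bit TIFF
#'
#' Maps are scaled by the smallest power of two not below their maximum
#' (recorded in a JSON sidecar) so that quantization error is at most
#' `scale / 2^32`; `NA` pixels are stored as zero with a companion mask.
#'
#' @param map Numeric matrix (e.g. `tau_map` or `intensity_map`).
#' @param path TIFF file path; the sidecar is `<path>.json`.
#' @return `write_map()` returns `path` invisibly; `read_map()` the matrix.
#' @export
write_map <- function(map, path) {
  stopifnot(is.matrix(map))
  defined <- is.finite(map)
  mx <- if (any(defined)) max(map[defined]) else 0
  scale <- 2^max(ceiling(log2(max(mx, 1))), 0)
  vals <- map / scale
  vals[!defined] <- 0
  tiff::writeTIFF(vals, path, bits.per.sample = 32, compression = "none")
  jsonlite::write_json(list(scale = scale, defined = defined), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_map
#' @export
read_map <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  m <- tiff::readTIFF(path) * meta$scale
  m[!meta$defined] <- NA_real_
  m
}

#' Read and write long-form replicate/series tables as CSV
#'
#' Plain CSV with a header row; values are never rounded on write.
#'
#' @param table A data.frame.
#' @param path CSV file path.
#' @return `write_table_csv()` returns `path` invisibly; `read_table_csv()`
#'   a data.frame.
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Run configuration files
#'
#' A run config bundles the seed, time-axis parameters, generator
#' parameters and fit options of a simulation/fitting run as YAML, and
#' round-trips losslessly. `config_hash()` gives a stable digest (MD5 of
#' the canonical JSON serialization) for embedding in outputs so that two
#' runs with identical configs are identifiable.
#'
#' @param config A named list.
#' @param path YAML file path.
#' @return `write_run_config()` returns `path` invisibly;
#'   `read_run_config()` the named list; `config_hash()` a hex string.
#' @export
write_run_config <- function(config, path) {
  stopifnot(is.list(config))
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname write_run_config
#' @export
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  canonical <- config[order(names(config))]
  jsonlite::write_json(canonical, tmp, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}
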