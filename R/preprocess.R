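#' Preprocessing configuration
#'
#' Defaults: Hampel-style despiking with a 5-channel running median and an
#' 8-MAD threshold against a 25-channel local intensity scale; 12-segment
#' polyline baseline; vector normalization over the entire spectral region;
#' SNR quality control with signal band 1420--1470 cm^-1 (CH2 deformation),
#' noise band 1800--2600 cm^-1 (silent region), minimum SNR 3.
#'
#' @param despike_window Odd integer >= 3, running-median width (channels).
#' @param despike_threshold Spike threshold in multiples of the local MAD.
#' @param despike_neighborhood Odd integer, width of the local-scale window.
#' @param baseline_segments Number of equal wavenumber spans (>= 2).
#' @param norm_region `"entire"` or `c(start, end)` cm^-1 (e.g. fingerprint
#'   region `c(300, 1800)`).
#' @param snr_signal_band,snr_noise_band Wavenumber ranges `c(start, end)`.
#' @param snr_min Minimum signal-to-noise ratio retained.
#' @param normalize_per `"scrs"` (default: average first, then normalize the
#'   per-cell spectrum) or `"acquisition"` (normalize each acquisition before
#'   averaging).
#' @return List of class `preprocess_config`.
#' @export
preprocess_config <- function(despike_window = 5, despike_threshold = 8,
                              despike_neighborhood = 25,
                              baseline_segments = 12,
                              norm_region = "entire",
                              snr_signal_band = c(1420, 1470),
                              snr_noise_band = c(1800, 2600),
                              snr_min = 3,
                              normalize_per = c("scrs", "acquisition")) {
  if (despike_window %% 2 == 0 || despike_window < 3)
    stop("despike_window must be an odd integer >= 3")
  if (baseline_segments < 2) stop("baseline_segments must be >= 2")
  if (snr_min <= 0) stop("snr_min must be > 0")
  structure(list(despike_window = as.integer(despike_window),
                 despike_threshold = despike_threshold,
                 despike_neighborhood = as.integer(despike_neighborhood),
                 baseline_segments = as.integer(baseline_segments),
                 norm_region = norm_region,
                 snr_signal_band = snr_signal_band,
                 snr_noise_band = snr_noise_band,
                 snr_min = snr_min,
                 normalize_per = match.arg(normalize_per)),
            class = "preprocess_config")
}

# median absolute deviation of the intensities inside a sliding window
# (truncated at the spectrum ends), scaled to be consistent for a normal
rolling_mad <- function(y, k) {
  n <- length(y)
  h <- k %/% 2
  out <- numeric(n)
  for (j in seq_len(n)) {
    w <- y[max(1, j - h):min(n, j + h)]
    out[j] <- stats::median(abs(w - stats::median(w)))
  }
  1.4826 * out
}

#' Remove cosmic-ray spikes from a spectrum
#'
#' A channel is flagged when its residual from a running median (width
#' `window`) exceeds `threshold` times the local intensity MAD, estimated over
#' a `neighborhood`-channel window as a running median of absolute deviations.
#' Flagged channels are replaced by the running-median value; all others are
#' untouched. Using the MAD of the *intensities* (not of the residuals) makes
#' the local scale large near genuine Raman peaks — protecting peaks whose
#' width is comparable to the filter — while staying noise-sized in flat
#' regions where cosmic spikes stand out. A strict inequality leaves constant
#' spectra unchanged (zero-MAD guard) yet still removes a lone spike on a
#' constant background.
#'
#' @param y Numeric spectrum.
#' @param window Odd running-median width (channels), default 5.
#' @param threshold Multiples of local MAD, default 8.
#' @param neighborhood Odd local-scale window (channels), default 25.
#' @return Despiked numeric spectrum. Idempotent on its own output for
#'   practical spectra.
#' @export
despike <- function(y, window = 5, threshold = 8, neighborhood = 25) {
  if (window >= length(y)) stop("despike window must be smaller than the spectrum")
  if (window %% 2 == 0 || window < 3) stop("window must be odd >= 3")
  if (neighborhood %% 2 == 0) neighborhood <- neighborhood + 1L
  med <- stats::runmed(y, window, endrule = "median")
  resid <- y - med
  local_mad <- rolling_mad(y, neighborhood)
  bad <- abs(resid) > threshold * local_mad
  y[bad] <- med[bad]
  y
}

#' Fit and subtract a polyline (piecewise-linear) baseline
#'
#' The axis is split into `segments` equal wavenumber spans; the minimum
#' intensity point of each span is an anchor, and the first and last channels
#' are always anchored so the polyline covers the whole axis. The baseline is
#' the linear interpolation through the anchors; the corrected spectrum is the
#' input minus the baseline with negative values clipped to zero.
#'
#' @param y Numeric spectrum.
#' @param wavenumbers Axis matching `y`.
#' @param segments Number of spans (>= 2).
#' @return List with `baseline` and `corrected` numeric vectors.
#' @export
fit_polyline_baseline <- function(y, wavenumbers, segments = 12) {
  p <- length(y)
  if (length(wavenumbers) != p) stop("axis length mismatch")
  if (segments < 2) stop("baseline_segments must be >= 2")
  if (p < segments) stop("fewer channels than segments")
  edges <- seq(wavenumbers[1], wavenumbers[p], length.out = segments + 1)
  span <- findInterval(wavenumbers, edges, rightmost.closed = TRUE)
  anchors <- vapply(seq_len(segments), function(s) {
    idx <- which(span == s)
    if (length(idx) == 0) return(NA_integer_)
    idx[which.min(y[idx])]
  }, integer(1))
  anchors <- sort(unique(c(1L, anchors[!is.na(anchors)], p)))
  baseline <- stats::approx(wavenumbers[anchors], y[anchors],
                            xout = wavenumbers, rule = 2)$y
  corrected <- pmax(y - baseline, 0)
  list(baseline = baseline, corrected = corrected)
}

#' Vector-normalize a spectrum
#'
#' Divides the whole spectrum by the L2 norm computed over `region` (the
#' entire axis by default, per the preprocessing chain; a fingerprint-only
#' region is selectable).
#'
#' @param y Numeric spectrum.
#' @param wavenumbers Axis matching `y` (only needed for a sub-region).
#' @param region `"entire"` or `c(start, end)` cm^-1.
#' @return Normalized spectrum whose L2 norm over `region` is 1.
#' @export
vector_normalize <- function(y, wavenumbers = NULL, region = "entire") {
  idx <- if (identical(region, "entire")) seq_along(y) else {
    if (is.null(wavenumbers)) stop("wavenumbers required for a sub-region")
    channels_in(wavenumbers, region[1], region[2])
  }
  nrm <- sqrt(sum(y[idx]^2))
  if (nrm == 0) stop("zero-norm spectrum cannot be normalized")
  y / nrm
}

#' Signal-to-noise quality control
#'
#' SNR is the maximum baseline-corrected intensity in the signal band divided
#' by the standard deviation of baseline-corrected intensities in the noise
#' band. Spectra below `snr_min` are discarded.
#'
#' @param x A [spectra_set] of baseline-corrected spectra.
#' @param config A [preprocess_config].
#' @return List with `kept` and `discarded` [spectra_set]s and a `report`
#'   data frame (spectrum key, snr, kept flag).
#' @export
qc_filter <- function(x, config = preprocess_config()) {
  stopifnot(inherits(x, "spectra_set"))
  wn <- x$wavenumbers
  sig_idx <- channels_in(wn, config$snr_signal_band[1], config$snr_signal_band[2])
  noi_idx <- channels_in(wn, config$snr_noise_band[1], config$snr_noise_band[2])
  if (length(sig_idx) < 1) stop("signal band outside axis")
  if (length(noi_idx) < 3) stop("noise band has fewer than 3 channels")
  n <- nrow(x$intensities)
  if (n == 0) {
    return(list(kept = x, discarded = x,
                report = data.frame(key = character(0), snr = numeric(0),
                                    kept = logical(0))))
  }
  snr <- apply(x$intensities, 1, function(y)
    max(y[sig_idx]) / stats::sd(y[noi_idx]))
  keep <- snr >= config$snr_min
  report <- data.frame(key = spectrum_keys(x$meta), snr = snr, kept = keep,
                       stringsAsFactors = FALSE)
  list(kept = spectra_set(wn, x$intensities[keep, , drop = FALSE],
                          x$meta[keep, , drop = FALSE]),
       discarded = spectra_set(wn, x$intensities[!keep, , drop = FALSE],
                               x$meta[!keep, , drop = FALSE]),
       report = report)
}

#' Average a cell's acquisitions into its single-cell Raman spectrum
#'
#' Channel-wise arithmetic mean of all acquisitions of one cell.
#'
#' @param x A [spectra_set] whose rows all belong to one cell.
#' @return A one-cell [scrs_set] recording `n_acquisitions`.
#' @export
average_to_scrs <- function(x) {
  stopifnot(inherits(x, "spectra_set"))
  if (nrow(x$intensities) < 1) stop("at least one acquisition required")
  if (length(unique(x$meta$cell_id)) != 1) stop("acquisitions from multiple cells")
  if (length(unique(x$meta$subject_id)) != 1) stop("acquisitions from multiple subjects")
  m <- colMeans(x$intensities)
  scrs_set(x$wavenumbers, matrix(m, 1),
           data.frame(cell_id = x$meta$cell_id[1],
                      subject_id = x$meta$subject_id[1],
                      n_acquisitions = nrow(x$intensities),
                      stringsAsFactors = FALSE))
}

#' Run the full preprocessing chain
#'
#' Pipeline order: optional resampling to a target axis, despiking, polyline
#' baseline correction, SNR quality control, per-cell averaging into SCRS,
#' then vector normalization (per SCRS by default; per acquisition before
#' averaging when `config$normalize_per == "acquisition"`). Cells losing all
#' acquisitions to QC are dropped and listed in the `dropped_cells` attribute;
#' the QC report is attached as the `qc_report` attribute.
#'
#' @param x A [spectra_set] of raw spectra.
#' @param config A [preprocess_config].
#' @param target_axis Optional axis to resample onto first.
#' @return An [scrs_set] of preprocessed single-cell spectra.
#' @export
run_preprocess <- function(x, config = preprocess_config(), target_axis = NULL) {
  stopifnot(inherits(x, "spectra_set"))
  if (!is.null(target_axis)) x <- resample_to_axis(x, target_axis)
  wn <- x$wavenumbers
  n <- nrow(x$intensities)
  if (n == 0) {
    out <- scrs_set(wn, matrix(numeric(0), 0, length(wn)),
                    data.frame(cell_id = character(0), subject_id = character(0),
                               n_acquisitions = integer(0)),
                    normalized = TRUE)
    attr(out, "qc_report") <- data.frame(key = character(0), snr = numeric(0),
                                         kept = logical(0))
    attr(out, "dropped_cells") <- character(0)
    return(out)
  }
  ints <- x$intensities
  for (i in seq_len(n)) {
    d <- despike(ints[i, ], config$despike_window, config$despike_threshold,
                 config$despike_neighborhood)
    ints[i, ] <- fit_polyline_baseline(d, wn, config$baseline_segments)$corrected
  }
  corrected <- spectra_set(wn, ints, x$meta)
  qc <- qc_filter(corrected, config)
  kept <- qc$kept
  if (config$normalize_per == "acquisition" && nrow(kept$intensities) > 0) {
    kept$intensities <- t(apply(kept$intensities, 1, vector_normalize,
                                wavenumbers = wn, region = config$norm_region))
  }
  all_cells <- unique(x$meta$cell_id)
  if (nrow(kept$intensities) == 0) {
    out <- scrs_set(wn, matrix(numeric(0), 0, length(wn)),
                    data.frame(cell_id = character(0), subject_id = character(0),
                               n_acquisitions = integer(0)),
                    normalized = TRUE)
    attr(out, "qc_report") <- qc$report
    attr(out, "dropped_cells") <- all_cells
    return(out)
  }
  cell <- kept$meta$cell_id
  sums <- rowsum(kept$intensities, cell, reorder = FALSE)
  counts <- as.integer(table(factor(cell, levels = rownames(sums))))
  means <- sums / counts
  subj <- kept$meta$subject_id[match(rownames(sums), cell)]
  meta <- data.frame(cell_id = rownames(sums), subject_id = subj,
                     n_acquisitions = counts, stringsAsFactors = FALSE)
  if (config$normalize_per == "scrs") {
    means <- t(apply(means, 1, vector_normalize, wavenumbers = wn,
                     region = config$norm_region))
  }
  out <- scrs_set(wn, means, meta, normalized = TRUE)
  attr(out, "qc_report") <- qc$report
  attr(out, "dropped_cells") <- setdiff(all_cells, meta$cell_id)
  out
}
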