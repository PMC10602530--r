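#' Collection of raw per-acquisition spectra on a shared axis
#'
#' A `spectra_set` holds one intensity row per acquisition together with the
#' subject/cell/acquisition identifiers needed downstream. Intensities are in
#' arbitrary units (a.u.); no absolute calibration is implied.
#'
#' @param wavenumbers Strictly increasing numeric axis (cm^-1).
#' @param intensities Numeric matrix, one row per acquisition, `length(wavenumbers)`
#'   columns. Finite values required.
#' @param meta Data frame with columns `subject_id`, `cell_id`, `acquisition_id`
#'   (one row per spectrum). `subject_id:cell_id:acquisition_id` must be unique.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(wavenumbers, intensities, meta) {
  check_axis(wavenumbers)
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(wavenumbers))
    stop("intensity columns must match axis length")
  if (nrow(intensities) > 0 && any(!is.finite(intensities)))
    stop("intensities must be finite")
  need <- c("subject_id", "cell_id", "acquisition_id")
  if (!is.data.frame(meta) || !all(need %in% names(meta)))
    stop("meta must contain subject_id, cell_id, acquisition_id")
  if (nrow(meta) != nrow(intensities))
    stop("meta rows must match intensity rows")
  meta <- as.data.frame(lapply(meta, as.character), stringsAsFactors = FALSE)
  key <- spectrum_keys(meta)
  if (anyDuplicated(key)) stop("duplicate acquisition keys")
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 intensities = unname(intensities),
                 meta = meta),
            class = "spectra_set")
}

spectrum_keys <- function(meta) {
  paste(meta$subject_id, meta$cell_id, meta$acquisition_id, sep = ":")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("spectra_set: %d acquisitions x %d channels (%.1f-%.1f cm^-1), %d cells, %d subjects\n",
              nrow(x$intensities), length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers),
              length(unique(paste(x$meta$subject_id, x$meta$cell_id))),
              length(unique(x$meta$subject_id))))
  invisible(x)
}

#' Collection of single-cell Raman spectra (SCRS)
#'
#' One averaged spectrum per cell (see [average_to_scrs()]); `normalized`
#' records whether rows have been vector-normalized to unit L2 norm.
#'
#' @param wavenumbers Axis (cm^-1).
#' @param intensities Matrix, one row per cell.
#' @param meta Data frame with columns `cell_id`, `subject_id`,
#'   `n_acquisitions` (integer >= 1).
#' @param normalized Logical flag.
#' @return Object of class `scrs_set`.
#' @export
scrs_set <- function(wavenumbers, intensities, meta, normalized = FALSE) {
  check_axis(wavenumbers)
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(wavenumbers))
    stop("intensity columns must match axis length")
  need <- c("cell_id", "subject_id", "n_acquisitions")
  if (!is.data.frame(meta) || !all(need %in% names(meta)))
    stop("meta must contain cell_id, subject_id, n_acquisitions")
  if (nrow(meta) != nrow(intensities))
    stop("meta rows must match intensity rows")
  if (nrow(meta) > 0 && any(meta$n_acquisitions < 1))
    stop("n_acquisitions must be >= 1")
  if (anyDuplicated(meta$cell_id)) stop("duplicate cell_id")
  structure(list(wavenumbers = as.numeric(wavenumbers),
                 intensities = unname(intensities),
                 meta = meta, normalized = isTRUE(normalized)),
            class = "scrs_set")
}

#' @export
print.scrs_set <- function(x, ...) {
  cat(sprintf("scrs_set: %d cells x %d channels, %d subjects%s\n",
              nrow(x$intensities), length(x$wavenumbers),
              length(unique(x$meta$subject_id)),
              if (x$normalized) ", vector-normalized" else ""))
  invisible(x)
}

# channels whose wavenumber lies in [lo, hi]
channels_in <- function(wavenumbers, lo, hi) {
  which(wavenumbers >= lo & wavenumbers <= hi)
}
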