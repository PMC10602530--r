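#' Write spectra to a delimited text file
#'
#' Two interchange layouts are supported. `wide`: first column `wavenumber`,
#' one column per acquisition headed `subject:cell:acq`. `long`: columns
#' `subject_id, cell_id, acquisition_id, wavenumber, intensity`. The delimiter
#' is chosen from the file extension (`.tsv` = tab, otherwise comma). Values
#' are written with 15 significant digits so a write/read round trip is
#' lossless to better than 1e-9 relative.
#'
#' @param x A [spectra_set].
#' @param path Output file path.
#' @param format `"wide"` or `"long"`.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(x, path, format = c("wide", "long")) {
  format <- match.arg(format)
  stopifnot(inherits(x, "spectra_set"))
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  if (format == "wide") {
    df <- data.frame(wavenumber = x$wavenumbers, check.names = FALSE)
    vals <- t(x$intensities)
    colnames(vals) <- spectrum_keys(x$meta)
    df <- cbind(df, as.data.frame(vals, check.names = FALSE))
  } else {
    n <- nrow(x$intensities); p <- length(x$wavenumbers)
    df <- data.frame(
      subject_id = rep(x$meta$subject_id, each = p),
      cell_id = rep(x$meta$cell_id, each = p),
      acquisition_id = rep(x$meta$acquisition_id, each = p),
      wavenumber = rep(x$wavenumbers, times = n),
      intensity = as.vector(t(x$intensities)),
      stringsAsFactors = FALSE)
  }
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) format(v, digits = 15, scientific = TRUE, trim = TRUE))
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read spectra from a delimited text file
#'
#' Inverse of [write_spectra()]; see that help page for the layouts. The axis
#' is checked for strict monotonicity and duplicate acquisition keys are
#' rejected.
#'
#' @param path File path (`.csv` or `.tsv`).
#' @param format `"wide"` or `"long"`.
#' @return A [spectra_set].
#' @export
read_spectra <- function(path, format = c("wide", "long")) {
  format <- match.arg(format)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (format == "wide") {
    if (names(df)[1] != "wavenumber") stop("wide format requires a leading wavenumber column")
    wn <- as.numeric(df[[1]])
    check_axis(wn)
    keys <- names(df)[-1]
    parts <- strsplit(keys, ":", fixed = TRUE)
    if (any(lengths(parts) != 3)) stop("column headers must be subject:cell:acq")
    meta <- data.frame(subject_id = vapply(parts, `[`, "", 1),
                       cell_id = vapply(parts, `[`, "", 2),
                       acquisition_id = vapply(parts, `[`, "", 3),
                       stringsAsFactors = FALSE)
    ints <- t(as.matrix(df[, -1, drop = FALSE]))
    spectra_set(wn, ints, meta)
  } else {
    need <- c("subject_id", "cell_id", "acquisition_id", "wavenumber", "intensity")
    if (!all(need %in% names(df))) stop("long format requires columns ", paste(need, collapse = ", "))
    key <- paste(df$subject_id, df$cell_id, df$acquisition_id, sep = ":")
    ukey <- unique(key)
    first <- key == ukey[1]
    wn <- df$wavenumber[first]
    check_axis(wn)
    p <- length(wn)
    if (nrow(df) != p * length(ukey)) stop("ragged long-format file")
    ord <- order(match(key, ukey))
    df <- df[ord, ]
    if (!all(abs(df$wavenumber - rep(wn, length(ukey))) < 1e-9))
      stop("inconsistent wavenumber grids across spectra")
    ints <- matrix(df$intensity, nrow = length(ukey), ncol = p, byrow = TRUE)
    parts <- strsplit(ukey, ":", fixed = TRUE)
    meta <- data.frame(subject_id = vapply(parts, `[`, "", 1),
                       cell_id = vapply(parts, `[`, "", 2),
                       acquisition_id = vapply(parts, `[`, "", 3),
                       stringsAsFactors = FALSE)
    spectra_set(wn, ints, meta)
  }
}

#' Resample spectra onto a target axis
#'
#' Linear interpolation channel-by-channel. Target channels outside the source
#' range are filled with the nearest edge value and flagged in the returned
#' object's `qc_flags` attribute. At least two target channels must fall inside
#' the source range.
#'
#' @param x A [spectra_set] (or a single numeric spectrum with attribute-free
#'   handling via `axis`).
#' @param target Target wavenumber axis.
#' @return A [spectra_set] on `target`.
#' @export
resample_to_axis <- function(x, target) {
  stopifnot(inherits(x, "spectra_set"))
  check_axis(target)
  src <- x$wavenumbers
  inside <- target >= src[1] & target <= src[length(src)]
  if (sum(inside) < 2) stop("axes overlap in fewer than 2 channels")
  if (isTRUE(all.equal(src, as.numeric(target)))) return(x)
  ints <- t(apply(x$intensities, 1, function(y)
    stats::approx(src, y, xout = target, rule = 2)$y))
  if (nrow(x$intensities) == 1) ints <- matrix(ints, nrow = 1)
  out <- spectra_set(target, ints, x$meta)
  attr(out, "qc_flags") <- if (any(!inside)) "edge_filled" else character(0)
  out
}

#' Write / read a cohort manifest
#'
#' Manifest schema: one row per subject with `subject_id`, `group`, `severity`,
#' demographic and clinical covariates (sex, age, bmi, disease_duration,
#' medication flags, fss, sf36_pf).
#'
#' @param subjects Data frame of subjects.
#' @param path CSV path.
#' @return `path` (write) or the data frame (read).
#' @export
write_manifest <- function(subjects, path) {
  utils::write.csv(subjects, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write / read an ordinal symptom table
#'
#' Subjects in rows, symptom variables in columns; entries 0--3, blank cells
#' encode missing data.
#'
#' @param symptoms Integer matrix with rownames = subject ids.
#' @param path CSV path.
#' @return `path` (write) or the matrix (read).
#' @export
write_symptoms <- function(symptoms, path) {
  df <- as.data.frame(symptoms)
  df <- cbind(subject_id = rownames(symptoms), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' @rdname write_symptoms
#' @export
read_symptoms <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$subject_id
  storage.mode(m) <- "integer"
  m
}
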