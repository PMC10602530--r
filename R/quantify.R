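#' Raman band registry
#'
#' Band definitions used for relative metabolite quantification. The default
#' (`profile = "single"`) quantifies each biomolecule at its single
#' characteristic wavenumber: tryptophan 758, tyrosine 860, phenylalanine
#' 1003, glycerol 1114, unsaturated fatty acids 3010, cholesterol/cholesteryl
#' esters 617, glycogen 485 and glucose 405 cm^-1, each integrated over a
#' window of `half_width` cm^-1 on either side. The `"methods"` profile keeps
#' the alternate multi-band definitions for the aromatic amino acids
#' (tryptophan 758, 880, 1013, 1550 and the 1022--1036 range; phenylalanine
#' 1003 and 1032; tyrosine 642, 830, 850).
#'
#' @param profile `"single"` or `"methods"`.
#' @param half_width Half window around point centers (cm^-1), default 8.
#' @return Named list of band definitions; each has `name`, `centers`
#'   (numeric), `ranges` (2-column matrix of start/end, possibly 0 rows) and
#'   `half_width`.
#' @export
band_registry <- function(profile = c("single", "methods"), half_width = 8) {
  profile <- match.arg(profile)
  if (half_width <= 0) stop("half_width must be > 0")
  mk <- function(name, centers, ranges = NULL) {
    list(name = name, centers = centers,
         ranges = if (is.null(ranges)) matrix(numeric(0), 0, 2) else ranges,
         half_width = half_width)
  }
  if (profile == "single") {
    defs <- list(
      mk("tryptophan", 758), mk("tyrosine", 860), mk("phenylalanine", 1003),
      mk("glycerol", 1114), mk("unsat_fa", 3010), mk("cholesterol", 617),
      mk("glycogen", 485), mk("glucose", 405))
  } else {
    defs <- list(
      mk("tryptophan", c(758, 880, 1013, 1550), matrix(c(1022, 1036), 1)),
      mk("phenylalanine", c(1003, 1032)),
      mk("tyrosine", c(642, 830, 850)))
  }
  names(defs) <- vapply(defs, `[[`, "", "name")
  defs
}

#' Integrate a Raman band in one spectrum
#'
#' For every point center the window is `center +/- half_width`; explicit
#' ranges are used as-is. Within each window a straight chord joining the
#' window's endpoint intensities is subtracted (local background) and the
#' remainder is integrated by the trapezoid rule over wavenumber; the band
#' value is the sum over the band's windows. A constant spectrum therefore
#' integrates to zero.
#'
#' @param y Numeric spectrum (typically one SCRS row).
#' @param wavenumbers Axis matching `y`.
#' @param band One element of [band_registry()].
#' @return Integrated intensity (a.u. cm^-1).
#' @export
integrate_band <- function(y, wavenumbers, band) {
  windows <- rbind(cbind(band$centers - band$half_width,
                         band$centers + band$half_width),
                   band$ranges)
  total <- 0
  for (w in seq_len(nrow(windows))) {
    idx <- channels_in(wavenumbers, windows[w, 1], windows[w, 2])
    if (length(idx) < 3) stop("window narrower than 3 channels")
    wx <- wavenumbers[idx]; wy <- y[idx]
    chord <- wy[1] + (wy[length(wy)] - wy[1]) *
      (wx - wx[1]) / (wx[length(wx)] - wx[1])
    v <- wy - chord
    total <- total + sum(diff(wx) * (v[-length(v)] + v[-1]) / 2)
  }
  total
}

#' Quantify all registry bands across an SCRS collection
#'
#' @param scrs An [scrs_set].
#' @param bands A [band_registry()] list.
#' @param groups Optional named vector or data frame mapping `subject_id` to
#'   group (e.g. the cohort manifest); adds a `group` column.
#' @return Long data frame: `cell_id`, `subject_id`, `group` (if available),
#'   `band`, `intensity`.
#' @export
quantify_bands <- function(scrs, bands = band_registry(), groups = NULL) {
  stopifnot(inherits(scrs, "scrs_set"))
  wn <- scrs$wavenumbers
  out <- do.call(rbind, lapply(bands, function(b) {
    vals <- apply(scrs$intensities, 1, integrate_band, wavenumbers = wn, band = b)
    data.frame(cell_id = scrs$meta$cell_id, subject_id = scrs$meta$subject_id,
               band = b$name, intensity = as.numeric(vals),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  if (!is.null(groups)) {
    if (is.data.frame(groups))
      groups <- stats::setNames(as.character(groups$group), groups$subject_id)
    out$group <- unname(groups[out$subject_id])
  }
  out
}

star_code <- function(p) {
  ifelse(p < 1e-4, "****", ifelse(p < 1e-3, "***", ifelse(p < 0.01, "**", "ns")))
}

#' Welch comparisons of band intensities against a reference group
#'
#' For each band, every non-reference group's sample mean is compared with the
#' reference (healthy controls by default) using Welch's two-sample t-test for
#' unequal variances, with Welch--Satterthwaite degrees of freedom. Star codes
#' follow the convention ns: p >= 0.01; **: p < 0.01; ***: p < 0.001;
#' ****: p < 0.0001.
#'
#' @param quant Output of [quantify_bands()] including a `group` column.
#' @param reference Reference group label, default `"HC"`.
#' @return Data frame: band, group, reference and group means, t, df,
#'   two-sided p, star code.
#' @export
group_compare <- function(quant, reference = "HC") {
  if (!"group" %in% names(quant)) stop("quant must contain a group column")
  if (!reference %in% quant$group) stop("reference group absent")
  rows <- list()
  for (b in unique(quant$band)) {
    qb <- quant[quant$band == b, ]
    ref <- qb$intensity[qb$group == reference]
    for (g in setdiff(unique(qb$group), reference)) {
      x <- qb$intensity[qb$group == g]
      if (length(x) < 2 || length(ref) < 2) stop("each group needs n >= 2")
      if (stats::var(x) == 0 && stats::var(ref) == 0)
        stop("zero variance in both groups")
      tt <- stats::t.test(x, ref, var.equal = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        band = b, group = g, reference = reference,
        mean_group = mean(x), mean_reference = mean(ref),
        t = unname(tt$statistic), df = unname(tt$parameter),
        p = tt$p.value, stars = star_code(tt$p.value),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Per-group mean/SD spectra and fluctuation summaries
#'
#' The cell-to-cell fluctuation of a group is the channel-wise sample standard
#' deviation; its summary is `fluctuation_sum = 100 * sum(SD) / sum(|mean|)`
#' (percent), invariant under uniform rescaling of all spectra.
#'
#' @param scrs An [scrs_set].
#' @param groups Named vector or manifest data frame mapping subjects to groups.
#' @return List of class `group_spectrum_summary`, one element per group with
#'   `mean`, `sd` (numeric spectra) and `fluctuation_sum` (percent).
#' @export
group_spectrum_summary <- function(scrs, groups) {
  stopifnot(inherits(scrs, "scrs_set"))
  if (is.data.frame(groups))
    groups <- stats::setNames(as.character(groups$group), groups$subject_id)
  g <- unname(groups[scrs$meta$subject_id])
  out <- lapply(unique(g), function(gi) {
    m <- scrs$intensities[g == gi, , drop = FALSE]
    if (nrow(m) < 2) stop("group ", gi, " has fewer than 2 cells")
    mu <- colMeans(m)
    sdv <- apply(m, 2, stats::sd)
    list(group = gi, mean = mu, sd = sdv,
         fluctuation_sum = 100 * sum(sdv) / sum(abs(mu)))
  })
  names(out) <- unique(g)
  class(out) <- "group_spectrum_summary"
  out
}

#' @export
print.group_spectrum_summary <- function(x, ...) {
  for (g in names(x))
    cat(sprintf("%-8s fluctuation sum %.1f%%\n", g, x[[g]]$fluctuation_sum))
  invisible(x)
}

#' Difference spectrum between two group means
#'
#' @param group_mean,reference_mean Numeric spectra on the same axis.
#' @return Channel-wise difference (`group_mean - reference_mean`); the
#'   reference appears as the zero line.
#' @export
difference_spectrum <- function(group_mean, reference_mean) {
  if (length(group_mean) != length(reference_mean)) stop("axis mismatch")
  group_mean - reference_mean
}
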