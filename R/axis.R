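#' Construct the canonical wavenumber axis
#'
#' Builds a uniformly spaced Raman shift axis including both endpoints. The
#' default arguments reproduce the analysis grid used throughout the package:
#' 1019 channels spanning 319--3401 cm\eqn{^{-1}} (step \eqn{\approx} 3.027
#' cm\eqn{^{-1}}). Instrument grids quoted as 320--3400 cm\eqn{^{-1}} are
#' accepted on input and harmonized via [resample_to_axis()].
#'
#' @param start First wavenumber (cm^-1).
#' @param end Last wavenumber (cm^-1); must exceed `start`.
#' @param n_channels Number of channels (>= 2).
#' @return Numeric vector of length `n_channels`, strictly increasing.
#' @examples
#' ax <- make_canonical_axis()
#' length(ax)            # 1019
#' diff(ax)[1]           # ~3.027
#' @export
make_canonical_axis <- function(start = 319, end = 3401, n_channels = 1019) {
  if (!is.numeric(start) || !is.numeric(end) || end <= start)
    stop("axis end must exceed start")
  n_channels <- as.integer(n_channels)
  if (is.na(n_channels) || n_channels < 2)
    stop("n_channels must be an integer >= 2")
  seq(start, end, length.out = n_channels)
}

# strictly increasing finite axis check, shared by readers/constructors
check_axis <- function(wavenumbers) {
  if (!is.numeric(wavenumbers) || length(wavenumbers) < 2)
    stop("axis must be a numeric vector of length >= 2")
  if (any(!is.finite(wavenumbers))) stop("axis contains non-finite values")
  if (any(diff(wavenumbers) <= 0)) stop("axis must be strictly increasing")
  invisible(wavenumbers)
}
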