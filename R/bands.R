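#' Canonical EEG frequency bands
#'
#' The six-band scheme used for all spectral features: delta (1-4), theta
#' (4-8), alpha (8-12), beta (12-25), high beta (25-30) and gamma
#' (30-40) Hz. Bands are half-open intervals `[low, high)` on the analysis
#' frequency grid, so shared edges belong to exactly one band.
#'
#' @return A tibble with columns `band` (factor in canonical order), `low`
#'   and `high` in Hz.
#' @examples
#' qeeg_bands()
#' @export
qeeg_bands <- function() {
  tibble::tibble(
    band = factor(band_names(), levels = band_names()),
    low  = c(1, 4, 8, 12, 25, 30),
    high = c(4, 8, 12, 25, 30, 40)
  )
}

band_names <- function() {
  c("delta", "theta", "alpha", "beta", "high_beta", "gamma")
}

band_limits <- function(band) {
  bands <- qeeg_bands()
  row <- bands[bands$band == band, ]
  if (nrow(row) != 1) {
    qeeg_abort(paste0("unknown band: ", band), "qeeg_error_domain")
  }
  c(low = row$low, high = row$high)
}

# Indices of frequency-grid bins falling in [low, high).
band_bin_index <- function(bin_freqs, band) {
  lim <- band_limits(band)
  if (lim["low"] < min(bin_freqs) || lim["high"] > max(bin_freqs) + 1e-9) {
    qeeg_abort(
      paste0("band ", band, " outside the ", min(bin_freqs), "-",
             max(bin_freqs), " Hz analysis grid"),
      "qeeg_error_domain"
    )
  }
  which(bin_freqs >= lim["low"] - 1e-9 & bin_freqs < lim["high"] - 1e-9)
}
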