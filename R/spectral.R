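#' Sliding-window FFT cross-spectrum
#'
#' Accumulates tapered 256-point FFT auto- and cross-spectral sums over
#' windows advanced in 64-point steps (75% overlap) across every
#' artifact-free span of the recording. With the default 2-s window at
#' 128 samples/s the frequency grid has 0.5 Hz resolution and is retained
#' over 0.5-40 Hz. Windows never straddle rejected epochs: the sliding
#' sequence restarts at each accepted span.
#'
#' For channels x, y with per-window cosine/sine coefficients
#' a(x), b(x), u(y), v(y) at frequency f, the object stores the sums over
#' the N windows of a(x)^2+b(x)^2 (auto power) and of the real and
#' imaginary cross terms a(x)u(y)+b(x)v(y) and a(x)v(y)-b(x)u(y), from
#' which band power and magnitude-squared coherence are computed.
#'
#' @param rec An [eeg_recording()] at 128 samples/s, screened or clean,
#'   with at least 60 s of accepted data.
#' @param window_len FFT window length in samples (power of two). Default 256.
#' @param step Window advance in samples. Default 64.
#' @param taper `"hann"` (cosine taper, the default) or `"rect"`.
#' @param min_accepted_s Minimum accepted duration required, seconds.
#' @param pairs Accumulate the pairwise cross terms? Setting `FALSE` keeps
#'   only the auto-power sums (sufficient for band power) and makes
#'   coherence unavailable.
#' @return An object of class `cross_spectrum`.
#' @export
sliding_cross_spectrum <- function(rec, window_len = 256, step = 64,
                                   taper = c("hann", "rect"),
                                   min_accepted_s = 60, pairs = TRUE) {
  stopifnot(inherits(rec, "eeg_recording"))
  taper <- match.arg(taper)
  if (abs(rec$rate - 128) > 1e-9) {
    qeeg_abort("cross-spectral analysis expects a 128 samples/s recording; resample first",
               "qeeg_error_validation")
  }
  L <- as.integer(window_len)
  if (L < 2 || bitwAnd(L, L - 1L) != 0) {
    qeeg_abort("window_len must be a power of two", "qeeg_error_validation")
  }
  if (step < 1 || step > L) {
    qeeg_abort("step must be in [1, window_len]", "qeeg_error_validation")
  }
  spans <- accepted_spans(rec)
  acc_samples <- if (nrow(spans)) sum(spans[, "end"] - spans[, "start"] + 1) else 0
  if (acc_samples < min_accepted_s * rec$rate) {
    qeeg_abort(sprintf("accepted duration %.1f s < %g s required",
                       acc_samples / rec$rate, min_accepted_s),
               "qeeg_error_insufficient_data")
  }
  w <- if (taper == "hann") 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L) else rep(1, L)
  df <- rec$rate / L
  n_bin <- as.integer(floor(40 / df + 1e-9))
  bin_freqs <- (1:n_bin) * df
  C <- nrow(rec$data)
  want_pairs <- isTRUE(pairs)
  pairs <- channel_pairs(rec$montage)
  starts <- unlist(lapply(seq_len(nrow(spans)), function(s) {
    span_len <- spans[s, "end"] - spans[s, "start"] + 1
    if (span_len < L) return(integer(0))
    spans[s, "start"] + seq(0, span_len - L, by = step)
  }))
  N <- length(starts)
  if (N == 0L) {
    qeeg_abort("no accepted span long enough for a single FFT window",
               "qeeg_error_insufficient_data")
  }
  # batch all windows x channels through one FFT call: columns of Y are the
  # tapered 256-sample series, window-major within channel
  idx <- outer(0:(L - 1), starts, "+")           # L x N sample indices
  Y <- t(rec$data)[as.vector(idx), , drop = FALSE]
  dim(Y) <- c(L, N * C)
  X <- stats::mvfft(Y * w)[2:(n_bin + 1), , drop = FALSE]  # bins x (N*C)
  P <- Re(X)^2 + Im(X)^2
  auto <- vapply(seq_len(C), function(ch) {
    cols <- ((ch - 1) * N + 1):(ch * N)
    if (N == 1) P[, cols] else rowSums(P[, cols, drop = FALSE])
  }, numeric(n_bin))
  if (n_bin == 1) auto <- matrix(auto, 1, C)
  cross <- matrix(0 + 0i, if (want_pairs) n_bin else 0, nrow(pairs))
  if (want_pairs) {
    flat <- (pairs$j - 1L) * C + pairs$i          # upper-triangle positions
    for (k in seq_len(n_bin)) {
      Xk <- matrix(X[k, ], N, C)                  # windows x channels
      Ck <- Conj(t(Conj(Xk)) %*% Xk)              # Ck[i,j] = sum_w Xi * Conj(Xj)
      cross[k, ] <- Ck[flat]
    }
  }
  structure(
    list(
      bin_freqs = bin_freqs, n_windows = N,
      auto_power = auto, cross_real = Re(cross), cross_imag = Im(cross),
      pairs = pairs, montage = rec$montage, subject_id = rec$subject_id,
      window_len = L, step = as.integer(step), rate = rec$rate,
      taper = taper, sum_w2 = sum(w^2)
    ),
    class = "cross_spectrum"
  )
}

#' @export
print.cross_spectrum <- function(x, ...) {
  cat("<cross_spectrum> ", x$subject_id, ": ", length(x$montage),
      " channels, ", x$n_windows, " windows of ", x$window_len,
      " samples (step ", x$step, "), bins ", min(x$bin_freqs), "-",
      max(x$bin_freqs), " Hz\n", sep = "")
  invisible(x)
}

# Scale factor turning accumulated |X|^2 sums into band power in uV^2:
# averages over windows, removes taper power, and applies the one-sided
# 2/L periodogram normalisation so that summing over all bins recovers the
# signal variance (Parseval).
psd_scale <- function(cs) 2 / (cs$window_len * cs$sum_w2 * cs$n_windows)

#' Absolute band power
#'
#' Band power in microvolts squared for one channel: the mean over windows
#' of the tapered periodogram, summed over the frequency bins falling in
#' `[low, high)`. Summed over all six bands this approximates the signal
#' variance within 1-40 Hz (Parseval, taper-corrected).
#'
#' @param cs A [sliding_cross_spectrum()] result.
#' @param channel Montage channel label.
#' @param band Band name (see [qeeg_bands()]).
#' @return Band power, a non-negative scalar in uV^2.
#' @export
band_psd <- function(cs, channel, band) {
  stopifnot(inherits(cs, "cross_spectrum"))
  ch <- match_channel(cs, channel)
  bins <- band_bin_index(cs$bin_freqs, band)
  psd_scale(cs) * sum(cs$auto_power[bins, ch])
}

match_channel <- function(cs, channel) {
  ch <- match(normalize_channel_labels(channel, cs$montage), as.character(cs$montage))
  if (anyNA(ch)) {
    qeeg_abort(paste0("unknown channel: ", paste(channel[is.na(ch)], collapse = ", ")),
               "qeeg_error_validation")
  }
  ch
}

#' Magnitude-squared coherence between two channels
#'
#' Per frequency bin, with sums taken over the N sliding windows,
#' \deqn{coh(f) = \frac{(\sum a(x)u(y)+b(x)v(y))^2 + (\sum a(x)v(y)-b(x)u(y))^2}
#'   {\sum(a(x)^2+b(x)^2)\,\sum(u(y)^2+v(y)^2)}}
#' and the band value is the unweighted mean of `coh(f)` over the bins in
#' `[low, high)`. The value is symmetric in the two channels and lies in
#' `[0, 1]`. Bins at which either channel has exactly zero accumulated
#' power are excluded from the band mean; if every bin of the band is
#' degenerate the coherence is undefined and an error is raised.
#'
#' @param cs A [sliding_cross_spectrum()] result.
#' @param pair Character vector of two distinct montage channel labels.
#' @param band Band name.
#' @return Band coherence in `[0, 1]`.
#' @export
coherence <- function(cs, pair, band) {
  stopifnot(inherits(cs, "cross_spectrum"), length(pair) == 2)
  ch <- match_channel(cs, pair)
  if (ch[1] == ch[2]) {
    qeeg_abort("coherence requires two distinct channels", "qeeg_error_validation")
  }
  check_cross_available(cs)
  ij <- sort(ch)
  p <- which(cs$pairs$i == ij[1] & cs$pairs$j == ij[2])
  bins <- band_bin_index(cs$bin_freqs, band)
  num <- cs$cross_real[bins, p]^2 + cs$cross_imag[bins, p]^2
  den <- cs$auto_power[bins, ij[1]] * cs$auto_power[bins, ij[2]]
  ok <- den > 0
  if (!any(ok)) {
    qeeg_abort(
      sprintf("coherence undefined for pair %s-%s in band %s: zero power at every bin",
              pair[1], pair[2], band),
      "qeeg_error_undefined_coherence"
    )
  }
  mean(pmin(num[ok] / den[ok], 1))
}

# All-channel / all-pair band aggregates, vectorised over the stored sums.
# These back the per-subject feature extraction.
band_psd_matrix <- function(cs) {
  bands <- qeeg_bands()
  out <- vapply(as.character(bands$band), function(b) {
    bins <- band_bin_index(cs$bin_freqs, b)
    psd_scale(cs) * colSums(cs$auto_power[bins, , drop = FALSE])
  }, numeric(length(cs$montage)))
  rownames(out) <- as.character(cs$montage)
  out  # channels x bands
}

check_cross_available <- function(cs) {
  if (nrow(cs$cross_real) == 0) {
    qeeg_abort("cross terms were not accumulated (pairs = FALSE); coherence unavailable",
               "qeeg_error_validation")
  }
}

band_coherence_matrix <- function(cs) {
  check_cross_available(cs)
  bands <- qeeg_bands()
  den_all <- cs$auto_power[, cs$pairs$i, drop = FALSE] *
    cs$auto_power[, cs$pairs$j, drop = FALSE]
  num_all <- cs$cross_real^2 + cs$cross_imag^2
  out <- vapply(as.character(bands$band), function(b) {
    bins <- band_bin_index(cs$bin_freqs, b)
    num <- num_all[bins, , drop = FALSE]
    den <- den_all[bins, , drop = FALSE]
    ok <- den > 0
    if (!all(colSums(ok) > 0)) {
      bad <- which(colSums(ok) == 0)[1]
      qeeg_abort(
        sprintf("coherence undefined for pair %s-%s in band %s",
                cs$pairs$chan_i[bad], cs$pairs$chan_j[bad], b),
        "qeeg_error_undefined_coherence"
      )
    }
    coh <- pmin(num / den, 1)
    coh[!ok] <- NA
    colMeans(coh, na.rm = TRUE)
  }, numeric(nrow(cs$pairs)))
  rownames(out) <- paste(cs$pairs$chan_i, cs$pairs$chan_j, sep = "_")
  out  # pairs x bands
}

#' Tidy a cross-spectrum into a columnar table
#'
#' @param x A `cross_spectrum`.
#' @param ... Unused.
#' @return A tibble with columns `subject`, `target` (channel or pair),
#'   `bin_hz`, `statistic` (`auto_power`, `cross_real`, `cross_imag`) and
#'   `value` (raw accumulated sums).
#' @export
as_tibble.cross_spectrum <- function(x, ...) {
  chans <- as.character(x$montage)
  pair_lab <- paste(x$pairs$chan_i, x$pairs$chan_j, sep = "_")
  # expand_grid varies bin_hz fastest, matching column-major stacking of the
  # bins-x-targets sum matrices
  dplyr::bind_rows(
    tidyr::expand_grid(target = chans, bin_hz = x$bin_freqs) |>
      dplyr::mutate(statistic = "auto_power", value = as.vector(x$auto_power)),
    tidyr::expand_grid(target = pair_lab, bin_hz = x$bin_freqs) |>
      dplyr::mutate(statistic = "cross_real", value = as.vector(x$cross_real)),
    tidyr::expand_grid(target = pair_lab, bin_hz = x$bin_freqs) |>
      dplyr::mutate(statistic = "cross_imag", value = as.vector(x$cross_imag))
  ) |>
    dplyr::mutate(subject = x$subject_id, .before = 1)
}
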