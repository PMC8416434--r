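#' Down-sample a recording with anti-alias filtering
#'
#' Decimates each channel to the target rate after FIR low-pass filtering
#' (zero-phase, cutoff at the new Nyquist frequency). Only down-sampling is
#' supported; integer rate ratios use direct decimation and non-integer
#' ratios use rational polyphase resampling. The per-channel mean (DC
#' level) is restored exactly after filtering.
#'
#' @param rec An [eeg_recording()].
#' @param target_rate Target sampling rate, samples/s. Default 128.
#' @return An [eeg_recording()] at `target_rate`.
#' @export
resample_to_rate <- function(rec, target_rate = 128) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (target_rate > rec$rate) {
    qeeg_abort(
      sprintf("up-sampling (%g -> %g Hz) is not supported", rec$rate, target_rate),
      "qeeg_error_unsupported"
    )
  }
  if (isTRUE(all.equal(target_rate, rec$rate))) return(rec)
  factor <- rec$rate / target_rate
  if (abs(factor - round(factor)) < 1e-9) {
    q <- as.integer(round(factor))
    # linear-phase FIR low-pass at 80% of the new Nyquist, applied forward
    # and backward (zero phase), then take every q-th sample
    fir <- signal::fir1(64, 0.8 / q)
    ds <- t(apply(rec$data, 1, function(x) {
      mu <- mean(x)
      y <- signal::filtfilt(fir, x - mu)
      y[seq(1, length(y), by = q)] + mu
    }))
  } else {
    rr <- rational_ratio(target_rate / rec$rate)
    ds <- t(apply(rec$data, 1, function(x) {
      mu <- mean(x)
      signal::resample(x - mu, rr[1], rr[2]) + mu
    }))
  }
  out <- eeg_recording(ds, rate = target_rate, subject_id = rec$subject_id,
                       montage = rec$montage)
  # restore per-channel DC exactly (filter edge effects can shift it slightly)
  out$data <- out$data - (rowMeans(out$data) - rowMeans(rec$data))
  out
}

rational_ratio <- function(x, max_den = 1024) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    if (p < 1) next
    e <- abs(x - p / q)
    if (e < err - 1e-15) { err <- e; best <- c(as.integer(p), as.integer(q)) }
    if (err < 1e-12) break
  }
  best
}

#' Screen 2-s epochs for amplitude artifacts
#'
#' Marks every contiguous 2-s epoch in which any channel exceeds the
#' amplitude limit (in absolute value) as rejected. The returned recording
#' carries the acceptance mask; downstream spectral analysis slides its FFT
#' windows only within runs of accepted epochs. This is a deliberately
#' generic amplitude-threshold rejector: clinical pipelines typically apply
#' site-specific artifact protocols, for which this is a parameterised
#' stand-in.
#'
#' @param rec An [eeg_recording()] (any duration; at least 60 s must
#'   survive screening).
#' @param amplitude_limit Rejection threshold in microvolts. Default 100.
#' @param min_clean_s Minimum accepted duration, seconds. Default 60.
#' @return The recording with an epoch acceptance mask attached
#'   (`rec$accepted`, one logical per 2-s epoch).
#' @export
reject_artifact_windows <- function(rec, amplitude_limit = 100,
                                    min_clean_s = 60) {
  stopifnot(inherits(rec, "eeg_recording"))
  epoch_len <- as.integer(2 * rec$rate)
  n_epoch <- ncol(rec$data) %/% epoch_len
  if (n_epoch < 1) {
    qeeg_abort("recording shorter than one 2-s epoch", "qeeg_error_insufficient_data")
  }
  accepted <- vapply(seq_len(n_epoch), function(e) {
    cols <- ((e - 1) * epoch_len + 1):(e * epoch_len)
    max(abs(rec$data[, cols])) <= amplitude_limit
  }, logical(1))
  if (sum(accepted) * 2 < min_clean_s) {
    qeeg_abort(
      sprintf("insufficient clean data: %d s accepted < %d s required",
              sum(accepted) * 2L, as.integer(min_clean_s)),
      "qeeg_error_insufficient_clean_data"
    )
  }
  rec$accepted <- accepted
  rec
}

# Runs of accepted 2-s epochs as (start_sample, end_sample) spans.
# An unscreened recording counts as one fully accepted span (trimmed to
# whole epochs).
accepted_spans <- function(rec) {
  epoch_len <- as.integer(2 * rec$rate)
  if (is.null(rec$accepted)) {
    n <- (ncol(rec$data) %/% epoch_len) * epoch_len
    if (n == 0) return(matrix(numeric(0), 0, 2))
    return(matrix(c(1, n), 1, 2, dimnames = list(NULL, c("start", "end"))))
  }
  r <- rle(rec$accepted)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  ok <- r$values
  cbind(start = (starts[ok] - 1) * epoch_len + 1, end = ends[ok] * epoch_len)
}

#' Export the rejection mask
#'
#' Writes rejected epochs as a two-column `(start_s, end_s)` tab-separated
#' table.
#'
#' @param rec A screened [eeg_recording()].
#' @param path Output path.
#' @return A tibble of rejected spans, invisibly (also written to `path`).
#' @export
write_rejection_mask <- function(rec, path) {
  if (is.null(rec$accepted)) {
    qeeg_abort("recording has not been screened; run reject_artifact_windows()",
               "qeeg_error_validation")
  }
  r <- rle(!rec$accepted)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  bad <- r$values
  tab <- tibble::tibble(start_s = (starts[bad] - 1) * 2, end_s = ends[bad] * 2)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(tab)
}
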