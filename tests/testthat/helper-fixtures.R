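# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code; no binary fixtures.

# A 19-channel recording where every channel is the same deterministic
# function or an independent seeded noise draw.
make_recording <- function(duration_s = 60, rate = 128, seed = NULL,
                           signal = NULL, sd = 1, subject_id = "fix") {
  n <- round(duration_s * rate)
  m <- default_montage()
  if (!is.null(signal)) {
    t <- (0:(n - 1)) / rate
    data <- matrix(signal(t), length(m), n, byrow = TRUE)
  } else {
    stopifnot(!is.null(seed))
    set.seed(seed)
    data <- matrix(rnorm(length(m) * n, sd = sd), length(m), n)
  }
  eeg_recording(data, rate = rate, subject_id = subject_id, montage = m)
}

sine_recording <- function(freq, amp = 1, duration_s = 60, rate = 128) {
  make_recording(duration_s, rate,
                 signal = function(t) amp * sin(2 * pi * freq * t))
}

# Brute-force AUC oracle: concordant-pair counting over all case-control
# pairs, ties half-credited.
auc_pairs_oracle <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  tot <- 0
  for (a in cases) for (b in controls) {
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  }
  tot / (length(cases) * length(controls))
}

# Naive cross-spectral oracle: explicit cosine/sine coefficient sums per
# window, no FFT, no vectorisation. Returns sums in the same layout notation
# as the package object for the requested channels.
naive_cross_spectrum <- function(data, rate, window_len, step, hann = TRUE) {
  L <- window_len
  w <- if (hann) 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L) else rep(1, L)
  n_bin <- floor(40 / (rate / L))
  starts <- seq(1, ((ncol(data) %/% (2 * rate)) * 2 * rate) - L + 1, by = step)
  C <- nrow(data)
  a <- array(0, c(n_bin, C, length(starts)))
  b <- array(0, c(n_bin, C, length(starts)))
  for (wi in seq_along(starts)) {
    seg <- data[, starts[wi]:(starts[wi] + L - 1), drop = FALSE]
    for (ch in seq_len(C)) {
      x <- seg[ch, ] * w
      for (k in seq_len(n_bin)) {
        a[k, ch, wi] <- sum(x * cos(2 * pi * k * (0:(L - 1)) / L))
        b[k, ch, wi] <- sum(x * sin(2 * pi * k * (0:(L - 1)) / L))
      }
    }
  }
  auto <- apply(a^2 + b^2, c(1, 2), sum)
  list(
    a = a, b = b, auto = auto,
    cross_real = function(i, j) apply(a[, i, , drop = FALSE] * a[, j, , drop = FALSE] +
                                        b[, i, , drop = FALSE] * b[, j, , drop = FALSE],
                                      1, sum),
    cross_imag = function(i, j) apply(a[, i, , drop = FALSE] * b[, j, , drop = FALSE] -
                                        b[, i, , drop = FALSE] * a[, j, , drop = FALSE],
                                      1, sum)
  )
}

# Small tabular cohort for classifier tests: p noise features, optionally
# one separating feature with effect size d (in SD units).
toy_feature_matrix <- function(n_cases = 50, n_controls = 50, p_noise = 5,
                               d = 0, seed = 1) {
  set.seed(seed)
  n <- n_cases + n_controls
  label <- rep(c(0, 1), c(n_controls, n_cases))
  x <- matrix(rnorm(n * p_noise), n, p_noise)
  colnames(x) <- paste0("noise_", seq_len(p_noise))
  if (d != 0) {
    sig <- rnorm(n) + d * label
    x <- cbind(signal = sig, x)
  }
  fm <- tibble::tibble(subject_id = sprintf("s%03d", seq_len(n)), label = label)
  dplyr::bind_cols(fm, tibble::as_tibble(x))
}

# Long feature table + covariates for grid/sweep tests without EEG
# simulation: every QEEG feature is noise unless listed in `shift`
# (feature name -> additive case effect).
toy_long_features <- function(n_cases, n_controls, shift = NULL, seed = 1) {
  set.seed(seed)
  n <- n_cases + n_controls
  ids <- sprintf("s%03d", seq_len(n))
  label <- rep(c(0, 1), c(n_controls, n_cases))
  pairs <- channel_pairs()
  template <- dplyr::bind_rows(
    tidyr::expand_grid(band = band_names(), channel = as.character(default_montage())) |>
      dplyr::mutate(kind = "psd",
                    feature = paste("psd", band, channel, sep = "_")),
    tidyr::expand_grid(band = band_names(), pr = seq_len(nrow(pairs))) |>
      dplyr::mutate(kind = "coh", chan_i = pairs$chan_i[pr], chan_j = pairs$chan_j[pr],
                    feature = paste("coh", band, chan_i, chan_j, sep = "_")) |>
      dplyr::select(-pr)
  )
  feats <- purrr::map(seq_len(n), function(i) {
    v <- rnorm(nrow(template), sd = 1)
    if (!is.null(shift) && label[i] == 1) {
      hit <- match(names(shift), template$feature)
      v[hit] <- v[hit] + unlist(shift)
    }
    dplyr::mutate(template, subject_id = ids[i], value = v, .before = 1)
  }) |> dplyr::bind_rows()
  covs <- tibble::tibble(
    subject_id = ids, label = label,
    age = runif(n, 20, 40), sex = rbinom(n, 1, 0.5),
    education = runif(n, 12, 18), iq = rnorm(n, 110, 10)
  )
  list(features = feats, covariates = covs)
}

# Minimal single-record EDF writer used only to exercise the reader.
# Writes the 256-byte fixed header, per-signal headers, and one data
# record of 16-bit little-endian samples.
write_minimal_edf <- function(path, data, labels, rate,
                              phys_range = c(-1000, 1000)) {
  ns <- nrow(data)
  n_samp <- ncol(data)
  dur <- n_samp / rate
  pad <- function(x, w) {
    s <- substr(format(x, scientific = FALSE, trim = TRUE), 1, w)
    paste0(s, strrep(" ", w - nchar(s)))
  }
  con <- file(path, open = "wb")
  on.exit(close(con))
  wr <- function(s) writeBin(charToRaw(s), con)
  wr(pad("0", 8)); wr(pad("testsubj", 80)); wr(pad("testrec", 80))
  wr(pad("01.01.20", 8)); wr(pad("00.00.00", 8))
  wr(pad(256 + ns * 256, 8)); wr(pad("", 44))
  wr(pad(1, 8)); wr(pad(dur, 8)); wr(pad(ns, 4))
  for (l in labels) wr(pad(l, 16))
  for (i in 1:ns) wr(pad("", 80))          # transducer
  for (i in 1:ns) wr(pad("uV", 8))
  for (i in 1:ns) wr(pad(phys_range[1], 8))
  for (i in 1:ns) wr(pad(phys_range[2], 8))
  for (i in 1:ns) wr(pad(-32768, 8))
  for (i in 1:ns) wr(pad(32767, 8))
  for (i in 1:ns) wr(pad("", 80))          # prefiltering
  for (i in 1:ns) wr(pad(n_samp, 8))
  for (i in 1:ns) wr(pad("", 32))
  gain <- (phys_range[2] - phys_range[1]) / 65535
  for (i in 1:ns) {
    dig <- as.integer(round((data[i, ] - phys_range[1]) / gain + (-32768)))
    writeBin(dig, con, size = 2, endian = "little")
  }
  invisible(path)
}
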