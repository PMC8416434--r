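test_that("window count and bin grid follow the 2-s / 64-step / 128 Hz scheme", {
  rec <- make_recording(duration_s = 60, seed = 31)
  cs <- sliding_cross_spectrum(rec)
  expect_equal(cs$n_windows, floor((7680 - 256) / 64) + 1)  # 117
  expect_equal(cs$bin_freqs, seq(0.5, 40, by = 0.5))
  expect_equal(diff(cs$bin_freqs)[1], 128 / 256)
  short <- make_recording(duration_s = 1, seed = 31)
  expect_error(sliding_cross_spectrum(short, min_accepted_s = 0),
               class = "qeeg_error_insufficient_data")
  bad_rate <- make_recording(duration_s = 60, rate = 100, seed = 31)
  expect_error(sliding_cross_spectrum(bad_rate), class = "qeeg_error_validation")
})

test_that("a zero recording accumulates exactly zero sums", {
  rec <- eeg_recording(matrix(0, 19, 7680), 128)
  cs <- sliding_cross_spectrum(rec)
  expect_equal(cs$n_windows, 117)
  expect_true(all(cs$auto_power == 0))
  expect_true(all(cs$cross_real == 0) && all(cs$cross_imag == 0))
  expect_equal(band_psd(cs, "O1", "alpha"), 0)
  expect_error(coherence(cs, c("F3", "P4"), "alpha"),
               class = "qeeg_error_undefined_coherence")
})

test_that("accumulated sums match a naive trigonometric-sum oracle", {
  rec <- make_recording(duration_s = 6, seed = 32)
  cs <- sliding_cross_spectrum(rec, min_accepted_s = 6)
  oracle <- naive_cross_spectrum(rec$data, 128, 256, 64)
  expect_equal(cs$auto_power, oracle$auto, tolerance = 1e-10,
               ignore_attr = TRUE)
  for (pr in c(1, 50, 171)) {
    i <- cs$pairs$i[pr]; j <- cs$pairs$j[pr]
    expect_equal(cs$cross_real[, pr], oracle$cross_real(i, j), tolerance = 1e-10)
    expect_equal(cs$cross_imag[, pr], oracle$cross_imag(i, j), tolerance = 1e-10)
  }
})

test_that("cross sums respect the Cauchy-Schwarz bound", {
  rec <- make_recording(duration_s = 60, seed = 33)
  cs <- sliding_cross_spectrum(rec)
  lhs <- cs$cross_real^2 + cs$cross_imag^2
  rhs <- cs$auto_power[, cs$pairs$i] * cs$auto_power[, cs$pairs$j]
  expect_true(all(lhs <= rhs * (1 + 1e-9)))
})

test_that("a pure tone carries A^2/2 band power confined to its band", {
  rec <- sine_recording(freq = 10, amp = 2)
  cs <- sliding_cross_spectrum(rec)
  alpha <- band_psd(cs, "O1", "alpha")
  expect_equal(alpha, 2^2 / 2, tolerance = 0.05)
  for (b in setdiff(band_names(), "alpha")) {
    expect_lt(band_psd(cs, "O1", b), 0.01 * alpha)
  }
})

test_that("white-noise band powers sum to the 1-40 Hz variance share", {
  rec <- make_recording(duration_s = 300, seed = 34)
  cs <- sliding_cross_spectrum(rec)
  tot <- sum(vapply(band_names(), function(b) band_psd(cs, "Cz", b), numeric(1)))
  # analytic share of unit variance between 1 and 40 Hz
  expect_equal(tot, (40 - 1) / 64, tolerance = 0.05)
  # independent oracle: variance of an FFT-masked band-pass copy
  x <- rec$data[10, ]
  X <- fft(x)
  f <- pmin(0:(length(x) - 1), length(x) - (0:(length(x) - 1))) * 128 / length(x)
  X[f < 1 | f >= 40] <- 0
  oracle_var <- var(Re(fft(X, inverse = TRUE)) / length(x))
  expect_equal(tot, oracle_var, tolerance = 0.05)
})

test_that("band power scales quadratically with amplitude", {
  rec <- make_recording(duration_s = 60, seed = 35)
  rec2 <- rec; rec2$data <- 2 * rec2$data
  cs <- sliding_cross_spectrum(rec); cs2 <- sliding_cross_spectrum(rec2)
  for (b in band_names()) {
    expect_equal(band_psd(cs2, "F7", b), 4 * band_psd(cs, "F7", b),
                 tolerance = 1e-6)
  }
})

test_that("identical signals are perfectly coherent in every powered band", {
  rec <- make_recording(duration_s = 60, seed = 36)
  rec$data[which(rownames(rec$data) == "P4"), ] <-
    rec$data[which(rownames(rec$data) == "F3"), ]
  cs <- sliding_cross_spectrum(rec)
  for (b in band_names()) {
    expect_equal(coherence(cs, c("F3", "P4"), b), 1, tolerance = 1e-9)
  }
})

test_that("a single window makes every pair perfectly coherent (algebraic identity)", {
  rec <- make_recording(duration_s = 2, seed = 37)
  cs <- sliding_cross_spectrum(rec, min_accepted_s = 2)
  expect_equal(cs$n_windows, 1)
  for (pr in c(1, 42, 171)) {
    pair <- c(cs$pairs$chan_i[pr], cs$pairs$chan_j[pr])
    for (b in band_names()) expect_equal(coherence(cs, pair, b), 1, tolerance = 1e-9)
  }
})

test_that("coherence is symmetric and gain-invariant", {
  rec <- make_recording(duration_s = 60, seed = 38)
  cs <- sliding_cross_spectrum(rec)
  expect_identical(coherence(cs, c("F3", "P4"), "theta"),
                   coherence(cs, c("P4", "F3"), "theta"))
  rec5 <- rec
  f3 <- which(rownames(rec5$data) == "F3")
  rec5$data[f3, ] <- 5 * rec5$data[f3, ]
  cs5 <- sliding_cross_spectrum(rec5)
  for (b in band_names()) {
    expect_equal(coherence(cs5, c("F3", "O2"), b), coherence(cs, c("F3", "O2"), b),
                 tolerance = 1e-9)
  }
})

test_that("coherence lies in [0,1] across random recordings", {
  for (s in 1:5) {
    rec <- make_recording(duration_s = 60, seed = 300 + s)
    coh <- qeegclass:::band_coherence_matrix(sliding_cross_spectrum(rec))
    expect_true(all(coh >= 0 & coh <= 1))
  }
})

test_that("a shared band-limited component raises band coherence monotonically", {
  set.seed(39)
  n <- 7680
  bf <- signal::butter(2, c(8, 12) / 64, "pass")
  shared <- signal::filtfilt(bf, rnorm(n))
  shared <- shared / sd(shared)
  base <- make_recording(duration_s = 60, seed = 40)
  coh_at <- function(w) {
    rec <- base
    for (ch in c("O1", "O2")) {
      r <- which(rownames(rec$data) == ch)
      rec$data[r, ] <- rec$data[r, ] + w * shared
    }
    coherence(sliding_cross_spectrum(rec), c("O1", "O2"), "alpha")
  }
  vals <- vapply(c(0.5, 1, 2), coh_at, numeric(1))
  expect_true(all(diff(vals) > 0))
})

test_that("FFT windows restart at artifact boundaries instead of straddling them", {
  rec <- make_recording(duration_s = 64, seed = 41, sd = 10)
  rec$data[5, (15 * 256 + 1):(16 * 256)] <- 400   # reject epoch 16
  screened <- reject_artifact_windows(rec)
  cs <- sliding_cross_spectrum(screened)
  n1 <- floor((15 * 256 - 256) / 64) + 1
  n2 <- floor((16 * 256 - 256) / 64) + 1
  expect_equal(cs$n_windows, n1 + n2)
  # an unscreened copy slides across everything
  expect_equal(sliding_cross_spectrum(rec)$n_windows, floor((8192 - 256) / 64) + 1)
})

test_that("the columnar export tallies with the stored sums", {
  rec <- make_recording(duration_s = 60, seed = 42)
  cs <- sliding_cross_spectrum(rec)
  tab <- tibble::as_tibble(cs)
  expect_equal(nrow(tab), 80 * (19 + 171 * 2))
  row <- tab[tab$target == "Cz" & tab$bin_hz == 10 & tab$statistic == "auto_power", ]
  expect_equal(row$value, cs$auto_power[which(cs$bin_freqs == 10),
                                        which(as.character(cs$montage) == "Cz")])
})
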