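test_that("cohorts have the configured shape and are byte-reproducible", {
  cc <- cohort_config(n_cases = 2, n_controls = 2, seed = 81)
  co <- generate_cohort(cc)
  expect_length(co$recordings, 4)
  for (r in co$recordings) expect_identical(dim(r$data), c(19L, 7680L))
  expect_identical(co$covariates$label, c(0L, 0L, 1L, 1L))
  co2 <- generate_cohort(cc)
  for (i in 1:4) expect_identical(co$recordings[[i]]$data, co2$recordings[[i]]$data)
  expect_identical(co$covariates, co2$covariates)
  # different seed, different data
  co3 <- generate_cohort(cohort_config(2, 2, seed = 82))
  expect_false(identical(co$recordings[[1]]$data, co3$recordings[[1]]$data))
  expect_error(generate_cohort(cohort_config(0, 2)), class = "qeeg_error_validation")
  expect_error(cohort_config(2, 2, duration_s = 30), class = "qeeg_error_validation")
})

test_that("effect specifications validate channels and bands", {
  expect_error(effect_spec(power_effects = data.frame(
    channel = "XX", band = "alpha", multiplier = 2)),
    class = "qeeg_error_validation")
  expect_error(effect_spec(power_effects = data.frame(
    channel = "O1", band = "sigma", multiplier = 2)),
    class = "qeeg_error_validation")
  expect_error(effect_spec(power_effects = data.frame(
    channel = "O1", band = "alpha", multiplier = 0)),
    class = "qeeg_error_validation")
  expect_error(preset_effects("nonexistent"), class = "qeeg_error_validation")
})

test_that("clinical covariate presets shift case covariates as configured", {
  cc <- cohort_config(n_cases = 150, n_controls = 30, seed = 83)
  eff <- preset_effects("schizophrenia_like")
  covs <- qeegclass:::draw_covariates(
    150, cc$control_covariates, eff$covariate_shift,
    qeegclass:::derive_seed(cc$seed, "covariates", "case"))
  expect_equal(mean(covs$iq), 89.62, tolerance = 2 * 17.51 / sqrt(150) / 89.62)
  expect_lt(mean(covs$sex), 0.75)
  expect_true(all(covs$age >= 18 & covs$age <= 70))
  # unshifted cases follow the control (healthy) distributions
  covs_hc <- qeegclass:::draw_covariates(150, cc$control_covariates, NULL, 4)
  expect_equal(mean(covs_hc$iq), 116.24, tolerance = 0.03)
})

test_that("a power multiplier scales case band power by its square", {
  eff <- effect_spec(power_effects = data.frame(channel = "O1", band = "alpha",
                                                multiplier = 2))
  cc <- cohort_config(n_cases = 25, n_controls = 25, seed = 84)
  co <- generate_cohort(cc, eff)
  alpha_o1 <- vapply(co$recordings, function(r) {
    band_psd(sliding_cross_spectrum(r), "O1", "alpha")
  }, numeric(1))
  ratio <- mean(alpha_o1[co$covariates$label == 1]) /
    mean(alpha_o1[co$covariates$label == 0])
  expect_equal(ratio, 4, tolerance = 0.15)
  # untargeted channel unchanged
  alpha_o2 <- vapply(co$recordings, function(r) {
    band_psd(sliding_cross_spectrum(r), "O2", "alpha")
  }, numeric(1))
  ratio_o2 <- mean(alpha_o2[co$covariates$label == 1]) /
    mean(alpha_o2[co$covariates$label == 0])
  expect_equal(ratio_o2, 1, tolerance = 0.15)
})

test_that("coupling raises pair coherence consistently with a direct simulation oracle", {
  zero_amp <- c(delta = 0, theta = 0, alpha = 0, beta = 0, high_beta = 0, gamma = 0)
  cc <- cohort_config(n_cases = 15, n_controls = 15, seed = 85,
                      band_amplitudes = zero_amp, background_1f_scale = 0,
                      sensor_noise_sd = 1)
  eff <- effect_spec(coupling_effects = data.frame(
    chan_i = "O1", chan_j = "O2", band = "alpha", weight = 1))
  co <- generate_cohort(cc, eff)
  coh <- vapply(co$recordings, function(r) {
    coherence(sliding_cross_spectrum(r), c("O1", "O2"), "alpha")
  }, numeric(1))
  case_coh <- coh[co$covariates$label == 1]
  ctrl_coh <- coh[co$covariates$label == 0]
  # brute-force two-channel oracle: shared source built independently by
  # spelling out the oscillator magnitude model (alpha pass-band 9-11 Hz,
  # power-response exponent 8) in fresh code
  set.seed(86)
  n <- 7680
  f <- pmin(0:(n - 1), n - (0:(n - 1))) * 128 / n
  h <- ifelse(f > 0, 1 / sqrt(1 + ((f^2 - 9 * 11) / (f * (11 - 9)))^8), 0)
  h <- h / sqrt(mean(h^2))
  oracle <- replicate(30, {
    s <- Re(fft(fft(rnorm(n)) * h, inverse = TRUE)) / n
    d <- matrix(rnorm(19 * n), 19, n)
    d[18, ] <- d[18, ] + s
    d[19, ] <- d[19, ] + s
    coherence(sliding_cross_spectrum(eeg_recording(d, 128)), c("O1", "O2"), "alpha")
  })
  se <- sqrt(var(oracle) / length(oracle) + var(case_coh) / length(case_coh))
  expect_lt(abs(mean(case_coh) - mean(oracle)), 3 * se)
  # controls sit at the uncoupled baseline, far below the coupled level
  expect_gt(mean(case_coh), 0.5)
  expect_lt(mean(ctrl_coh), 0.1)
})

test_that("uncoupled channels show only finite-window baseline coherence", {
  cc <- cohort_config(n_cases = 10, n_controls = 10, seed = 87)
  co <- generate_cohort(cc)
  coh <- vapply(co$recordings[1:10], function(r) {
    coherence(sliding_cross_spectrum(r), c("F3", "P4"), "alpha")
  }, numeric(1))
  expect_lt(mean(coh), 0.1)
  expect_gt(mean(coh), 0)
})

test_that("classifier AUC grows with the injected effect size", {
  auc_at <- function(mult, seed) {
    cc <- cohort_config(n_cases = 15, n_controls = 15, seed = seed)
    eff <- preset_effects("alpha_posterior", multiplier = mult)
    co <- generate_cohort(cc, eff)
    # generator output carries no artifacts; screening is validated elsewhere
    feats <- cohort_features(co, amplitude_limit = Inf, parameters = "psd")
    fm <- build_feature_matrix(feats$features, feats$covariates,
                               feature_combination("PSD", "alpha"))
    glance(cross_validate(fm, model_spec("en", inner_cv_folds = 3,
                                         en_nlambda = 20, seed = seed)))$mean_auc
  }
  expect_gt(auc_at(2, 88), auc_at(1, 88))
})

test_that("cohorts round-trip through the on-disk CSV manifest layout", {
  cc <- cohort_config(n_cases = 1, n_controls = 1, seed = 89)
  co <- generate_cohort(cc)
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- qeegclass:::load_cohort_manifest(dir)
  expect_length(back$recordings, 2)
  expect_equal(back$recordings[[1]]$data, co$recordings[[1]]$data,
               tolerance = 1e-12)
  expect_equal(back$covariates$iq, co$covariates$iq, tolerance = 1e-6)
})
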