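#' Covariate presets for synthetic cohorts
#'
#' Group-wise demographic distributions (age, sex, years of education,
#' full-scale IQ) used as sampling defaults by [generate_cohort()]. The
#' healthy-control row is the default for control subjects; the clinical
#' rows parameterise case groups in the named presets.
#'
#' @return A tibble with one row per group: means, SDs and the male
#'   proportion.
#' @export
covariate_presets <- function() {
  tibble::tribble(
    ~group,                  ~n,  ~age_mean, ~age_sd, ~male_prop, ~education_mean, ~education_sd, ~iq_mean, ~iq_sd,
    "healthy_control",        95, 25.72,  4.55, 0.632, 14.91, 2.06, 116.24, 10.94,
    "schizophrenia",         117, 31.73, 12.10, 0.556, 12.84, 2.95,  89.62, 17.51,
    "mood",                  266, 30.87, 12.70, 0.568, 13.31, 2.48, 101.58, 15.70,
    "depressive",            199, 31.26, 13.23, 0.548, 13.05, 2.51, 101.85, 15.28,
    "bipolar",                67, 29.71, 11.01, 0.627, 14.11, 2.21, 100.81, 16.98,
    "anxiety",               107, 29.01, 10.56, 0.738, 13.14, 2.42,  98.31, 16.31,
    "panic",                  59, 31.05, 11.30, 0.644, 13.45, 2.91, 100.31, 14.77,
    "social_anxiety",         48, 26.51,  9.09, 0.854, 12.78, 1.60,  95.85, 17.89,
    "obsessive_compulsive",   46, 28.48,  9.83, 0.826, 13.93, 2.33, 107.80, 15.24,
    "addictive",             186, 29.63, 10.89, 0.882, 13.23, 2.53, 103.88, 16.19,
    "alcohol_use",            93, 34.16, 11.88, 0.806, 13.29, 3.07, 103.38, 13.61,
    "behavioral_addiction",   93, 25.09,  7.48, 0.957, 13.16, 1.89, 104.38, 18.49,
    "trauma_stress",         128, 36.09, 13.82, 0.344, 13.57, 2.45,  98.89, 15.86,
    "ptsd",                   52, 42.74, 13.00, 0.269, 13.37, 2.54,  98.90, 15.69,
    "acute_stress",           38, 28.90,  9.05, 0.079, 14.26, 2.27, 104.06, 15.43,
    "adjustment",             38, 34.19, 14.90, 0.750, 13.26, 2.41,  94.24, 15.41
  )
}

#' Specify synthetic group effects
#'
#' Describes how case subjects differ from controls: band-power
#' multipliers at chosen channels, coupling (shared-source) weights at
#' chosen channel pairs, and covariate distribution overrides. A
#' multiplier of 1 and a weight of 0 encode "no effect".
#'
#' @param power_effects Tibble/data frame with columns `channel`, `band`,
#'   `multiplier` (> 0), or NULL.
#' @param coupling_effects Tibble with columns `chan_i`, `chan_j`, `band`,
#'   `weight` (>= 0, in microvolts of shared unit-variance source), or NULL.
#' @param covariate_shift Named list overriding case covariate sampling:
#'   entries `age`, `education`, `iq` as `c(mean, sd)` and `sex` as the
#'   male proportion. NULL means cases share the control distributions.
#' @param montage Montage the channels must belong to.
#' @return An object of class `qeeg_effects`.
#' @export
effect_spec <- function(power_effects = NULL, coupling_effects = NULL,
                        covariate_shift = NULL, montage = default_montage()) {
  chk_band <- function(b) {
    bad <- setdiff(b, band_names())
    if (length(bad)) qeeg_abort(paste0("unknown band(s): ", paste(bad, collapse = ", ")),
                                "qeeg_error_validation")
  }
  chk_chan <- function(ch) {
    if (anyNA(normalize_channel_labels(ch, montage))) {
      bad <- ch[is.na(normalize_channel_labels(ch, montage))]
      qeeg_abort(paste0("unknown channel(s): ", paste(bad, collapse = ", ")),
                 "qeeg_error_validation")
    }
  }
  if (!is.null(power_effects)) {
    power_effects <- tibble::as_tibble(power_effects)
    stopifnot(all(c("channel", "band", "multiplier") %in% names(power_effects)))
    chk_band(power_effects$band); chk_chan(power_effects$channel)
    if (any(power_effects$multiplier <= 0)) {
      qeeg_abort("power multipliers must be > 0", "qeeg_error_validation")
    }
  }
  if (!is.null(coupling_effects)) {
    coupling_effects <- tibble::as_tibble(coupling_effects)
    stopifnot(all(c("chan_i", "chan_j", "band", "weight") %in% names(coupling_effects)))
    chk_band(coupling_effects$band)
    chk_chan(c(coupling_effects$chan_i, coupling_effects$chan_j))
    if (any(coupling_effects$weight < 0)) {
      qeeg_abort("coupling weights must be >= 0", "qeeg_error_validation")
    }
  }
  structure(list(power_effects = power_effects,
                 coupling_effects = coupling_effects,
                 covariate_shift = covariate_shift),
            class = "qeeg_effects")
}

#' Named effect presets
#'
#' `"schizophrenia_like"` (and the other group names of
#' [covariate_presets()] suffixed `_like`) shift case covariates to the
#' corresponding clinical row without any EEG effect.
#' `"alpha_posterior"` multiplies alpha-band power at eight
#' parieto-occipital/midline channels (P7, P3, Pz, P4, P8, O1, O2, Cz) by
#' `multiplier` in cases.
#'
#' @param name Preset name.
#' @param multiplier Power multiplier for `"alpha_posterior"`. Default 1.5.
#' @return A [effect_spec()].
#' @export
preset_effects <- function(name, multiplier = 1.5) {
  if (identical(name, "alpha_posterior")) {
    return(effect_spec(power_effects = tibble::tibble(
      channel = alpha_posterior_channels(), band = "alpha",
      multiplier = multiplier
    )))
  }
  grp <- sub("_like$", "", name)
  row <- covariate_presets()[covariate_presets()$group == grp, ]
  if (nrow(row) != 1) {
    qeeg_abort(paste0("unknown preset: ", name), "qeeg_error_validation")
  }
  effect_spec(covariate_shift = list(
    age = c(row$age_mean, row$age_sd), sex = row$male_prop,
    education = c(row$education_mean, row$education_sd),
    iq = c(row$iq_mean, row$iq_sd)
  ))
}

alpha_posterior_channels <- function() {
  c("P7", "P3", "Pz", "P4", "P8", "O1", "O2", "Cz")
}

#' Configure a synthetic cohort
#'
#' Baseline signal model for every subject: per band, a band-limited
#' Gaussian oscillation (white noise shaped by a zero-phase Butterworth
#' band-pass magnitude response of configurable order, normalised to unit
#' variance and scaled by the band amplitude), plus 1/f (pink) background and
#' independent white sensor noise. Default band amplitudes give an
#' eyes-closed-like spectrum with dominant posterior-style alpha.
#' Control covariates default to the healthy-control preset row.
#'
#' @param n_cases,n_controls Group sizes.
#' @param duration_s Recording length in seconds (>= 60). Default 60.
#' @param rate Sampling rate. Default 128.
#' @param band_amplitudes Named vector of per-band RMS amplitudes (uV).
#' @param background_1f_scale RMS amplitude of the pink background (uV).
#' @param sensor_noise_sd White sensor noise SD (uV).
#' @param pink_exponent Power-spectral exponent of the background. Default 1.
#' @param filter_order Order `n` of the oscillator band-pass magnitude
#'   `1/sqrt(1 + ((f^2 - f0^2)/(f BW))^(2n))`. The default 4 (an
#'   8th-order Butterworth shape) keeps injected band effects confined to
#'   their band; 2 gives a classic 4th-order response with markedly fatter
#'   skirts.
#' @param band_inset Hz by which each oscillator's pass-band edges sit
#'   inside its nominal analysis band (default 1).
#'   Real oscillations peak inside their band rather than filling it
#'   edge-to-edge, and the inset keeps the Hann-window main lobe of the
#'   spectral estimator from smearing an injected band effect into the
#'   first bins of the neighbouring bands.
#' @param control_covariates One row of [covariate_presets()] layout used
#'   for control (and unshifted case) covariate sampling.
#' @param seed Master seed for the cohort.
#' @return An object of class `qeeg_cohort_config`.
#' @export
cohort_config <- function(n_cases, n_controls, duration_s = 60, rate = 128,
                          band_amplitudes = c(delta = 6, theta = 5, alpha = 8,
                                              beta = 4, high_beta = 2, gamma = 1.5),
                          background_1f_scale = 4, sensor_noise_sd = 2,
                          pink_exponent = 1, filter_order = 4,
                          band_inset = 1,
                          control_covariates = covariate_presets()[1, ],
                          seed = 1) {
  if (duration_s < 60) {
    qeeg_abort("duration_s must be at least 60 s", "qeeg_error_validation")
  }
  stopifnot(setequal(names(band_amplitudes), band_names()),
            all(band_amplitudes >= 0), background_1f_scale >= 0,
            sensor_noise_sd >= 0)
  structure(
    list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
         duration_s = duration_s, rate = rate,
         band_amplitudes = band_amplitudes[band_names()],
         background_1f_scale = background_1f_scale,
         sensor_noise_sd = sensor_noise_sd, pink_exponent = pink_exponent,
         filter_order = filter_order, band_inset = band_inset,
         control_covariates = control_covariates, seed = as.integer(seed)),
    class = "qeeg_cohort_config"
  )
}

# Fourth-order Butterworth band-pass magnitude response on the full FFT
# frequency grid (f = 0 maps to 0), normalised to unit noise variance.
butter_bp_response <- function(n, rate, low, high, order = 2) {
  f <- pmin(0:(n - 1), n - (0:(n - 1))) * rate / n
  f0sq <- low * high
  bw <- high - low
  h <- ifelse(f > 0, 1 / sqrt(1 + ((f^2 - f0sq) / (f * bw))^(2 * order)), 0)
  h / sqrt(mean(h^2))
}

pink_response <- function(n, rate, exponent = 1) {
  f <- pmin(0:(n - 1), n - (0:(n - 1))) * rate / n
  h <- ifelse(f > 0, f^(-exponent / 2), 0)
  h / sqrt(mean(h^2))
}

# Per-channel amplitude spectra sqrt(S_c(f)). Because all components are
# independent Gaussian processes, their sum is a single Gaussian process
# whose power spectrum is the sum of the component spectra; each subject
# then needs one white-noise draw and one FFT pair per channel.
channel_amplitude_spectra <- function(config, effects, group, montage) {
  n <- round(config$duration_s * config$rate)
  C <- length(montage)
  bands <- qeeg_bands()
  S <- matrix(config$sensor_noise_sd^2, n, C)
  if (config$background_1f_scale > 0) {
    S <- S + (config$background_1f_scale *
                pink_response(n, config$rate, config$pink_exponent))^2
  }
  inset <- config$band_inset %||% 1
  for (b in seq_len(nrow(bands))) {
    h <- butter_bp_response(n, config$rate,
                            bands$low[b] + inset, bands$high[b] - inset,
                            order = config$filter_order %||% 4)
    amp <- rep(config$band_amplitudes[[as.character(bands$band[b])]], C)
    if (group == "case" && !is.null(effects) && !is.null(effects$power_effects)) {
      pe <- effects$power_effects
      hit <- pe$band == as.character(bands$band[b])
      if (any(hit)) {
        ch <- match(normalize_channel_labels(pe$channel[hit], montage),
                    as.character(montage))
        amp[ch] <- amp[ch] * pe$multiplier[hit]
      }
    }
    S <- S + h^2 %o% amp^2
  }
  sqrt(S)
}

#' Generate one synthetic subject
#'
#' @param config A [cohort_config()].
#' @param effects A [effect_spec()] or NULL; EEG effects apply only when
#'   `group = "case"`.
#' @param group `"control"` or `"case"`.
#' @param subject_seed Integer seed; the recording is a deterministic
#'   function of (config, effects, group, subject_seed).
#' @param subject_id Identifier for the recording.
#' @param montage Channel montage.
#' @return An [eeg_recording()].
#' @export
generate_subject <- function(config, effects = NULL,
                             group = c("control", "case"),
                             subject_seed = 1, subject_id = "synthetic",
                             montage = default_montage(), .spectra = NULL) {
  group <- match.arg(group)
  stopifnot(inherits(config, "qeeg_cohort_config"))
  n <- round(config$duration_s * config$rate)
  C <- length(montage)
  sqrtS <- .spectra %||% channel_amplitude_spectra(config, effects, group, montage)
  x <- with_seed(subject_seed, {
    z <- matrix(rnorm(n * C), n, C)
    xx <- Re(stats::mvfft(stats::mvfft(z) * sqrtS, inverse = TRUE)) / n
    if (group == "case" && !is.null(effects) &&
        !is.null(effects$coupling_effects) && nrow(effects$coupling_effects)) {
      ce <- effects$coupling_effects
      for (r in seq_len(nrow(ce))) {
        lim <- band_limits(ce$band[r])
        inset <- config$band_inset %||% 1
        h <- butter_bp_response(n, config$rate,
                                lim["low"] + inset, lim["high"] - inset,
                                order = config$filter_order %||% 4)
        s <- Re(stats::fft(stats::fft(rnorm(n)) * h, inverse = TRUE)) / n
        ij <- match(normalize_channel_labels(c(ce$chan_i[r], ce$chan_j[r]), montage),
                    as.character(montage))
        xx[, ij[1]] <- xx[, ij[1]] + ce$weight[r] * s
        xx[, ij[2]] <- xx[, ij[2]] + ce$weight[r] * s
      }
    }
    xx
  })
  eeg_recording(t(x), rate = config$rate, subject_id = subject_id,
                montage = montage)
}

draw_covariates <- function(n, preset_row, shift, seed) {
  g <- function(nm, default_mean, default_sd) {
    if (!is.null(shift[[nm]])) shift[[nm]] else c(default_mean, default_sd)
  }
  with_seed(seed, {
    age_p <- g("age", preset_row$age_mean, preset_row$age_sd)
    edu_p <- g("education", preset_row$education_mean, preset_row$education_sd)
    iq_p <- g("iq", preset_row$iq_mean, preset_row$iq_sd)
    male_p <- if (!is.null(shift$sex)) shift$sex[1] else preset_row$male_prop
    tibble::tibble(
      age = pmin(pmax(rnorm(n, age_p[1], age_p[2]), 18), 70),
      sex = rbinom(n, 1, male_p),
      education = pmax(rnorm(n, edu_p[1], edu_p[2]), 6),
      iq = pmax(rnorm(n, iq_p[1], iq_p[2]), 55)
    )
  })
}

#' Generate a synthetic cohort
#'
#' Draws `n_controls` control and `n_cases` case recordings plus a
#' covariate table. Case EEG effects and covariate shifts come from
#' `effects`; without a covariate shift, case covariates follow the
#' control distributions (no covariate-label confounding). Ages are
#' clipped to the 18-70 eligibility window. Byte-identical given the
#' config seed.
#'
#' @param config A [cohort_config()].
#' @param effects A [effect_spec()] or NULL.
#' @param montage Channel montage.
#' @return An object of class `qeeg_cohort`: `recordings` (list of
#'   [eeg_recording()]), `covariates` (tibble with `subject_id`, `label`,
#'   `age`, `sex`, `education`, `iq`), `config`, `effects`.
#' @export
generate_cohort <- function(config, effects = NULL, montage = default_montage()) {
  stopifnot(inherits(config, "qeeg_cohort_config"))
  if (config$n_cases < 1 || config$n_controls < 1) {
    qeeg_abort("both groups need at least one subject", "qeeg_error_validation")
  }
  ids <- c(sprintf("ctrl_%03d", seq_len(config$n_controls)),
           sprintf("case_%03d", seq_len(config$n_cases)))
  groups <- rep(c("control", "case"), c(config$n_controls, config$n_cases))
  spectra <- list(
    control = channel_amplitude_spectra(config, effects, "control", montage),
    case = channel_amplitude_spectra(config, effects, "case", montage)
  )
  recs <- purrr::map(seq_along(ids), function(i) {
    generate_subject(config, effects, groups[i],
                     subject_seed = derive_seed(config$seed, "subject", ids[i]),
                     subject_id = ids[i], montage = montage,
                     .spectra = spectra[[groups[i]]])
  })
  preset <- config$control_covariates
  covs_ctrl <- draw_covariates(config$n_controls, preset, NULL,
                               derive_seed(config$seed, "covariates", "control"))
  covs_case <- draw_covariates(config$n_cases, preset,
                               if (!is.null(effects)) effects$covariate_shift,
                               derive_seed(config$seed, "covariates", "case"))
  covariates <- dplyr::bind_rows(covs_ctrl, covs_case) |>
    dplyr::mutate(subject_id = ids, label = as.integer(groups == "case"),
                  .before = 1)
  structure(list(recordings = recs, covariates = covariates,
                 config = config, effects = effects),
            class = "qeeg_cohort")
}

#' @export
print.qeeg_cohort <- function(x, ...) {
  cat("<qeeg_cohort> ", x$config$n_controls, " controls + ", x$config$n_cases,
      " cases, ", x$config$duration_s, " s @ ", x$config$rate, " Hz\n", sep = "")
  invisible(x)
}

#' Extract features for a whole cohort
#'
#' Convenience wrapper running artifact screening, cross-spectral
#' accumulation and per-subject feature extraction over every recording.
#'
#' @param cohort A [generate_cohort()] result (or any list with
#'   `recordings` and `covariates`).
#' @param amplitude_limit Artifact rejection threshold, uV.
#' @param transform PSD transform passed to [extract_subject_features()].
#' @param parameters Feature families passed to [extract_subject_features()].
#' @return A list with `features` (long tibble over all subjects) and
#'   `covariates`.
#' @export
cohort_features <- function(cohort, amplitude_limit = 100,
                            transform = c("log10", "raw"),
                            parameters = c("psd", "coh")) {
  transform <- match.arg(transform)
  feats <- purrr::map(cohort$recordings, function(rec) {
    rec <- reject_artifact_windows(rec, amplitude_limit)
    cs <- sliding_cross_spectrum(rec, pairs = "coh" %in% parameters)
    extract_subject_features(cs, transform = transform, parameters = parameters)
  })
  list(features = dplyr::bind_rows(feats), covariates = cohort$covariates)
}

#' Write a cohort to disk
#'
#' One CSV recording per subject plus a `manifest.csv` with labels,
#' covariates and the per-subject seeds.
#'
#' @param cohort A `qeeg_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (rec in cohort$recordings) {
    write_recording_csv(rec, file.path(dir, paste0(rec$subject_id, ".csv")))
  }
  manifest <- dplyr::mutate(
    cohort$covariates,
    seed = vapply(.data$subject_id, function(id)
      derive_seed(cohort$config$seed, "subject", id), integer(1)),
    file = paste0(.data$subject_id, ".csv")
  )
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(dir)
}
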