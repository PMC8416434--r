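#' Extract the full per-subject QEEG feature record
#'
#' Computes absolute band power for every (band, channel) and band
#' coherence for every (band, channel pair): 19 x 6 = 114 power values and
#' 171 x 6 = 1,026 coherence values per subject. Power is log10-transformed
#' by default (`log10(power + 1e-12)`); coherence is never transformed.
#'
#' @param cs A [sliding_cross_spectrum()] result.
#' @param transform `"log10"` (default) or `"raw"`, applied to power only.
#' @param parameters Which feature families to extract; the default, both,
#'   yields the full 1,140-value record. Restricting to `"psd"` skips the
#'   pairwise coherence computation when only power features are needed.
#' @return A tibble with one row per feature: `subject_id`, `kind`
#'   (`"psd"`/`"coh"`), `band`, `channel` (PSD rows), `chan_i`, `chan_j`
#'   (coherence rows), `feature` (unique name such as `psd_alpha_O1` or
#'   `coh_theta_F3_P4`) and `value`.
#' @export
extract_subject_features <- function(cs, transform = c("log10", "raw"),
                                     parameters = c("psd", "coh")) {
  stopifnot(inherits(cs, "cross_spectrum"))
  transform <- match.arg(transform)
  parameters <- match.arg(parameters, several.ok = TRUE)
  psd <- band_psd_matrix(cs)              # channels x bands
  if (transform == "log10") psd <- log10(psd + 1e-12)
  bands <- colnames(psd)
  psd_tb <- tidyr::expand_grid(band = bands, channel = rownames(psd)) |>
    dplyr::mutate(
      kind = "psd",
      feature = paste("psd", .data$band, .data$channel, sep = "_"),
      # expand_grid varies channel fastest within band, matching
      # column-major stacking of the channels-x-bands matrix
      value = as.vector(psd)
    )
  coh_tb <- NULL
  if ("coh" %in% parameters) {
    coh <- band_coherence_matrix(cs)      # pairs x bands
    coh_tb <- tidyr::expand_grid(band = bands,
                                 pair = seq_len(nrow(cs$pairs))) |>
      dplyr::mutate(
        kind = "coh",
        chan_i = cs$pairs$chan_i[.data$pair],
        chan_j = cs$pairs$chan_j[.data$pair],
        feature = paste("coh", .data$band, .data$chan_i, .data$chan_j, sep = "_"),
        value = as.vector(coh)
      ) |>
      dplyr::select(-"pair")
  }
  dplyr::bind_rows(if ("psd" %in% parameters) psd_tb, coh_tb) |>
    dplyr::mutate(subject_id = cs$subject_id, .before = 1) |>
    dplyr::select("subject_id", "kind", "band", dplyr::any_of(c("channel", "chan_i", "chan_j")),
                  "feature", "value")
}

#' Parse feature names back to their components
#'
#' Inverse of the feature naming scheme: recovers kind, band and
#' channel(s) from names such as `psd_alpha_O1`, `coh_high_beta_F3_P4` or
#' `cov_age`.
#'
#' @param feature Character vector of feature names.
#' @return A tibble with columns `feature`, `kind`, `band`, `chan_i`, `chan_j`.
#' @export
parse_feature_name <- function(feature) {
  band_re <- paste(band_names(), collapse = "|")
  re <- paste0("^(psd|coh)_(", band_re, ")_(.+)$")
  kind <- ifelse(grepl("^cov_", feature), "cov",
                 ifelse(grepl(re, feature), sub(re, "\\1", feature), NA))
  band <- ifelse(kind %in% c("psd", "coh"), sub(re, "\\2", feature), NA)
  rest <- ifelse(kind %in% c("psd", "coh"), sub(re, "\\3", feature),
                 sub("^cov_", "", feature))
  chan_i <- ifelse(kind == "coh", sub("_.*$", "", rest),
                   ifelse(kind == "psd", rest, NA))
  chan_j <- ifelse(kind == "coh", sub("^[^_]+_", "", rest), NA)
  tibble::tibble(feature = feature, kind = kind, band = band,
                 chan_i = chan_i, chan_j = chan_j)
}

#' Define a feature combination
#'
#' One cell of the combination grid: which spectral parameter(s) enter
#' (PSD, FC = coherence, or both), which band(s), and whether IQ joins
#' age, sex and education as a covariate.
#'
#' @param parameter `"PSD"`, `"FC"` or `"PSD+FC"`.
#' @param bands Character vector of band names, or `"whole"` for all six.
#' @param adjust_iq Include IQ as a covariate?
#' @return An object of class `qeeg_combo`.
#' @examples
#' n_combo_features(feature_combination("PSD", "delta"))        # 22
#' n_combo_features(feature_combination("PSD+FC", "whole", TRUE)) # 1144
#' @export
feature_combination <- function(parameter = c("PSD", "FC", "PSD+FC"),
                                bands = "whole", adjust_iq = FALSE) {
  parameter <- match.arg(parameter)
  if (identical(bands, "whole")) bands <- band_names()
  bad <- setdiff(bands, band_names())
  if (length(bad) > 0 || length(bands) == 0) {
    qeeg_abort(paste0("unknown bands: ", paste(bad, collapse = ", ")),
               "qeeg_error_validation")
  }
  bands <- band_names()[band_names() %in% bands]
  structure(
    list(parameter = parameter, bands = bands, adjust_iq = isTRUE(adjust_iq)),
    class = "qeeg_combo"
  )
}

#' @export
print.qeeg_combo <- function(x, ...) {
  cat("<qeeg_combo> ", combo_label(x), " (", n_combo_features(x),
      " features)\n", sep = "")
  invisible(x)
}

combo_label <- function(combo) {
  b <- if (length(combo$bands) == 6) "whole" else paste(combo$bands, collapse = "+")
  paste0(combo$parameter, ":", b, if (combo$adjust_iq) ":iq" else "")
}

#' @rdname feature_combination
#' @param combo A `qeeg_combo`.
#' @return `n_combo_features()`: the closed-form predictor count
#'   `(19 [PSD] + 171 [FC]) * n_bands + 3 + [IQ]`.
#' @export
n_combo_features <- function(combo) {
  per_band <- switch(combo$parameter, "PSD" = 19L, "FC" = 171L, "PSD+FC" = 190L)
  per_band * length(combo$bands) + 3L + as.integer(combo$adjust_iq)
}

#' Enumerate the combination grid
#'
#' The 3 parameters x 7 band choices (each band alone, plus all six
#' together) = 21 feature combinations evaluated for one IQ setting, in
#' deterministic order: parameter-major (PSD, FC, PSD+FC), bands in
#' canonical order with `whole` last.
#'
#' @param adjust_iq Include IQ in every combination?
#' @return A tibble with columns `parameter`, `bands` (list-column),
#'   `label`, `n_features`, and `combo` (list-column of `qeeg_combo`).
#' @export
enumerate_combination_grid <- function(adjust_iq = FALSE) {
  grid <- tidyr::expand_grid(
    parameter = c("PSD", "FC", "PSD+FC"),
    band_choice = c(as.list(band_names()), list("whole"))
  )
  combos <- purrr::map2(grid$parameter, grid$band_choice,
                        ~ feature_combination(.x, .y, adjust_iq))
  tibble::tibble(
    parameter = grid$parameter,
    bands = purrr::map(combos, "bands"),
    label = purrr::map_chr(combos, combo_label),
    n_features = purrr::map_int(combos, n_combo_features),
    combo = combos
  )
}

covariate_columns <- function(adjust_iq) {
  c("age", "sex", "education", if (adjust_iq) "iq")
}

validate_covariates <- function(covariates, need_iq = TRUE) {
  need <- c("subject_id", "label", "age", "sex", "education", if (need_iq) "iq")
  miss <- setdiff(need, names(covariates))
  if (length(miss) > 0) {
    qeeg_abort(paste0("covariate table lacks columns: ", paste(miss, collapse = ", ")),
               "qeeg_error_validation")
  }
  num <- intersect(c("age", "sex", "education", "iq"), names(covariates))
  bad <- covariates$subject_id[!stats::complete.cases(covariates[num]) |
                                 rowSums(!sapply(covariates[num], is.finite)) > 0]
  if (length(bad) > 0) {
    qeeg_abort(paste0("missing/non-finite covariates for subjects: ",
                      paste(bad, collapse = ", ")),
               "qeeg_error_validation", subjects = bad)
  }
  out_age <- covariates$subject_id[covariates$age < 18 | covariates$age > 70]
  if (length(out_age) > 0) {
    qeeg_abort(paste0("age outside the 18-70 eligibility window for: ",
                      paste(out_age, collapse = ", ")),
               "qeeg_error_validation", subjects = out_age)
  }
  invisible(covariates)
}

#' Assemble a subjects-by-features matrix for one combination
#'
#' Pivots the long per-subject feature records into a wide analysis table:
#' the selected QEEG features (parameter x bands, in band-major canonical
#' order) followed by the covariates (`cov_age`, `cov_sex`,
#' `cov_education`, and `cov_iq` when IQ-adjusted). Subject order follows
#' the covariate table; no silent re-sorting.
#'
#' @param features Long feature tibble: [extract_subject_features()] rows
#'   bound over subjects.
#' @param covariates Tibble with `subject_id`, `label` (patient = 1,
#'   control = 0), `age`, `sex` (male = 1, female = 0), `education`, `iq`.
#' @param combo A [feature_combination()].
#' @return A tibble of class `qeeg_features`: `subject_id`, `label`, then
#'   predictor columns.
#' @export
build_feature_matrix <- function(features, covariates, combo) {
  stopifnot(inherits(combo, "qeeg_combo"))
  validate_covariates(covariates, need_iq = combo$adjust_iq)
  kinds <- switch(combo$parameter, "PSD" = "psd", "FC" = "coh",
                  "PSD+FC" = c("psd", "coh"))
  wanted <- unlist(lapply(kinds, function(k) {
    unlist(lapply(combo$bands, function(b) {
      unique(features$feature[features$kind == k & features$band == b])
    }))
  }))
  no_feat <- setdiff(covariates$subject_id, unique(features$subject_id))
  if (length(no_feat) > 0) {
    qeeg_abort(paste0("no feature records for subjects: ",
                      paste(no_feat, collapse = ", ")),
               "qeeg_error_validation", subjects = no_feat)
  }
  wide <- features |>
    dplyr::filter(.data$feature %in% wanted) |>
    dplyr::select("subject_id", "feature", "value") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value")
  wide <- wide[match(covariates$subject_id, wide$subject_id),
               c("subject_id", wanted)]
  covs <- covariates[, c("subject_id", "label", covariate_columns(combo$adjust_iq))]
  names(covs) <- c("subject_id", "label",
                   paste0("cov_", covariate_columns(combo$adjust_iq)))
  out <- dplyr::left_join(covs["subject_id"], wide, by = "subject_id") |>
    dplyr::left_join(covs, by = "subject_id") |>
    dplyr::select("subject_id", "label", dplyr::all_of(wanted),
                  dplyr::starts_with("cov_"))
  if (anyNA(out)) {
    qeeg_abort("feature matrix contains missing values", "qeeg_error_validation")
  }
  structure(out, combo = combo, class = c("qeeg_features", class(out)))
}

#' @rdname build_feature_matrix
#' @param fm A `qeeg_features` matrix.
#' @return `feature_matrix_predictors()`: the numeric predictor matrix
#'   (everything except `subject_id` and `label`), with row names the
#'   subject ids.
#' @export
feature_matrix_predictors <- function(fm) {
  x <- as.matrix(fm[, setdiff(names(fm), c("subject_id", "label"))])
  rownames(x) <- fm$subject_id
  x
}

#' Write / read a feature matrix as CSV
#'
#' The on-disk layout places `subject_id`, `label` and the covariates
#' first, then the QEEG features.
#'
#' @param fm A `qeeg_features` tibble.
#' @param path File path.
#' @return `path` invisibly for the writer; a tibble for the reader.
#' @export
write_feature_matrix <- function(fm, path) {
  cov_cols <- grep("^cov_", names(fm), value = TRUE)
  ord <- c("subject_id", "label", cov_cols,
           setdiff(names(fm), c("subject_id", "label", cov_cols)))
  utils::write.csv(fm[, ord], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}
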