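#' Feature survival across CV folds
#'
#' The stability rule for elastic-net features: a feature "survives" when
#' its coefficient is non-zero in strictly more than `threshold` of the
#' cross-validation folds (with the default threshold of 7 over 10 folds,
#' at least 8 of 10). Counts are taken on exact zeros of the per-fold
#' coefficient vectors.
#'
#' @param cv A `qeeg_cv` produced with an elastic-net [model_spec()].
#' @param threshold Survival threshold (strict `>`). Default 7.
#' @return A tibble of class `qeeg_survival`: one row per feature with
#'   `nonzero_count` (0..k), `survived`, `sign_consistency` (fraction of
#'   non-zero folds sharing the modal coefficient sign) and
#'   `mean_coefficient` (average over non-zero folds).
#' @export
extract_survival <- function(cv, threshold = 7) {
  stopifnot(inherits(cv, "qeeg_cv"))
  if (cv$method != "en" || is.null(cv$coefficients)) {
    qeeg_abort("feature survival requires an elastic-net qeeg_cv with retained coefficients",
               "qeeg_error_unsupported_method")
  }
  B <- cv$coefficients
  nz <- B != 0
  count <- rowSums(nz)
  sign_cons <- vapply(seq_len(nrow(B)), function(i) {
    s <- sign(B[i, nz[i, ]])
    if (length(s) == 0) return(NA_real_)
    max(table(s)) / length(s)
  }, numeric(1))
  mean_coef <- ifelse(count > 0, rowSums(B) / pmax(count, 1), 0)
  out <- tibble::tibble(
    feature = rownames(B),
    nonzero_count = as.integer(unname(count)),
    survived = unname(count > threshold),
    sign_consistency = sign_cons,
    mean_coefficient = unname(mean_coef)
  )
  structure(out, threshold = threshold, k = ncol(B),
            class = c("qeeg_survival", class(out)))
}

#' Permutation test of a cross-validated model
#'
#' Builds the null distribution of the mean cross-validated AUC by
#' shuffling the group labels and re-running the full 10-fold procedure
#' (fold re-splitting and all hyperparameter tuning included) for each
#' permutation. The p-value is the plain fraction of null AUCs at or
#' above the observed one; when no null value reaches it the result is
#' reported as `< 1/n_perm`. An add-one estimator
#' `(count + 1)/(n_perm + 1)` is available by flag.
#'
#' @param fm A `qeeg_features` tibble.
#' @param spec A [model_spec()].
#' @param n_perm Number of permutations. Default 200 (a desk-scale
#'   default; 1,000 for publication-grade resolution).
#' @param seed Seed governing permutations (and, through the per-
#'   permutation derived seeds, fold re-splitting).
#' @param add_one Use the add-one p-value estimator? Default FALSE.
#' @return An object of class `qeeg_permutation` with `observed_auc`
#'   (percent), `null_aucs`, `p_value` and `p_label`.
#' @export
permutation_test <- function(fm, spec = model_spec("en"), n_perm = 200,
                             seed = 1, add_one = FALSE) {
  if (n_perm < 20) {
    warn("n_perm < 20 gives a very low-resolution permutation p-value")
  }
  observed <- glance(cross_validate(fm, spec))$mean_auc
  y <- fm$label
  x <- feature_matrix_predictors(fm)
  null_aucs <- vapply(seq_len(n_perm), function(b) {
    perm <- with_seed(derive_seed(seed, "perm-labels", b), sample(y))
    spec_b <- spec
    spec_b$seed <- derive_seed(seed, "perm-cv", b)
    100 * mean(cv_core(x, perm, spec_b)$auc)
  }, numeric(1))
  count <- sum(null_aucs >= observed)
  p <- if (add_one) (count + 1) / (n_perm + 1) else count / n_perm
  label <- if (!add_one && count == 0) paste0("< ", format(1 / n_perm)) else format(p)
  structure(
    list(observed_auc = observed, null_aucs = null_aucs,
         p_value = p, p_label = label, n_perm = n_perm,
         add_one = add_one, low_resolution = n_perm < 20),
    class = "qeeg_permutation"
  )
}

#' @export
print.qeeg_permutation <- function(x, ...) {
  cat("<qeeg_permutation> observed mean AUC ", sprintf("%.2f%%", x$observed_auc),
      ", ", x$n_perm, " permutations, p ", x$p_label, "\n", sep = "")
  invisible(x)
}

#' @rdname permutation_test
#' @param x A `qeeg_permutation`.
#' @param ... Unused.
#' @export
tidy.qeeg_permutation <- function(x, ...) {
  tibble::tibble(permutation = seq_len(x$n_perm), null_auc = x$null_aucs)
}

#' @rdname permutation_test
#' @export
glance.qeeg_permutation <- function(x, ...) {
  tibble::tibble(observed_auc = x$observed_auc, n_perm = x$n_perm,
                 p_value = x$p_value, p_label = x$p_label)
}

#' Sweep the feature-combination grid
#'
#' Cross-validates one model over every combination of the grid (21 per
#' IQ setting) and identifies the best combination by mean AUC, ties
#' broken towards fewer features and then grid order.
#'
#' @param features Long feature tibble over all subjects
#'   (rows of [extract_subject_features()]).
#' @param covariates Covariate tibble (`subject_id`, `label`, `age`,
#'   `sex`, `education`, `iq`).
#' @param spec A [model_spec()].
#' @param adjust_iq Include IQ as a covariate throughout the grid?
#' @param keep_cv Keep every combination's `qeeg_cv` (memory permitting)?
#'   The best combination's is always kept.
#' @return An object of class `qeeg_sweep`: the sweep table ([tidy()]),
#'   the best row index, and the best combination's `qeeg_cv`.
#' @export
combination_sweep <- function(features, covariates, spec = model_spec("en"),
                              adjust_iq = FALSE, keep_cv = FALSE) {
  grid <- enumerate_combination_grid(adjust_iq)
  rows <- vector("list", nrow(grid))
  cvs <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    combo <- grid$combo[[g]]
    res <- tryCatch({
      fm <- build_feature_matrix(features, covariates, combo)
      cv <- cross_validate(fm, spec)
      list(cv = cv, glance = glance(cv), error = NA_character_)
    }, error = function(e) list(cv = NULL, glance = NULL,
                                error = conditionMessage(e)))
    rows[[g]] <- tibble::tibble(
      combination = grid$label[g],
      parameter = grid$parameter[g],
      bands = paste(grid$bands[[g]], collapse = "+"),
      n_features = grid$n_features[g],
      mean_auc = res$glance$mean_auc %||% NA_real_,
      sd_auc = res$glance$sd_auc %||% NA_real_,
      mean_sensitivity = res$glance$mean_sensitivity %||% NA_real_,
      sd_sensitivity = res$glance$sd_sensitivity %||% NA_real_,
      mean_specificity = res$glance$mean_specificity %||% NA_real_,
      sd_specificity = res$glance$sd_specificity %||% NA_real_,
      error = res$error
    )
    cvs[[g]] <- res$cv
  }
  table <- dplyr::bind_rows(rows)
  best <- select_best_combination(table)
  structure(
    list(table = table, best = best,
         best_combination = table$combination[best],
         best_cv = cvs[[best]],
         cv_results = if (keep_cv) cvs,
         method = spec$method, adjust_iq = adjust_iq),
    class = "qeeg_sweep"
  )
}

#' Re-select the winning combination from a sweep table
#'
#' A pure function of the serialized sweep table: maximal mean AUC, ties
#' broken by fewer features, then by table (grid) order.
#'
#' @param table A sweep table as produced by [combination_sweep()].
#' @return The winning row index.
#' @export
select_best_combination <- function(table) {
  ok <- which(!is.na(table$mean_auc))
  if (length(ok) == 0) {
    qeeg_abort("every combination failed; no best model", "qeeg_error_fit_failure")
  }
  ord <- ok[order(-table$mean_auc[ok], table$n_features[ok], ok)]
  ord[1]
}

#' @export
print.qeeg_sweep <- function(x, ...) {
  b <- x$table[x$best, ]
  cat("<qeeg_sweep> ", toupper(x$method), ", ", nrow(x$table),
      " combinations (adjust_iq=", x$adjust_iq, ")\n", sep = "")
  cat(sprintf("  best: %s  AUC %.2f (%.2f)%%  Sens %.2f (%.2f)%%  Spec %.2f (%.2f)%%\n",
              b$combination, b$mean_auc, b$sd_auc, b$mean_sensitivity,
              b$sd_sensitivity, b$mean_specificity, b$sd_specificity))
  invisible(x)
}

#' @rdname combination_sweep
#' @param x A `qeeg_sweep`.
#' @param ... Unused.
#' @export
tidy.qeeg_sweep <- function(x, ...) x$table

#' @rdname combination_sweep
#' @export
glance.qeeg_sweep <- function(x, ...) {
  dplyr::mutate(x$table[x$best, ], method = x$method,
                adjust_iq = x$adjust_iq, .before = 1)
}

#' Compare classification methods over the combination grid
#'
#' Runs [combination_sweep()] for each supplied model specification and
#' reports each method's best-combination performance.
#'
#' @param features Long feature tibble over all subjects.
#' @param covariates Covariate tibble.
#' @param specs Named list of [model_spec()] objects (e.g. EN, SVM, RF).
#' @param adjust_iq Include IQ as a covariate?
#' @return A tibble with one row per method: best combination and its
#'   mean (SD) AUC, sensitivity, specificity on the percent scale, plus a
#'   `sweep` list-column with the full `qeeg_sweep` objects.
#' @export
compare_methods <- function(features, covariates,
                            specs = list(en = model_spec("en"),
                                         svm = model_spec("svm"),
                                         rf = model_spec("rf")),
                            adjust_iq = FALSE) {
  sweeps <- purrr::map(specs, function(sp) {
    combination_sweep(features, covariates, sp, adjust_iq = adjust_iq)
  })
  out <- purrr::imap(sweeps, function(sw, nm) {
    dplyr::mutate(glance(sw), method = nm)
  }) |> dplyr::bind_rows()
  out$sweep <- unname(sweeps)
  out
}
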