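#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_histogram
#'   geom_vline geom_errorbar labs facet_wrap theme_minimal coord_flip
NULL

#' Plot a combination sweep
#'
#' Mean cross-validated AUC (with +-1 SD bars) for every feature
#' combination, grouped by spectral parameter.
#'
#' @param object A `qeeg_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qeeg_sweep <- function(object, ...) {
  tab <- dplyr::mutate(object$table,
                       combination = factor(.data$combination,
                                            levels = rev(.data$combination)),
                       best = dplyr::row_number() == object$best)
  ggplot(tab, aes(x = .data$combination, y = .data$mean_auc,
                  fill = .data$best)) +
    geom_col(show.legend = FALSE) +
    geom_errorbar(aes(ymin = .data$mean_auc - .data$sd_auc,
                      ymax = .data$mean_auc + .data$sd_auc), width = 0.3) +
    coord_flip() +
    labs(x = NULL, y = "mean CV AUC (%)",
         title = paste0("Combination sweep (", toupper(object$method), ")")) +
    theme_minimal()
}

#' Plot per-fold cross-validation metrics
#'
#' @param object A `qeeg_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qeeg_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, -"fold",
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = factor(.data$fold), y = 100 * .data$value)) +
    geom_point() +
    facet_wrap(~metric) +
    labs(x = "fold", y = "%",
         title = paste0(toupper(object$method), " 10-fold metrics")) +
    theme_minimal()
}

#' Plot a permutation null distribution
#'
#' Histogram of the null mean-AUC distribution with the observed value
#' marked.
#'
#' @param object A `qeeg_permutation`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qeeg_permutation <- function(object, ...) {
  ggplot(tidy(object), aes(x = .data$null_auc)) +
    geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    geom_vline(xintercept = object$observed_auc, colour = "red") +
    labs(x = "null mean CV AUC (%)", y = "count",
         title = paste0("Permutation test (p ", object$p_label, ")")) +
    theme_minimal()
}

#' Plot feature-survival counts
#'
#' Non-zero coefficient counts across folds for the surviving features
#' (and the nearest non-survivors), signed by the mean coefficient.
#'
#' @param object A `qeeg_survival`.
#' @param top Maximum number of features shown. Default 40.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.qeeg_survival <- function(object, top = 40, ...) {
  tab <- dplyr::arrange(tibble::as_tibble(object),
                        dplyr::desc(.data$nonzero_count)) |>
    head(top) |>
    dplyr::mutate(feature = factor(.data$feature, levels = rev(.data$feature)),
                  direction = ifelse(.data$mean_coefficient >= 0,
                                     "risk up", "risk down"))
  ggplot(tab, aes(x = .data$feature, y = .data$nonzero_count,
                  fill = .data$direction)) +
    geom_col() +
    geom_vline(xintercept = 0) +
    coord_flip() +
    labs(x = NULL, y = "non-zero folds (of 10)",
         title = paste0("Feature survival (threshold > ",
                        attr(object, "threshold"), ")")) +
    theme_minimal()
}
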