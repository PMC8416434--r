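#' Specify a classification model
#'
#' Bundles the method and its hyperparameter policy for use in
#' [cross_validate()] and the combination sweep. Elastic-net logistic
#' regression (`"en"`) selects its penalty strength lambda by nested
#' K-fold cross-validation on binomial deviance over a log-spaced path;
#' the support-vector machine (`"svm"`) selects its cost C from a fixed
#' candidate grid `(0.1, 0.5, 1, 5, 10)` by inner-CV AUC; the random
#' forest (`"rf"`) uses `floor(sqrt(p))` features per split and 500 trees.
#' All randomness (fold splits, tree bootstraps, inner CV) derives from
#' the single `seed`.
#'
#' @param method `"en"`, `"svm"` or `"rf"`.
#' @param en_mixing Elastic-net mixing weight in (0, 1] between ridge
#'   (towards 0) and lasso (1). Default 0.5.
#' @param en_nlambda Length of the lambda path. Default 50.
#' @param en_lambda_min_ratio Smallest lambda as a fraction of the largest;
#'   `NULL` uses the glmnet default.
#' @param svm_c_grid Candidate SVM cost values.
#' @param svm_kernel `"radial"` (median-heuristic bandwidth) or `"linear"`.
#' @param rf_n_trees Number of trees. Default 500.
#' @param rf_mtry Features per split; `NULL` means `floor(sqrt(p))`.
#' @param inner_cv_folds Inner folds for hyperparameter selection
#'   (reduced automatically when a class is too small). Default 10.
#' @param outer_folds Outer CV folds. Default 10.
#' @param stratify Stratify outer folds by class? Default TRUE.
#' @param penalize_covariates Should covariate columns be penalized like
#'   any feature under the elastic net? Default TRUE.
#' @param seed Master seed for this model's randomness.
#' @return An object of class `qeeg_model_spec`.
#' @export
model_spec <- function(method = c("en", "svm", "rf"),
                       en_mixing = 0.5, en_nlambda = 50,
                       en_lambda_min_ratio = NULL,
                       svm_c_grid = c(0.1, 0.5, 1, 5, 10),
                       svm_kernel = c("radial", "linear"),
                       rf_n_trees = 500, rf_mtry = NULL,
                       inner_cv_folds = 10, outer_folds = 10,
                       stratify = TRUE, penalize_covariates = TRUE,
                       seed = 1) {
  method <- match.arg(method)
  svm_kernel <- match.arg(svm_kernel)
  if (en_mixing <= 0 || en_mixing > 1) {
    qeeg_abort("en_mixing must be in (0, 1]", "qeeg_error_validation")
  }
  structure(
    list(method = method, en_mixing = en_mixing, en_nlambda = en_nlambda,
         en_lambda_min_ratio = en_lambda_min_ratio,
         svm_c_grid = svm_c_grid, svm_kernel = svm_kernel,
         rf_n_trees = rf_n_trees, rf_mtry = rf_mtry,
         inner_cv_folds = inner_cv_folds, outer_folds = outer_folds,
         stratify = isTRUE(stratify),
         penalize_covariates = isTRUE(penalize_covariates),
         seed = as.integer(seed)),
    class = "qeeg_model_spec"
  )
}

#' @export
print.qeeg_model_spec <- function(x, ...) {
  cat("<qeeg_model_spec> method=", x$method, ", outer folds=", x$outer_folds,
      ", inner folds=", x$inner_cv_folds, ", seed=", x$seed, "\n", sep = "")
  invisible(x)
}

#' Stratified k-fold assignment
#'
#' Assigns subjects to k folds so that fold sizes differ by at most one
#' and each fold's class counts are within one subject of proportionality.
#' Deterministic given the seed.
#'
#' @param labels Binary label vector (0/1).
#' @param k Number of folds. Default 10.
#' @param seed Integer seed.
#' @param stratify If `FALSE`, plain (unstratified) balanced folds.
#' @return Integer vector of fold indices in 1..k.
#' @export
stratified_kfold <- function(labels, k = 10, seed = 1, stratify = TRUE) {
  n <- length(labels)
  if (!stratify) {
    return(with_seed(seed, sample(rep_len(sample.int(k), n))))
  }
  tab <- table(labels)
  if (any(tab < k)) {
    qeeg_abort(
      sprintf("stratification infeasible: class '%s' has %d < %d members",
              names(tab)[which.min(tab)], min(tab), k),
      "qeeg_error_infeasible_stratification"
    )
  }
  fold <- integer(n)
  fold_sizes <- integer(k)
  with_seed(seed, {
    for (cl in names(tab)) {
      idx <- sample(which(labels == as.numeric(cl)))
      n_c <- length(idx)
      base <- n_c %/% k
      counts <- rep(base, k)
      extra <- n_c - base * k
      if (extra > 0) {
        # hand the remainder to the currently smallest folds, ties broken
        # at random, keeping overall fold sizes within one of each other
        ord <- order(fold_sizes + stats::runif(k))
        counts[ord[seq_len(extra)]] <- base + 1
      }
      fold[idx] <- rep.int(seq_len(k), counts)
      fold_sizes <- fold_sizes + counts
    }
  })
  fold
}

binomial_deviance <- function(y, p) {
  p <- pmin(pmax(p, 1e-10), 1 - 1e-10)
  -2 * mean(y * log(p) + (1 - y) * log(1 - p))
}

check_two_class_train <- function(y) {
  if (length(unique(y)) < 2) {
    qeeg_abort("degenerate training fold: only one class present",
               "qeeg_error_fit_failure")
  }
}

inner_fold_count <- function(spec, y) {
  max(2L, min(spec$inner_cv_folds, min(table(y))))
}

# ---- elastic net ----------------------------------------------------------

# glmnet warns when an inner fold leaves a class with few members; at the
# fold sizes used here that is expected, not actionable
quiet_glmnet <- function(expr) {
  withCallingHandlers(expr, warning = function(w) {
    if (grepl("fewer than 8 observations|one multinomial or binomial class",
              conditionMessage(w))) {
      invokeRestart("muffleWarning")
    }
  })
}

fit_en_core <- function(x, y, spec, seed) {
  check_two_class_train(y)
  zs <- zscore_fit(x)
  xs <- zscore_apply(x, zs)
  if (all(xs == 0)) {
    # every predictor constant: the elastic net degenerates to the
    # intercept-only model at any lambda
    return(structure(
      list(coef = stats::setNames(rep(0, ncol(x)), colnames(x)),
           intercept = qlogis(mean(y)), lambda = Inf,
           lambda_path = Inf, cv_deviance = NA_real_, scaling = zs,
           glmnet_fit = NULL, method = "en"),
      class = "qeeg_en_fit"
    ))
  }
  pf <- rep(1, ncol(x))
  if (!spec$penalize_covariates) pf[grepl("^cov_", colnames(x))] <- 0
  args <- list(x = xs, y = y, family = "binomial", alpha = spec$en_mixing,
               nlambda = spec$en_nlambda, standardize = FALSE,
               penalty.factor = pf)
  if (!is.null(spec$en_lambda_min_ratio)) {
    args$lambda.min.ratio <- spec$en_lambda_min_ratio
  }
  fit0 <- tryCatch(quiet_glmnet(do.call(glmnet::glmnet, args)),
                   error = function(e) {
                     qeeg_abort(paste0("elastic-net fit failed: ", conditionMessage(e)),
                                "qeeg_error_fit_failure")
                   })
  lam <- fit0$lambda
  k_in <- inner_fold_count(spec, y)
  inner <- stratified_kfold(y, k_in, seed = derive_seed(seed, "inner"))
  dev <- matrix(NA_real_, k_in, length(lam))
  for (f in seq_len(k_in)) {
    tr <- inner != f
    fit_f <- quiet_glmnet(do.call(glmnet::glmnet,
                                  modifyList(args, list(x = xs[tr, , drop = FALSE],
                                                        y = y[tr], lambda = lam))))
    p_f <- predict(fit_f, xs[!tr, , drop = FALSE], type = "response")
    # pad if the inner path stopped early
    if (ncol(p_f) < length(lam)) {
      p_f <- cbind(p_f, matrix(p_f[, ncol(p_f)], nrow(p_f),
                               length(lam) - ncol(p_f)))
    }
    P <- pmin(pmax(p_f, 1e-10), 1 - 1e-10)
    dev[f, ] <- -2 * colMeans(y[!tr] * log(P) + (1 - y[!tr]) * log(1 - P))
  }
  cvm <- colMeans(dev)
  idx <- which.min(cvm)
  lambda_min <- lam[idx]
  # lambda_min lies on fit0's own path, so coefficients are read off
  # directly rather than interpolated
  beta <- fit0$beta[, idx]
  names(beta) <- colnames(x)
  a0 <- fit0$a0[[idx]]
  structure(
    list(coef = beta, intercept = a0, lambda = lambda_min,
         lambda_path = lam, cv_deviance = cvm, scaling = zs,
         glmnet_fit = fit0, method = "en"),
    class = "qeeg_en_fit"
  )
}

predict_en <- function(fit, xnew) {
  eta <- drop(zscore_apply(xnew, fit$scaling) %*% fit$coef) + fit$intercept
  plogis(eta)
}

#' Fit the elastic-net classifier on one training fold
#'
#' Features are z-scored with training-fold statistics, lambda is chosen
#' by inner K-fold cross-validation minimizing binomial deviance over a
#' log-spaced path, and the coefficients (on the standardized scale, exact
#' zeros possible) are returned with names preserved.
#'
#' @param train A `qeeg_features` tibble (training subjects only).
#' @param spec A [model_spec()] with `method = "en"`.
#' @return A `qeeg_en_fit`: coefficients, intercept, chosen `lambda`, the
#'   inner-CV deviance path and the training scaling.
#' @export
fit_en_fold <- function(train, spec = model_spec("en")) {
  fit_en_core(feature_matrix_predictors(train), train$label, spec,
              seed = derive_seed(spec$seed, "fit-en"))
}

# ---- SVM ------------------------------------------------------------------

median_heuristic_gamma <- function(xs) {
  n <- nrow(xs)
  idx <- unique(round(seq(1, n, length.out = min(n, 128))))
  d2 <- as.numeric(stats::dist(xs[idx, , drop = FALSE]))^2
  m <- stats::median(d2[d2 > 0])
  if (!is.finite(m) || m <= 0) 1 / ncol(xs) else 1 / m
}

fit_svm_core <- function(x, y, spec, seed) {
  check_two_class_train(y)
  zs <- zscore_fit(x)
  xs <- zscore_apply(x, zs)
  gamma <- if (spec$svm_kernel == "radial") median_heuristic_gamma(xs) else NULL
  yf <- factor(y, levels = c(0, 1))
  svm_fit <- function(rows, cost) {
    args <- list(x = xs[rows, , drop = FALSE], y = yf[rows], scale = FALSE,
                 kernel = spec$svm_kernel, cost = cost, probability = FALSE)
    if (!is.null(gamma)) args$gamma <- gamma
    do.call(e1071::svm, args)
  }
  oriented_scores <- function(fit, rows, train_rows) {
    dv <- attr(predict(fit, xs[rows, , drop = FALSE], decision.values = TRUE),
               "decision.values")[, 1]
    dv_tr <- attr(predict(fit, xs[train_rows, , drop = FALSE],
                          decision.values = TRUE), "decision.values")[, 1]
    flip <- mean(dv_tr[y[train_rows] == 1]) < mean(dv_tr[y[train_rows] == 0])
    if (isTRUE(flip)) -dv else dv
  }
  k_in <- inner_fold_count(spec, y)
  inner <- stratified_kfold(y, k_in, seed = derive_seed(seed, "inner"))
  grid_auc <- vapply(spec$svm_c_grid, function(cost) {
    aucs <- vapply(seq_len(k_in), function(f) {
      tr <- which(inner != f); te <- which(inner == f)
      if (length(unique(y[te])) < 2) return(NA_real_)
      fit <- svm_fit(tr, cost)
      auc_mann_whitney(oriented_scores(fit, te, tr), y[te])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  }, numeric(1))
  best_c <- spec$svm_c_grid[which.max(grid_auc)]
  fit <- svm_fit(seq_along(y), best_c)
  structure(
    list(svm = fit, cost = best_c, grid_auc = stats::setNames(grid_auc, spec$svm_c_grid),
         gamma = gamma, scaling = zs, orient = local({
           all_rows <- seq_along(y)
           dv_tr <- attr(predict(fit, xs, decision.values = TRUE),
                         "decision.values")[, 1]
           if (mean(dv_tr[y == 1]) < mean(dv_tr[y == 0])) -1 else 1
         }), method = "svm"),
    class = "qeeg_svm_fit"
  )
}

predict_svm <- function(fit, xnew) {
  xs <- zscore_apply(xnew, fit$scaling)
  dv <- attr(predict(fit$svm, xs, decision.values = TRUE), "decision.values")[, 1]
  fit$orient * dv
}

#' Fit the SVM classifier on one training fold
#'
#' Radial-basis kernel with a median-heuristic bandwidth on z-scored
#' features; the cost C is chosen from the candidate grid by inner-CV AUC.
#' Decision scores (oriented so larger means more case-like) serve for
#' ranking; class predictions fall at the decision boundary.
#'
#' @inheritParams fit_en_fold
#' @return A `qeeg_svm_fit`.
#' @export
fit_svm_fold <- function(train, spec = model_spec("svm")) {
  fit_svm_core(feature_matrix_predictors(train), train$label, spec,
               seed = derive_seed(spec$seed, "fit-svm"))
}

# ---- random forest --------------------------------------------------------

fit_rf_core <- function(x, y, spec, seed) {
  check_two_class_train(y)
  mtry <- spec$rf_mtry %||% max(1L, floor(sqrt(ncol(x))))
  rf <- with_seed(seed,
    randomForest::randomForest(x = x, y = factor(y, levels = c(0, 1)),
                               ntree = spec$rf_n_trees, mtry = mtry))
  structure(list(rf = rf, mtry = mtry, method = "rf"), class = "qeeg_rf_fit")
}

predict_rf <- function(fit, xnew) {
  predict(fit$rf, xnew, type = "prob")[, "1"]
}

#' Fit the random-forest classifier on one training fold
#'
#' 500 trees by default with `floor(sqrt(p))` candidate features per
#' split; class probabilities are tree vote fractions.
#'
#' @inheritParams fit_en_fold
#' @return A `qeeg_rf_fit` (the underlying forest in `$rf`).
#' @export
fit_rf_fold <- function(train, spec = model_spec("rf")) {
  fit_rf_core(feature_matrix_predictors(train), train$label, spec,
              seed = derive_seed(spec$seed, "fit-rf"))
}

# ---- evaluation -----------------------------------------------------------

#' Mann-Whitney AUC
#'
#' Probability that a randomly chosen case outranks a randomly chosen
#' control, with ties counted half.
#'
#' @param scores Numeric ranking scores (larger = more case-like).
#' @param labels Binary labels (case = 1).
#' @return AUC in `[0, 1]`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    qeeg_abort("AUC undefined: test set contains a single class",
               "qeeg_error_metric_undefined")
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Fold-level classification metrics
#'
#' AUC from ranking scores (Mann-Whitney form, ties half-credited) and
#' sensitivity/specificity from class probabilities at threshold 0.5 with
#' cases positive.
#'
#' @param scores Ranking scores.
#' @param probs Class-1 probabilities (or any score on a 0-1 scale whose
#'   0.5 point is the decision boundary).
#' @param labels Binary labels (case = 1).
#' @return A one-row tibble with `auc`, `sensitivity`, `specificity`.
#' @export
evaluate_fold <- function(scores, probs, labels) {
  auc <- auc_mann_whitney(scores, labels)
  tibble::tibble(
    auc = auc,
    sensitivity = mean(probs[labels == 1] > 0.5),
    specificity = mean(probs[labels == 0] <= 0.5)
  )
}

# Lean numeric core shared by cross_validate() and the permutation loop:
# identical algorithm, no tibble construction on the hot path.
cv_core <- function(x, y, spec) {
  k <- spec$outer_folds
  folds <- stratified_kfold(y, k, seed = derive_seed(spec$seed, "outer-folds"),
                            stratify = spec$stratify)
  auc <- sens <- spc <- numeric(k)
  coefs <- if (spec$method == "en") matrix(NA_real_, ncol(x), k,
                                           dimnames = list(colnames(x), NULL))
  fold_lambda <- rep(NA_real_, k)
  for (f in seq_len(k)) {
    te <- folds == f
    res <- tryCatch(
      fold_fit_predict(spec$method, x[!te, , drop = FALSE], y[!te],
                       x[te, , drop = FALSE], spec,
                       seed = derive_seed(spec$seed, "fold", f)),
      error = function(e) {
        qeeg_abort(paste0("fold ", f, ": ", conditionMessage(e)),
                   "qeeg_error_fold", parent = e)
      }
    )
    y_te <- y[te]
    auc[f] <- auc_mann_whitney(res$scores, y_te)
    sens[f] <- mean(res$probs[y_te == 1] > 0.5)
    spc[f] <- mean(res$probs[y_te == 0] <= 0.5)
    if (spec$method == "en") {
      coefs[, f] <- res$fit$coef
      fold_lambda[f] <- res$fit$lambda
    }
  }
  list(folds = folds, auc = auc, sensitivity = sens, specificity = spc,
       coefficients = coefs, fold_lambda = fold_lambda)
}

fold_fit_predict <- function(method, x_tr, y_tr, x_te, spec, seed) {
  fit <- switch(method,
    en  = fit_en_core(x_tr, y_tr, spec, seed),
    svm = fit_svm_core(x_tr, y_tr, spec, seed),
    rf  = fit_rf_core(x_tr, y_tr, spec, seed)
  )
  out <- switch(method,
    en  = { p <- predict_en(fit, x_te);  list(scores = p, probs = p) },
    svm = { s <- predict_svm(fit, x_te); list(scores = s, probs = plogis(s)) },
    rf  = { p <- predict_rf(fit, x_te);  list(scores = p, probs = p) }
  )
  out$fit <- fit
  out
}

#' Cross-validate a model on a feature matrix
#'
#' Stratified 10-fold cross-validation: for each fold the model is fitted
#' on the other nine tenths (all preprocessing, z-scoring and
#' hyperparameter selection confined to the training part) and evaluated
#' on the held-out tenth. For the elastic net the per-fold coefficient
#' vectors are retained for the feature-survival rule.
#'
#' @param fm A `qeeg_features` tibble from [build_feature_matrix()].
#' @param spec A [model_spec()].
#' @return An object of class `qeeg_cv` with per-fold metrics
#'   ([tidy()]), a mean (SD) summary on the percent scale ([glance()]),
#'   fold assignments and (EN only) the p x k coefficient matrix.
#' @export
cross_validate <- function(fm, spec = model_spec("en")) {
  stopifnot(is.data.frame(fm))
  y <- fm$label
  if (!all(y %in% c(0, 1))) {
    qeeg_abort("labels must be binary 0/1 (case = 1)", "qeeg_error_validation")
  }
  x <- feature_matrix_predictors(fm)
  core <- cv_core(x, y, spec)
  metrics <- tibble::tibble(fold = seq_along(core$auc), auc = core$auc,
                            sensitivity = core$sensitivity,
                            specificity = core$specificity)
  structure(
    list(
      method = spec$method, spec = spec,
      folds = tibble::tibble(subject_id = fm$subject_id, label = y,
                             fold = core$folds),
      metrics = metrics,
      coefficients = core$coefficients, fold_lambda = core$fold_lambda,
      n = nrow(fm), p = ncol(x),
      combo = attr(fm, "combo")
    ),
    class = "qeeg_cv"
  )
}

#' @export
print.qeeg_cv <- function(x, ...) {
  g <- glance(x)
  cat("<qeeg_cv> ", toupper(x$method), ", ", x$n, " subjects x ", x$p,
      " features, ", max(x$folds$fold), " folds\n", sep = "")
  cat(sprintf("  AUC %.2f (%.2f)%%  Sens %.2f (%.2f)%%  Spec %.2f (%.2f)%%\n",
              g$mean_auc, g$sd_auc, g$mean_sensitivity, g$sd_sensitivity,
              g$mean_specificity, g$sd_specificity))
  invisible(x)
}

#' @rdname cross_validate
#' @param x A `qeeg_cv` object.
#' @param ... Unused.
#' @export
tidy.qeeg_cv <- function(x, ...) x$metrics

#' @rdname cross_validate
#' @export
glance.qeeg_cv <- function(x, ...) {
  m <- x$metrics
  tibble::tibble(
    method = x$method, n = x$n, p = x$p, k = max(m$fold),
    mean_auc = 100 * mean(m$auc), sd_auc = stats::sd(100 * m$auc),
    mean_sensitivity = 100 * mean(m$sensitivity),
    sd_sensitivity = stats::sd(100 * m$sensitivity),
    mean_specificity = 100 * mean(m$specificity),
    sd_specificity = stats::sd(100 * m$specificity)
  )
}
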