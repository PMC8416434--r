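test_that("stratified folds balance classes and sizes deterministically", {
  y <- rep(c(0, 1), each = 50)
  f <- stratified_kfold(y, k = 10, seed = 7)
  expect_equal(unname(table(f)), rep(10L, 10), ignore_attr = TRUE)
  for (k in 1:10) expect_equal(sum(y[f == k]), 5)
  expect_identical(f, stratified_kfold(y, k = 10, seed = 7))
  expect_false(identical(f, stratified_kfold(y, k = 10, seed = 8)))
  # uneven classes still satisfy the +-1 contracts
  y2 <- rep(c(0, 1), c(41, 62))
  f2 <- stratified_kfold(y2, k = 10, seed = 3)
  expect_lte(diff(range(table(f2))), 1)
  for (k in 1:10) {
    expect_lte(abs(sum(y2[f2 == k]) - 6.2), 1)
  }
  expect_error(stratified_kfold(rep(c(0, 1), c(9, 91)), k = 10, seed = 1),
               class = "qeeg_error_infeasible_stratification")
})

test_that("Mann-Whitney AUC equals brute-force pair counting", {
  expect_equal(auc_mann_whitney(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  set.seed(61)
  for (r in 1:100) {
    n1 <- sample(2:8, 1); n0 <- sample(2:8, 1)
    labels <- rep(c(1, 0), c(n1, n0))
    scores <- sample(seq(0, 1, by = 0.1), n1 + n0, replace = TRUE)  # many ties
    expect_equal(auc_mann_whitney(scores, labels),
                 auc_pairs_oracle(scores, labels))
  }
  expect_equal(auc_mann_whitney(rep(0.3, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auc_mann_whitney(1:4, rep(1, 4)), class = "qeeg_error_metric_undefined")
})

test_that("the AUC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(60)
  for (r in 1:10) {
    labels <- rep(c(0, 1), c(20, 15))
    scores <- rnorm(35) + 0.8 * labels
    ref <- as.numeric(suppressMessages(pROC::auc(labels, scores,
                                                 direction = "<")))
    expect_equal(auc_mann_whitney(scores, labels), ref)
  }
})

test_that("fold metrics report perfect and tied rankings correctly", {
  m <- evaluate_fold(scores = c(0.9, 0.8, 0.2, 0.1), probs = c(0.9, 0.8, 0.2, 0.1),
                     labels = c(1, 1, 0, 0))
  expect_equal(m$auc, 1)
  expect_equal(m$sensitivity, 1)
  expect_equal(m$specificity, 1)
})

test_that("the elastic net recovers its null-model and strong-signal limits", {
  fm <- toy_feature_matrix(n_cases = 30, n_controls = 20, d = 0, seed = 62)
  fit <- fit_en_fold(fm, model_spec("en", seed = 1))
  # at the top of the path all coefficients vanish and the intercept is the
  # training log-odds
  cf <- as.matrix(coef(fit$glmnet_fit, s = max(fit$lambda_path)))
  expect_true(all(cf[-1, 1] == 0))
  expect_equal(cf[1, 1], qlogis(30 / 50), tolerance = 1e-6)
  # a d = 3 separating feature is selected essentially always
  hits <- 0
  for (s in 1:25) {
    fm_s <- toy_feature_matrix(n_cases = 50, n_controls = 50, d = 3, seed = 100 + s)
    f <- fit_en_fold(fm_s, model_spec("en", seed = s))
    hits <- hits + (f$coef["signal"] > 0)
  }
  expect_gte(hits, 24)
})

test_that("correlated duplicates share weight under the elastic-net penalty", {
  fm <- toy_feature_matrix(n_cases = 100, n_controls = 100, d = 2, seed = 63)
  fm$signal_copy <- fm$signal
  fit <- fit_en_fold(fm, model_spec("en", en_mixing = 0.5, seed = 2))
  b1 <- fit$coef["signal"]; b2 <- fit$coef["signal_copy"]
  expect_gt(b1, 0); expect_gt(b2, 0)
  expect_gt(b1 / b2, 0.5); expect_lt(b1 / b2, 2)
})

test_that("elastic-net mixing spans the lasso-ridge continuum", {
  fm <- toy_feature_matrix(n_cases = 40, n_controls = 40, p_noise = 20, d = 1.5,
                           seed = 64)
  lasso <- fit_en_fold(fm, model_spec("en", en_mixing = 1, seed = 3))
  expect_gt(sum(lasso$coef == 0), 0)
  ridge_ish <- fit_en_fold(fm, model_spec("en", en_mixing = 0.01, seed = 3))
  expect_equal(sum(ridge_ish$coef == 0), 0)
})

test_that("the SVM separates separable data and honours in-fold standardization", {
  set.seed(65)
  n <- 40
  x1 <- c(rnorm(n / 2, -3), rnorm(n / 2, 3))
  fm <- tibble::tibble(subject_id = as.character(1:n),
                       label = rep(c(0, 1), each = n / 2),
                       f1 = x1, f2 = rnorm(n))
  fit <- fit_svm_fold(fm, model_spec("svm", seed = 4))
  scores <- qeegclass:::predict_svm(fit, qeegclass:::feature_matrix_predictors(fm))
  expect_equal(auc_mann_whitney(scores, fm$label), 1)
  # rescaling a feature by 1000 leaves predictions invariant (z-scoring)
  fm2 <- fm; fm2$f1 <- fm2$f1 * 1000
  fit2 <- fit_svm_fold(fm2, model_spec("svm", seed = 4))
  scores2 <- qeegclass:::predict_svm(fit2, qeegclass:::feature_matrix_predictors(fm2))
  expect_equal(scores2, scores, tolerance = 1e-6)
})

test_that("shuffled labels give chance-level inner-CV AUC for the SVM", {
  inside <- 0
  for (s in 1:20) {
    set.seed(200 + s)
    n <- 60
    fm <- tibble::tibble(subject_id = as.character(1:n),
                         label = sample(rep(c(0, 1), each = n / 2)),
                         f1 = rnorm(n), f2 = rnorm(n), f3 = rnorm(n))
    fit <- fit_svm_fold(fm, model_spec("svm", inner_cv_folds = 5, seed = s))
    best_auc <- max(fit$grid_auc)
    inside <- inside + (best_auc > 0.3 && best_auc < 0.75)
  }
  expect_gte(inside, 17)
})

test_that("random-forest uses sqrt(p) split candidates and ranks a pure signal first", {
  fm <- toy_feature_matrix(n_cases = 20, n_controls = 20, p_noise = 189, d = 0,
                           seed = 66)
  fit <- fit_rf_fold(fm, model_spec("rf", rf_n_trees = 50, seed = 5))
  expect_equal(fit$mtry, floor(sqrt(190)))   # 13
  hits <- 0
  for (s in 1:20) {
    fm_s <- toy_feature_matrix(n_cases = 30, n_controls = 30, p_noise = 10, d = 3,
                               seed = 300 + s)
    f <- fit_rf_fold(fm_s, model_spec("rf", rf_n_trees = 200, seed = s))
    imp <- randomForest::importance(f$rf)
    hits <- hits + (rownames(imp)[which.max(imp)] == "signal")
  }
  expect_gte(hits, 19)
})

test_that("degenerate single-class training folds fail loudly", {
  fm <- toy_feature_matrix(n_cases = 10, n_controls = 10, seed = 67)
  fm$label <- 1
  expect_error(fit_en_fold(fm), class = "qeeg_error_fit_failure")
  expect_error(fit_svm_fold(fm), class = "qeeg_error_fit_failure")
  expect_error(fit_rf_fold(fm), class = "qeeg_error_fit_failure")
})

test_that("cross-validation is deterministic and its summary recomputes exactly", {
  fm <- toy_feature_matrix(n_cases = 30, n_controls = 30, d = 1, seed = 68)
  spec <- model_spec("en", inner_cv_folds = 5, seed = 11)
  cv1 <- cross_validate(fm, spec)
  cv2 <- cross_validate(fm, spec)
  expect_identical(tidy(cv1), tidy(cv2))
  expect_identical(cv1$coefficients, cv2$coefficients)
  g <- glance(cv1)
  expect_equal(g$mean_auc, 100 * mean(cv1$metrics$auc))
  expect_equal(g$sd_auc, sd(100 * cv1$metrics$auc))
  expect_equal(sort(unique(cv1$folds$fold)), 1:10)
  expect_equal(ncol(cv1$coefficients), 10)
})

test_that("test-fold feature values never influence the training fit", {
  fm <- toy_feature_matrix(n_cases = 20, n_controls = 20, d = 1, seed = 69)
  spec <- model_spec("en", inner_cv_folds = 3, seed = 12)
  folds <- stratified_kfold(fm$label, 10,
                            seed = qeegclass:::derive_seed(spec$seed, "outer-folds"))
  te <- folds == 1
  x <- qeegclass:::feature_matrix_predictors(fm)
  fit_a <- qeegclass:::fit_en_core(x[!te, ], fm$label[!te], spec, seed = 99)
  x2 <- x
  x2[te, "signal"] <- rev(x2[te, "signal"])   # permute test rows only
  fit_b <- qeegclass:::fit_en_core(x2[!te, ], fm$label[!te], spec, seed = 99)
  expect_identical(fit_a$coef, fit_b$coef)
  expect_identical(fit_a$lambda, fit_b$lambda)
})
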