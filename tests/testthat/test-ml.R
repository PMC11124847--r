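small_clf <- function(seed = 3) {
  generate_classification_dataset(classification_spec(), acq_fast(),
                                  seed = seed)
}

test_that("make_split divides 97 rows into 73 train / 24 test, deterministically", {
  sp <- make_split(97, split_spec(0.75, seed = 1))
  expect_equal(length(sp$train), 73)
  expect_equal(length(sp$test), 24)
  expect_equal(sort(c(sp$train, sp$test)), 1:97)
  expect_identical(sp, make_split(97, split_spec(0.75, seed = 1)))
  expect_false(identical(sp, make_split(97, split_spec(0.75, seed = 2))))
  expect_error(make_split(3, split_spec()), "n >= 4")
})

test_that("stratified splits keep every class on both sides", {
  y <- factor(rep(1:4, each = 5))
  sp <- make_split(20, split_spec(0.75, seed = 2, stratify = TRUE),
                   labels = y)
  expect_equal(length(sp$train), 16)
  for (lv in levels(y)) {
    expect_gte(sum(y[sp$train] == lv), 1)
    expect_gte(sum(y[sp$test] == lv), 1)
  }
  expect_error(
    make_split(5, split_spec(stratify = TRUE),
               labels = factor(c(1, 1, 1, 1, 2))),
    ">= 2 rows")
})

test_that("a realizable linear target gives R^2 = 1 and constant labels follow the convention", {
  set.seed(10)
  X <- matrix(rnorm(40 * 6), 40)
  grid <- seq(0, 1, length.out = 6)
  y <- 2 * X[, 1] - X[, 3]
  ds <- structure(
    list(signals = X, grid = grid, labels = tibble::tibble(target = y),
         truth = tibble::tibble(target = y), kind = "regression",
         spec = NULL, acq = acquisition_config(), seed = 1),
    class = "otter_dataset")
  rownames(ds$signals) <- sprintf("s%03d", 1:40)
  rep1 <- run_regression_suite(ds, split_spec(seed = 1),
                               models = "linear")
  expect_equal(rep1$r2_train, 1, tolerance = 1e-10)
  expect_equal(rep1$r2_test, 1, tolerance = 1e-10)
  ds$labels$target <- rep(0.4, 40)
  rep2 <- run_regression_suite(ds, split_spec(seed = 1),
                               models = "linear")
  expect_equal(rep2$r2_train, 0)   # R^2 := 0 for a degenerate target
  expect_equal(rep2$rmse_train, 0, tolerance = 1e-12)
})

test_that("unknown registry names are rejected", {
  ds <- generate_regression_dataset(regression_spec(n_signals = 12),
                                    acq_fast(), seed = 1)
  rep <- run_regression_suite(ds, split_spec(seed = 1),
                              models = c("linear", "no_such_model"))
  expect_match(rep$error[rep$model == "no_such_model"], "unknown")
  expect_error(fit_estimator("no_such_model", ds$signals,
                             ds$labels$hydration),
               "unknown regression model")
})

test_that("regression reports are complete and deterministic", {
  ds <- generate_regression_dataset(regression_spec(n_signals = 16),
                                    acq_fast(), seed = 2)
  models <- c("linear", "knn", "ridgecv")
  r1 <- run_regression_suite(ds, split_spec(seed = 5), models = models)
  r2 <- run_regression_suite(ds, split_spec(seed = 5), models = models)
  expect_equal(r1$model, models)
  expect_equal(r1$r2_test, r2$r2_test)
  expect_equal(r1$predictions, r2$predictions)
})

test_that("two constant, distinct classes are perfectly classified by every model", {
  spec <- classification_spec(n_classes = 2, per_class = 6,
                              class_hydration = c(0.35, 0.75),
                              class_amplitude = c(0.9, 1.2),
                              hydration_sd = 0, amplitude_sd = 0)
  ds <- generate_classification_dataset(spec, acq_fast(noise_sd = 0),
                                        seed = 1)
  rep <- run_classification_suite(ds, split_spec(seed = 1, stratify = TRUE))
  expect_equal(rep$model, classification_models())
  expect_true(all(is.na(rep$error)))
  expect_true(all(rep$accuracy_train_pct == 100))
  expect_true(all(rep$accuracy_test_pct == 100))
})

test_that("classification reports carry consistent confusion tables", {
  ds <- small_clf()
  rep <- run_classification_suite(ds, split_spec(seed = 2, stratify = TRUE),
                                  models = c("logistic", "lda"))
  expect_true(all(rep$accuracy_train_pct >= 0 & rep$accuracy_train_pct <= 100))
  sp <- attr(rep, "split")
  for (i in seq_len(nrow(rep))) {
    expect_equal(sum(rep$confusion_train[[i]]), length(sp$train))
    expect_equal(sum(rep$confusion_test[[i]]), length(sp$test))
  }
})

test_that("training predictions do not depend on the test rows (no leakage)", {
  ds <- small_clf()
  X <- ds$signals
  y <- ds$labels$subject
  sp <- make_split(20, split_spec(seed = 4, stratify = TRUE), labels = y)
  est <- fit_estimator("random_forest", X[sp$train, ], y[sp$train],
                       seed = 7)
  pred_full <- predict(est, X[sp$train, ])
  # dropping a test row changes nothing the model saw
  est2 <- fit_estimator("random_forest", X[sp$train, ], y[sp$train],
                        seed = 7)
  expect_identical(as.character(pred_full),
                   as.character(predict(est2, X[sp$train, ])))
})

test_that("PCA embedding matches a brute-force eigendecomposition up to sign", {
  set.seed(12)
  X <- matrix(rnorm(10 * 6), 10)
  ds <- structure(
    list(signals = X, grid = seq(0, 1, length.out = 6),
         labels = tibble::tibble(value = rnorm(10)),
         truth = tibble::tibble(value = rnorm(10)), kind = "regression",
         spec = NULL, acq = acquisition_config(), seed = 1),
    class = "otter_dataset")
  rownames(ds$signals) <- sprintf("s%03d", 1:10)
  emb <- embed_signals(ds, "pca", 2)
  ref <- brute_pca_scores(X, 2)
  for (k in 1:2) {
    got <- emb[[paste0("comp", k)]]
    expect_lt(min(max(abs(got - ref[, k])), max(abs(got + ref[, k]))), 1e-8)
  }
  evr <- attr(emb, "explained_variance_ratio")
  expect_true(all(diff(evr) <= 1e-12))
  expect_equal(sum(evr), 1)
})

test_that("PCA reconstructs exactly planar data from two components", {
  set.seed(13)
  basis <- qr.Q(qr(matrix(rnorm(36), 6)))[, 1:2]
  scores <- matrix(rnorm(24), 12)
  X <- scores %*% t(basis) + 1          # rank-2 + offset
  pc <- stats::prcomp(X)
  recon <- pc$x[, 1:2] %*% t(pc$rotation[, 1:2])
  recon <- sweep(recon, 2, pc$center, "+")
  expect_lt(max(abs(recon - X)), 1e-10)
})

test_that("LDA separates the default subjects and enforces its dimension limit", {
  ds <- small_clf()
  emb <- embed_signals(ds, "lda", 2)
  Z <- cbind(emb$comp1, emb$comp2)
  y <- ds$labels$subject
  centroids <- t(vapply(levels(y),
                        function(lv) colMeans(Z[y == lv, , drop = FALSE]),
                        numeric(2)))
  pred <- levels(y)[apply(Z, 1, function(z)
    which.min(colSums((t(centroids) - z)^2)))]
  expect_equal(mean(pred == as.character(y)), 1)
  expect_error(embed_signals(ds, "lda", 4), "n_classes - 1")
  expect_error(embed_signals(ds, "pca", 1000), "exceeds")
})

test_that("a lossless PCA rotation leaves a rotation-invariant classifier unchanged", {
  ds <- small_clf()
  sp_spec <- split_spec(seed = 6, stratify = TRUE)
  # RBF-kernel SVM without per-feature scaling depends on inter-row
  # distances only, which an orthogonal rotation preserves
  full <- pca_then_classify(ds, n_components = 16, model = "svc",
                            split = sp_spec, scale_scores = FALSE,
                            model_options = list(scale = FALSE))
  X <- ds$signals
  y <- ds$labels$subject
  sp <- make_split(20, sp_spec, labels = y)
  est <- fit_estimator("svc", X[sp$train, ], y[sp$train],
                       seed = sp_spec$seed + 1L, scale_features = FALSE,
                       options = list(scale = FALSE))
  direct_tr <- mean(predict(est, X[sp$train, ]) == y[sp$train]) * 100
  direct_te <- mean(predict(est, X[sp$test, ]) == y[sp$test]) * 100
  expect_equal(full$accuracy_train_pct, round(direct_tr, 1))
  expect_equal(full$accuracy_test_pct, round(direct_te, 1))
  expect_error(pca_then_classify(ds, n_components = 0), "whole number")
})

test_that("feature importance zeroes constant features and ranks a copied label first", {
  set.seed(14)
  X <- matrix(rnorm(30 * 5), 30)
  X[, 4] <- 1.7                        # constant feature
  y <- X[, 2]
  est <- fit_estimator("linear", X, y, scale_features = FALSE)
  imp_s <- feature_importance(est, X, y, method = "shapley")
  expect_lt(imp_s$score[4], 1e-10)
  expect_equal(imp_s$rank[2], 1)
  imp_p <- feature_importance(est, X, y, method = "permutation",
                              n_repeats = 3, seed = 2)
  expect_equal(imp_p$score[4], 0)
  expect_equal(imp_p$rank[2], 1)
  expect_error(feature_importance("linear", X, y), "fitted estimator")
})

test_that("permutation importance on the subject dataset favours the early signal", {
  ds <- small_clf(seed = 8)
  X <- ds$signals
  y <- ds$labels$subject
  sp <- make_split(20, split_spec(seed = 1, stratify = TRUE), labels = y)
  est <- fit_estimator("random_forest", X[sp$train, ], y[sp$train],
                       seed = 1)
  imp <- feature_importance(est, X, y, method = "permutation",
                            n_repeats = 3, seed = 1,
                            feature_times = ds$grid)
  quartile_cut <- min(ds$grid) + 0.25 * diff(range(ds$grid))
  top5 <- imp$time_s[imp$rank <= 5]
  expect_gte(mean(top5 <= quartile_cut), 0.8)
  expect_setequal(imp$rank, seq_len(ncol(X)))
})
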