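#' Train/test split specification
#'
#' @param train_fraction Fraction of rows assigned to training
#'   (default 0.75).
#' @param seed Integer seed for the random division.
#' @param stratify Stratify by class label (classification only).
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.75, seed = 1, stratify = FALSE) {
  if (!is.numeric(train_fraction) || length(train_fraction) != 1 ||
      train_fraction <= 0 || train_fraction >= 1) {
    stop("`train_fraction` must lie strictly between 0 and 1",
         call. = FALSE)
  }
  structure(list(train_fraction = train_fraction, seed = as.integer(seed),
                 stratify = isTRUE(stratify)),
            class = "split_spec")
}

#' Randomly divide rows into training and testing sets
#'
#' Deterministic given the seed; the training set holds
#' `round(train_fraction * n)` rows (per class when stratified, with each
#' class contributing at least one row to both sets).
#'
#' @param n Number of rows, at least 4.
#' @param spec A [split_spec()].
#' @param labels Optional class labels; required when `spec$stratify` is
#'   `TRUE`.
#' @return A list with sorted integer vectors `train` and `test`, disjoint
#'   and jointly exhaustive.
#' @examples
#' sp <- make_split(97, split_spec(0.75, seed = 1))
#' lengths(sp)   # 73 train, 24 test
#' @export
make_split <- function(n, spec = split_spec(), labels = NULL) {
  if (n < 4) stop("need n >= 4 rows to split", call. = FALSE)
  set.seed(spec$seed)
  if (spec$stratify) {
    if (is.null(labels)) {
      stop("stratified split requires `labels`", call. = FALSE)
    }
    labels <- as.factor(labels)
    if (length(labels) != n) stop("`labels` must have length n",
                                  call. = FALSE)
    tab <- table(labels)
    if (any(tab < 2)) {
      stop("stratification impossible: every class needs >= 2 rows",
           call. = FALSE)
    }
    train <- integer(0)
    for (lv in levels(labels)) {
      idx <- which(labels == lv)
      k <- round(spec$train_fraction * length(idx))
      k <- min(max(k, 1L), length(idx) - 1L)
      train <- c(train, sample(idx, k))
    }
  } else {
    k <- round(spec$train_fraction * n)
    k <- min(max(k, 1L), n - 1L)
    train <- sample.int(n, k)
  }
  list(train = sort(train), test = sort(setdiff(seq_len(n), train)))
}

r_squared <- function(truth, predicted) {
  ss_tot <- sum((truth - mean(truth))^2)
  if (ss_tot == 0) return(0)   # degenerate constant target: R^2 := 0
  1 - sum((truth - predicted)^2) / ss_tot
}

rmse <- function(truth, predicted) sqrt(mean((truth - predicted)^2))

dataset_features <- function(data) {
  stopifnot(inherits(data, "otter_dataset"))
  X <- data$signals
  colnames(X) <- feature_names(ncol(X))
  X
}

#' Benchmark the regression registry on a labelled dataset
#'
#' Reproduces the study design of a hydration-regression campaign: one
#' random train/test division, every requested registry model fitted on the
#' training rows only, and coefficient of determination plus RMSE reported
#' on both partitions. R-squared on each partition uses that partition's own
#' mean as baseline. A model failure is recorded in the report, never
#' raised. When the dataset carries a label pair (gradient mode), each
#' label column is regressed separately.
#'
#' @param data An `otter_dataset` with continuous labels.
#' @param split A [split_spec()].
#' @param models Registry names to run (default: all thirteen).
#' @param scale_features Standardise features inside each model pipeline
#'   (default `TRUE`).
#' @param model_options Named list of per-model option lists.
#' @return A tibble of class `otter_regression_report`: one row per
#'   model/target with `r2_train`, `r2_test`, `rmse_train`, `rmse_test`, an
#'   `error` column (NA on success), and a `predictions` list-column of
#'   per-row predicted-vs-true pairs. Split indices and seeds are attached
#'   as attributes.
#' @examples
#' \donttest{
#' ds <- generate_regression_dataset(regression_spec(n_signals = 24),
#'                                   acquisition_config(n_points = 64),
#'                                   seed = 1)
#' run_regression_suite(ds, split_spec(seed = 1), models = c("linear", "knn"))
#' }
#' @export
run_regression_suite <- function(data, split = split_spec(),
                                 models = regression_models(),
                                 scale_features = TRUE,
                                 model_options = list()) {
  stopifnot(inherits(data, "otter_dataset"))
  lab <- data$labels
  if (!all(vapply(lab, is.numeric, logical(1)))) {
    stop("regression requires continuous labels", call. = FALSE)
  }
  X <- dataset_features(data)
  sp <- make_split(nrow(X), split)
  rows <- list()
  for (target in names(lab)) {
    y <- lab[[target]]
    for (i in seq_along(models)) {
      m <- models[i]
      seed_m <- split$seed + 1000L * i
      out <- tryCatch({
        est <- fit_estimator(m, X[sp$train, , drop = FALSE], y[sp$train],
                             seed = seed_m, scale_features = scale_features,
                             options = model_options[[m]] %||% list())
        pr_tr <- predict(est, X[sp$train, , drop = FALSE])
        pr_te <- predict(est, X[sp$test, , drop = FALSE])
        preds <- tibble::tibble(
          row = c(sp$train, sp$test),
          partition = rep(c("train", "test"), c(length(sp$train),
                                                length(sp$test))),
          truth = c(y[sp$train], y[sp$test]),
          predicted = c(pr_tr, pr_te))
        tibble::tibble(
          model = m, target = target,
          r2_train = r_squared(y[sp$train], pr_tr),
          r2_test = r_squared(y[sp$test], pr_te),
          rmse_train = rmse(y[sp$train], pr_tr),
          rmse_test = rmse(y[sp$test], pr_te),
          error = NA_character_, predictions = list(preds))
      }, error = function(e) {
        tibble::tibble(model = m, target = target, r2_train = NA_real_,
                       r2_test = NA_real_, rmse_train = NA_real_,
                       rmse_test = NA_real_, error = conditionMessage(e),
                       predictions = list(NULL))
      })
      rows[[length(rows) + 1]] <- out
    }
  }
  report <- dplyr::bind_rows(rows)
  attr(report, "split") <- sp
  attr(report, "split_spec") <- split
  class(report) <- c("otter_regression_report", class(report))
  report
}

accuracy_pct <- function(truth, predicted) {
  round(100 * mean(as.character(truth) == as.character(predicted)), 1)
}

#' Benchmark the classification registry on a labelled dataset
#'
#' One random (by default stratified) train/test division; each requested
#' classifier fitted on training rows only; train and test accuracy in
#' percent (one decimal) and confusion tables reported. Failures are
#' recorded, not raised.
#'
#' @param data An `otter_dataset` with categorical labels.
#' @param split A [split_spec()]; stratification is recommended with few
#'   rows per class.
#' @param models Registry names to run (default: all nine).
#' @inheritParams run_regression_suite
#' @return A tibble of class `otter_classification_report` with per-model
#'   `accuracy_train_pct`, `accuracy_test_pct`, an `error` column, and
#'   `confusion_train` / `confusion_test` list-columns of contingency
#'   tables.
#' @export
run_classification_suite <- function(data,
                                     split = split_spec(stratify = TRUE),
                                     models = classification_models(),
                                     scale_features = TRUE,
                                     model_options = list()) {
  stopifnot(inherits(data, "otter_dataset"))
  y <- data$labels[[1]]
  if (!is.factor(y) && !is.character(y)) {
    stop("classification requires categorical labels", call. = FALSE)
  }
  y <- as.factor(y)
  X <- dataset_features(data)
  sp <- make_split(nrow(X), split,
                   labels = if (split$stratify) y else NULL)
  if (!all(levels(y) %in% unique(as.character(y[sp$train])))) {
    stop("a class is absent from the training partition; use a stratified ",
         "split", call. = FALSE)
  }
  rows <- list()
  for (i in seq_along(models)) {
    m <- models[i]
    seed_m <- split$seed + 1000L * i
    out <- tryCatch({
      est <- fit_estimator(m, X[sp$train, , drop = FALSE], y[sp$train],
                           seed = seed_m, scale_features = scale_features,
                           options = model_options[[m]] %||% list())
      pr_tr <- predict(est, X[sp$train, , drop = FALSE])
      pr_te <- predict(est, X[sp$test, , drop = FALSE])
      tibble::tibble(
        model = m,
        accuracy_train_pct = accuracy_pct(y[sp$train], pr_tr),
        accuracy_test_pct = accuracy_pct(y[sp$test], pr_te),
        error = NA_character_,
        confusion_train = list(table(truth = y[sp$train],
                                     predicted = pr_tr)),
        confusion_test = list(table(truth = y[sp$test],
                                    predicted = pr_te)))
    }, error = function(e) {
      tibble::tibble(model = m, accuracy_train_pct = NA_real_,
                     accuracy_test_pct = NA_real_,
                     error = conditionMessage(e),
                     confusion_train = list(NULL),
                     confusion_test = list(NULL))
    })
    rows[[length(rows) + 1]] <- out
  }
  report <- dplyr::bind_rows(rows)
  attr(report, "split") <- sp
  attr(report, "split_spec") <- split
  class(report) <- c("otter_classification_report", class(report))
  report
}

#' Two-component LDA or PCA embedding of a signal dataset
#'
#' Projects the raw signal rows onto the first components of principal
#' component analysis (maximal variance) or linear discriminant analysis
#' (maximal between- to within-class scatter; requires labels and at most
#' `n_classes - 1` components). PCA coordinates match a brute-force
#' eigendecomposition of the centred covariance matrix up to per-component
#' sign.
#'
#' @param data An `otter_dataset`.
#' @param method `"pca"` or `"lda"`.
#' @param n_components Number of components (default 2).
#' @return A tibble of class `otter_embedding` with columns `row`,
#'   `comp1`, `comp2`, ... and the dataset's first label column; for PCA
#'   the attribute `explained_variance_ratio` holds per-component variance
#'   fractions.
#' @export
embed_signals <- function(data, method = c("pca", "lda"),
                          n_components = 2) {
  stopifnot(inherits(data, "otter_dataset"))
  method <- match.arg(method)
  X <- dataset_features(data)
  if (n_components < 1 || n_components != round(n_components)) {
    stop("`n_components` must be a whole number >= 1", call. = FALSE)
  }
  if (method == "pca") {
    if (n_components > min(nrow(X), ncol(X))) {
      stop("`n_components` exceeds min(n_rows, n_features)", call. = FALSE)
    }
    pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
    coords <- pc$x[, seq_len(n_components), drop = FALSE]
    evr <- pc$sdev^2 / sum(pc$sdev^2)
  } else {
    y <- as.factor(data$labels[[1]])
    if (nlevels(y) < 2) stop("LDA requires labelled classes", call. = FALSE)
    if (n_components > nlevels(y) - 1) {
      stop("LDA allows at most n_classes - 1 components", call. = FALSE)
    }
    fit <- fit_lda_reduced(X, y)
    scores <- predict_lda_reduced(fit, X, type = "scores")
    coords <- scores[, seq_len(n_components), drop = FALSE]
    evr <- NULL
  }
  colnames(coords) <- paste0("comp", seq_len(n_components))
  out <- tibble::as_tibble(coords)
  out <- tibble::add_column(out, row = seq_len(nrow(X)), .before = 1)
  out[[names(data$labels)[1]]] <- data$labels[[1]]
  attr(out, "method") <- method
  if (!is.null(evr)) attr(out, "explained_variance_ratio") <- evr
  class(out) <- c("otter_embedding", class(out))
  out
}

#' Chain a PCA fitted on the training rows into a classifier
#'
#' Principal components are estimated from the training partition only;
#' training and test rows are projected with that transform and the chosen
#' registry classifier consumes the component scores. With all components
#' retained the chain is an information-preserving rotation, so
#' rotation-invariant models (e.g. k-nearest neighbours without feature
#' scaling) reproduce their no-PCA accuracy exactly.
#'
#' @param data An `otter_dataset` with categorical labels.
#' @param n_components Number of principal components fed to the
#'   classifier.
#' @param model Registry classifier name (default `"random_forest"`).
#' @param split A [split_spec()].
#' @param scale_scores Standardise the component scores before the
#'   classifier (default `FALSE`; PCA scores are already centred).
#' @param model_options Options passed to the classifier.
#' @return A one-row `otter_classification_report` tibble.
#' @export
pca_then_classify <- function(data, n_components = 2,
                              model = "random_forest",
                              split = split_spec(stratify = TRUE),
                              scale_scores = FALSE,
                              model_options = list()) {
  stopifnot(inherits(data, "otter_dataset"))
  y <- as.factor(data$labels[[1]])
  X <- dataset_features(data)
  sp <- make_split(nrow(X), split,
                   labels = if (split$stratify) y else NULL)
  if (n_components < 1 || n_components != round(n_components)) {
    stop("`n_components` must be a whole number >= 1", call. = FALSE)
  }
  if (n_components > min(length(sp$train), ncol(X))) {
    stop("`n_components` exceeds the training dimensionality",
         call. = FALSE)
  }
  pc <- stats::prcomp(X[sp$train, , drop = FALSE], center = TRUE,
                      scale. = FALSE)
  Z_tr <- pc$x[, seq_len(n_components), drop = FALSE]
  Z_te <- stats::predict(pc, X[sp$test, , drop = FALSE])[
    , seq_len(n_components), drop = FALSE]
  est <- fit_estimator(model, Z_tr, y[sp$train], seed = split$seed + 1L,
                       scale_features = scale_scores,
                       options = model_options)
  pr_tr <- predict(est, Z_tr)
  pr_te <- predict(est, Z_te)
  report <- tibble::tibble(
    model = sprintf("pca%d_%s", n_components, model),
    accuracy_train_pct = accuracy_pct(y[sp$train], pr_tr),
    accuracy_test_pct = accuracy_pct(y[sp$test], pr_te),
    error = NA_character_,
    confusion_train = list(table(truth = y[sp$train], predicted = pr_tr)),
    confusion_test = list(table(truth = y[sp$test], predicted = pr_te)))
  attr(report, "split") <- sp
  attr(report, "split_spec") <- split
  class(report) <- c("otter_classification_report", class(report))
  report
}

#' Per-feature importance attribution for a fitted estimator
#'
#' Attributes the predictive performance of a fitted registry estimator to
#' the individual signal samples used as features. For linear additive
#' models, exact Shapley values are available in closed form
#' (`|w_j (x_ij - mean_j)|`, averaged over rows); for every other model
#' family, seeded permutation importance (mean performance drop over
#' `n_repeats` column permutations) is the documented general method.
#' `method = "auto"` picks the Shapley route for linear regression models
#' and permutation otherwise.
#'
#' @param model A fitted [fit_estimator()] object. Passing an unfitted
#'   registry name is an error.
#' @param X Evaluation feature matrix.
#' @param y Evaluation labels (continuous or factor, matching the
#'   estimator's kind).
#' @param method `"auto"`, `"permutation"`, or `"shapley"`.
#' @param n_repeats Permutations per feature (default 5).
#' @param seed Seed for the permutation draws.
#' @param feature_times Optional vector of the grid times backing each
#'   column, carried into the report.
#' @return A tibble of class `otter_importance_report` with columns
#'   `feature`, `time_s` (if supplied), `score`, `rank`, and `method`;
#'   `rank` is a permutation of the feature indices (score ties broken by
#'   earliest feature).
#' @export
feature_importance <- function(model, X, y,
                               method = c("auto", "permutation", "shapley"),
                               n_repeats = 5, seed = 1,
                               feature_times = NULL) {
  if (is.character(model)) {
    stop("`model` must be a fitted estimator (see fit_estimator()), not a ",
         "registry name", call. = FALSE)
  }
  stopifnot(inherits(model, "otter_estimator"))
  method <- match.arg(method)
  X <- prep_X(X)
  linear_names <- c("linear", "lasso", "elastic_net", "ridgecv")
  if (method == "auto") {
    method <- if (model$kind == "regression" &&
                  model$name %in% linear_names) "shapley" else "permutation"
  }
  p <- ncol(X)

  if (method == "shapley") {
    if (!(model$kind == "regression" && model$name %in% linear_names)) {
      stop("closed-form Shapley values are available for linear additive ",
           "regression models only; use method = \"permutation\"",
           call. = FALSE)
    }
    coef <- linear_coefficients(model, p)
    ctr <- colMeans(X)
    phi <- sweep(X, 2, ctr, "-") %*% diag(coef, p)
    score <- colMeans(abs(phi))
    tag <- "shapley_linear"
  } else {
    if (model$kind == "classification") {
      y <- factor(as.character(y), levels = model$levels)
      metric <- function(Xe) mean(as.character(predict(model, Xe)) ==
                                    as.character(y))
    } else {
      y <- as.numeric(y)
      metric <- function(Xe) r_squared(y, predict(model, Xe))
    }
    base <- metric(X)
    set.seed(seed)
    perms <- replicate(n_repeats, sample.int(nrow(X)), simplify = FALSE)
    score <- vapply(seq_len(p), function(j) {
      drops <- vapply(perms, function(pm) {
        Xp <- X
        Xp[, j] <- Xp[pm, j]
        base - metric(Xp)
      }, numeric(1))
      mean(drops)
    }, numeric(1))
    tag <- "permutation"
  }

  ord <- order(-score, seq_len(p))
  rank <- integer(p)
  rank[ord] <- seq_len(p)
  out <- tibble::tibble(feature = colnames(X), score = score, rank = rank,
                        method = tag)
  if (!is.null(feature_times)) {
    out <- tibble::add_column(out, time_s = feature_times,
                              .after = "feature")
  }
  class(out) <- c("otter_importance_report", class(out))
  out
}

linear_coefficients <- function(model, p) {
  raw <- if (model$name == "linear") {
    drop(model$fit$coef)
  } else {
    drop(as.matrix(stats::coef(model$fit, s = "lambda.min")))[-1]
  }
  # undo feature standardisation so coefficients act on the raw scale
  if (!is.null(model$scaler)) raw <- raw / model$scaler$scale
  if (length(raw) != p) stop("coefficient/feature mismatch", call. = FALSE)
  raw
}

`%||%` <- function(a, b) if (is.null(a)) b else a
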