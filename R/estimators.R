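# Model registry backing the benchmarking suites. Each entry wraps an
# established estimator behind a common fit/predict pair so that reports,
# importance attribution, and chaining treat all models uniformly.

feature_names <- function(p) sprintf("f%04d", seq_len(p))

prep_X <- function(X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- feature_names(ncol(X))
  X
}

fit_scaler <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1   # constant features pass through
  list(center = ctr, scale = scl)
}

apply_scaler <- function(X, scaler) {
  if (is.null(scaler)) return(X)
  sweep(sweep(X, 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' Names of the regression model registry
#'
#' The thirteen regression estimators benchmarked by the package: lasso,
#' elastic net, decision tree, support vector machine, gradient boosting,
#' ordinary linear regression, random forest, k-nearest neighbours, extreme
#' gradient boosting, partial least squares, a voting (averaging) ensemble,
#' ridge regression with built-in cross-validation, and a neural network.
#'
#' @return Character vector of registry names.
#' @export
regression_models <- function() {
  c("lasso", "elastic_net", "decision_tree", "svm", "gradient_boosting",
    "linear", "random_forest", "knn", "extreme_gradient_boosting", "pls",
    "voting", "ridgecv", "neural_network")
}

#' Names of the classification model registry
#'
#' The nine classifiers benchmarked by the package: multinomial logistic
#' regression, Gaussian naive Bayes, support vector classifier, random
#' forest, bagged trees, AdaBoost (SAMME), gradient boosting, a neural
#' network, and linear discriminant analysis.
#'
#' @return Character vector of registry names.
#' @export
classification_models <- function() {
  c("logistic", "naive_bayes", "svc", "random_forest", "bagging",
    "adaboost", "gradient_boosting", "deep_learning", "lda")
}

opt_or <- function(options, key, default) {
  if (!is.null(options[[key]])) options[[key]] else default
}

# ---- regression backends ----------------------------------------------------

# minimum-norm ordinary least squares via SVD: with more features than
# training rows the interpolating solution of smallest coefficient norm is
# used (the standard behaviour of SVD-based linear solvers)
fit_ols_minnorm <- function(X, y) {
  ctr <- colMeans(X)
  Xc <- sweep(X, 2, ctr, "-")
  ybar <- mean(y)
  sv <- svd(Xc)
  pos <- sv$d > max(sv$d, .Machine$double.eps) * 1e-10
  coef <- if (any(pos)) {
    sv$v[, pos, drop = FALSE] %*%
      (crossprod(sv$u[, pos, drop = FALSE], y - ybar) / sv$d[pos])
  } else {
    matrix(0, ncol(X), 1)
  }
  list(center = ctr, coef = coef, intercept = ybar)
}

predict_ols_minnorm <- function(fit, X) {
  drop(sweep(X, 2, fit$center, "-") %*% fit$coef) + fit$intercept
}

fit_glmnet_cv <- function(X, y, alpha, seed) {
  set.seed(seed)
  nf <- max(3, min(10, floor(length(y) / 3)))
  fit <- glmnet::cv.glmnet(X, y, alpha = alpha, nfolds = nf)
  fit
}

# exact greedy splits (midpoint thresholds): with tens of training rows the
# histogram method can pin a threshold onto a training value and misassign
# points falling marginally outside their class's training range
xgb_reg <- function(X, y, eta, max_depth, nrounds) {
  xgboost::xgb.train(
    params = list(eta = eta, max_depth = max_depth,
                  objective = "reg:squarederror", nthread = 1,
                  tree_method = "exact"),
    data = xgboost::xgb.DMatrix(X, label = y), nrounds = nrounds)
}

regression_backend <- function(name, options = list()) {
  switch(
    name,
    linear = list(
      fit = function(X, y, seed) fit_ols_minnorm(X, y),
      predict = predict_ols_minnorm),
    lasso = list(
      fit = function(X, y, seed) fit_glmnet_cv(X, y, alpha = 1, seed),
      predict = function(f, X) drop(stats::predict(f, X, s = "lambda.min"))),
    elastic_net = list(
      fit = function(X, y, seed) fit_glmnet_cv(X, y, alpha = 0.5, seed),
      predict = function(f, X) drop(stats::predict(f, X, s = "lambda.min"))),
    ridgecv = list(
      fit = function(X, y, seed) fit_glmnet_cv(X, y, alpha = 0, seed),
      predict = function(f, X) drop(stats::predict(f, X, s = "lambda.min"))),
    decision_tree = list(
      fit = function(X, y, seed) {
        set.seed(seed)
        rpart::rpart(y ~ ., data = data.frame(y = y, X), method = "anova")
      },
      predict = function(f, X) stats::predict(f, data.frame(X))),
    svm = list(
      fit = function(X, y, seed) { set.seed(seed); e1071::svm(X, y) },
      predict = function(f, X) as.numeric(stats::predict(f, X))),
    gradient_boosting = list(
      fit = function(X, y, seed)
        xgb_reg(X, y, eta = opt_or(options, "eta", 0.1),
                max_depth = opt_or(options, "max_depth", 3),
                nrounds = opt_or(options, "nrounds", 100)),
      predict = function(f, X) stats::predict(f, X)),
    extreme_gradient_boosting = list(
      fit = function(X, y, seed)
        xgb_reg(X, y, eta = opt_or(options, "eta", 0.3),
                max_depth = opt_or(options, "max_depth", 6),
                nrounds = opt_or(options, "nrounds", 100)),
      predict = function(f, X) stats::predict(f, X)),
    random_forest = list(
      fit = function(X, y, seed) {
        set.seed(seed)
        randomForest::randomForest(X, y,
                                   ntree = opt_or(options, "ntree", 500))
      },
      predict = function(f, X) as.numeric(stats::predict(f, X))),
    knn = list(
      fit = function(X, y, seed)
        caret::knnreg(as.data.frame(X), y, k = opt_or(options, "k", 5)),
      predict = function(f, X) stats::predict(f, as.data.frame(X))),
    pls = list(
      fit = function(X, y, seed) {
        nc <- min(opt_or(options, "ncomp", 2), ncol(X), nrow(X) - 1)
        mixOmics::pls(X, y, ncomp = nc, mode = "regression")
      },
      predict = function(f, X) {
        pr <- stats::predict(f, newdata = X)$predict
        pr[, 1, dim(pr)[3]]
      }),
    voting = list(
      fit = function(X, y, seed) {
        members <- opt_or(options, "members",
                          c("linear", "random_forest", "knn"))
        fits <- lapply(seq_along(members), function(i) {
          b <- regression_backend(members[i])
          list(backend = b, fit = b$fit(X, y, seed + i))
        })
        list(fits = fits)
      },
      predict = function(f, X) {
        preds <- vapply(f$fits,
                        function(m) m$backend$predict(m$fit, X),
                        numeric(nrow(X)))
        rowMeans(preds)
      }),
    neural_network = list(
      fit = function(X, y, seed) {
        set.seed(seed)
        nnet::nnet(x = X, y = y, size = opt_or(options, "size", 16),
                   linout = TRUE, decay = opt_or(options, "decay", 1e-2),
                   maxit = opt_or(options, "maxit", 500),
                   MaxNWts = 1e6, trace = FALSE)
      },
      predict = function(f, X) as.numeric(stats::predict(f, X))),
    stop(sprintf("unknown regression model `%s`; see regression_models()",
                 name), call. = FALSE)
  )
}

# ---- classification backends ------------------------------------------------

# SAMME multi-class AdaBoost over shallow CART trees
fit_adaboost <- function(X, y, n_rounds = 50, maxdepth = 2, seed = 1) {
  set.seed(seed)
  n <- length(y)
  K <- nlevels(y)
  w <- rep(1 / n, n)
  df <- data.frame(y = y, X)
  trees <- list()
  alphas <- numeric(0)
  for (m in seq_len(n_rounds)) {
    tree <- rpart::rpart(
      y ~ ., data = df, weights = w, method = "class",
      control = rpart::rpart.control(maxdepth = maxdepth, cp = 0,
                                     minsplit = 2, xval = 0))
    pred <- stats::predict(tree, df, type = "class")
    err <- sum(w * (pred != y))
    if (err >= 1 - 1 / K) break           # no better than chance: stop
    if (err < 1e-12) {                    # perfect weak learner
      trees[[length(trees) + 1]] <- tree
      alphas[length(alphas) + 1] <- 10
      break
    }
    a <- log((1 - err) / err) + log(K - 1)
    trees[[length(trees) + 1]] <- tree
    alphas[length(alphas) + 1] <- a
    w <- w * exp(a * (pred != y))
    w <- w / sum(w)
  }
  if (!length(trees)) {
    trees <- list(rpart::rpart(y ~ ., data = df, method = "class",
                               control = rpart::rpart.control(xval = 0)))
    alphas <- 1
  }
  list(trees = trees, alphas = alphas, levels = levels(y))
}

predict_adaboost <- function(fit, X) {
  df <- data.frame(X)
  K <- length(fit$levels)
  scores <- matrix(0, nrow(df), K, dimnames = list(NULL, fit$levels))
  for (m in seq_along(fit$trees)) {
    pred <- stats::predict(fit$trees[[m]], df, type = "class")
    scores <- scores + fit$alphas[m] *
      (matrix(fit$levels, nrow(df), K, byrow = TRUE) == as.character(pred))
  }
  factor(fit$levels[max.col(scores, ties.method = "first")],
         levels = fit$levels)
}

# Gaussian naive Bayes with a variance floor so that features constant
# within a class do not produce degenerate densities
fit_naive_bayes <- function(X, y) {
  fit <- e1071::naiveBayes(as.data.frame(X), y)
  eps <- 1e-9 * max(abs(X), 1)
  fit$tables <- lapply(fit$tables, function(tab) {
    tab[, 2] <- pmax(tab[, 2], eps)
    tab
  })
  fit
}

# LDA on a variance-preserving principal-component reduction (rank <= n-1),
# the standard route when there are more features than samples
fit_lda_reduced <- function(X, y, seed = 1) {
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  keep <- which(pc$sdev > max(pc$sdev) * 1e-8)
  if (!length(keep)) keep <- 1L
  Z <- pc$x[, keep, drop = FALSE]
  ld <- tryCatch(
    suppressWarnings(MASS::lda(Z, grouping = y, tol = 1e-10)),
    error = function(e) {
      # degenerate within-class covariance (e.g. exactly repeated signals):
      # break ties with a numerically negligible seeded jitter
      set.seed(seed)
      Zj <- Z + matrix(stats::rnorm(length(Z), sd = max(abs(Z), 1) * 1e-8),
                       nrow(Z))
      suppressWarnings(MASS::lda(Zj, grouping = y, tol = 1e-12))
    })
  list(pc = pc, keep = keep, lda = ld, levels = levels(y))
}

predict_lda_reduced <- function(fit, X, type = c("class", "scores")) {
  type <- match.arg(type)
  Z <- stats::predict(fit$pc, X)[, fit$keep, drop = FALSE]
  pr <- stats::predict(fit$lda, Z)
  if (type == "class") factor(as.character(pr$class), levels = fit$levels)
  else pr$x
}

classification_backend <- function(name, options = list()) {
  switch(
    name,
    logistic = list(
      # multinomial logistic with the customary ridge penalty of penalized
      # logistic solvers (strength 1/(n C), C = 1), which keeps margins
      # finite when small separable classes are fitted
      fit = function(X, y, seed) {
        C <- opt_or(options, "C", 1)
        fit <- suppressWarnings(
          glmnet::glmnet(X, y, family = "multinomial", alpha = 0,
                         lambda = 1 / (length(y) * C),
                         standardize = FALSE))
        list(net = fit, levels = levels(y))
      },
      predict = function(f, X)
        factor(drop(stats::predict(f$net, X, type = "class")),
               levels = f$levels)),
    naive_bayes = list(
      fit = function(X, y, seed) fit_naive_bayes(X, y),
      predict = function(f, X) stats::predict(f, as.data.frame(X))),
    svc = list(
      fit = function(X, y, seed) {
        set.seed(seed)
        e1071::svm(X, y, scale = opt_or(options, "scale", TRUE))
      },
      predict = function(f, X) stats::predict(f, X)),
    random_forest = list(
      fit = function(X, y, seed) {
        set.seed(seed)
        randomForest::randomForest(X, y,
                                   ntree = opt_or(options, "ntree", 500))
      },
      predict = function(f, X) stats::predict(f, X)),
    bagging = list(
      fit = function(X, y, seed) {
        set.seed(seed)
        randomForest::randomForest(X, y, mtry = ncol(X),
                                   ntree = opt_or(options, "ntree", 100))
      },
      predict = function(f, X) stats::predict(f, X)),
    adaboost = list(
      fit = function(X, y, seed)
        fit_adaboost(X, y, n_rounds = opt_or(options, "n_rounds", 50),
                     maxdepth = opt_or(options, "maxdepth", 2),
                     seed = seed),
      predict = predict_adaboost),
    gradient_boosting = list(
      fit = function(X, y, seed) {
        fit <- xgboost::xgb.train(
          params = list(eta = opt_or(options, "eta", 0.1),
                        max_depth = opt_or(options, "max_depth", 3),
                        objective = "multi:softprob",
                        num_class = nlevels(y), nthread = 1,
                        tree_method = "exact"),
          data = xgboost::xgb.DMatrix(X, label = as.integer(y) - 1),
          nrounds = opt_or(options, "nrounds", 100))
        list(booster = fit, levels = levels(y))
      },
      predict = function(f, X) {
        p <- stats::predict(f$booster, xgboost::xgb.DMatrix(X))
        p <- matrix(p, nrow = nrow(X), byrow = FALSE)
        if (ncol(p) != length(f$levels)) {
          p <- matrix(as.numeric(t(p)), nrow = nrow(X), byrow = TRUE)
        }
        factor(f$levels[max.col(p, ties.method = "first")],
               levels = f$levels)
      }),
    deep_learning = list(
      fit = function(X, y, seed) {
        set.seed(seed)
        fit <- nnet::nnet(x = X, y = nnet::class.ind(y),
                          size = opt_or(options, "size", 16),
                          softmax = TRUE,
                          decay = opt_or(options, "decay", 1e-2),
                          maxit = opt_or(options, "maxit", 300),
                          MaxNWts = 1e6, trace = FALSE)
        list(net = fit, levels = levels(y))
      },
      predict = function(f, X) {
        p <- stats::predict(f$net, X)
        factor(f$levels[max.col(p, ties.method = "first")],
               levels = f$levels)
      }),
    lda = list(
      fit = function(X, y, seed) fit_lda_reduced(X, y, seed),
      predict = function(f, X) predict_lda_reduced(f, X)),
    stop(sprintf("unknown classification model `%s`; see classification_models()",
                 name), call. = FALSE)
  )
}

#' Fit a registry estimator
#'
#' Fits one named model from the regression or classification registry on a
#' feature matrix, optionally standardising features (train statistics are
#' stored and re-applied at prediction). This is the building block behind
#' [run_regression_suite()] and [run_classification_suite()]; it is exported
#' so that single models can be fitted, inspected, and passed to
#' [feature_importance()].
#'
#' @param name Registry name (see [regression_models()],
#'   [classification_models()]).
#' @param X Feature matrix, rows = signals.
#' @param y Continuous target (regression) or factor (classification).
#' @param seed Integer seed for stochastic learners.
#' @param scale_features Standardise each feature using training statistics
#'   (default `TRUE`; tree ensembles are unaffected).
#' @param options Named list of per-model overrides (e.g. `list(k = 3)` for
#'   knn, `list(size = 8)` for the neural network).
#' @return An object of class `otter_estimator` with a [predict][stats::predict]
#'   method.
#' @examples
#' X <- matrix(rnorm(200), 40)
#' y <- X[, 1] + rnorm(40, sd = 0.1)
#' est <- fit_estimator("linear", X, y)
#' predict(est, X)[1:3]
#' @export
fit_estimator <- function(name, X, y, seed = 1, scale_features = TRUE,
                          options = list()) {
  X <- prep_X(X)
  kind <- if (is.factor(y) || is.character(y)) "classification" else
    "regression"
  if (kind == "classification") {
    y <- droplevels(as.factor(y))
    backend <- classification_backend(name, options)
  } else {
    y <- as.numeric(y)
    backend <- regression_backend(name, options)
  }
  scaler <- if (scale_features) fit_scaler(X) else NULL
  fit <- backend$fit(apply_scaler(X, scaler), y, seed)
  structure(
    list(name = name, kind = kind, scaler = scaler, fit = fit,
         backend = backend, levels = if (is.factor(y)) levels(y) else NULL,
         feature_names = colnames(X)),
    class = "otter_estimator"
  )
}

#' @export
predict.otter_estimator <- function(object, newdata, ...) {
  X <- prep_X(newdata)
  object$backend$predict(object$fit, apply_scaler(X, object$scaler))
}

#' @export
print.otter_estimator <- function(x, ...) {
  cat(sprintf("<otter_estimator: %s (%s), %d features%s>\n", x$name, x$kind,
              length(x$feature_names),
              if (is.null(x$scaler)) "" else ", standardized"))
  invisible(x)
}
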