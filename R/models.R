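#' Configuration for a window-level classifier
#'
#' Families and printed hyperparameters: random forest and XGBoost default to
#' 100 trees with maximum depth 30; the SVM uses an RBF kernel (cost and
#' gamma are not printed anywhere authoritative, so `cost = 1` and
#' `gamma = 1/n_features` are documented defaults); naive Bayes is Gaussian
#' and has no concept of class weights, so it rejects `class_weights`.
#'
#' @param family one of `"xgboost"`, `"random_forest"`, `"svm_rbf"`,
#'   `"naive_bayes"`.
#' @param n_trees trees / boosting rounds for the tree ensembles.
#' @param max_depth maximum tree depth.
#' @param class_weights optional named weight vector (cost-sensitive
#'   learning), e.g. from [balanced_class_weights()].
#' @param seed RNG seed used at fit time.
#' @param svm_cost,svm_gamma SVM-RBF regularization and kernel width
#'   (`NULL` gamma means `1/n_features`).
#' @return object of class `adl_model_config`.
#' @export
model_config <- function(family = c("xgboost", "random_forest", "svm_rbf",
                                    "naive_bayes"),
                         n_trees = 100, max_depth = 30,
                         class_weights = NULL, seed = 1,
                         svm_cost = 1, svm_gamma = NULL) {
  family <- match.arg(family)
  if (family == "naive_bayes" && !is.null(class_weights)) {
    stop("naive Bayes does not support class weights")
  }
  structure(list(family = family, n_trees = n_trees, max_depth = max_depth,
                 class_weights = class_weights, seed = seed,
                 svm_cost = svm_cost, svm_gamma = svm_gamma),
            class = "adl_model_config")
}

#' Train a window-level classifier
#'
#' Fits the configured model on the feature columns of `features`. Features
#' are z-scored with training-split statistics for the scale-sensitive
#' learners (SVM, naive Bayes); tree models consume raw features. The fitted
#' model stores its feature schema and label vocabulary and refuses
#' mismatched feature matrices at prediction time.
#'
#' @param features training `adl_features` (label column + 106 features).
#' @param cfg an [model_config()].
#' @return object of class `adl_model`.
#' @export
train_model <- function(features, cfg = model_config()) {
  stopifnot(inherits(cfg, "adl_model_config"))
  X <- feature_matrix(features)
  if (any(!is.finite(X))) stop("non-finite feature values in training data")
  y <- factor(as.character(features$label),
              levels = intersect(label_vocabulary(),
                                 unique(as.character(features$label))))
  if (nlevels(y) < 2L) stop("training set contains a single class")
  w <- cfg$class_weights
  if (!is.null(w)) {
    miss <- setdiff(levels(y), names(w))
    if (length(miss)) stop("class_weights missing class(es): ",
                           paste(miss, collapse = ", "))
    w <- w[levels(y)]
  }
  center <- scale_ <- NULL
  if (cfg$family %in% c("svm_rbf", "naive_bayes")) {
    center <- colMeans(X)
    scale_ <- apply(X, 2, stats::sd)
    scale_[scale_ == 0] <- 1
    X <- sweep(sweep(X, 2, center), 2, scale_, "/")
  }
  fit <- with_seed(cfg$seed, switch(
    cfg$family,
    random_forest = ranger::ranger(
      x = as.data.frame(X), y = y,
      num.trees = cfg$n_trees, max.depth = cfg$max_depth,
      class.weights = if (is.null(w)) NULL else unname(w),
      seed = cfg$seed, num.threads = 1),
    xgboost = {
      y0 <- as.integer(y) - 1L
      rw <- if (is.null(w)) rep(1, length(y0)) else unname(w[as.integer(y)])
      dm <- xgboost::xgb.DMatrix(X, label = y0, weight = rw)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = nlevels(y),
                      max_depth = cfg$max_depth,
                      nthread = 1, seed = cfg$seed),
        data = dm, nrounds = cfg$n_trees, verbose = 0)
    },
    svm_rbf = e1071::svm(
      x = X, y = y, kernel = "radial", cost = cfg$svm_cost,
      gamma = cfg$svm_gamma %||% (1 / ncol(X)),
      class.weights = w, scale = FALSE),
    naive_bayes = e1071::naiveBayes(as.data.frame(X), y)))
  structure(list(family = cfg$family, fit = fit, levels = levels(y),
                 schema = colnames(feature_matrix(features)),
                 center = center, scale = scale_, cfg = cfg),
            class = "adl_model")
}

#' @export
print.adl_model <- function(x, ...) {
  cat(sprintf("<adl_model> %s, %d classes, %d features\n",
              x$family, length(x$levels), length(x$schema)))
  invisible(x)
}

#' Predict a label stream from window features
#'
#' One predicted label per feature row, in window time order; stride metadata
#' is propagated from the feature matrix so the result can be postprocessed
#' and scored on the window grid.
#'
#' @param model a fitted [train_model()] result.
#' @param features `adl_features` with the same schema as at training.
#' @return a [prediction_stream()].
#' @export
predict_stream <- function(model, features) {
  stopifnot(inherits(model, "adl_model"))
  miss <- setdiff(model$schema, names(features))
  if (length(miss)) {
    stop("feature schema mismatch; missing column(s): ",
         paste(miss, collapse = ", "))
  }
  X <- as.matrix(features[, model$schema, drop = FALSE])
  if (!identical(colnames(X), model$schema)) {
    stop("feature schema does not match the trained model")
  }
  if (!is.null(model$center)) {
    X <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  }
  lab <- switch(
    model$family,
    random_forest = as.character(
      stats::predict(model$fit, data = as.data.frame(X),
                     num.threads = 1)$predictions),
    xgboost = {
      pr <- stats::predict(model$fit, xgboost::xgb.DMatrix(X))
      model$levels[max.col(matrix(pr, ncol = length(model$levels)),
                           ties.method = "first")]
    },
    svm_rbf = as.character(stats::predict(model$fit, X)),
    naive_bayes = as.character(stats::predict(model$fit,
                                              as.data.frame(X))))
  prediction_stream(lab,
                    stride_s = attr(features, "stride_s") %||% 0.25,
                    start_s = if (nrow(features)) features$window_start_s[1L]
                              else 0)
}
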