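#' Assemble a labeled train/test dataset
#'
#' Stacks positive- and negative-site feature tables, labels them 1/0, and
#' draws a stratified random train/test split.
#'
#' @param pos_features,neg_features Feature tibbles with identical columns
#'   (e.g. from [featurize_sites()]).
#' @param test_fraction Fraction of each class held out for testing
#'   (default 0.3).
#' @param seed Integer seed for the split.
#' @return A `dsb_dataset`: list with `features` (tibble), `labels`
#'   (integer 0/1), `split` (`"train"`/`"test"`), `seed`.
#' @export
assemble_dataset <- function(pos_features, neg_features, test_fraction = 0.3,
                             seed = 1L) {
  if (test_fraction <= 0 || test_fraction >= 1) {
    abort("`test_fraction` must be in (0, 1)")
  }
  pos_features <- as_tibble(pos_features)
  neg_features <- as_tibble(neg_features)
  sym <- c(
    setdiff(names(pos_features), names(neg_features)),
    setdiff(names(neg_features), names(pos_features))
  )
  if (length(sym)) {
    abort(paste0(
      "feature columns differ between classes: ", paste(sym, collapse = ", ")
    ))
  }
  feats <- dplyr::bind_rows(pos_features, neg_features[names(pos_features)])
  if (anyNA(feats)) abort("feature matrix contains missing values")
  labels <- c(rep(1L, nrow(pos_features)), rep(0L, nrow(neg_features)))
  split <- rep("train", length(labels))
  withr::with_seed(seed, {
    for (cl in c(0L, 1L)) {
      i <- which(labels == cl)
      n_test <- round(test_fraction * length(i))
      if (n_test < 1 || n_test >= length(i)) {
        abort("each class needs at least one train and one test row")
      }
      split[sample(i, n_test)] <- "test"
    }
  })
  structure(
    list(features = feats, labels = labels, split = split, seed = seed),
    class = "dsb_dataset"
  )
}

#' @exportS3Method base::print
print.dsb_dataset <- function(x, ...) {
  cat(
    "<dsb_dataset> ", nrow(x$features), " sites x ", ncol(x$features),
    " features (", sum(x$labels == 1L), " pos / ", sum(x$labels == 0L),
    " neg; ", sum(x$split == "train"), " train / ", sum(x$split == "test"),
    " test)\n",
    sep = ""
  )
  invisible(x)
}

dataset_matrix <- function(data, split = NULL) {
  i <- if (is.null(split)) seq_along(data$labels) else which(data$split == split)
  list(
    x = as.matrix(data$features[i, , drop = FALSE]),
    y = data$labels[i]
  )
}

new_dsb_model <- function(family, fit, feature_names, hyperparams, seed,
                          importance = NULL, coefficients = NULL) {
  structure(
    list(
      family = family, fit = fit, feature_names = feature_names,
      hyperparams = hyperparams, seed = seed,
      importance = importance, coefficients = coefficients
    ),
    class = "dsb_model"
  )
}

#' @exportS3Method base::print
print.dsb_model <- function(x, ...) {
  cat("<dsb_model> family: ", x$family, ", ",
    length(x$feature_names), " features\n",
    sep = ""
  )
  invisible(x)
}

#' Train a random forest DSB classifier
#'
#' Ensemble of bootstrap-resampled Gini-split decision trees with
#' per-node feature subsampling, matching the defaults of the original
#' implementation: 500 trees, `mtry = floor(sqrt(p))`, unlimited depth.
#' The prediction score is the fraction of trees voting positive.
#' Variable importance is the mean decrease in out-of-bag accuracy under
#' per-feature permutation.
#'
#' @param data A `dsb_dataset` from [assemble_dataset()].
#' @param num_trees Number of trees (default 500).
#' @param mtry Features tried per split (default `floor(sqrt(p))`).
#' @param min_node_size Minimal node size to attempt a split on
#'   (default 1).
#' @param min_class_size Floor on per-class training rows (default 20).
#' @param seed Integer seed.
#' @return A `dsb_model` with an `importance` tibble and out-of-bag error.
#' @export
train_forest <- function(data, num_trees = 500L, mtry = NULL,
                         min_node_size = 1L, min_class_size = 20L,
                         seed = 1L) {
  stopifnot(inherits(data, "dsb_dataset"))
  tr <- dataset_matrix(data, "train")
  if (length(unique(tr$y)) < 2L) abort("training set has a single class")
  if (min(table(tr$y)) < min_class_size) {
    abort(paste0("need >= ", min_class_size, " training rows per class"))
  }
  p <- ncol(tr$x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  mtry <- min(as.integer(mtry), p)
  fit <- withr::with_seed(seed, {
    forest_train_cpp(tr$x, as.integer(tr$y), as.integer(num_trees),
      mtry, as.integer(min_node_size),
      importance = TRUE
    )
  })
  imp <- tibble(
    feature = colnames(tr$x),
    importance = as.numeric(fit$importance)
  )
  new_dsb_model(
    family = "forest", fit = fit, feature_names = colnames(tr$x),
    hyperparams = list(
      num_trees = as.integer(num_trees), mtry = mtry,
      min_node_size = as.integer(min_node_size)
    ),
    seed = seed,
    importance = dplyr::arrange(imp, dplyr::desc(.data$importance))
  )
}

#' Train an L1-penalized (lasso) logistic DSB classifier
#'
#' Lasso logistic regression with the penalty chosen by cross-validated
#' deviance (glmnet). Features are standardized internally; reported
#' coefficients are on the original feature scale. Constant features are
#' dropped with a warning.
#'
#' @param data A `dsb_dataset`.
#' @param n_folds Cross-validation folds (default 10).
#' @param lambda Which CV-selected penalty to report, `"lambda.min"`
#'   (default) or `"lambda.1se"`.
#' @param seed Integer seed for fold assignment.
#' @return A `dsb_model` with a `coefficients` tibble (including the
#'   intercept).
#' @export
train_lasso <- function(data, n_folds = 10L, lambda = c("lambda.min", "lambda.1se"),
                        seed = 1L) {
  stopifnot(inherits(data, "dsb_dataset"))
  lambda <- match.arg(lambda)
  tr <- dataset_matrix(data, "train")
  if (length(tr$y) < 2L * n_folds) abort("too few training rows for CV")
  if (length(unique(tr$y)) < 2L) abort("training set has a single class")
  const <- apply(tr$x, 2, function(v) length(unique(v)) == 1L)
  if (any(const)) {
    warn(paste0(
      "dropping constant feature(s): ",
      paste(colnames(tr$x)[const], collapse = ", ")
    ))
    tr$x <- tr$x[, !const, drop = FALSE]
  }
  if (ncol(tr$x) < 2L) {
    # glmnet requires >= 2 columns; pad with a zero dummy it will ignore
    tr$x <- cbind(tr$x, .dummy = 0)
  }
  fit <- withr::with_seed(seed, {
    foldid <- sample(rep_len(seq_len(n_folds), length(tr$y)))
    glmnet::cv.glmnet(tr$x, tr$y,
      family = "binomial", alpha = 1,
      foldid = foldid, standardize = TRUE
    )
  })
  cf <- as.matrix(coef(fit, s = lambda))
  coefs <- tibble(
    feature = rownames(cf),
    beta = as.numeric(cf[, 1])
  )
  coefs <- coefs[coefs$feature != ".dummy", , drop = FALSE]
  new_dsb_model(
    family = "lasso_logistic", fit = fit,
    feature_names = setdiff(colnames(tr$x), ".dummy"),
    hyperparams = list(
      n_folds = as.integer(n_folds), lambda = lambda,
      lambda_value = unname(fit[[lambda]])
    ),
    seed = seed, coefficients = coefs
  )
}

#' Train an unpenalized logistic DSB classifier
#'
#' Maximum-likelihood logistic regression with Wald p-values per
#' coefficient, used to attach significance to the lasso's selections.
#' Perfect or quasi-perfect separation is detected and raised as an error
#' (the model has no finite MLE there; use [train_lasso()]).
#'
#' @param data A `dsb_dataset`.
#' @param coef_limit Absolute coefficient size (on standardized-ish scale)
#'   beyond which separation is declared (default 15).
#' @return A `dsb_model` with a `coefficients` tibble (`beta`,
#'   `std_error`, `p_value`).
#' @export
train_logistic <- function(data, coef_limit = 15) {
  stopifnot(inherits(data, "dsb_dataset"))
  tr <- dataset_matrix(data, "train")
  if (length(unique(tr$y)) < 2L) abort("training set has a single class")
  df <- as.data.frame(tr$x)
  df$.y <- tr$y
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = df, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- summary(fit)$coefficients
  if (sep_warn || !fit$converged || anyNA(coef(fit)) ||
    any(abs(coef(fit)[-1]) > coef_limit, na.rm = TRUE)) {
    abort(paste0(
      "(quasi-)separation detected: coefficients diverge; ",
      "use penalized regression (train_lasso) instead"
    ))
  }
  new_dsb_model(
    family = "logistic", fit = fit, feature_names = colnames(tr$x),
    hyperparams = list(), seed = NA_integer_,
    coefficients = tibble(
      feature = rownames(cf),
      beta = unname(cf[, "Estimate"]),
      std_error = unname(cf[, "Std. Error"]),
      p_value = unname(cf[, "Pr(>|z|)"])
    )
  )
}

#' Predict DSB scores
#'
#' Scores new sites with a trained model. The forest returns vote
#' fractions; the logistic families return predicted probabilities. The
#' feature columns of `newdata` must contain the model's features (extra
#' columns are ignored, order is irrelevant).
#'
#' @param object A `dsb_model`.
#' @param newdata Feature tibble, or a `dsb_dataset` (then its `split`
#'   selects rows, default `"test"`).
#' @param split When `newdata` is a dataset: which split to score.
#' @param ... Unused.
#' @return Numeric scores in `[0, 1]`.
#' @export
predict.dsb_model <- function(object, newdata, split = "test", ...) {
  if (inherits(newdata, "dsb_dataset")) {
    newdata <- newdata$features[newdata$split == split, , drop = FALSE]
  }
  newdata <- as_tibble(newdata)
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss)) {
    abort(paste0(
      "feature(s) required by the model are unavailable: ",
      paste(miss, collapse = ", ")
    ))
  }
  x <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  switch(object$family,
    forest = as.numeric(forest_predict_cpp(object$fit$trees, x)),
    lasso_logistic = {
      if (ncol(x) < 2L) x <- cbind(x, .dummy = 0)
      as.numeric(predict(object$fit,
        newx = x, s = object$hyperparams$lambda, type = "response"
      ))
    },
    logistic = as.numeric(predict(object$fit,
      newdata = as.data.frame(x), type = "response"
    )),
    abort(paste0("unknown model family: ", object$family))
  )
}
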