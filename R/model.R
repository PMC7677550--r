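# Boosted-tree regression of iHRV on selected behavioral features:
# STAI-stratified split, TPE hyperparameter tuning, fitting, correlation
# evaluation and exact tree-SHAP attribution.

#' STAI-stratified train/test split
#'
#' Training/discovery subjects have low (STAI-T < 35) or moderately high
#' (STAI-T > 45) trait anxiety; test/replication subjects have moderate
#' scores. Boundary values (exactly 35 or 45) go to the test set, keeping
#' the extremes for training.
#'
#' @param stai_t numeric STAI-T scores.
#' @param ids subject ids (default positional indices).
#' @param low_cut,high_cut stratification cutoffs.
#' @return object of class `split_spec`: `train_ids`, `test_ids`, `rule`.
#' @export
stratified_split <- function(stai_t, ids = seq_along(stai_t),
                             low_cut = 35, high_cut = 45) {
  if (anyNA(stai_t)) stopf("STAI scores must be present for all subjects")
  train <- stai_t < low_cut | stai_t > high_cut
  if (!any(train) || all(train)) {
    stopf("stratified split yields an empty stratum (train n=%d, test n=%d)",
          sum(train), sum(!train))
  }
  structure(list(train_ids = ids[train], test_ids = ids[!train],
                 rule = c(low_cut = low_cut, high_cut = high_cut)),
            class = "split_spec")
}

#' Hyperparameter search space for the boosted-tree model
#'
#' @param eta learning-rate bounds (log-uniform).
#' @param max_depth integer tree-depth bounds.
#' @param min_child_weight minimum child hessian-sum bounds.
#' @param nrounds integer boosting-round bounds (log-uniform).
#' @return list of parameter definitions for [tune_hyperparameters()].
#' @export
hyperparam_space <- function(eta = c(0.01, 0.3), max_depth = c(2, 8),
                             min_child_weight = c(1, 10),
                             nrounds = c(50, 1000)) {
  chk <- function(b, nm) if (b[1] >= b[2]) stopf("%s bounds must be ordered", nm)
  chk(eta, "eta"); chk(max_depth, "max_depth")
  chk(min_child_weight, "min_child_weight"); chk(nrounds, "nrounds")
  list(
    eta = list(type = "lognum", low = eta[1], high = eta[2]),
    max_depth = list(type = "int", low = max_depth[1], high = max_depth[2]),
    min_child_weight = list(type = "num", low = min_child_weight[1],
                            high = min_child_weight[2]),
    nrounds = list(type = "logint", low = nrounds[1], high = nrounds[2])
  )
}

as_feature_matrix <- function(features) {
  X <- as.matrix(features)
  if (is.null(colnames(X))) stopf("features must have column names")
  storage.mode(X) <- "double"
  X
}

#' Fit a gradient-boosted tree regression
#'
#' Squared-error boosted ensemble (exact greedy splits, xgboost-style gain
#' with L2 leaf penalty `lambda = 1`). The base score is the training-target
#' mean. Predictions are deterministic given model and input.
#'
#' @param features numeric matrix or data.frame of predictors (no missing
#'   values; >= 2 rows).
#' @param target numeric response.
#' @param params list with `eta`, `max_depth`, `min_child_weight`,
#'   `nrounds` (e.g. from [tune_hyperparameters()]).
#' @param lambda L2 regularization of leaf weights.
#' @return object of class `gbt_model`; `$train_pred` holds training-set
#'   predictions for diagnostics.
#' @export
fit_model <- function(features, target, params, lambda = 1) {
  X <- as_feature_matrix(features)
  if (nrow(X) < 2) stopf("need at least 2 training rows")
  if (anyNA(X) || anyNA(target)) stopf("missing values must be handled upstream")
  if (length(target) != nrow(X)) stopf("target length must match rows")
  fit <- gbt_fit_cpp(X, as.numeric(target), params$eta,
                     as.integer(params$max_depth), params$min_child_weight,
                     as.integer(params$nrounds), lambda, mean(target))
  structure(list(trees = fit$trees, base_score = fit$base_score,
                 train_pred = as.numeric(fit$train_pred),
                 params = params, lambda = lambda,
                 feature_names = colnames(X)), class = "gbt_model")
}

#' Predict from a fitted boosted-tree model
#'
#' @param object a `gbt_model`.
#' @param newdata matrix or data.frame with the model's feature columns.
#' @param ... unused.
#' @return numeric predictions.
#' @export
predict.gbt_model <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata)[, object$feature_names, drop = FALSE]
  as.numeric(gbt_predict_cpp(object$trees, X, object$base_score))
}

# Mean k-fold CV squared error for one hyperparameter setting; fold
# assignment is supplied so every trial sees identical folds.
cv_mse <- function(X, y, params, foldid, lambda = 1) {
  gbt_cv_mse_cpp(X, as.numeric(y), params$eta, as.integer(params$max_depth),
                 params$min_child_weight, as.integer(params$nrounds), lambda,
                 as.integer(foldid))
}

#' Tune hyperparameters with a tree-structured Parzen estimator
#'
#' Minimizes the mean 10-fold cross-validated squared error over the
#' search space with a TPE sampler: after a seeded random start-up, trials
#' are split at the gamma quantile into good/bad sets, one-dimensional
#' kernel densities are fit to each, and the candidate maximizing the
#' good/bad density ratio is evaluated next. Fully seeded.
#'
#' @param features predictors (>= 20 rows recommended).
#' @param target response.
#' @param space a [hyperparam_space()].
#' @param folds number of CV folds.
#' @param n_trials number of TPE trials (>= 1).
#' @param seed integer seed.
#' @return list with `best` (named parameter list), `best_score` and
#'   `trials` (full history data.frame).
#' @export
tune_hyperparameters <- function(features, target, space = hyperparam_space(),
                                 folds = 10, n_trials = 100, seed = 1) {
  if (n_trials < 1) stopf("n_trials must be >= 1")
  X <- as_feature_matrix(features)
  y <- as.numeric(target)
  if (nrow(X) < folds + 2) stopf("too few rows for %d-fold CV", folds)
  set.seed(derive_seed(seed, "cv-folds"))
  foldid <- sample(rep(seq_len(folds), length.out = nrow(X)))
  res <- tpe_optimize(function(p) cv_mse(X, y, p, foldid), space,
                      n_trials = n_trials, seed = derive_seed(seed, "tpe"))
  res
}

#' Correlation-based model evaluation
#'
#' Pearson and Spearman correlations between predictions and truth with
#' exact two-sided p-values (t approximation) and a Fisher-z 95% confidence
#' interval for the Pearson coefficient.
#'
#' @param predictions,truth numeric vectors (n >= 3).
#' @return list with `pearson_r`, `pearson_p`, `pearson_ci`,
#'   `spearman_rho`, `spearman_p`, `n`.
#' @export
evaluate_predictions <- function(predictions, truth) {
  if (length(predictions) != length(truth)) stopf("length mismatch")
  n <- length(predictions)
  if (n < 3) stopf("need at least 3 pairs")
  if (sd(predictions) < 1e-12 || sd(truth) < 1e-12) {
    warning("zero-variance input: correlation undefined")
    return(list(pearson_r = NA_real_, pearson_p = NA_real_,
                pearson_ci = c(NA_real_, NA_real_),
                spearman_rho = NA_real_, spearman_p = NA_real_, n = n))
  }
  pt <- cor.test(predictions, truth, method = "pearson")
  st <- suppressWarnings(cor.test(predictions, truth, method = "spearman"))
  z <- atanh(pt$estimate)
  se <- 1 / sqrt(n - 3)
  ci <- tanh(z + c(-1, 1) * qnorm(0.975) * se)
  list(pearson_r = unname(pt$estimate), pearson_p = pt$p.value,
       pearson_ci = unname(ci),
       spearman_rho = unname(st$estimate), spearman_p = st$p.value, n = n)
}

#' Exact tree-SHAP attributions
#'
#' Path-dependent tree SHAP for the boosted ensemble. The base value plus
#' the per-row attribution sum reproduces the model prediction to numerical
#' precision (additivity), and the global feature ranking is the mean
#' absolute attribution per feature.
#'
#' @param model a `gbt_model`.
#' @param features rows to explain (model schema).
#' @return matrix (rows x features) of class `shap_matrix` with attributes
#'   `base_value` and `ranking` (feature names by decreasing mean |SHAP|).
#' @export
shap_attributions <- function(model, features) {
  X <- as_feature_matrix(features)
  if (!all(model$feature_names %in% colnames(X))) {
    stopf("feature schema mismatch: missing %s",
          paste(setdiff(model$feature_names, colnames(X)), collapse = ", "))
  }
  X <- X[, model$feature_names, drop = FALSE]
  res <- gbt_shap_cpp(model$trees, X, model$base_score)
  phi <- res$phi
  colnames(phi) <- model$feature_names
  rank_names <- model$feature_names[order(colMeans(abs(phi)), decreasing = TRUE)]
  structure(phi, base_value = res$base_value, ranking = rank_names,
            class = c("shap_matrix", class(phi)))
}
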