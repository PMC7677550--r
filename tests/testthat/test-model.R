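test_that("STAI-stratified split follows the cutoffs and boundary rule", {
  stai <- c(30, 40, 45, 50, 34.9, 35, 44.9, 60)
  sp <- stratified_split(stai, ids = letters[1:8])
  expect_setequal(sp$train_ids, c("a", "d", "e", "h"))
  expect_setequal(sp$test_ids, c("b", "c", "f", "g"))
  expect_error(stratified_split(c(40, 40, 40)), "stratum")
  expect_error(stratified_split(c(NA, 30)), "present")
})

test_that("boosted trees fit, predict deterministically and respect edge cases", {
  set.seed(1)
  n <- 70
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- 2 * X[, 1] - X[, 2] + rnorm(n, 0, 0.3)
  params <- list(eta = 0.1, max_depth = 3, min_child_weight = 2, nrounds = 300)
  m <- fit_model(X, y, params)
  expect_gte(cor(m$train_pred, y), 0.8)
  expect_identical(predict(m, X), predict(m, X))
  expect_equal(predict(m, X), m$train_pred, tolerance = 1e-12)

  # constant target: every prediction equals that constant
  mc <- fit_model(X, rep(3.5, n), list(eta = 0.3, max_depth = 3,
                                       min_child_weight = 1, nrounds = 10))
  expect_true(all(predict(mc, X) == 3.5))
  expect_error(fit_model(X[1, , drop = FALSE], y[1], params), "2 training rows")
})

test_that("TPE tuning is seeded, in-bounds and beats midpoint defaults on signal", {
  set.seed(2)
  n <- 60
  X <- matrix(rnorm(n * 6), n, 6, dimnames = list(NULL, paste0("f", 1:6)))
  y <- 1.5 * X[, 1] + X[, 2]^2 + rnorm(n, 0, 0.3)
  sp <- hyperparam_space()
  t1 <- tune_hyperparameters(X, y, sp, folds = 5, n_trials = 20, seed = 9)
  t2 <- tune_hyperparameters(X, y, sp, folds = 5, n_trials = 20, seed = 9)
  expect_identical(t1$best, t2$best)
  expect_identical(t1$trials, t2$trials)
  b <- t1$best
  expect_true(b$eta >= 0.01 && b$eta <= 0.3)
  expect_true(b$max_depth >= 2 && b$max_depth <= 8 &&
                b$max_depth == round(b$max_depth))
  expect_true(b$min_child_weight >= 1 && b$min_child_weight <= 10)
  expect_true(b$nrounds >= 50 && b$nrounds <= 1000)

  # midpoint defaults evaluated on the same folds the tuner used
  set.seed(derive_seed(9, "cv-folds"))
  foldid <- sample(rep(1:5, length.out = n))
  mid <- list(eta = sqrt(0.01 * 0.3), max_depth = 5, min_child_weight = 5.5,
              nrounds = round(sqrt(50 * 1000)))
  expect_lte(t1$best_score, stresswalk:::cv_mse(X, y, mid, foldid))
  expect_error(tune_hyperparameters(X, y, sp, n_trials = 0), "n_trials")
})

test_that("evaluation reports both correlations with sane nulls", {
  x <- rnorm(50)
  ev <- evaluate_predictions(x, x)
  expect_equal(ev$pearson_r, 1)
  expect_equal(ev$spearman_rho, 1)
  ev2 <- evaluate_predictions(x, -x)
  expect_equal(ev2$pearson_r, -1)

  # independent pairs: |r| concentrated near zero
  rs <- vapply(1:50, function(s) {
    set.seed(s)
    evaluate_predictions(rnorm(1000), rnorm(1000))$pearson_r
  }, numeric(1))
  expect_gte(mean(abs(rs) < 0.1), 0.99)

  expect_warning(evz <- evaluate_predictions(rep(1, 10), rnorm(10)), "zero-variance")
  expect_true(is.na(evz$pearson_r))
  expect_error(evaluate_predictions(1:2, 1:2), "at least 3")
})

test_that("tree SHAP is additive, exact against brute-force Shapley, and ranks signal", {
  set.seed(4)
  n <- 50
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  y <- X[, 1] + 0.5 * X[, 2] * X[, 3] + rnorm(n, 0, 0.1)
  m <- fit_model(X, y, list(eta = 0.3, max_depth = 3, min_child_weight = 2,
                            nrounds = 8))
  sh <- shap_attributions(m, X)
  pred <- predict(m, X)
  expect_lt(max(abs(attr(sh, "base_value") + rowSums(sh) - pred)), 1e-6)

  # independent exact-Shapley oracle on a handful of rows
  for (i in 1:4) {
    expect_equal(unname(sh[i, ]), oracle_shapley(m, X[i, ]), tolerance = 1e-9)
  }

  # one informative + nine noise features: informative ranks first
  set.seed(5)
  X2 <- matrix(rnorm(120 * 10), 120, 10,
               dimnames = list(NULL, c("sig", paste0("n", 1:9))))
  y2 <- 2 * X2[, 1] + rnorm(120, 0, 0.4)
  m2 <- fit_model(X2, y2, list(eta = 0.1, max_depth = 3, min_child_weight = 2,
                               nrounds = 150))
  sh2 <- shap_attributions(m2, X2)
  expect_equal(attr(sh2, "ranking")[1], "sig")

  # constant model attributes nothing
  m3 <- fit_model(X, rep(2, n), list(eta = 0.3, max_depth = 2,
                                     min_child_weight = 1, nrounds = 5))
  expect_equal(max(abs(shap_attributions(m3, X))), 0)
  expect_error(shap_attributions(m, X[, 1:2]), "schema")
})
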