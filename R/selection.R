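# Three-stage feature-selection cascade: zero-variance removal, Spearman
# screen against the iHRV target, then per-family cross-validated Lasso.

#' Drop zero-variance features
#'
#' Removes columns whose variance (after missing-value exclusion) is at or
#' below `tol`, so constant columns and columns varying only by float noise
#' are both dropped.
#'
#' @param table a [build_feature_table()] result.
#' @param tol variance tolerance.
#' @return list with `table` (reduced) and `dropped` (names).
#' @export
drop_zero_variance <- function(table, tol = 1e-12) {
  if (nrow(table) < 2) stopf("need at least 2 rows")
  cols <- feature_columns(table)
  v <- vapply(cols, function(cn) {
    x <- table[[cn]][!is.na(table[[cn]])]
    if (length(x) < 2) 0 else var(x)
  }, numeric(1))
  dropped <- cols[v <= tol]
  keep <- setdiff(cols, dropped)
  if (!length(keep)) stopf("all features have zero variance")
  list(table = subset_features(table, keep), dropped = dropped)
}

#' Spearman screen against the prediction target
#'
#' Keeps features whose Spearman correlation with the target reaches the
#' threshold; by default the absolute value is used so strong negative
#' correlates survive. Missing values are handled pairwise-complete.
#'
#' @param table a feature table.
#' @param target numeric target (e.g. iHRV scores), aligned with rows.
#' @param threshold minimal (absolute) Spearman rho.
#' @param signed if TRUE, keep only rho >= threshold (signed rule).
#' @return list with `table`, `dropped` (named numeric of rho values for
#'   removed features) and `rho` (all correlations).
#' @export
spearman_screen <- function(table, target, threshold = 0.1, signed = FALSE) {
  if (length(target) != nrow(table)) stopf("target length must match table rows")
  cols <- feature_columns(table)
  rho <- vapply(cols, function(cn) {
    suppressWarnings(cor(table[[cn]], target, method = "spearman",
                         use = "pairwise.complete.obs"))
  }, numeric(1))
  stat <- if (signed) rho else abs(rho)
  keep <- cols[!is.na(stat) & stat >= threshold]
  if (!length(keep)) stopf("no features survive the Spearman screen")
  list(table = subset_features(table, keep),
       dropped = rho[setdiff(cols, keep)], rho = rho)
}

#' Per-family cross-validated Lasso selection
#'
#' For each feature family (position, gait, burst) separately: complete
#' rows are z-scored and a Gaussian-response Lasso path is fit; the penalty
#' minimizing 10-fold cross-validated squared error is chosen and the
#' features with nonzero coefficients are selected. The final set is the
#' union across families. Families with no surviving columns are logged and
#' skipped; single-column families are kept when their cross-validated
#' error beats the intercept-only model.
#'
#' @param table a feature table (post screen).
#' @param target numeric target aligned with rows.
#' @param folds number of CV folds.
#' @param seed integer seed for the fold assignment.
#' @return object of class `selection_report`: `per_family_selected` (named
#'   list of coefficient vectors), `final_selected`, `cv_settings`.
#' @export
lasso_select_per_family <- function(table, target, folds = 10, seed = 1) {
  info <- feature_info(table)
  cols <- feature_columns(table)
  fam_of <- setNames(info$family, info$name)
  per_family <- list()
  for (fam in c("position", "gait", "burst")) {
    fcols <- cols[fam_of[cols] == fam]
    if (!length(fcols)) {
      message(sprintf("family '%s' has no surviving features; skipped", fam))
      next
    }
    X <- as.matrix(table[, fcols, drop = FALSE])
    cc <- complete.cases(X) & !is.na(target)
    X <- X[cc, , drop = FALSE]
    y <- target[cc]
    if (nrow(X) < folds + 2) {
      message(sprintf("family '%s' has too few complete rows; skipped", fam))
      next
    }
    set.seed(derive_seed(seed, paste("lasso", fam)))
    foldid <- sample(rep(seq_len(folds), length.out = nrow(X)))
    if (length(fcols) == 1) {
      # glmnet needs >= 2 columns; compare univariate lm vs intercept by CV
      mse <- c(single = 0, null = 0)
      for (f in seq_len(folds)) {
        tr <- foldid != f; te <- !tr
        b <- coef(stats::lm(y[tr] ~ X[tr, 1]))
        mse["single"] <- mse["single"] + sum((y[te] - (b[1] + b[2] * X[te, 1]))^2)
        mse["null"] <- mse["null"] + sum((y[te] - mean(y[tr]))^2)
      }
      if (mse["single"] < mse["null"]) {
        b1 <- coef(stats::lm(y ~ X[, 1]))[2]
        per_family[[fam]] <- setNames(b1, fcols)
      } else {
        per_family[[fam]] <- setNames(numeric(0), character(0))
      }
      next
    }
    cvfit <- glmnet::cv.glmnet(X, y, family = "gaussian", foldid = foldid,
                               standardize = TRUE)
    cf <- coef(cvfit, s = "lambda.min")
    nz <- rownames(cf)[as.vector(cf != 0)]
    nz <- setdiff(nz, "(Intercept)")
    per_family[[fam]] <- setNames(as.numeric(cf[nz, ]), nz)
  }
  final <- unique(unlist(lapply(per_family, names)))
  structure(list(per_family_selected = per_family,
                 final_selected = final %||% character(0),
                 cv_settings = list(folds = folds, seed = seed,
                                    lambda_rule = "lambda.min")),
            class = "selection_report")
}

#' Run the full selection cascade
#'
#' Fixed order: zero-variance removal, Spearman screen, per-family Lasso.
#'
#' @param table a feature table.
#' @param target numeric target aligned with rows.
#' @param threshold Spearman threshold.
#' @param folds,seed Lasso CV settings.
#' @param signed signed Spearman rule (default absolute).
#' @return object of class `selection_report` with the additional fields
#'   `dropped_zero_variance`, `dropped_spearman` and `table` (the reduced
#'   feature table restricted to the final selection).
#' @export
select_features <- function(table, target, threshold = 0.1, folds = 10,
                            seed = 1, signed = FALSE) {
  s1 <- drop_zero_variance(table)
  s2 <- spearman_screen(s1$table, target, threshold = threshold, signed = signed)
  rep3 <- lasso_select_per_family(s2$table, target, folds = folds, seed = seed)
  rep3$dropped_zero_variance <- s1$dropped
  rep3$dropped_spearman <- s2$dropped
  rep3$table <- if (length(rep3$final_selected)) {
    subset_features(s2$table, rep3$final_selected)
  } else s2$table[, "subject_id", drop = FALSE]
  rep3
}
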