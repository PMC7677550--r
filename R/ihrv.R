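# Integrated HRV index: a principal component of {HR, RMSSD, SDNN, HRVTi,
# RR} constrained to load on the HRV metrics and HR but not on respiration.

CARDIO_COLS <- c("HR", "RMSSD", "SDNN", "HRVTi", "RR")

#' Assemble a cardio matrix
#'
#' @param hr,rmssd,sdnn,hrvti,rr numeric vectors, one value per subject.
#' @param subject_id optional row names.
#' @return numeric matrix with columns `HR, RMSSD, SDNN, HRVTi, RR`.
#' @export
cardio_matrix <- function(hr, rmssd, sdnn, hrvti, rr, subject_id = NULL) {
  m <- cbind(HR = hr, RMSSD = rmssd, SDNN = sdnn, HRVTi = hrvti, RR = rr)
  if (!is.null(subject_id)) rownames(m) <- subject_id
  m
}

check_cardio_matrix <- function(m) {
  if (!is.matrix(m) || !identical(colnames(m), CARDIO_COLS)) {
    stopf("cardio matrix must have columns exactly (%s)",
          paste(CARDIO_COLS, collapse = ", "))
  }
  if (anyNA(m)) stopf("cardio matrix must not contain missing values (apply the exclusion policy first)")
  if (nrow(m) < 6) stopf("need at least 6 rows to fit the iHRV component")
  invisible(m)
}

#' Fit the integrated HRV index (iHRV)
#'
#' Columns are z-scored and the correlation matrix eigendecomposed. Each
#' component is oriented so the sum of the three HRV loadings (RMSSD, SDNN,
#' HRVTi) is positive. Candidate components must load at least `hrv_floor`
#' on each HRV metric, at most `-hrv_floor` on HR, and at most `rr_bound`
#' in magnitude on respiration rate; among candidates the one explaining
#' the most variance is selected. Higher scores mean greater vagal
#' prevalence.
#'
#' @param matrix a [cardio_matrix()] (>= 6 complete rows).
#' @param rr_bound maximal tolerated |RR| loading (respiration
#'   decontamination bound).
#' @param hrv_floor minimal |loading| on each of RMSSD/SDNN/HRVTi and HR.
#' @return object of class `ihrv_model`: unit-norm `loadings`,
#'   `explained_variance_fraction`, per-column `center`/`scale`,
#'   `component_index`.
#' @export
fit_ihrv <- function(matrix, rr_bound = 0.2, hrv_floor = 0.3) {
  check_cardio_matrix(matrix)
  ctr <- colMeans(matrix)
  scl <- apply(matrix, 2, sd)
  if (any(scl < 1e-12)) stopf("constant cardio column: %s",
                              paste(CARDIO_COLS[scl < 1e-12], collapse = ", "))
  z <- scale(matrix, center = ctr, scale = scl)
  eig <- eigen(cor(matrix), symmetric = TRUE)
  load <- eig$vectors
  rownames(load) <- CARDIO_COLS
  # orient: HRV loadings sum positive
  for (j in seq_len(ncol(load))) {
    if (sum(load[c("RMSSD", "SDNN", "HRVTi"), j]) < 0) load[, j] <- -load[, j]
  }
  hrv_ok <- apply(load[c("RMSSD", "SDNN", "HRVTi"), , drop = FALSE] >= hrv_floor, 2, all)
  hr_ok <- load["HR", ] <= -hrv_floor
  rr_ok <- abs(load["RR", ]) <= rr_bound
  cand <- which(hrv_ok & hr_ok & rr_ok)
  if (!length(cand)) {
    # name the best near-miss: smallest total constraint violation
    viol <- vapply(seq_len(ncol(load)), function(j) {
      sum(pmax(hrv_floor - load[c("RMSSD", "SDNN", "HRVTi"), j], 0)) +
        max(load["HR", j] + hrv_floor, 0) +
        max(abs(load["RR", j]) - rr_bound, 0)
    }, numeric(1))
    b <- which.min(viol)
    stopf(paste0("no component satisfies the iHRV loading constraints; ",
                 "best near-miss is component %d with loadings (%s)"),
          b, paste(sprintf("%s=%.2f", CARDIO_COLS, load[, b]), collapse = ", "))
  }
  sel <- cand[which.max(eig$values[cand])]
  structure(list(loadings = setNames(load[, sel], CARDIO_COLS),
                 explained_variance_fraction = eig$values[sel] / sum(eig$values),
                 center = ctr, scale = scl,
                 component_index = sel), class = "ihrv_model")
}

#' Score subjects on a fitted iHRV model
#'
#' Score = standardized row (fitting-sample column means/SDs) times the
#' component loadings; affine in each input column. Scoring the fitting
#' matrix yields mean-zero scores.
#'
#' @param model an [fit_ihrv()] result.
#' @param matrix a [cardio_matrix()] with matching columns.
#' @return numeric vector of iHRV scores (higher = more vagal prevalence).
#' @export
score_ihrv <- function(model, matrix) {
  if (!is.matrix(matrix) || !identical(colnames(matrix), CARDIO_COLS)) {
    stopf("matrix columns must match the model schema (%s)",
          paste(CARDIO_COLS, collapse = ", "))
  }
  if (anyNA(matrix)) stopf("matrix must not contain missing values")
  z <- scale(matrix, center = model$center, scale = model$scale)
  drop(z %*% model$loadings)
}
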