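# End-to-end orchestration: simulate -> cardio -> iHRV -> features ->
# selection -> boosted-tree model -> evaluation + SHAP, with text-file
# artifacts and a manifest.

#' Pipeline run configuration
#'
#' Collects every tunable decision with its documented default; unknown
#' names are rejected.
#'
#' @param n cohort size.
#' @param coupling vulnerability-to-physiology effect size.
#' @param seed master seed (per-stage seeds are derived from it).
#' @param n_trials TPE trials for hyperparameter tuning.
#' @param folds CV folds (Lasso and tuning).
#' @param spearman_threshold screen threshold.
#' @param signed_spearman use the signed screen rule.
#' @param rr_bound,hrv_floor iHRV loading constraints.
#' @param low_cut,high_cut STAI-T split cutoffs.
#' @param ecg_snr synthetic ECG signal-to-noise ratio, dB.
#' @param ecg_decimate,resp_decimate integer decimation factors applied
#'   before processing (1 = none; the synthetic cohort is generated at the
#'   post-decimation acquisition rates of 500 and 100 Hz directly).
#' @param duration session length, s.
#' @param out_dir artifact directory, or NULL to skip writing.
#' @return list of class `run_config`.
#' @export
run_config <- function(n = 140, coupling = 1, seed = 1, n_trials = 100,
                       folds = 10, spearman_threshold = 0.1,
                       signed_spearman = FALSE, rr_bound = 0.2,
                       hrv_floor = 0.3, low_cut = 35, high_cut = 45,
                       ecg_snr = 15, ecg_decimate = 1, resp_decimate = 1,
                       duration = 90, out_dir = NULL) {
  structure(as.list(environment()), class = "run_config")
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Stages, in fixed order: cohort simulation; scenario-3 cardio processing
#' (R-peak detection, 3-SD RR cleaning, whole-90-s HRV/respiration
#' summaries); iHRV fitting and scoring; scenario 1-2 behavioral
#' featurization; STAI-stratified split; selection cascade on the training
#' set; TPE tuning; boosted-tree fit; test-set evaluation (against measured
#' iHRV and against the independent STAI-T); tree-SHAP attribution. Every
#' artifact is written (when `out_dir` is set) along with a manifest of
#' config, seeds and per-stage counts.
#'
#' @param config a [run_config()].
#' @param cohort optionally, a pre-generated [generate_cohort()] result.
#' @return list with all stage artifacts (see Details).
#' @export
run_pipeline <- function(config = run_config(), cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  log_counts <- list()

  cohort <- cohort %||% generate_cohort(
    config$n, coupling = config$coupling,
    seed = derive_seed(config$seed, "cohort"),
    duration = config$duration, ecg_snr = config$ecg_snr)
  ids <- vapply(cohort, function(s) s$subject_id, character(1))
  stai <- vapply(cohort, function(s) s$stai_t, numeric(1))
  log_counts$subjects <- length(cohort)

  # --- cardio stage: scenario-3 whole-session summaries -------------------
  cardio_rows <- lapply(cohort, function(s) {
    ses <- s$sessions$dark_maze
    if (is.null(ses$ecg)) stopf("subject %s: missing ECG channel", s$subject_id)
    if (is.null(ses$respiration)) stopf("subject %s: missing respiration channel", s$subject_id)
    ecg <- ses$ecg
    if (config$ecg_decimate > 1) ecg <- decimate_signal(ecg, config$ecg_decimate)
    resp <- ses$respiration
    if (config$resp_decimate > 1) resp <- decimate_signal(resp, config$resp_decimate)
    beats <- detect_r_peaks(ecg)
    if (length(beats$r_times) < 4) {
      return(data.frame(hr = NA, rmssd = NA, sdnn = NA, hrvti = NA, rr = NA))
    }
    nn <- clean_rr(beats)
    sm <- segment_summary(nn, resp, segments = list(c(0, ses$duration)))
    data.frame(hr = sm$hr, rmssd = sm$rmssd, sdnn = sm$sdnn,
               hrvti = sm$hrvti, rr = sm$rr)
  })
  cardio_df <- do.call(rbind, cardio_rows)
  cm <- cardio_matrix(cardio_df$hr, cardio_df$rmssd, cardio_df$sdnn,
                      cardio_df$hrvti, cardio_df$rr, subject_id = ids)
  ok <- complete.cases(cm)
  if (!all(ok)) {
    message(sprintf("excluding %d subject(s) with incomplete cardio summaries", sum(!ok)))
  }
  log_counts$cardio_complete <- sum(ok)

  ihrv <- fit_ihrv(cm[ok, , drop = FALSE], rr_bound = config$rr_bound,
                   hrv_floor = config$hrv_floor)
  scores <- setNames(score_ihrv(ihrv, cm[ok, , drop = FALSE]), ids[ok])

  # --- behavior stage -----------------------------------------------------
  ftab <- build_feature_table(cohort)
  keep <- intersect(ftab$subject_id, names(scores))
  ftab <- structure(ftab[match(keep, ftab$subject_id), , drop = FALSE],
                    feature_info = feature_info(ftab),
                    class = class(ftab))
  scores <- scores[keep]
  stai_k <- stai[match(keep, ids)]
  log_counts$features_total <- length(feature_columns(ftab))
  log_counts$analysed_subjects <- length(keep)

  # --- split + selection on the training set ------------------------------
  split <- stratified_split(stai_k, ids = keep, low_cut = config$low_cut,
                            high_cut = config$high_cut)
  tr <- ftab$subject_id %in% split$train_ids
  sel <- select_features(
    structure(ftab[tr, , drop = FALSE], feature_info = feature_info(ftab),
              class = class(ftab)),
    scores[tr], threshold = config$spearman_threshold,
    folds = config$folds, seed = derive_seed(config$seed, "lasso"),
    signed = config$signed_spearman)
  selected <- sel$final_selected
  if (!length(selected)) {
    warning("Lasso selected no features; falling back to the 5 strongest Spearman correlates")
    rho <- sel$rho %||% numeric(0)
    selected <- names(sort(abs(rho), decreasing = TRUE))[seq_len(min(5, length(rho)))]
  }
  log_counts$features_selected <- length(selected)

  # --- model stage --------------------------------------------------------
  Xtr <- as.matrix(ftab[tr, selected, drop = FALSE])
  Xte <- as.matrix(ftab[!tr, selected, drop = FALSE])
  cc_tr <- complete.cases(Xtr); cc_te <- complete.cases(Xte)
  tuning <- tune_hyperparameters(Xtr[cc_tr, , drop = FALSE], scores[tr][cc_tr],
                                 folds = config$folds,
                                 n_trials = config$n_trials,
                                 seed = derive_seed(config$seed, "tune"))
  model <- fit_model(Xtr[cc_tr, , drop = FALSE], scores[tr][cc_tr], tuning$best)
  pred_te <- predict(model, Xte[cc_te, , drop = FALSE])
  truth_te <- scores[!tr][cc_te]
  stai_te <- stai_k[!tr][cc_te]
  evaluation <- evaluate_predictions(pred_te, truth_te)
  eval_stai <- evaluate_predictions(pred_te, stai_te)
  shap <- shap_attributions(model, Xte[cc_te, , drop = FALSE])

  manifest <- list(
    package_version = as.character(utils::packageVersion("stresswalk")),
    config = unclass(config)[setdiff(names(config), "out_dir")],
    config_hash = config_hash(config),
    counts = log_counts,
    train_n = sum(cc_tr), test_n = sum(cc_te),
    selected_features = selected,
    best_params = tuning$best)

  result <- list(cardio_matrix = cm[ok, , drop = FALSE], ihrv_model = ihrv,
                 ihrv_scores = scores, feature_table = ftab, split = split,
                 selection = sel, selected_features = selected,
                 tuning = tuning, model = model,
                 test_predictions = setNames(pred_te, names(truth_te)),
                 evaluation = evaluation, evaluation_stai = eval_stai,
                 shap = shap, manifest = manifest)
  if (!is.null(config$out_dir)) write_outputs(result, config$out_dir)
  result
}

config_hash <- function(config) {
  s <- paste(deparse(unclass(config)[setdiff(names(config), "out_dir")]),
             collapse = "")
  v <- utf8ToInt(s)
  sprintf("%08x", sum(v * (seq_along(v) %% 97 + 1)) %% 4294967296)
}

# --- text-file artifact I/O ------------------------------------------------

#' Write pipeline artifacts
#'
#' Writes the cardio matrix, iHRV scores and loadings, feature table
#' (family tags preserved), selection report, tuning trials, evaluation
#' report and manifest as CSV/JSON under `dir`.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the directory.
#' @export
write_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(data.frame(subject_id = rownames(result$cardio_matrix),
                       result$cardio_matrix),
            file.path(dir, "cardio_matrix.csv"), row.names = FALSE)
  write.csv(data.frame(subject_id = names(result$ihrv_scores),
                       ihrv = as.numeric(result$ihrv_scores)),
            file.path(dir, "ihrv_scores.csv"), row.names = FALSE)
  write_feature_table(result$feature_table, file.path(dir, "feature_table.csv"))
  jsonlite::write_json(
    list(loadings = as.list(result$ihrv_model$loadings),
         explained_variance_fraction = result$ihrv_model$explained_variance_fraction,
         component_index = result$ihrv_model$component_index),
    file.path(dir, "ihrv_model.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(dropped_zero_variance = result$selection$dropped_zero_variance,
         dropped_spearman = as.list(result$selection$dropped_spearman),
         per_family_selected = lapply(result$selection$per_family_selected, as.list),
         final_selected = result$selection$final_selected,
         cv_settings = result$selection$cv_settings),
    file.path(dir, "selection_report.json"), auto_unbox = TRUE, digits = NA)
  write.csv(result$tuning$trials, file.path(dir, "tuning_trials.csv"),
            row.names = FALSE)
  jsonlite::write_json(
    list(ihrv = result$evaluation, stai = result$evaluation_stai,
         best_params = result$tuning$best,
         counts = result$manifest$counts),
    file.path(dir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
  shap_df <- data.frame(subject_id = rownames(result$shap) %||%
                          names(result$test_predictions),
                        as.data.frame(unclass(result$shap)))
  write.csv(shap_df, file.path(dir, "shap_values.csv"), row.names = FALSE)
  jsonlite::write_json(result$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Trajectory and physiology CSV round-trips
#'
#' Trajectories are headered CSV with columns `t,x,y,z,yaw`; physiology is
#' `t,value` with the sampling rate in a `# fs=` header comment. Malformed
#' rows (non-monotone time) are rejected with their row number.
#'
#' @param traj data.frame `t,x,y,z,yaw`.
#' @param path file path.
#' @return `read_trajectory_csv` returns the data.frame;
#'   `read_physio_csv` returns an [ecg_signal()]/[resp_signal()] according
#'   to `channel`.
#' @export
write_trajectory_csv <- function(traj, path) {
  write.csv(traj[, intersect(c("t", "x", "y", "z", "yaw"), names(traj))],
            path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path) {
  df <- read.csv(path)
  if (!all(c("t", "x", "y") %in% names(df))) stopf("%s: missing t/x/y columns", path)
  bad <- which(diff(df$t) <= 0)
  if (length(bad)) stopf("%s: non-monotone timestamps at row %d", path, bad[1] + 1L)
  df
}

#' @rdname write_trajectory_csv
#' @param signal a `physio_signal`.
#' @export
write_physio_csv <- function(signal, path) {
  con <- file(path, "w")
  writeLines(sprintf("# fs=%.10g t0=%.10g", signal$fs, signal$t0), con)
  write.csv(data.frame(t = signal$t0 + (seq_along(signal$samples) - 1) / signal$fs,
                       value = signal$samples), con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @param channel `"ecg"` or `"resp"`.
#' @export
read_physio_csv <- function(path, channel = c("ecg", "resp")) {
  channel <- match.arg(channel)
  hdr <- readLines(path, n = 1)
  m <- regmatches(hdr, regexec("fs=([0-9.eE+-]+) t0=([0-9.eE+-]+)", hdr))[[1]]
  if (length(m) != 3) stopf("%s: missing '# fs=... t0=...' header", path)
  df <- read.csv(path, comment.char = "#")
  ctor <- if (channel == "ecg") ecg_signal else resp_signal
  ctor(df$value, as.numeric(m[2]), as.numeric(m[3]))
}

#' Feature-table CSV round-trip preserving family tags
#'
#' @param table a [build_feature_table()] result.
#' @param path file path.
#' @return `read_feature_table` returns the `feature_table`.
#' @export
write_feature_table <- function(table, path) {
  info <- feature_info(table)
  con <- file(path, "w")
  writeLines(c(paste0("# family: ", paste(info$family, collapse = ",")),
               paste0("# scenario: ", paste(info$scenario, collapse = ","))), con)
  write.csv(table, con, row.names = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  hdr <- readLines(path, n = 2)
  fam <- strsplit(sub("^# family: ", "", hdr[1]), ",")[[1]]
  scn <- strsplit(sub("^# scenario: ", "", hdr[2]), ",")[[1]]
  df <- read.csv(path, comment.char = "#", check.names = FALSE)
  info <- data.frame(name = setdiff(colnames(df), "subject_id"),
                     family = fam, scenario = scn)
  structure(df, feature_info = info,
            class = c("feature_table", "data.frame"))
}

#' Session recording round-trip
#'
#' Writes one session as a directory of plain CSV files (head track, foot
#' tracks, ECG, respiration).
#'
#' @param session a [session_recording()].
#' @param dir target directory.
#' @return `read_session` returns the [session_recording()] (without
#'   generator truth, which is not serialized).
#' @export
write_session <- function(session, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_trajectory_csv(session$head_track, file.path(dir, "head.csv"))
  if (!is.null(session$foot_tracks)) {
    write_trajectory_csv(session$foot_tracks$left, file.path(dir, "foot_left.csv"))
    write_trajectory_csv(session$foot_tracks$right, file.path(dir, "foot_right.csv"))
  }
  if (!is.null(session$ecg)) write_physio_csv(session$ecg, file.path(dir, "ecg.csv"))
  if (!is.null(session$respiration)) {
    write_physio_csv(session$respiration, file.path(dir, "resp.csv"))
  }
  writeLines(c(paste0("subject_id: ", session$subject_id),
               paste0("scenario_id: ", session$scenario_id),
               paste0("duration: ", format(session$duration, digits = 12))),
             file.path(dir, "meta.txt"))
  invisible(dir)
}

#' @rdname write_session
#' @export
read_session <- function(dir) {
  meta <- readLines(file.path(dir, "meta.txt"))
  val <- function(key) sub(paste0("^", key, ": "), "",
                           grep(paste0("^", key, ":"), meta, value = TRUE))
  ft <- NULL
  if (file.exists(file.path(dir, "foot_left.csv"))) {
    ft <- list(left = read_trajectory_csv(file.path(dir, "foot_left.csv")),
               right = read_trajectory_csv(file.path(dir, "foot_right.csv")))
  }
  session_recording(
    subject_id = val("subject_id"), scenario_id = val("scenario_id"),
    head_track = read_trajectory_csv(file.path(dir, "head.csv")),
    foot_tracks = ft,
    ecg = if (file.exists(file.path(dir, "ecg.csv"))) {
      read_physio_csv(file.path(dir, "ecg.csv"), "ecg")
    },
    respiration = if (file.exists(file.path(dir, "resp.csv"))) {
      read_physio_csv(file.path(dir, "resp.csv"), "resp")
    },
    duration = as.numeric(val("duration")))
}
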