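#' Serialize project results to JSON + CSV
#'
#' Writes `<stem>.json` (per-project metrics, pFI, best-F1 threshold)
#' and `<stem>_oof.csv` (out-of-fold predictions, one column per
#' project). Numeric formatting is fixed so identical runs produce
#' byte-identical files.
#'
#' @param results list of `project_result`s.
#' @param stem output path stem (no extension).
#' @return the JSON path, invisibly.
#' @export
write_project_results <- function(results, stem) {
  payload <- lapply(results, function(r) {
    list(blueprint = r$blueprint, plan_seed = r$plan_seed, k = r$k,
         cv_logloss = round(r$cv_logloss, 10),
         cv_auc = round(r$cv_auc, 10),
         fold_logloss = round(r$fold_logloss, 10),
         fold_auc = round(r$fold_auc, 10),
         best_f1_threshold = round(r$best_f1_threshold, 10),
         pfi = if (!is.null(r$pfi)) {
           list(feature = r$pfi$feature,
                importance = round(r$pfi$importance, 10),
                rank = r$pfi$rank)
         })
  })
  jp <- paste0(stem, ".json")
  jsonlite::write_json(payload, jp, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  oof <- as.data.frame(lapply(results, function(r) round(r$oof_predictions, 10)))
  names(oof) <- sprintf("project_%d", seq_along(results))
  utils::write.csv(oof, paste0(stem, "_oof.csv"), row.names = FALSE)
  invisible(jp)
}

#' Write a stability curve as tidy CSV
#' @param curve a `stability_curve`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_stability_curve <- function(curve, path) {
  df <- as.data.frame(curve)
  df$metric <- attr(curve, "metric") %||% NA_character_
  for (cl in c("mean", "ci_low", "ci_high")) df[[cl]] <- round(df[[cl]], 10)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a reduction trace to JSON and tidy CSV
#' @param trace a `reduction_trace`.
#' @param stem output path stem.
#' @return the JSON path, invisibly.
#' @export
write_reduction_trace <- function(trace, stem) {
  steps <- lapply(trace$steps, function(s) {
    list(phase = s$phase, n_features = s$n_features,
         features = s$features, eliminated = s$eliminated,
         step_size = s$step_size,
         mean_logloss = round(s$agg_logloss$mean, 10),
         logloss_ci = round(c(s$agg_logloss$ci_low, s$agg_logloss$ci_high), 10),
         mean_auc = round(s$agg_auc$mean, 10),
         auc_ci = round(c(s$agg_auc$ci_low, s$agg_auc$ci_high), 10))
  })
  jp <- paste0(stem, ".json")
  jsonlite::write_json(
    list(blueprint = trace$blueprint, protected = trace$protected,
         phase1_best_size = trace$phase1_best_size,
         window = trace$window, steps = steps),
    jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  df <- reduction_trace_df(trace)
  sf <- reduction_step_fri(trace)
  df$fri_after <- NA_real_
  if (!is.null(sf)) df$fri_after[sf$step] <- sf$fri
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 10)
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  invisible(jp)
}

#' Write a threshold sweep result as tidy CSV
#' @param sweep a `sweep_result`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_sweep_result <- function(sweep, path) {
  df <- as.data.frame(sweep)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 10)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a validation score (JSON confusion + CSV predictions)
#' @param score a `validation_score`.
#' @param stem output path stem.
#' @return the JSON path, invisibly.
#' @export
write_validation_score <- function(score, stem) {
  jp <- paste0(stem, ".json")
  jsonlite::write_json(
    list(threshold_mean = round(score$threshold$mean, 10),
         threshold_ci = round(c(score$threshold$ci_low,
                                score$threshold$ci_high), 10),
         confusion = as.list(score$confusion)),
    jp, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  df <- score$predictions
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, 10)
  utils::write.csv(df, paste0(stem, ".csv"), row.names = FALSE)
  invisible(jp)
}

#' Serialize a drift report and cluster summaries
#'
#' Writes `feature_psi.csv` and, when clusters are supplied,
#' `cluster_summary.csv` (per-cluster cohort counts and numeric means)
#' into `dir`.
#'
#' @param report a [drift_report()] data.frame.
#' @param dir output directory (created if needed).
#' @param clusters optional [cluster_cohorts()] result.
#' @param cluster_summary optional [summarize_clusters()] result.
#' @return `dir`, invisibly.
#' @export
write_drift_report <- function(report, dir, clusters = NULL,
                               cluster_summary = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  rep <- report
  rep$psi <- round(rep$psi, 10)
  utils::write.csv(rep, file.path(dir, "feature_psi.csv"), row.names = FALSE)
  if (!is.null(cluster_summary)) {
    cs <- cluster_summary$numeric
    counts <- as.data.frame(cluster_summary$counts)
    num <- vapply(cs, is.numeric, logical(1))
    cs[num] <- lapply(cs[num], round, 10)
    utils::write.csv(cs, file.path(dir, "cluster_summary.csv"),
                     row.names = FALSE)
    utils::write.csv(counts, file.path(dir, "cluster_counts.csv"),
                     row.names = FALSE)
  }
  invisible(dir)
}
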