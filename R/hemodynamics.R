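#' Moment summaries of an intraoperative vitals series
#'
#' Sample mean, standard deviation (n-1 denominator), Fisher-Pearson
#' skew and excess kurtosis (bias-uncorrected population moments),
#' computed on the sample values ignoring timing. Moments undefined at
#' the series length (sd needs 2 samples, skew 3, kurtosis 4) or for a
#' constant series are returned as `NA`, not as errors.
#'
#' @param values numeric sample values (bpm or mmHg).
#' @return named vector `mean`, `sd`, `skew`, `kurtosis`.
#' @export
summarize_signal <- function(values) {
  v <- values[!is.na(values)]
  n <- length(v)
  out <- c(mean = NA_real_, sd = NA_real_, skew = NA_real_,
           kurtosis = NA_real_)
  if (n == 0) return(out)
  out["mean"] <- mean(v)
  if (n >= 2) out["sd"] <- stats::sd(v)
  m2 <- mean((v - mean(v))^2)
  if (n >= 3 && m2 > 0) out["skew"] <- mean((v - mean(v))^3) / m2^1.5
  if (n >= 4 && m2 > 0) out["kurtosis"] <- mean((v - mean(v))^4) / m2^2 - 3
  out
}

#' Minutes spent strictly beyond a MAP threshold
#'
#' Integration convention for (possibly irregular) sampling: each sample
#' owns the interval from its own time to the next sample's time; the
#' last sample owns the median sampling interval (0 for a single-sample
#' series). A sample counts when its value strictly exceeds (`"above"`)
#' or strictly falls under (`"below"`) the threshold; equality is inside
#' range.
#'
#' @param time sample times in minutes, strictly increasing.
#' @param value MAP values (mmHg).
#' @param threshold threshold in mmHg (> 0).
#' @param direction `"above"` or `"below"`.
#' @return total minutes outside the threshold.
#' @export
time_outside_threshold <- function(time, value, threshold,
                                   direction = c("above", "below")) {
  direction <- match.arg(direction)
  if (!length(time)) stop("empty series")
  if (length(time) != length(value)) stop("length mismatch")
  if (threshold <= 0) stop("threshold must be positive")
  if (is.unsorted(time, strictly = TRUE)) stop("times must be strictly increasing")
  n <- length(time)
  gaps <- if (n > 1) diff(time) else numeric(0)
  own <- c(gaps, if (n > 1) stats::median(gaps) else 0)
  outside <- if (direction == "above") value > threshold else value < threshold
  sum(own[outside])
}

# long-format vitals: patient_id, signal, time_min, value
.check_vitals <- function(vitals) {
  need <- c("patient_id", "signal", "time_min", "value")
  if (!all(need %in% names(vitals))) {
    stop("vitals must have columns: ", paste(need, collapse = ", "))
  }
  vitals
}

#' Summary-statistic features from long-format vitals
#'
#' One row per patient with `<signal>_<stat>` columns (mean, sd, skew,
#' kurtosis) for every signal present, e.g. `MAP_mean`, `HR_kurtosis`.
#'
#' @param vitals long data.frame with `patient_id`, `signal`,
#'   `time_min`, `value`.
#' @return data.frame keyed by `patient_id`.
#' @export
summarize_vitals <- function(vitals) {
  .check_vitals(vitals)
  pats <- unique(vitals$patient_id)
  sigs <- sort(unique(vitals$signal))
  rows <- lapply(pats, function(p) {
    sub <- vitals[vitals$patient_id == p, ]
    vals <- lapply(sigs, function(s) {
      v <- sub$value[sub$signal == s][order(sub$time_min[sub$signal == s])]
      summarize_signal(v)
    })
    stats <- unlist(vals)
    names(stats) <- as.vector(t(outer(sigs, c("mean", "sd", "skew", "kurtosis"),
                                      paste, sep = "_")))
    c(list(patient_id = p), as.list(stats))
  })
  do.call(rbind, lapply(rows, as.data.frame, stringsAsFactors = FALSE))
}

#' Append time-outside-MAP-threshold features to a feature table
#'
#' Adds numeric columns `time_MAP_Avg_above_<upper>` and
#' `time_MAP_Avg_below_<lower>` computed from each patient's MAP series;
#' patients without a MAP series get missing values.
#'
#' @param table a `feature_table`.
#' @param vitals long-format vitals (see [summarize_vitals()]).
#' @param lower,upper thresholds in mmHg (canonical 76 and 104).
#' @return the extended `feature_table`.
#' @export
build_threshold_features <- function(table, vitals, lower = 76, upper = 104) {
  .check_vitals(vitals)
  map <- vitals[vitals$signal == "MAP", ]
  above <- below <- rep(NA_real_, length(table$patient_id))
  for (i in seq_along(table$patient_id)) {
    sub <- map[map$patient_id == table$patient_id[i], ]
    if (!nrow(sub)) next
    o <- order(sub$time_min)
    above[i] <- time_outside_threshold(sub$time_min[o], sub$value[o],
                                       upper, "above")
    below[i] <- time_outside_threshold(sub$time_min[o], sub$value[o],
                                       lower, "below")
  }
  df <- table$predictors
  df[[sprintf("time_MAP_Avg_above_%g", upper)]] <- above
  df[[sprintf("time_MAP_Avg_below_%g", lower)]] <- below
  feature_table(df, target = table$target, patient_id = table$patient_id,
                kinds = table$kinds)
}

#' Single-threshold sweep over candidate MAP thresholds
#'
#' Starting from a base feature list without any threshold feature, fits
#' the blueprint across all projects for: the baseline list (no
#' threshold feature), each single lower-threshold list over
#' `lower_range`, and each single upper-threshold list over
#' `upper_range`. All conditions reuse the same partition plans, so
#' performance differences are attributable to the features. The full
#' integer ranges 70-85 and 95-115 give 1 + 16 + 21 = 38 conditions.
#'
#' @param spec a [blueprint_spec()].
#' @param base_features feature list excluding any time-outside-threshold
#'   feature (typically the parsimonious list minus threshold features).
#' @param table a `feature_table` containing `base_features`.
#' @param vitals long-format vitals with MAP series.
#' @param projects a [make_project_set()] result.
#' @param lower_range,upper_range integer mmHg candidate thresholds.
#' @return data.frame `side` ("baseline"/"lower"/"upper"),
#'   `threshold_mmHg`, `mean_logloss`, `logloss_ci_low/high`,
#'   `mean_auc`, `auc_ci_low/high` (class `sweep_result`).
#' @export
threshold_sweep <- function(spec, base_features, table, vitals, projects,
                            lower_range = 70:85, upper_range = 95:115) {
  if (any(grepl("^time_MAP_Avg_(above|below)_", base_features))) {
    stop("base_features must exclude time-outside-threshold features")
  }
  if (!length(lower_range) && !length(upper_range)) stop("empty sweep range")

  eval_condition <- function(feats, tab) {
    results <- fit_projects(spec, tab, projects, features = feats,
                            compute_pfi = FALSE, keep_models = FALSE)
    ll <- aggregate_values(vapply(results, `[[`, numeric(1), "cv_logloss"))
    au <- aggregate_values(vapply(results, `[[`, numeric(1), "cv_auc"))
    c(ll$mean, ll$ci_low, ll$ci_high, au$mean, au$ci_low, au$ci_high)
  }

  rows <- list()
  base <- eval_condition(base_features, table)
  rows[[1]] <- data.frame(side = "baseline", threshold_mmHg = NA_real_,
                          t(base))
  for (thr in lower_range) {
    tab <- build_threshold_features(table, vitals, lower = thr, upper = 999)
    feat <- sprintf("time_MAP_Avg_below_%g", thr)
    rows[[length(rows) + 1]] <- data.frame(side = "lower",
                                           threshold_mmHg = thr,
                                           t(eval_condition(c(base_features, feat), tab)))
  }
  for (thr in upper_range) {
    tab <- build_threshold_features(table, vitals, lower = 1e-9 + 0.001,
                                    upper = thr)
    feat <- sprintf("time_MAP_Avg_above_%g", thr)
    rows[[length(rows) + 1]] <- data.frame(side = "upper",
                                           threshold_mmHg = thr,
                                           t(eval_condition(c(base_features, feat), tab)))
  }
  out <- do.call(rbind, rows)
  names(out)[3:8] <- c("mean_logloss", "logloss_ci_low", "logloss_ci_high",
                       "mean_auc", "auc_ci_low", "auc_ci_high")
  rownames(out) <- NULL
  class(out) <- c("sweep_result", "data.frame")
  out
}

#' @exportS3Method base::print
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d conditions\n", nrow(x)))
  best <- x[which.min(x$mean_logloss), ]
  cat(sprintf("  best by LogLoss: %s %s (%.4f)\n", best$side,
              ifelse(is.na(best$threshold_mmHg), "",
                     sprintf("%g mmHg", best$threshold_mmHg)),
              best$mean_logloss))
  invisible(x)
}
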