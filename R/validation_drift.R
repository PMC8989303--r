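#' Score an external validation cohort with aggregated project models
#'
#' Every project contributes one prediction per validation patient (the
#' mean of its fold models' probabilities; all preprocessing uses
#' training-fitted encoders and imputers only). Per-patient means and
#' 95% CIs are computed across projects, the decision threshold is the
#' mean of the per-project best-F1 thresholds, and a patient is
#' classified improved iff the mean probability strictly exceeds the
#' mean threshold.
#'
#' @param results list of `project_result`s (fitted with kept models) for
#'   one parsimonious blueprint.
#' @param validation_table a `feature_table` carrying all parsimonious
#'   features and (optionally) targets.
#' @return A `validation_score`: `predictions` data.frame (`patient_id`,
#'   `mean`, `ci_low`, `ci_high`, `predicted_class`), `threshold`
#'   aggregate, and (when targets exist) `confusion` with TP/FP/TN/FN.
#' @export
score_validation <- function(results, validation_table) {
  stopifnot(length(results) >= 1)
  feats <- results[[1]]$features
  missing_cols <- setdiff(feats, ft_features(validation_table))
  if (length(missing_cols)) {
    stop("validation table is missing parsimonious feature(s): ",
         paste(missing_cols, collapse = ", "))
  }
  n <- nrow(validation_table$predictors)
  P <- vapply(results, predict_project, numeric(n),
              newdata = validation_table)
  P <- matrix(P, nrow = n)
  m <- rowMeans(P)
  if (ncol(P) > 1) {
    sdv <- apply(P, 1, stats::sd)
    half <- stats::qt(0.975, df = ncol(P) - 1) * sdv / sqrt(ncol(P))
  } else half <- rep(0, n)
  thr_values <- vapply(results, `[[`, numeric(1), "best_f1_threshold")
  thr <- if (length(thr_values) > 1) aggregate_values(thr_values)
         else list(n = 1, mean = thr_values, ci_low = thr_values,
                   ci_high = thr_values, values = thr_values)
  pred_class <- as.integer(m > thr$mean)
  preds <- data.frame(patient_id = validation_table$patient_id,
                      mean = m, ci_low = m - half, ci_high = m + half,
                      predicted_class = pred_class,
                      stringsAsFactors = FALSE)
  confusion <- NULL
  if (!is.null(validation_table$target)) {
    y <- validation_table$target
    confusion <- c(TP = sum(pred_class == 1 & y == 1),
                   FP = sum(pred_class == 1 & y == 0),
                   TN = sum(pred_class == 0 & y == 0),
                   FN = sum(pred_class == 0 & y == 1))
  }
  structure(list(predictions = preds, threshold = thr,
                 confusion = confusion),
            class = "validation_score")
}

#' @exportS3Method base::print
print.validation_score <- function(x, ...) {
  cat(sprintf("<validation_score> %d patients, mean best-F1 threshold %.3f\n",
              nrow(x$predictions), x$threshold$mean))
  if (!is.null(x$confusion)) {
    cat(sprintf("  TP=%d FP=%d TN=%d FN=%d\n", x$confusion["TP"],
                x$confusion["FP"], x$confusion["TN"], x$confusion["FN"]))
  }
  invisible(x)
}

#' Population stability index between two samples of one feature
#'
#' Numeric features are binned at training-sample quantiles (`n_bins`
#' bins, duplicate edges collapsed); categorical features get one bin per
#' level of the union. PSI = sum over bins of
#' `(v_b - t_b) * ln(v_b / t_b)` on bin proportions, with empty-bin
#' proportions floored at `eps`.
#'
#' @param train_values,valid_values numeric or character/factor vectors
#'   (missing values dropped).
#' @param n_bins quantile bin count for numerics (default 10).
#' @param eps proportion floor for empty bins (default 1e-4).
#' @return non-negative PSI value.
#' @export
psi <- function(train_values, valid_values, n_bins = 10, eps = 1e-4) {
  tv <- train_values[!is.na(train_values)]
  vv <- valid_values[!is.na(valid_values)]
  if (!length(tv) || !length(vv)) stop("both samples must be non-empty")
  if (is.numeric(tv) && is.numeric(vv)) {
    edges <- unique(stats::quantile(tv, probs = seq(0, 1, length.out = n_bins + 1),
                                    type = 7, names = FALSE))
    edges <- edges[-c(1, length(edges))]
    tb <- findInterval(tv, edges) + 1L
    vb <- findInterval(vv, edges) + 1L
    nb <- length(edges) + 1L
  } else {
    levs <- sort(unique(c(as.character(tv), as.character(vv))))
    tb <- match(as.character(tv), levs)
    vb <- match(as.character(vv), levs)
    nb <- length(levs)
  }
  tp <- tabulate(tb, nb) / length(tb)
  vp <- tabulate(vb, nb) / length(vb)
  tp <- pmax(tp, eps)
  vp <- pmax(vp, eps)
  sum((vp - tp) * log(vp / tp))
}

#' Classify a PSI value into a drift class
#'
#' Below 0.1: `"none"`; 0.1 to 0.25 (closed at both ends): `"moderate"`;
#' above 0.25: `"significant"`.
#'
#' @param psi_value non-negative PSI value (vectorized).
#' @return character vector of drift classes.
#' @export
classify_drift <- function(psi_value) {
  if (any(psi_value < 0)) stop("PSI must be non-negative")
  ifelse(psi_value > 0.25, "significant",
         ifelse(psi_value >= 0.1, "moderate", "none"))
}

#' Per-feature PSI drift report between two cohorts
#'
#' @param train_table,valid_table `feature_table`s sharing `features`.
#' @param features features to audit (default: shared predictors).
#' @param n_bins,eps passed to [psi()].
#' @return data.frame `feature`, `psi`, `drift_class`.
#' @export
drift_report <- function(train_table, valid_table, features = NULL,
                         n_bins = 10, eps = 1e-4) {
  features <- features %||% intersect(ft_features(train_table),
                                      ft_features(valid_table))
  vals <- vapply(features, function(f) {
    psi(train_table$predictors[[f]], valid_table$predictors[[f]],
        n_bins = n_bins, eps = eps)
  }, numeric(1))
  data.frame(feature = features, psi = unname(vals),
             drift_class = classify_drift(unname(vals)),
             stringsAsFactors = FALSE)
}

# Single-linkage density-style clustering on a 2-D embedding: take the
# largest cut count for which every resulting cluster meets the minimum
# size (records in undersized clusters would be noise under a density
# clusterer; here the cut simply falls back to fewer clusters).
.density_cluster <- function(emb, min_cluster_size) {
  n <- nrow(emb)
  hc <- stats::hclust(stats::dist(emb), method = "single")
  kmax <- max(1L, n %/% min_cluster_size)
  for (k in rev(seq_len(kmax))) {
    if (k == 1L) return(rep(1L, n))
    lab <- stats::cutree(hc, k = k)
    if (min(tabulate(lab)) >= min_cluster_size) return(lab)
  }
  rep(1L, n)
}

#' Cluster pooled training + validation cohorts
#'
#' Pools both cohorts on the chosen features, removes records with any
#' missing feature value (listwise deletion), scales numerics and
#' one-hot-encodes categoricals, embeds to 2-D (UMAP by default) and
#' clusters the embedding with a density-style minimum-cluster-size rule.
#'
#' @param train_table,valid_table `feature_table`s.
#' @param features features to cluster on (e.g. the union of both
#'   parsimonious lists).
#' @param min_cluster_size minimum cluster size (default 8).
#' @param embedding_seed seed controlling the embedding; the pipeline is
#'   reproducible given it.
#' @param method `"umap"` (nonlinear, default) or `"pca"` (linear
#'   fallback adapter).
#' @param n_neighbors UMAP neighborhood size (clipped to n - 2).
#' @return A `cohort_clusters`: `labels`, `cohort` ("train"/"valid"),
#'   `patient_id`, `embedding` (n x 2), `n_removed` (listwise-deleted
#'   records), `retained` (logical index into the pooled rows).
#' @export
cluster_cohorts <- function(train_table, valid_table, features,
                            min_cluster_size = 8, embedding_seed = 1,
                            method = c("umap", "pca"), n_neighbors = 15) {
  method <- match.arg(method)
  for (f in features) {
    if (!f %in% ft_features(train_table) || !f %in% ft_features(valid_table)) {
      stop("feature not present in both tables: ", f)
    }
  }
  pooled <- rbind(train_table$predictors[features],
                  valid_table$predictors[features])
  cohort <- c(rep("train", nrow(train_table$predictors)),
              rep("valid", nrow(valid_table$predictors)))
  pid <- c(train_table$patient_id, valid_table$patient_id)
  keep <- stats::complete.cases(pooled)
  n_removed <- sum(!keep)
  sub <- pooled[keep, , drop = FALSE]
  if (nrow(sub) < 2 * min_cluster_size) {
    stop("fewer than 2 * min_cluster_size records retained after listwise deletion")
  }
  kinds <- train_table$kinds[features]
  Xs <- lapply(features, function(f) {
    v <- sub[[f]]
    if (kinds[[f]] == "numeric") {
      s <- stats::sd(v); if (!is.finite(s) || s == 0) s <- 1
      matrix((v - mean(v)) / s, ncol = 1, dimnames = list(NULL, f))
    } else {
      levs <- sort(unique(as.character(v)))
      m <- matrix(0, length(v), length(levs),
                  dimnames = list(NULL, paste(f, levs, sep = ".")))
      m[cbind(seq_along(v), match(as.character(v), levs))] <- 1
      m
    }
  })
  X <- do.call(cbind, Xs)
  emb <- if (method == "umap") {
    nn <- max(2L, min(as.integer(n_neighbors), nrow(X) - 2L))
    .with_seed(embedding_seed,
               uwot::umap(X, n_neighbors = nn, n_components = 2,
                          n_threads = 1, n_sgd_threads = 0, verbose = FALSE))
  } else {
    stats::prcomp(X, rank. = 2)$x[, 1:2, drop = FALSE]
  }
  labels <- .density_cluster(emb, min_cluster_size)
  structure(list(labels = labels, cohort = cohort[keep],
                 patient_id = pid[keep], embedding = emb,
                 n_removed = n_removed, retained = keep,
                 features = features),
            class = "cohort_clusters")
}

#' @exportS3Method base::print
print.cohort_clusters <- function(x, ...) {
  cat(sprintf("<cohort_clusters> %d records in %d clusters (%d removed by listwise deletion)\n",
              length(x$labels), length(unique(x$labels)), x$n_removed))
  print(table(cluster = x$labels, cohort = x$cohort))
  invisible(x)
}

#' Per-cluster, per-cohort summaries of clustered cohorts
#'
#' Numeric features: within-cluster mean and Student-t 95% CI.
#' Categorical features: level frequencies. Plus per-cluster cohort
#' counts.
#'
#' @param clusters a [cluster_cohorts()] result.
#' @param train_table,valid_table the tables that were clustered.
#' @return list with `counts` (cluster x cohort), `numeric` (data.frame
#'   `cluster`, `feature`, `mean`, `ci_low`, `ci_high`, `n`) and
#'   `categorical` (data.frame `cluster`, `feature`, `level`,
#'   `frequency`).
#' @export
summarize_clusters <- function(clusters, train_table, valid_table) {
  feats <- clusters$features
  pooled <- rbind(train_table$predictors[feats],
                  valid_table$predictors[feats])[clusters$retained, ,
                                                 drop = FALSE]
  kinds <- train_table$kinds[feats]
  counts <- table(cluster = clusters$labels, cohort = clusters$cohort)
  num_rows <- list(); cat_rows <- list()
  for (cl in sort(unique(clusters$labels))) {
    in_cl <- clusters$labels == cl
    for (f in feats) {
      v <- pooled[[f]][in_cl]
      if (kinds[[f]] == "numeric") {
        n <- sum(!is.na(v))
        m <- mean(v, na.rm = TRUE)
        half <- if (n > 1) stats::qt(0.975, n - 1) * stats::sd(v, na.rm = TRUE) / sqrt(n)
                else 0
        num_rows[[length(num_rows) + 1]] <-
          data.frame(cluster = cl, feature = f, mean = m,
                     ci_low = m - half, ci_high = m + half, n = n)
      } else {
        tb <- table(v)
        cat_rows[[length(cat_rows) + 1]] <-
          data.frame(cluster = cl, feature = f, level = names(tb),
                     frequency = as.numeric(tb) / sum(tb))
      }
    }
  }
  list(counts = counts,
       numeric = if (length(num_rows)) do.call(rbind, num_rows) else NULL,
       categorical = if (length(cat_rows)) do.call(rbind, cat_rows) else NULL)
}
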