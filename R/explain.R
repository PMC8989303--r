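#' Permutation feature importance of a fitted model
#'
#' For each feature, the values of that column are shuffled (all other
#' columns fixed) and the increase in LogLoss over the unshuffled
#' predictions is averaged over `n_permutations` independent shuffles.
#' Raw importances are floored at zero and normalized so the maximum
#' equals one.
#'
#' Because every fitted encoder is a per-column map, shuffling the raw
#' column is equivalent to shuffling the rows of its encoded block; the
#' implementation uses the latter for speed.
#'
#' @param model a `bp_model` (see [fit_model()]).
#' @param table a `feature_table` (with target) or data.frame plus
#'   `targets`.
#' @param n_permutations shuffles per feature (default 10).
#' @param seed RNG seed; results are deterministic given it.
#' @param targets binary outcomes when `table` is a plain data.frame.
#' @return data.frame `feature`, `importance` (normalized), `rank`.
#' @export
permutation_importance <- function(model, table, n_permutations = 10,
                                   seed = 1, targets = NULL) {
  stopifnot(inherits(model, "bp_model"))
  if (inherits(table, "feature_table")) {
    targets <- table$target
    df <- table$predictors
  } else df <- table
  missing_cols <- setdiff(model$features, names(df))
  if (length(missing_cols)) {
    stop("feature(s) absent from model input: ",
         paste(missing_cols, collapse = ", "))
  }
  X <- .pp_transform(model$pp, df[model$features])
  base_ll <- logloss(targets, .est_predict(model$est, X))
  n <- nrow(X)
  imp <- .with_seed(seed, {
    vapply(model$features, function(f) {
      blk <- model$pp$blocks[[f]]
      d <- numeric(n_permutations)
      for (r in seq_len(n_permutations)) {
        perm <- sample.int(n)
        Xp <- X
        Xp[, blk] <- X[perm, blk, drop = FALSE]
        d[r] <- logloss(targets, .est_predict(model$est, Xp)) - base_ll
      }
      mean(d)
    }, numeric(1))
  })
  imp <- pmax(imp, 0)
  if (max(imp) > 0) imp <- imp / max(imp)
  out <- data.frame(feature = model$features, importance = unname(imp),
                    stringsAsFactors = FALSE)
  out$rank <- unname(.pfi_ranks(stats::setNames(out$importance,
                                                out$feature))[out$feature])
  out
}

#' Aggregate per-project pFI lists
#'
#' Per-feature mean of the normalized importances plus a Student-t 95%
#' CI; ranks are recomputed from the means (ties broken by descending
#' importance then ascending feature name).
#'
#' @param lists list of pFI data.frames (or named vectors) over a common
#'   feature set; `project_result`s are also accepted.
#' @return data.frame `feature`, `importance` (mean), `ci_low`,
#'   `ci_high`, `rank`, `n_projects`.
#' @export
aggregate_pfi <- function(lists) {
  if (length(lists) && inherits(lists[[1]], "project_result")) {
    lists <- lapply(lists, function(r) r$pfi)
  }
  if (length(lists) < 2) stop("need at least 2 pFI lists")
  vecs <- lapply(lists, .pfi_vec)
  feats <- names(vecs[[1]])
  M <- vapply(vecs, function(v) {
    if (!setequal(names(v), feats)) stop("pFI lists must share a feature set")
    v[feats]
  }, numeric(length(feats)))
  M <- matrix(M, nrow = length(feats))   # keep shape for single-feature lists
  m <- rowMeans(M)
  sdv <- apply(M, 1, stats::sd)
  half <- stats::qt(0.975, df = ncol(M) - 1) * sdv / sqrt(ncol(M))
  out <- data.frame(feature = feats, importance = unname(m),
                    ci_low = unname(m - half), ci_high = unname(m + half),
                    n_projects = ncol(M), stringsAsFactors = FALSE)
  out$rank <- unname(.pfi_ranks(stats::setNames(out$importance,
                                                out$feature))[out$feature])
  out[order(out$rank), ]
}

#' Default partial-dependence grid for a feature
#'
#' Numeric features: the sorted unique values when there are at most 25,
#' otherwise 25 equally spaced quantiles of the full table (so grids are
#' identical across projects). Categorical features: all levels.
#'
#' @param table a `feature_table`.
#' @param feature feature name.
#' @param max_points grid resolution for dense numeric features.
#' @return vector of grid values.
#' @export
pdp_grid <- function(table, feature, max_points = 25) {
  v <- table$predictors[[feature]]
  if (table$kinds[[feature]] == "categorical") {
    sort(unique(v[!is.na(v)]))
  } else {
    u <- sort(unique(v[!is.na(v)]))
    if (length(u) <= max_points) u
    else unique(stats::quantile(v, probs = seq(0, 1, length.out = max_points),
                                type = 7, names = FALSE, na.rm = TRUE))
  }
}

#' Partial dependence of a fitted model on one feature
#'
#' For every grid value `v` the feature column is set to `v` for all
#' records, the model predicts, and the probabilities are averaged.
#'
#' @param model a `bp_model`.
#' @param table a `feature_table` or data.frame of predictors.
#' @param feature feature name.
#' @param grid grid values; default [pdp_grid()] on the table.
#' @return data.frame `feature`, `value`, `dependence` (class `pdp_grid`).
#' @export
partial_dependence <- function(model, table, feature, grid = NULL) {
  stopifnot(inherits(model, "bp_model"))
  df <- if (inherits(table, "feature_table")) table$predictors else table
  if (!feature %in% names(df)) stop("feature not in table: ", feature)
  if (is.null(grid) && inherits(table, "feature_table")) {
    grid <- pdp_grid(table, feature)
  }
  if (is.null(grid) || !length(grid)) stop("empty grid")
  dep <- vapply(grid, function(v) {
    d <- df
    d[[feature]] <- rep(v, nrow(d))
    mean(predict_bp(model, d))
  }, numeric(1))
  out <- data.frame(feature = feature, value = grid, dependence = dep,
                    stringsAsFactors = FALSE)
  class(out) <- c("pdp_grid", "data.frame")
  out
}

#' Per-project partial dependence
#'
#' The project-level curve is the average of the fold models' partial
#' dependence (each evaluated over the full table), so cross-project
#' aggregation reflects partition-induced variability.
#'
#' @param result a `project_result` with kept models.
#' @param table the training `feature_table`.
#' @param feature feature name.
#' @param grid shared grid; default [pdp_grid()] from the full table.
#' @return a `pdp_grid` data.frame.
#' @export
project_pdp <- function(result, table, feature, grid = NULL) {
  if (is.null(result$models)) stop("project_result was fitted without models")
  grid <- grid %||% pdp_grid(table, feature)
  curves <- vapply(result$models, function(m) {
    partial_dependence(m, table, feature, grid)$dependence
  }, numeric(length(grid)))
  out <- data.frame(feature = feature, value = grid,
                    dependence = rowMeans(matrix(curves, nrow = length(grid))),
                    stringsAsFactors = FALSE)
  class(out) <- c("pdp_grid", "data.frame")
  out
}

#' Aggregate per-project partial-dependence grids
#'
#' Pointwise mean plus Student-t 95% CI. All grids must be identical
#' (build numeric grids from the full table, not per fold).
#'
#' @param grids list of `pdp_grid` data.frames for one feature.
#' @return data.frame `feature`, `value`, `dependence`, `ci_low`,
#'   `ci_high`, `n_projects`.
#' @export
aggregate_pdp <- function(grids) {
  if (length(grids) < 2) stop("need at least 2 PDP grids")
  g0 <- grids[[1]]
  for (g in grids[-1]) {
    if (!identical(g$value, g0$value) || !identical(g$feature[1], g0$feature[1])) {
      stop("grid mismatch across projects")
    }
  }
  M <- vapply(grids, function(g) g$dependence, numeric(nrow(g0)))
  M <- matrix(M, nrow = nrow(g0))
  m <- rowMeans(M)
  sdv <- apply(M, 1, stats::sd)
  half <- stats::qt(0.975, df = ncol(M) - 1) * sdv / sqrt(ncol(M))
  data.frame(feature = g0$feature, value = g0$value, dependence = m,
             ci_low = m - half, ci_high = m + half, n_projects = ncol(M),
             stringsAsFactors = FALSE)
}
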