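#' Declare a preprocessing + estimator blueprint
#'
#' A blueprint fixes the full modeling recipe applied inside every fold:
#' numeric imputation (training-fold median) and encoding, categorical
#' imputation (explicit `"(missing)"` level) and encoding, and the
#' estimator with its hyperparameters.
#'
#' @param name unique identifier within a run.
#' @param numeric_encoder `"quintile-spline"` (quintile indicator bins
#'   with edges at the training-fold 20/40/60/80 percentiles) or
#'   `"passthrough-standardize"` (center/scale on training statistics).
#' @param categorical_encoder `"one-hot"` or `"ordinal"` (integer codes
#'   by sorted level name; unseen levels map to 0).
#' @param estimator `"l2-logistic"`, `"gradient-boosted-trees"` or
#'   `"majority-class"`.
#' @param hyperparameters name-value list. Defaults: `C = 1` for
#'   l2-logistic; `n_trees = 500`, `learning_rate = 0.05`,
#'   `max_depth = 3`, `lambda = 1`, `min_child_weight = 1` for boosted
#'   trees.
#' @param estimator_seed integer seed for any stochastic estimator or
#'   importance step.
#' @return A `blueprint_spec`.
#' @export
blueprint_spec <- function(name,
                           numeric_encoder = c("quintile-spline",
                                               "passthrough-standardize"),
                           categorical_encoder = c("one-hot", "ordinal"),
                           estimator = c("l2-logistic",
                                         "gradient-boosted-trees",
                                         "majority-class"),
                           hyperparameters = list(),
                           estimator_seed = 1L) {
  numeric_encoder <- match.arg(numeric_encoder)
  categorical_encoder <- match.arg(categorical_encoder)
  estimator <- match.arg(estimator)
  allowed <- switch(estimator,
    "l2-logistic" = c("C"),
    "gradient-boosted-trees" = c("n_trees", "learning_rate", "max_depth",
                                 "lambda", "min_child_weight"),
    "majority-class" = character(0))
  bad <- setdiff(names(hyperparameters), allowed)
  if (length(bad)) {
    stop("hyperparameter(s) not valid for ", estimator, ": ",
         paste(bad, collapse = ", "))
  }
  structure(list(name = name, numeric_encoder = numeric_encoder,
                 categorical_encoder = categorical_encoder,
                 estimator = estimator, hyperparameters = hyperparameters,
                 estimator_seed = as.integer(estimator_seed)),
            class = "blueprint_spec")
}

#' Canonical blueprints
#'
#' `bp_logistic()` mirrors a quintile-binned L2 logistic regression;
#' `bp_gbt()` a gradient-boosted-trees classifier with one-hot
#' categorical encoding (a documented stand-in for learned categorical
#' embeddings); `bp_majority()` the majority-class benchmark that always
#' predicts the training-fold prevalence.
#'
#' @param estimator_seed seed passed to [blueprint_spec()].
#' @param hyperparameters overrides merged over the defaults.
#' @return A `blueprint_spec`.
#' @export
bp_logistic <- function(estimator_seed = 1L, hyperparameters = list()) {
  blueprint_spec("BP_log", "quintile-spline", "one-hot", "l2-logistic",
                 utils::modifyList(list(C = 1), hyperparameters),
                 estimator_seed)
}

#' @rdname bp_logistic
#' @export
bp_gbt <- function(estimator_seed = 1L, hyperparameters = list()) {
  blueprint_spec("BP_XGB", "passthrough-standardize", "one-hot",
                 "gradient-boosted-trees",
                 utils::modifyList(
                   list(n_trees = 500, learning_rate = 0.05, max_depth = 3,
                        lambda = 1, min_child_weight = 1),
                   hyperparameters),
                 estimator_seed)
}

#' @rdname bp_logistic
#' @export
bp_majority <- function(estimator_seed = 1L) {
  blueprint_spec("Majority", estimator = "majority-class",
                 estimator_seed = estimator_seed)
}

#' Fit a quintile-bin encoder on training values
#'
#' Bin edges are the 20/40/60/80 linear-interpolation percentiles of the
#' (imputed) training values; duplicate edges collapse so degenerate
#' columns degrade to fewer bins (a constant column yields one bin).
#'
#' @param values numeric training-fold values (missing allowed; they are
#'   ignored when computing edges).
#' @return A `quintile_encoder` with `edges` and `n_bins`.
#' @export
quintile_bin_encode <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) stop("all-missing column")
  edges <- unique(stats::quantile(v, probs = c(0.2, 0.4, 0.6, 0.8),
                                  type = 7, names = FALSE))
  # an edge at the training maximum would create an empty top bin
  # (a constant column then degrades to a single bin)
  edges <- edges[edges < max(v)]
  structure(list(edges = edges, n_bins = length(edges) + 1L),
            class = "quintile_encoder")
}

#' Map values to quintile bin indices / indicator matrix
#' @param encoder a [quintile_bin_encode()] result.
#' @param values numeric vector; out-of-range values clamp to the
#'   extreme bins, missing values get a zero indicator row.
#' @param indicators if `TRUE` (default) return the 0/1 indicator
#'   matrix, else the integer bin index (NA for missing).
#' @return matrix or integer vector.
#' @export
quintile_bin_apply <- function(encoder, values, indicators = TRUE) {
  idx <- findInterval(values, encoder$edges, left.open = FALSE) + 1L
  idx[idx > encoder$n_bins] <- encoder$n_bins
  if (!indicators) return(idx)
  out <- matrix(0, nrow = length(values), ncol = encoder$n_bins)
  ok <- !is.na(idx)
  out[cbind(which(ok), idx[ok])] <- 1
  colnames(out) <- sprintf("q%d", seq_len(encoder$n_bins))
  out
}

# ---- column-wise preprocessing -------------------------------------------

# Fit per-column imputer+encoder on training rows only. Each fitted
# column is a self-contained map applied element-wise, so permuting a raw
# column commutes with encoding (exploited for fast permutation
# importance).
.fit_preproc <- function(df, kinds, spec) {
  cols <- lapply(names(df), function(nm) {
    v <- df[[nm]]
    if (kinds[[nm]] == "numeric") {
      med <- stats::median(v, na.rm = TRUE)
      if (is.na(med)) med <- 0
      vi <- ifelse(is.na(v), med, v)
      if (spec$numeric_encoder == "quintile-spline") {
        enc <- quintile_bin_encode(vi)
        list(name = nm, kind = "numeric", type = "quintile",
             median = med, enc = enc, width = enc$n_bins)
      } else {
        ctr <- mean(vi); scl <- stats::sd(vi)
        if (!is.finite(scl) || scl == 0) scl <- 1
        list(name = nm, kind = "numeric", type = "standardize",
             median = med, center = ctr, scale = scl, width = 1L)
      }
    } else {
      vi <- ifelse(is.na(v), "(missing)", v)
      levs <- sort(unique(vi))
      if (spec$categorical_encoder == "one-hot") {
        list(name = nm, kind = "categorical", type = "onehot",
             levels = levs, width = length(levs))
      } else {
        list(name = nm, kind = "categorical", type = "ordinal",
             levels = levs, width = 1L)
      }
    }
  })
  names(cols) <- names(df)
  widths <- vapply(cols, `[[`, integer(1), "width")
  ends <- cumsum(widths)
  starts <- ends - widths + 1L
  blocks <- lapply(seq_along(cols), function(i) starts[i]:ends[i])
  names(blocks) <- names(df)
  structure(list(cols = cols, blocks = blocks, total = sum(widths),
                 features = names(df)),
            class = "bp_preproc")
}

.pp_transform <- function(pp, df) {
  n <- nrow(df)
  out <- matrix(0, nrow = n, ncol = pp$total)
  cn <- character(pp$total)
  for (nm in pp$features) {
    col <- pp$cols[[nm]]
    blk <- pp$blocks[[nm]]
    v <- df[[nm]]
    if (col$kind == "numeric") {
      vi <- ifelse(is.na(v), col$median, as.numeric(v))
      if (col$type == "quintile") {
        out[, blk] <- quintile_bin_apply(col$enc, vi)
        cn[blk] <- sprintf("%s.q%d", nm, seq_along(blk))
      } else {
        out[, blk] <- (vi - col$center) / col$scale
        cn[blk] <- nm
      }
    } else {
      vi <- ifelse(is.na(v), "(missing)", as.character(v))
      if (col$type == "onehot") {
        m <- matrix(0, n, length(col$levels))
        idx <- match(vi, col$levels)       # unseen level -> zero row
        ok <- !is.na(idx)
        m[cbind(which(ok), idx[ok])] <- 1
        out[, blk] <- m
        cn[blk] <- sprintf("%s.%s", nm, col$levels)
      } else {
        idx <- match(vi, col$levels)
        idx[is.na(idx)] <- 0L
        out[, blk] <- idx
        cn[blk] <- nm
      }
    }
  }
  colnames(out) <- cn
  out
}

# ---- estimators -----------------------------------------------------------

.fit_estimator <- function(spec, X, y) {
  hp <- spec$hyperparameters
  if (spec$estimator == "majority-class") {
    return(list(type = "majority", p = mean(y)))
  }
  if (spec$estimator == "l2-logistic") {
    C <- hp$C %||% 1
    lambda <- 1 / (nrow(X) * C)
    Xg <- if (ncol(X) < 2) cbind(X, `.pad` = 0) else X
    solve_ridge <- function(lam) {
      # informational glmnet warnings (tiny classes etc.) are muffled;
      # convergence warnings and errors trigger the retry path
      trouble <- FALSE
      fit <- tryCatch(
        withCallingHandlers(
          glmnet::glmnet(Xg, factor(y, levels = c(0, 1)),
                         family = "binomial", alpha = 0, lambda = lam,
                         standardize = FALSE),
          warning = function(w) {
            if (grepl("onverg", conditionMessage(w))) trouble <<- TRUE
            invokeRestart("muffleWarning")
          }),
        error = function(e) { trouble <<- TRUE; NULL })
      list(fit = fit, trouble = trouble)
    }
    res <- solve_ridge(lambda)
    if (res$trouble || is.null(res$fit)) {
      # one retry under stronger regularization, then hard failure
      warning("l2-logistic did not converge; retrying with 10x penalty")
      res <- solve_ridge(10 * lambda)
      if (res$trouble || is.null(res$fit)) {
        stop("l2-logistic failed to converge after retry")
      }
    }
    fit <- res$fit
    return(list(type = "l2-logistic", fit = fit, padded = ncol(X) < 2))
  }
  model <- gbt_fit_cpp(X, as.numeric(y),
                       as.integer(hp$n_trees %||% 500),
                       hp$learning_rate %||% 0.05,
                       as.integer(hp$max_depth %||% 3),
                       hp$lambda %||% 1,
                       hp$min_child_weight %||% 1)
  list(type = "gbt", fit = model)
}

.est_predict <- function(est, X) {
  p <- switch(est$type,
    majority = rep(est$p, nrow(X)),
    `l2-logistic` = {
      Xg <- if (isTRUE(est$padded)) cbind(X, `.pad` = 0) else X
      as.numeric(predict(est$fit, newx = Xg, type = "response"))
    },
    gbt = as.numeric(gbt_predict_cpp(est$fit, X)))
  pmin(pmax(p, 1e-15), 1 - 1e-15)
}

#' Predict with a fitted blueprint model
#' @param model a `bp_model` (from [fit_model()] or a `project_result`'s
#'   per-fold models).
#' @param newdata data.frame of raw predictor columns (a `feature_table`
#'   is also accepted).
#' @return vector of predicted probabilities of class 1.
#' @export
predict_bp <- function(model, newdata) {
  if (inherits(newdata, "feature_table")) newdata <- newdata$predictors
  missing_cols <- setdiff(model$features, names(newdata))
  if (length(missing_cols)) {
    stop("missing feature(s): ", paste(missing_cols, collapse = ", "))
  }
  X <- .pp_transform(model$pp, newdata[model$features])
  .est_predict(model$est, X)
}

#' Fit a blueprint on an entire table (no cross-validation)
#'
#' Mostly useful for explanation tests; the repeated-CV entry point is
#' [fit_blueprint()].
#'
#' @param spec a [blueprint_spec()].
#' @param table a `feature_table` with target.
#' @param features predictor subset (default: all).
#' @return A `bp_model` with elements `pp`, `est`, `features`.
#' @export
fit_model <- function(spec, table, features = NULL) {
  features <- features %||% ft_features(table)
  df <- table$predictors[features]
  pp <- .fit_preproc(df, table$kinds[features], spec)
  X <- .pp_transform(pp, df)
  est <- .fit_estimator(spec, X, table$target)
  structure(list(pp = pp, est = est, features = features,
                 kinds = table$kinds[features], spec = spec),
            class = "bp_model")
}

#' Best-F1 probability threshold
#'
#' Candidate thresholds are 0, 1 and the midpoints between consecutive
#' sorted unique probabilities; predictions are positive when the
#' probability strictly exceeds the threshold. Ties in F1 break toward
#' the lower threshold.
#'
#' @param targets binary 0/1 vector (at least one positive).
#' @param probabilities predicted probabilities.
#' @return the F1-optimal threshold.
#' @export
best_f1_threshold <- function(targets, probabilities) {
  y <- as.integer(targets)
  if (!any(y == 1)) stop("no positive targets")
  u <- sort(unique(probabilities))
  cand <- c(0, if (length(u) > 1) (u[-1] + u[-length(u)]) / 2, 1)
  f1 <- vapply(cand, function(t) {
    pred <- probabilities > t
    tp <- sum(pred & y == 1)
    if (tp == 0) return(0)
    prec <- tp / sum(pred)
    rec <- tp / sum(y == 1)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  cand[which.max(f1)]   # which.max returns the first (lowest) maximizer
}

#' Fit a blueprint across one project's folds
#'
#' For each fold the preprocessing and estimator are fitted on the other
#' `k - 1` folds only and the held-out fold is predicted, yielding
#' out-of-fold probabilities, per-fold and pooled LogLoss/AUC, a
#' fold-held-out permutation feature importance list, and the best-F1
#' threshold on the out-of-fold predictions. Deterministic given the
#' blueprint's `estimator_seed` and the plan's seed.
#'
#' @param spec a [blueprint_spec()].
#' @param table a `feature_table` with target.
#' @param plan a [make_partition_plan()] result for the same records.
#' @param features predictor subset (default: all).
#' @param n_permutations shuffles per feature for importance (default 10).
#' @param compute_pfi set `FALSE` to skip importance (e.g. threshold
#'   sweeps), saving time.
#' @param keep_models keep per-fold fitted models for later prediction,
#'   partial dependence and external validation (default `TRUE`).
#' @return A `project_result`.
#' @export
fit_blueprint <- function(spec, table, plan, features = NULL,
                          n_permutations = 10, compute_pfi = TRUE,
                          keep_models = TRUE) {
  stopifnot(inherits(spec, "blueprint_spec"), inherits(plan, "partition_plan"))
  if (!identical(plan$patient_id, table$patient_id)) {
    stop("plan does not match the table's record set")
  }
  features <- features %||% ft_features(table)
  if (length(features) < 1 && spec$estimator != "majority-class") {
    stop("need at least one feature")
  }
  y <- table$target
  df <- table$predictors[features]
  kinds <- table$kinds[features]
  k <- plan$k
  n <- length(y)
  oof <- rep(NA_real_, n)
  fold_logloss <- fold_auc <- numeric(k)
  models <- if (keep_models) vector("list", k) else NULL
  raw_imp <- if (compute_pfi) matrix(0, length(features), k,
                                     dimnames = list(features, NULL)) else NULL

  for (j in seq_len(k)) {
    tr <- plan$fold_of != j
    va <- !tr
    pp <- .fit_preproc(df[tr, , drop = FALSE], kinds, spec)
    Xtr <- .pp_transform(pp, df[tr, , drop = FALSE])
    est <- .fit_estimator(spec, Xtr, y[tr])
    Xva <- .pp_transform(pp, df[va, , drop = FALSE])
    pv <- .est_predict(est, Xva)
    oof[va] <- pv
    fold_logloss[j] <- logloss(y[va], pv)
    fold_auc[j] <- auc(y[va], pv)
    if (keep_models) {
      models[[j]] <- structure(
        list(pp = pp, est = est, features = features, kinds = kinds,
             spec = spec),
        class = "bp_model")
    }
    if (compute_pfi) {
      base_ll <- fold_logloss[j]
      nv <- sum(va)
      pfi_seed <- .mix_seed(.mix_seed(spec$estimator_seed, plan$seed), j)
      raw_imp[, j] <- .with_seed(pfi_seed, {
        vapply(features, function(f) {
          blk <- pp$blocks[[f]]
          d <- numeric(n_permutations)
          for (r in seq_len(n_permutations)) {
            perm <- sample.int(nv)
            Xp <- Xva
            Xp[, blk] <- Xva[perm, blk, drop = FALSE]
            d[r] <- logloss(y[va], .est_predict(est, Xp)) - base_ll
          }
          mean(d)
        }, numeric(1))
      })
    }
  }

  pfi <- NULL
  if (compute_pfi) {
    imp <- pmax(rowMeans(raw_imp), 0)
    if (max(imp) > 0) imp <- imp / max(imp)
    pfi <- data.frame(feature = features, importance = unname(imp),
                      stringsAsFactors = FALSE)
    pfi$rank <- unname(.pfi_ranks(stats::setNames(pfi$importance,
                                                  pfi$feature))[pfi$feature])
  }

  structure(
    list(blueprint = spec$name, spec = spec, plan_seed = plan$seed, k = k,
         fold_logloss = fold_logloss, fold_auc = fold_auc,
         cv_logloss = logloss(y, oof), cv_auc = auc(y, oof),
         oof_predictions = oof, pfi = pfi,
         best_f1_threshold = best_f1_threshold(y, oof),
         targets = y, models = models, features = features),
    class = "project_result")
}

#' @exportS3Method base::print
print.project_result <- function(x, ...) {
  cat(sprintf("<project_result> %s seed=%d: LogLoss %.4f, AUC %.4f\n",
              x$blueprint, x$plan_seed, x$cv_logloss, x$cv_auc))
  invisible(x)
}

#' Fit a blueprint across every project of a set
#'
#' @inheritParams fit_blueprint
#' @param projects a [make_project_set()] result.
#' @param ... passed to [fit_blueprint()].
#' @return list of `project_result`s, one per project.
#' @export
fit_projects <- function(spec, table, projects, features = NULL, ...) {
  stopifnot(inherits(projects, "project_set"))
  lapply(projects$plans, function(plan) {
    fit_blueprint(spec, table, plan, features = features, ...)
  })
}

#' Average the fold models of a project over new data
#' @param result a `project_result` fitted with `keep_models = TRUE`.
#' @param newdata data.frame or `feature_table`.
#' @return per-record mean probability across the project's fold models.
#' @export
predict_project <- function(result, newdata) {
  if (is.null(result$models)) stop("project_result was fitted without models")
  preds <- vapply(result$models, predict_bp, numeric(
    if (inherits(newdata, "feature_table")) nrow(newdata$predictors)
    else nrow(newdata)), newdata = newdata)
  rowMeans(preds)
}
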