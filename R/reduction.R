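#' Expert-protected backward feature elimination
#'
#' The iterative backward wrapper stabilized by cross-project pFI
#' aggregation. Phase 1: at every step the blueprint is fitted across
#' all projects on the current feature list, pFI is aggregated, and the
#' five unprotected features with the lowest mean pFI are removed; when
#' a protected feature falls in the elimination set the next
#' lowest-importance unprotected feature is taken instead. Elimination
#' repeats while more than five unprotected features remain. Phase 2:
#' the feature-count window around the phase-1 LogLoss optimum
#' (plus/minus `window`, clipped) is re-traversed with step size 1.
#'
#' @param spec a [blueprint_spec()].
#' @param table a `feature_table` with target.
#' @param projects a [make_project_set()] result.
#' @param protected features the process may never eliminate.
#' @param features starting feature list (default: all predictors).
#' @param step_size phase-1 elimination count per step (default 5).
#' @param window phase-2 half-width around the phase-1 best size
#'   (default 5).
#' @param n_permutations importance shuffles per feature (default 10).
#' @param phase2 set `FALSE` to stop after phase 1.
#' @return A `reduction_trace`: list with `steps` (each holding `phase`,
#'   `features`, `eliminated`, `step_size`, `agg_logloss`, `agg_auc`,
#'   `pfi`), `protected`, `phase1_best_size`, `window`.
#' @export
backward_reduce <- function(spec, table, projects, protected = character(),
                            features = NULL, step_size = 5, window = 5,
                            n_permutations = 10, phase2 = TRUE) {
  features <- features %||% ft_features(table)
  if (!all(protected %in% features)) stop("protected must be a feature subset")
  if (!length(setdiff(features, protected))) stop("all features protected")

  fit_step <- function(feats, phase, ssize) {
    results <- fit_projects(spec, table, projects, features = feats,
                            n_permutations = n_permutations,
                            keep_models = FALSE)
    agg_pfi <- aggregate_pfi(results)
    list(phase = phase,
         n_features = length(feats),
         features = feats,
         eliminated = character(0),
         step_size = ssize,
         agg_logloss = aggregate_values(vapply(results, `[[`, numeric(1),
                                               "cv_logloss")),
         agg_auc = aggregate_values(vapply(results, `[[`, numeric(1),
                                           "cv_auc")),
         pfi = agg_pfi)
  }

  pick_victims <- function(step, n_remove) {
    unprot <- setdiff(step$features, protected)
    imp <- stats::setNames(step$pfi$importance, step$pfi$feature)[unprot]
    rk <- .pfi_ranks(imp)   # rank 1 = most important
    names(sort(rk, decreasing = TRUE))[seq_len(min(n_remove, length(unprot)))]
  }

  steps <- list()
  feats <- features
  repeat {
    step <- fit_step(feats, 1L, as.integer(step_size))
    steps[[length(steps) + 1L]] <- step
    unprot <- setdiff(feats, protected)
    if (length(unprot) <= step_size) break
    victims <- pick_victims(step, step_size)
    steps[[length(steps)]]$eliminated <- victims
    feats <- setdiff(feats, victims)
  }

  sizes <- vapply(steps, `[[`, integer(1), "n_features")
  lls <- vapply(steps, function(s) s$agg_logloss$mean, numeric(1))
  best_size <- sizes[which.min(lls)]
  win <- c(max(1L, best_size - as.integer(window)),
           min(length(features), best_size + as.integer(window)))

  if (phase2) {
    start_sizes <- sizes[sizes >= win[2]]
    start_feats <- if (length(start_sizes)) {
      steps[[which(sizes == min(start_sizes))[1]]]$features
    } else features
    feats <- start_feats
    repeat {
      step <- fit_step(feats, 2L, 1L)
      steps[[length(steps) + 1L]] <- step
      if (length(feats) <= win[1] ||
          !length(setdiff(feats, protected))) break
      victim <- pick_victims(step, 1L)
      steps[[length(steps)]]$eliminated <- victim
      feats <- setdiff(feats, victim)
    }
  }

  structure(list(steps = steps, protected = protected,
                 phase1_best_size = best_size, window = win,
                 blueprint = spec$name),
            class = "reduction_trace")
}

#' @exportS3Method base::print
print.reduction_trace <- function(x, ...) {
  df <- reduction_trace_df(x)
  cat(sprintf("<reduction_trace> %s: %d steps, phase-1 best size %d, window [%d, %d]\n",
              x$blueprint, nrow(df), x$phase1_best_size,
              x$window[1], x$window[2]))
  print.data.frame(df[, c("phase", "n_features", "mean_logloss", "mean_auc")])
  invisible(x)
}

#' Tidy summary of a reduction trace
#' @param trace a `reduction_trace`.
#' @return data.frame with one row per step: `step`, `phase`,
#'   `n_features`, `step_size`, `mean_logloss`, `logloss_ci_low/high`,
#'   `mean_auc`, `auc_ci_low/high`.
#' @export
reduction_trace_df <- function(trace) {
  do.call(rbind, lapply(seq_along(trace$steps), function(i) {
    s <- trace$steps[[i]]
    data.frame(step = i, phase = s$phase, n_features = s$n_features,
               step_size = s$step_size,
               mean_logloss = s$agg_logloss$mean,
               logloss_ci_low = s$agg_logloss$ci_low,
               logloss_ci_high = s$agg_logloss$ci_high,
               mean_auc = s$agg_auc$mean,
               auc_ci_low = s$agg_auc$ci_low,
               auc_ci_high = s$agg_auc$ci_high)
  }))
}

#' Select the parsimonious feature list from a reduction trace
#'
#' The phase-2 step with minimal mean cross-validation LogLoss wins;
#' ties break toward fewer features.
#'
#' @param trace a `reduction_trace` with phase-2 steps.
#' @return list with `features`, `n_features`, `agg_logloss`, `agg_auc`.
#' @export
select_parsimonious <- function(trace) {
  ph2 <- Filter(function(s) s$phase == 2L, trace$steps)
  if (!length(ph2)) stop("trace has no phase-2 steps")
  lls <- vapply(ph2, function(s) s$agg_logloss$mean, numeric(1))
  sizes <- vapply(ph2, `[[`, integer(1), "n_features")
  best <- which(lls == min(lls))
  best <- best[which.min(sizes[best])]
  s <- ph2[[best]]
  list(features = s$features, n_features = s$n_features,
       agg_logloss = s$agg_logloss, agg_auc = s$agg_auc)
}

#' Per-step feature rank instability along a reduction trace
#'
#' For each consecutive pair of steps, FRI over the surviving features:
#' their ranks within the pre-elimination list (restricted to survivors
#' and re-ranked) versus within the post-elimination list.
#'
#' @param trace a `reduction_trace` with at least 2 steps.
#' @return data.frame `step`, `phase`, `n_before`, `n_after`, `fri`.
#' @export
reduction_step_fri <- function(trace) {
  if (length(trace$steps) < 2) stop("trace needs at least 2 steps")
  out <- lapply(seq_len(length(trace$steps) - 1L), function(i) {
    before <- trace$steps[[i]]
    after <- trace$steps[[i + 1L]]
    if (!all(after$features %in% before$features)) return(NULL)
    data.frame(step = i, phase = after$phase,
               n_before = before$n_features, n_after = after$n_features,
               fri = fri(before$pfi, after$pfi))
  })
  do.call(rbind, Filter(Negate(is.null), out))
}
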