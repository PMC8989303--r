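#' Logarithmic loss of probabilistic predictions
#'
#' @param targets binary 0/1 vector.
#' @param probabilities predicted probabilities of class 1; clipped to
#'   `(clip, 1 - clip)` before the log.
#' @param clip clipping bound, default `1e-15`.
#' @return mean negative log-likelihood.
#' @export
logloss <- function(targets, probabilities, clip = 1e-15) {
  if (!length(targets)) stop("empty input")
  if (length(targets) != length(probabilities)) stop("length mismatch")
  p <- pmin(pmax(probabilities, clip), 1 - clip)
  y <- as.numeric(targets)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' Computed as P(score of a random positive > score of a random negative)
#' plus half the tie probability, via midranks.
#'
#' @param targets binary 0/1 vector with both classes present.
#' @param scores numeric scores.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(targets, scores) {
  y <- as.integer(targets)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes must be present")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Aggregate per-project scalars into mean and 95% confidence interval
#'
#' @param values numeric vector of per-project values (n >= 2).
#' @param conf confidence level, default 0.95.
#' @param method `"t"` (Student-t on n-1 df, the small-n default) or
#'   `"bootstrap"` (percentile bootstrap).
#' @param n_boot,seed bootstrap replicates and seed (bootstrap only).
#' @return An `aggregate_result`: list with `n`, `mean`, `ci_low`,
#'   `ci_high`, `values`.
#' @export
aggregate_values <- function(values, conf = 0.95, method = c("t", "bootstrap"),
                             n_boot = 2000, seed = 1) {
  method <- match.arg(method)
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("need at least 2 values for a confidence interval")
  m <- mean(values)
  if (method == "t") {
    half <- stats::qt(1 - (1 - conf) / 2, df = n - 1) * stats::sd(values) / sqrt(n)
    lo <- m - half; hi <- m + half
  } else {
    bm <- .with_seed(seed, vapply(seq_len(n_boot), function(i) {
      mean(values[sample.int(n, n, replace = TRUE)])
    }, numeric(1)))
    q <- stats::quantile(bm, c((1 - conf) / 2, 1 - (1 - conf) / 2), names = FALSE)
    lo <- q[1]; hi <- q[2]
  }
  structure(list(n = n, mean = m, ci_low = lo, ci_high = hi, values = values),
            class = "aggregate_result")
}

#' @exportS3Method base::print
print.aggregate_result <- function(x, ...) {
  cat(sprintf("<aggregate> n=%d mean=%.4f 95%% CI [%.4f, %.4f]\n",
              x$n, x$mean, x$ci_low, x$ci_high))
  invisible(x)
}

#' Standardized performance CI width
#'
#' The 95% confidence-interval width of a performance metric divided by
#' its mean, times 100: a scale-free measure of performance precision.
#'
#' @param agg an [aggregate_values()] result.
#' @return percent value.
#' @export
standardized_ci_width <- function(agg) {
  stopifnot(inherits(agg, "aggregate_result"))
  if (agg$mean == 0) stop("mean performance is zero; width undefined")
  (agg$ci_high - agg$ci_low) / agg$mean * 100
}

# Coerce a pFI representation to a named importance vector.
.pfi_vec <- function(p) {
  if (is.data.frame(p)) {
    stats::setNames(as.numeric(p$importance), as.character(p$feature))
  } else if (!is.null(names(p))) {
    as.numeric(p) -> v; names(v) <- names(p); v
  } else stop("pFI list must be a data.frame or named vector")
}

# Rank positions: rank 1 = highest importance; ties broken by feature name.
.pfi_ranks <- function(imp) {
  ord <- order(-imp, names(imp))
  r <- integer(length(imp))
  r[ord] <- seq_along(imp)
  stats::setNames(r, names(imp))
}

#' Feature rank instability between two pFI lists
#'
#' FRI is the sum over shared features of the absolute difference in
#' importance rank between two permutation-feature-importance lists.
#' It is an L1 distance on rank vectors: symmetric, non-negative, zero
#' iff the orderings agree. When the lists cover different feature sets,
#' ranks are recomputed within the shared subset.
#'
#' @param p,q pFI lists: data.frames with `feature` and `importance`
#'   columns, or named numeric vectors of importances.
#' @return FRI value (non-negative).
#' @export
fri <- function(p, q) {
  pv <- .pfi_vec(p); qv <- .pfi_vec(q)
  shared <- intersect(names(pv), names(qv))
  if (!length(shared)) stop("empty feature intersection")
  rp <- .pfi_ranks(pv[shared])
  rq <- .pfi_ranks(qv[shared])
  sum(abs(rp - rq[names(rp)]))
}

#' FRI restricted to the k least-important reference features
#'
#' Full-list ranks are computed on the shared feature set of both lists;
#' the sum runs only over the `k` lowest-importance features of the
#' reference list (by convention the smaller/earlier aggregate).
#'
#' @param p_reference reference pFI list defining the bottom-k set.
#' @param q comparison pFI list.
#' @param k number of least-important features (> 0).
#' @return bottom-k FRI value.
#' @export
fri_bottom_k <- function(p_reference, q, k) {
  if (k <= 0) stop("k must be positive")
  pv <- .pfi_vec(p_reference); qv <- .pfi_vec(q)
  shared <- intersect(names(pv), names(qv))
  if (!length(shared)) stop("empty feature intersection")
  if (k > length(shared)) stop("k exceeds shared feature count")
  rp <- .pfi_ranks(pv[shared])
  rq <- .pfi_ranks(qv[shared])
  bottom <- names(sort(rp, decreasing = TRUE))[seq_len(k)]
  sum(abs(rp[bottom] - rq[bottom]))
}

#' Sampling analysis of performance precision vs number of projects
#'
#' Implements the repeated-sampling procedure: draw projects one at a
#' time without replacement; after each draw recompute the standardized
#' performance CI width of the current aggregate; repeat `n_draws` times
#' and report the expected width with a 95% CI at every aggregate size.
#'
#' @param values per-project performance scalars (one blueprint, one
#'   metric), or a list of `project_result`s with `metric` naming the
#'   field (`"cv_logloss"` or `"cv_auc"`).
#' @param n_draws number of sampling replicates (default 1000).
#' @param seed RNG seed; the curve is reproducible bit-for-bit.
#' @param m_max largest aggregate size, default all projects.
#' @param metric field to extract when `values` is a list of results.
#' @return data.frame with `size`, `mean`, `ci_low`, `ci_high` (class
#'   `stability_curve`).
#' @export
precision_sampling_analysis <- function(values, n_draws = 1000, seed = 1,
                                        m_max = NULL, metric = "cv_logloss") {
  if (is.list(values) && !is.data.frame(values) && !is.numeric(values)) {
    values <- vapply(values, function(r) r[[metric]], numeric(1))
  }
  values <- as.numeric(values)
  n <- length(values)
  if (n < 2) stop("need at least 2 project results")
  if (n_draws < 1) stop("n_draws must be >= 1")
  values <- sort(values)   # canonical order: curve invariant to input order
  m_max <- min(m_max %||% n, n)
  sizes <- 2:m_max
  tfac <- stats::qt(0.975, df = sizes - 1)
  width_mat <- .with_seed(seed, {
    vapply(seq_len(n_draws), function(d) {
      v <- values[sample.int(n)]
      # Welford running moments: exact zeros for identical performances
      mean_r <- v[1]; m2 <- 0
      out <- numeric(length(sizes))
      for (m in 2:m_max) {
        delta <- v[m] - mean_r
        mean_r <- mean_r + delta / m
        m2 <- m2 + delta * (v[m] - mean_r)
        s <- sqrt(m2 / (m - 1))
        out[m - 1L] <- 2 * tfac[m - 1L] * s / sqrt(m) / mean_r * 100
      }
      out
    }, numeric(length(sizes)))
  })
  .curve_from_mat(width_mat, sizes, "standardized_ci_width")
}

.curve_from_mat <- function(mat, sizes, metric) {
  mat <- matrix(mat, nrow = length(sizes))
  m <- rowMeans(mat)
  nd <- ncol(mat)
  if (nd > 1) {
    sdv <- apply(mat, 1, stats::sd)
    half <- stats::qt(0.975, df = nd - 1) * sdv / sqrt(nd)
  } else half <- 0
  out <- data.frame(size = sizes, mean = m,
                    ci_low = m - half, ci_high = m + half)
  attr(out, "metric") <- metric
  class(out) <- c("stability_curve", "data.frame")
  out
}

#' Sampling analysis of feature rank instability vs number of projects
#'
#' Per replicate: draw projects without replacement; at each aggregate
#' size `m >= 2` rank features by mean normalized pFI over the aggregate
#' and compute FRI against the previous aggregate's ranking (for `m = 2`,
#' against the first drawn project's own list). With `bottom_k`, FRI is
#' restricted to the `bottom_k` least-important features of the smaller
#' (previous) aggregate, using full-list ranks.
#'
#' @param pfi_lists list of per-project pFI lists (data.frames with
#'   `feature`/`importance` or named vectors) over a common feature set,
#'   or a list of `project_result`s.
#' @param n_draws number of replicates (default 1000).
#' @param seed RNG seed.
#' @param bottom_k optional bottom-k restriction (e.g. 5).
#' @param m_max largest aggregate size, default all projects.
#' @return a `stability_curve` data.frame.
#' @export
fri_sampling_analysis <- function(pfi_lists, n_draws = 1000, seed = 1,
                                  bottom_k = NULL, m_max = NULL) {
  if (length(pfi_lists) && inherits(pfi_lists[[1]], "project_result")) {
    pfi_lists <- lapply(pfi_lists, function(r) r$pfi)
  }
  vecs <- lapply(pfi_lists, .pfi_vec)
  feats <- names(vecs[[1]])
  if (any(vapply(vecs, function(v) !setequal(names(v), feats), logical(1)))) {
    stop("all pFI lists must share one feature set")
  }
  M <- vapply(vecs, function(v) v[feats], numeric(length(feats)))
  rownames(M) <- feats
  M <- M[, do.call(order, as.data.frame(t(M))), drop = FALSE]  # canonical order
  P <- ncol(M)
  if (P < 2) stop("need at least 2 project pFI lists")
  m_max <- min(m_max %||% P, P)
  sizes <- 2:m_max
  fri_mat <- .with_seed(seed, {
    vapply(seq_len(n_draws), function(d) {
      perm <- sample.int(P)
      prev <- M[, perm[1]]
      run_sum <- prev
      out <- numeric(length(sizes))
      for (m in sizes) {
        run_sum <- run_sum + M[, perm[m]]
        cur <- run_sum / m
        out[m - 1L] <- if (is.null(bottom_k)) fri(prev, cur)
                       else fri_bottom_k(prev, cur, bottom_k)
        prev <- cur
      }
      out
    }, numeric(length(sizes)))
  })
  .curve_from_mat(fri_mat,
                  sizes,
                  if (is.null(bottom_k)) "fri" else sprintf("fri_bottom_%d", bottom_k))
}

#' @exportS3Method base::print
print.stability_curve <- function(x, ...) {
  cat(sprintf("<stability_curve> metric=%s, sizes %d..%d\n",
              attr(x, "metric") %||% "?", min(x$size), max(x$size)))
  print.data.frame(utils::head(as.data.frame(x), 5))
  invisible(x)
}
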