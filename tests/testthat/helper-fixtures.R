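# Shared fixtures and independent oracles, built in code at test time.

# Balanced binary table: n/2 of each class, one informative feature with a
# clear margin and one pure-noise feature.
balanced_table <- function(n = 20, seed = 1) {
  withr::with_seed(seed, {
    y <- rep(c(0L, 1L), each = n / 2)
    x <- ifelse(y == 1, 1, -1) + rnorm(n, 0, 0.2)
    z <- rnorm(n)
    feature_table(data.frame(x = x, z = z), target = y)
  })
}

# Fast linear blueprint used in recovery experiments.
bp_linear <- function(seed = 1L) {
  blueprint_spec("lin", "passthrough-standardize", "one-hot", "l2-logistic",
                 estimator_seed = seed)
}

# Independent AUC oracle: exhaustive pair counting.
auc_pairs <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  wins <- ties <- 0
  for (a in pos) for (b in neg) {
    if (a > b) wins <- wins + 1
    else if (a == b) ties <- ties + 1
  }
  (wins + ties / 2) / (length(pos) * length(neg))
}

# Independent FRI oracle: explicit rank construction + L1 sum.
fri_oracle <- function(p_imp, q_imp) {
  shared <- intersect(names(p_imp), names(q_imp))
  rank_of <- function(v) {
    ord <- order(-v[shared], shared)
    r <- integer(length(shared)); r[ord] <- seq_along(shared)
    names(r) <- shared
    r
  }
  rp <- rank_of(p_imp); rq <- rank_of(q_imp)
  total <- 0
  for (f in shared) total <- total + abs(rp[[f]] - rq[[f]])
  total
}

# Independent best-F1 oracle: dense scan over all observed probabilities
# plus offsets around them.
best_f1_oracle <- function(y, p) {
  cand <- sort(unique(c(0, 1, p, p - 1e-9, p + 1e-9)))
  f1 <- vapply(cand, function(t) {
    pred <- p > t
    tp <- sum(pred & y == 1)
    if (tp == 0) return(0)
    prec <- tp / sum(pred); rec <- tp / sum(y == 1)
    2 * prec * rec / (prec + rec)
  }, numeric(1))
  list(best = max(f1), thresholds = cand, f1 = f1)
}

# All permutations of 1..n (small n only).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

# A cached default synthetic cohort shared across test files.
.default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- simulate_cohort(cohort_config(), seed = 42)
    cache
  }
})
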