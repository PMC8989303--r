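test_that("logloss matches hand-computed values", {
  expect_lt(logloss(c(1, 0), c(1, 0)), 1e-13)
  expect_equal(logloss(c(1, 0), c(0.5, 0.5)), log(2), tolerance = 1e-12)
  expect_equal(logloss(c(1, 1, 0), c(0.9, 0.8, 0.3)),
               -(log(0.9) + log(0.8) + log(0.7)) / 3, tolerance = 1e-12)
  expect_error(logloss(numeric(0), numeric(0)), "empty")
})

test_that("auc matches exhaustive pair counting", {
  expect_equal(auc(c(1, 0, 1, 0), c(0.9, 0.8, 0.7, 0.1)), 0.75)
  expect_equal(auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(auc(c(1, 0, 1, 0), rep(0.4, 4)), 0.5)
  expect_error(auc(c(1, 1), c(0.1, 0.2)), "both classes")
  for (case in 1:50) {
    withr::with_seed(1000 + case, {
      n <- sample(4:12, 1)
      y <- c(0L, 1L, sample(0:1, n - 2, replace = TRUE))
      s <- round(runif(n), 2)   # rounding forces occasional ties
      expect_equal(auc(y, s), auc_pairs(y, s), tolerance = 1e-12)
    })
  }
})

test_that("aggregation yields Student-t intervals with nominal coverage", {
  a <- aggregate_values(rep(0.4, 5))
  expect_equal(a$mean, 0.4)
  expect_equal(a$ci_high - a$ci_low, 0)

  b <- aggregate_values(c(0.6, 0.7))
  expect_equal(b$mean, 0.65)
  expect_equal(b$ci_high - b$mean, qt(0.975, 1) * 0.05, tolerance = 1e-9)
  expect_equal(b$ci_high - b$mean, 0.6353102, tolerance = 1e-6)

  expect_error(aggregate_values(1), "at least 2")

  cover <- withr::with_seed(11, {
    mean(vapply(1:2000, function(i) {
      a <- aggregate_values(rnorm(25))
      a$ci_low <= 0 && a$ci_high >= 0
    }, logical(1)))
  })
  expect_gt(cover, 0.93)
  expect_lt(cover, 0.97)
})

test_that("standardized CI width is scale-free and matches substitution", {
  a <- structure(list(n = 3, mean = 0.5, ci_low = 0.4875, ci_high = 0.5125,
                      values = c(0.49, 0.5, 0.51)),
                 class = "aggregate_result")
  expect_equal(standardized_ci_width(a), 5)
  v <- c(0.61, 0.72, 0.66, 0.70)
  w1 <- standardized_ci_width(aggregate_values(v))
  w2 <- standardized_ci_width(aggregate_values(2 * v))
  expect_equal(w1, w2, tolerance = 1e-12)
  zero <- aggregate_values(c(-1, 1))
  expect_error(standardized_ci_width(zero), "zero")
})

test_that("fri is an L1 distance on ranks, verified by brute force", {
  p <- c(a = 1.0, b = 0.5, c = 0.2)
  q <- c(a = 0.5, b = 1.0, c = 0.2)
  expect_equal(fri(p, p), 0)
  expect_equal(fri(p, q), 2)
  expect_equal(fri(p, q), fri(q, p))
  expect_error(fri(c(a = 1), c(b = 1)), "empty feature intersection")

  # reversal maxima: f^2/2 (even), (f^2-1)/2 (odd), against brute force
  for (f in 2:8) {
    feats <- sprintf("f%02d", seq_len(f))
    fwd <- stats::setNames(rev(seq_len(f)) / f, feats)
    bwd <- stats::setNames(seq_len(f) / f, feats)
    expected_max <- if (f %% 2 == 0) f^2 / 2 else (f^2 - 1) / 2
    expect_equal(fri(fwd, bwd), expected_max)
    expect_equal(fri_oracle(fwd, bwd), expected_max)
  }

  # full enumeration at f = 5: oracle equivalence + maximum attained
  feats <- letters[1:5]
  base <- stats::setNames(rev(seq_len(5)), feats)
  perms <- all_perms(5)
  vals <- apply(perms, 1, function(pm) {
    other <- stats::setNames(rev(seq_len(5))[pm], feats)
    v <- fri(base, other)
    expect_equal(v, fri_oracle(base, other))
    v
  })
  expect_equal(max(vals), 12)   # (25 - 1) / 2

  # triangle inequality on random importance vectors, f <= 12
  for (case in 1:40) {
    withr::with_seed(2000 + case, {
      f <- sample(3:12, 1)
      nm <- sprintf("x%02d", seq_len(f))
      a <- stats::setNames(runif(f), nm)
      b <- stats::setNames(runif(f), nm)
      cc <- stats::setNames(runif(f), nm)
      expect_lte(fri(a, cc), fri(a, b) + fri(b, cc))
      expect_equal(fri(a, b), fri_oracle(a, b))
    })
  }
})

test_that("bottom-k fri restricts the sum to the reference's tail", {
  p <- c(a = 1.0, b = 0.8, c = 0.6, d = 0.4, e = 0.1)
  expect_equal(fri_bottom_k(p, p, 3), 0)
  expect_equal(fri_bottom_k(p, p, 5), fri(p, p))
  # bottom feature e moves from rank 5 to rank 2; others shift by one
  q <- c(a = 1.0, b = 0.8, c = 0.6, d = 0.4, e = 0.9)
  expect_equal(fri_bottom_k(p, q, 1), 3)
  expect_equal(fri_bottom_k(p, q, 5), fri(p, q))
  expect_error(fri_bottom_k(p, q, 0), "positive")
})

test_that("precision sampling reproduces the t/sqrt(n) shrinkage law", {
  flat <- precision_sampling_analysis(rep(0.68, 30), n_draws = 50, seed = 3)
  expect_true(all(flat$mean == 0))

  mu <- 0.67; sigma <- 0.02; n <- 150
  vals <- withr::with_seed(5, rnorm(n, mu, sigma))
  curve <- precision_sampling_analysis(vals, n_draws = 400, seed = 9,
                                       m_max = 25)
  # analytic expectation: E[width_m] = 2 t_{m-1} c4(m) sigma / sqrt(m)
  c4 <- function(m) sqrt(2 / (m - 1)) * gamma(m / 2) / gamma((m - 1) / 2)
  expected <- function(m) 2 * qt(0.975, m - 1) * c4(m) * sigma / sqrt(m) / mu * 100
  expect_equal(curve$mean[curve$size == 25], expected(25), tolerance = 0.1)
  ratio <- curve$mean[curve$size == 25] / curve$mean[curve$size == 2]
  expect_lt(ratio, 0.5)

  # bit-for-bit replicability and input-order invariance
  c2 <- precision_sampling_analysis(vals, n_draws = 400, seed = 9, m_max = 25)
  expect_identical(curve, c2)
  c3 <- precision_sampling_analysis(rev(vals), n_draws = 400, seed = 9,
                                    m_max = 25)
  expect_identical(curve, c3)
})

test_that("fri sampling stabilizes with aggregation", {
  feats <- sprintf("f%02d", 1:20)
  shared <- stats::setNames(seq(1, 0.05, length.out = 20), feats)
  lists <- replicate(10, shared, simplify = FALSE)
  flat <- fri_sampling_analysis(lists, n_draws = 30, seed = 2)
  expect_true(all(flat$mean == 0))

  noisy <- withr::with_seed(8, {
    lapply(1:30, function(i) pmax(shared + rnorm(20, 0, 0.25), 0))
  })
  full <- fri_sampling_analysis(noisy, n_draws = 150, seed = 4)
  bot <- fri_sampling_analysis(noisy, n_draws = 150, seed = 4, bottom_k = 5)
  expect_true(all(bot$mean <= full$mean + 1e-9))
  expect_lt(mean(full$mean[full$size >= 25]), mean(full$mean[full$size <= 5]))

  # replicable and invariant to list order
  full2 <- fri_sampling_analysis(rev(noisy), n_draws = 150, seed = 4)
  expect_identical(full, full2)
})
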