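test_that("quintile encoder puts edges at the 20/40/60/80 percentiles", {
  enc <- quintile_bin_encode(1:10)
  expect_equal(enc$edges, c(2.8, 4.6, 6.4, 8.2))
  expect_equal(unname(which(quintile_bin_apply(enc, 9)[1, ] == 1)), 5L)
  # out-of-range values clamp to the extreme bins
  expect_equal(unname(which(quintile_bin_apply(enc, -5)[1, ] == 1)), 1L)
  expect_equal(unname(which(quintile_bin_apply(enc, 50)[1, ] == 1)), 5L)

  const <- quintile_bin_encode(rep(3, 10))
  expect_equal(const$n_bins, 1L)
  expect_true(all(quintile_bin_apply(const, c(1, 3, 9)) == 1))

  withr::with_seed(3, {
    v <- rnorm(57)
    ind <- quintile_bin_apply(quintile_bin_encode(v), v)
    expect_true(all(rowSums(ind) == 1))
  })
  expect_error(quintile_bin_encode(c(NA_real_, NA_real_)), "all-missing")
})

test_that("majority-class blueprint predicts the training-fold prevalence", {
  tab <- balanced_table(20)
  plan <- make_partition_plan(tab, 10, seed = 4)
  res <- fit_blueprint(bp_majority(), tab, plan, compute_pfi = FALSE)
  # perfect stratification: every training fold is exactly 9/9
  expect_true(all(res$oof_predictions == 0.5))
  expect_equal(res$cv_logloss, log(2), tolerance = 1e-12)
  expect_true(all(res$fold_auc == 0.5))
})

test_that("l2-logistic separates a clean signal and is deterministic", {
  tab <- balanced_table(40, seed = 6)
  plan <- make_partition_plan(tab, 10, seed = 5)
  r1 <- fit_blueprint(bp_logistic(), tab, plan)
  expect_gte(r1$cv_auc, 0.95)
  r2 <- fit_blueprint(bp_logistic(), tab, plan)
  expect_identical(r1$oof_predictions, r2$oof_predictions)
  expect_identical(r1$pfi, r2$pfi)
  expect_identical(r1$cv_logloss, r2$cv_logloss)
  # pooled out-of-fold LogLoss equals direct recomputation
  p <- pmin(pmax(r1$oof_predictions, 1e-15), 1 - 1e-15)
  direct <- -sum(tab$target * log(p) + (1 - tab$target) * log(1 - p)) / 40
  expect_equal(r1$cv_logloss, direct, tolerance = 1e-12)
})

test_that("gradient-boosted trees learn the planted signal deterministically", {
  sim <- simulate_planted_cohort(n = 400, seed = 21)
  plan <- make_partition_plan(sim$table, 5, seed = 3)
  spec <- bp_gbt()
  r1 <- fit_blueprint(spec, sim$table, plan, n_permutations = 3)
  expect_gte(r1$cv_auc, 0.75)
  r2 <- fit_blueprint(spec, sim$table, plan, n_permutations = 3)
  expect_identical(r1$oof_predictions, r2$oof_predictions)
  expect_identical(r1$pfi, r2$pfi)
})

test_that("validation-fold targets never leak into predictions", {
  tab <- balanced_table(30, seed = 9)
  plan <- make_partition_plan(tab, 5, seed = 2)
  r1 <- fit_blueprint(bp_logistic(), tab, plan, compute_pfi = FALSE)
  fold1 <- plan$fold_of == 1
  flipped <- feature_table(tab$predictors,
                           target = ifelse(fold1, 1L - tab$target, tab$target),
                           kinds = tab$kinds, patient_id = tab$patient_id)
  r2 <- fit_blueprint(bp_logistic(), flipped, plan, compute_pfi = FALSE)
  expect_identical(r1$oof_predictions[fold1], r2$oof_predictions[fold1])
})

test_that("encoders separate fit and transform cleanly", {
  withr::with_seed(13, {
    df <- data.frame(x = rnorm(40), g = sample(c("u", "v", "w"), 40, TRUE))
  })
  kinds <- c(x = "numeric", g = "categorical")
  spec <- bp_logistic()
  tr <- df[1:25, ]; va <- df[26:40, ]
  pp <- stabml:::.fit_preproc(tr, kinds, spec)
  sep <- rbind(stabml:::.pp_transform(pp, tr), stabml:::.pp_transform(pp, va))
  joint <- stabml:::.pp_transform(pp, rbind(tr, va))
  expect_equal(sep, joint, tolerance = 1e-15)
})

test_that("best-F1 threshold matches brute force with lower-tie preference", {
  expect_equal(best_f1_threshold(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 0.5)
  expect_error(best_f1_threshold(c(0, 0), c(0.2, 0.3)), "no positive")

  # spec toy: optimum attained on a region; implementation must reach the
  # oracle's best F1 and prefer the lowest optimal candidate
  y <- c(0, 1, 1); p <- c(0.9, 0.4, 0.5)
  oracle <- best_f1_oracle(y, p)
  t_star <- best_f1_threshold(y, p)
  f1_at <- function(t) {
    pred <- p > t
    tp <- sum(pred & y == 1)
    if (tp == 0) return(0)
    2 * (tp / sum(pred)) * (tp / sum(y == 1)) /
      (tp / sum(pred) + tp / sum(y == 1))
  }
  expect_equal(f1_at(t_star), oracle$best, tolerance = 1e-12)
  expect_lt(t_star, 0.4 + 1e-9)   # ties break toward the lower threshold

  # all probabilities equal: threshold below them, F1 = 2p/(p+1)
  y2 <- c(1, 1, 0, 1); p2 <- rep(0.6, 4)
  t2 <- best_f1_threshold(y2, p2)
  expect_lt(t2, 0.6)
  prev <- mean(y2)
  expect_equal(f1_at2 <- {
    pred <- p2 > t2; tp <- sum(pred & y2 == 1)
    2 * (tp / sum(pred)) * (tp / sum(y2 == 1)) /
      (tp / sum(pred) + tp / sum(y2 == 1))
  }, 2 * prev / (prev + 1), tolerance = 1e-12)

  for (case in 1:30) {
    withr::with_seed(3000 + case, {
      n <- sample(5:14, 1)
      y <- c(1L, sample(0:1, n - 1, replace = TRUE))
      p <- round(runif(n), 2)
      t_hat <- best_f1_threshold(y, p)
      pred <- p > t_hat
      tp <- sum(pred & y == 1)
      f1 <- if (tp == 0) 0 else {
        2 * (tp / sum(pred)) * (tp / sum(y == 1)) /
          (tp / sum(pred) + tp / sum(y == 1))
      }
      expect_equal(f1, best_f1_oracle(y, p)$best, tolerance = 1e-12)
    })
  }
})

test_that("fit_blueprint validates its inputs", {
  tab <- balanced_table(20)
  plan <- make_partition_plan(tab, 10, seed = 1)
  other <- balanced_table(22)
  expect_error(fit_blueprint(bp_logistic(), other, plan), "record set")
  expect_error(blueprint_spec("x", estimator = "l2-logistic",
                              hyperparameters = list(n_trees = 5)),
               "not valid")
})
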