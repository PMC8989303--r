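test_that("validation scoring aggregates projects without refitting", {
  tab <- balanced_table(40, seed = 91)
  ps <- make_project_set(tab, 5, 3, master_seed = 92)
  res <- fit_projects(bp_linear(), tab, ps, compute_pfi = FALSE)
  vtab <- balanced_table(30, seed = 93)
  score <- score_validation(res, vtab)
  expect_equal(sum(score$confusion), 30)
  expect_equal(unname(score$confusion["TP"] + score$confusion["FN"]),
               sum(vtab$target == 1))
  expect_true(all(score$predictions$mean >= 0 & score$predictions$mean <= 1))

  # leakage check: perturbing validation targets leaves probabilities alone
  flipped <- feature_table(vtab$predictors, target = 1L - vtab$target,
                           kinds = vtab$kinds, patient_id = vtab$patient_id)
  score2 <- score_validation(res, flipped)
  expect_identical(score$predictions$mean, score2$predictions$mean)

  missing_tab <- feature_table(vtab$predictors["x"], target = vtab$target)
  expect_error(score_validation(res, missing_tab), "z")
})

test_that("degenerate scoring cases produce the expected confusion cells", {
  tab <- balanced_table(40, seed = 94)
  ps <- make_project_set(tab, 5, 2, master_seed = 95)
  res <- fit_projects(bp_linear(), tab, ps, compute_pfi = FALSE)
  vtab <- balanced_table(20, seed = 96)
  low <- vtab$predictors
  low$x <- low$x - 6   # push every record far below the decision boundary
  low_tab <- feature_table(low, target = vtab$target)
  score <- score_validation(res, low_tab)
  # all probabilities fall below the threshold: nothing is called positive
  expect_equal(unname(score$confusion["TP"] + score$confusion["FP"]), 0)
  expect_equal(unname(score$confusion["TN"]), sum(vtab$target == 0))
})

test_that("psi matches its closed forms and flags disjoint support", {
  withr::with_seed(101, {
    x <- rnorm(500)
    expect_equal(psi(x, x), 0)
  })
  # categorical disjoint support with the 1e-4 floor, exact closed form
  eps <- 1e-4
  expected <- (eps - 1) * log(eps) + (1 - eps) * log(1 / eps)
  expect_equal(psi(rep("a", 50), rep("b", 60)), expected, tolerance = 1e-12)
  expect_gt(expected, 0.25)

  # invariance under strictly monotone transforms (quantile bins)
  withr::with_seed(102, {
    a <- rlnorm(400); b <- rlnorm(400, 0.3)
    expect_equal(psi(a, b), psi(log(a), log(b)), tolerance = 1e-12)
    expect_equal(psi(a, b), psi(3 * a + 2, 3 * b + 2), tolerance = 1e-12)
  })
  expect_error(psi(numeric(0), 1), "non-empty")
})

test_that("drift classes use the stated boundaries", {
  expect_identical(classify_drift(0.05), "none")
  expect_identical(classify_drift(0.26), "significant")
  expect_identical(classify_drift(0.1), "moderate")
  expect_identical(classify_drift(0.25), "moderate")
  expect_identical(classify_drift(c(0, 0.12, 0.9)),
                   c("none", "moderate", "significant"))
  expect_error(classify_drift(-0.1), "non-negative")
})

test_that("drift report covers features with consistent classes", {
  sim <- simulate_cohort(cohort_config(n_patients = 80, missing_rate = 0),
                         seed = 103)
  drifted <- simulate_drifted_cohort(cohort_config(missing_rate = 0),
                                     drift_spec(n_patients = 80), seed = 104)
  rep <- drift_report(sim$table, drifted$table,
                      c("Time_to_OR", "TBI_Present", "MAP_mean"))
  expect_identical(rep$drift_class, classify_drift(rep$psi))
  expect_gt(rep$psi[rep$feature == "Time_to_OR"], 0.25)
  expect_lt(rep$psi[rep$feature == "TBI_Present"], 0.1)
})

test_that("well-separated blobs cluster with full purity", {
  withr::with_seed(105, {
    n <- 30
    df <- data.frame(u = c(rnorm(n, -8), rnorm(n, 8)),
                     v = c(rnorm(n, -8), rnorm(n, 8)))
  })
  t1 <- feature_table(df[1:n, ], target = rep(c(0L, 1L), n / 2))
  t2 <- feature_table(df[(n + 1):(2 * n), ], target = rep(c(0L, 1L), n / 2))
  cl <- cluster_cohorts(t1, t2, c("u", "v"), min_cluster_size = 8,
                        embedding_seed = 9)
  expect_equal(length(unique(cl$labels)), 2)
  purity <- max(table(cl$labels[cl$cohort == "train"])) +
    max(table(cl$labels[cl$cohort == "valid"]))
  expect_equal(purity, 2 * n)
  cl2 <- cluster_cohorts(t1, t2, c("u", "v"), min_cluster_size = 8,
                         embedding_seed = 9)
  expect_identical(cl$labels, cl2$labels)
})

test_that("listwise deletion counts are exact", {
  withr::with_seed(106, {
    df <- data.frame(a = rnorm(133), b = rnorm(133))
    df$a[c(3, 17, 40, 77, 90)] <- NA
    df$b[c(17, 101, 110, 120, 131)] <- NA   # overlap at row 17 -> 9 rows hit
  })
  t1 <- feature_table(df[1:74, ], target = rep_len(c(0L, 1L), 74))
  t2 <- feature_table(df[75:133, ], target = rep_len(c(0L, 1L), 59),
                      patient_id = sprintf("V%03d", 1:59))
  cl <- cluster_cohorts(t1, t2, c("a", "b"), min_cluster_size = 8,
                        embedding_seed = 2, method = "pca")
  expect_equal(cl$n_removed, 9)
  expect_equal(length(cl$labels), 124)
  expect_error(cluster_cohorts(t1, t2, c("a", "b"), min_cluster_size = 70),
               "min_cluster_size")
})

test_that("cluster summaries recover a planted subpopulation", {
  withr::with_seed(107, {
    n <- 24
    df <- data.frame(Time_to_OR = c(rlnorm(n, log(30), 0.2),
                                    rlnorm(n, log(400), 0.2)),
                     other = c(rnorm(n, -6), rnorm(n, 6)))
  })
  t1 <- feature_table(df[1:n, ], target = rep_len(c(0L, 1L), n))
  t2 <- feature_table(df[(n + 1):(2 * n), ], target = rep_len(c(0L, 1L), n),
                      patient_id = sprintf("V%03d", seq_len(n)))
  cl <- cluster_cohorts(t1, t2, c("Time_to_OR", "other"),
                        min_cluster_size = 8, embedding_seed = 3)
  cs <- summarize_clusters(cl, t1, t2)
  expect_equal(sum(cs$counts), length(cl$labels))
  num <- cs$numeric[cs$numeric$feature == "Time_to_OR", ]
  global_mean <- mean(df$Time_to_OR)
  expect_true(any(num$mean > global_mean))   # the high-Time_to_OR cluster
  # single cluster equals global summaries
  one <- cl; one$labels <- rep(1L, length(cl$labels))
  cs1 <- summarize_clusters(one, t1, t2)
  expect_equal(cs1$numeric$mean[cs1$numeric$feature == "Time_to_OR"],
               global_mean)
})
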