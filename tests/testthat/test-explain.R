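test_that("permutation importance normalizes to the top feature", {
  tab <- balanced_table(60, seed = 31)   # x drives y, z is noise
  model <- fit_model(bp_logistic(), tab)
  imp <- permutation_importance(model, tab, n_permutations = 20, seed = 5)
  expect_equal(imp$importance[imp$feature == "x"], 1)
  expect_lt(imp$importance[imp$feature == "z"], 0.15)
  expect_error(permutation_importance(model, data.frame(q = 1), targets = 1),
               "absent")
})

test_that("sampled importance agrees with exhaustive permutation averaging", {
  withr::with_seed(17, {
    df <- data.frame(x = rnorm(8), z = rnorm(8))
    y <- as.integer(df$x + 0.3 * rnorm(8) > 0)
    y[1] <- 1L; y[2] <- 0L
  })
  tab <- feature_table(df, target = y)
  spec <- bp_linear()
  model <- fit_model(spec, tab)
  X <- stabml:::.pp_transform(model$pp, df)
  base_ll <- logloss(y, stabml:::.est_predict(model$est, X))

  perms <- all_perms(8)   # all 40320 shuffles, evaluated in one batch
  exhaustive <- vapply(model$features, function(f) {
    blk <- model$pp$blocks[[f]]
    Xbig <- X[rep(1:8, nrow(perms)), , drop = FALSE]
    Xbig[, blk] <- X[as.vector(t(perms)), blk, drop = FALSE]
    pr <- stabml:::.est_predict(model$est, Xbig)
    ll <- -(rep(y, nrow(perms)) * log(pr) + (1 - rep(y, nrow(perms))) * log(1 - pr))
    mean(colMeans(matrix(ll, nrow = 8)) - base_ll)
  }, numeric(1))
  exhaustive <- pmax(exhaustive, 0)
  exhaustive <- exhaustive / max(exhaustive)

  sampled <- permutation_importance(model, tab, n_permutations = 400, seed = 1)
  got <- stats::setNames(sampled$importance, sampled$feature)[model$features]
  expect_equal(unname(got), unname(exhaustive), tolerance = 0.1)
})

test_that("pFI aggregation averages importances and ranks the means", {
  l1 <- c(a = 1.0, b = 0.5, c = 0.0)
  agg_same <- aggregate_pfi(list(l1, l1, l1))
  expect_equal(stats::setNames(agg_same$importance, agg_same$feature)[names(l1)],
               l1)
  expect_true(all(agg_same$ci_high - agg_same$ci_low == 0))

  l2 <- c(a = 0.5, b = 1.0, c = 0.2)
  agg <- aggregate_pfi(list(l1, l2))
  expect_equal(agg$importance[agg$feature == "a"], 0.75)
  expect_identical(agg$rank, rank(-agg$importance, ties.method = "first"))
  expect_error(aggregate_pfi(list(l1)), "at least 2")
})

test_that("collinear duplicates share importance", {
  tab <- balanced_table(80, seed = 41)
  lone <- permutation_importance(fit_model(bp_linear(), tab), tab,
                                 n_permutations = 10, seed = 2)
  dup_df <- tab$predictors
  dup_df$x2 <- dup_df$x
  dup_tab <- feature_table(dup_df, target = tab$target)
  dup <- permutation_importance(fit_model(bp_linear(), dup_tab), dup_tab,
                                n_permutations = 10, seed = 2)
  # raw (unnormalized) comparison is hidden by normalization; compare the
  # copies' margin over noise instead: each copy matters, but neither can
  # dominate the way the lone feature does
  lone_gap <- lone$importance[lone$feature == "x"] -
    lone$importance[lone$feature == "z"]
  expect_gt(lone_gap, 0.8)
  imp <- stats::setNames(dup$importance, dup$feature)
  expect_gt(imp[["x"]], imp[["z"]])
  expect_gt(imp[["x2"]], imp[["z"]])
})

test_that("partial dependence reflects what the model uses", {
  tab <- balanced_table(50, seed = 23)
  flat_model <- fit_model(bp_majority(), tab)
  flat <- partial_dependence(flat_model, tab, "x")
  expect_lt(max(flat$dependence) - min(flat$dependence), 1e-12)

  mono_model <- fit_model(bp_linear(), tab)
  mono <- partial_dependence(mono_model, tab, "x")
  expect_true(all(diff(mono$dependence) >= -1e-12))

  expect_error(partial_dependence(mono_model, tab, "x", grid = numeric(0)),
               "empty grid")
})

test_that("quintile-binned models give within-bin-constant dependence", {
  withr::with_seed(29, {
    x <- runif(120, 0, 200)
    y <- rbinom(120, 1, plogis(-0.02 * (x - 100)))
  })
  tab <- feature_table(data.frame(x = x, w = rnorm(120)), target = y)
  model <- fit_model(bp_logistic(), tab)
  enc <- model$pp$cols[["x"]]$enc
  pd <- partial_dependence(model, tab, "x")
  bins <- quintile_bin_apply(enc, pd$value, indicators = FALSE)
  for (b in unique(bins)) {
    vals <- pd$dependence[bins == b]
    expect_lt(max(vals) - min(vals), 1e-12)
  }
})

test_that("PDP aggregation is a pointwise mean with matching grids", {
  g <- function(dep) {
    out <- data.frame(feature = "x", value = 1:3, dependence = dep)
    class(out) <- c("pdp_grid", "data.frame")
    out
  }
  agg <- aggregate_pdp(list(g(rep(0.4, 3)), g(rep(0.6, 3))))
  expect_equal(agg$dependence, rep(0.5, 3))
  bad <- g(rep(0.4, 3)); bad$value <- 2:4
  expect_error(aggregate_pdp(list(g(rep(0.4, 3)), bad)), "grid mismatch")
})

test_that("project-level PDPs aggregate across projects and recover shape", {
  tab <- balanced_table(40, seed = 53)
  ps <- make_project_set(tab, 5, 3, master_seed = 77)
  res <- fit_projects(bp_linear(), tab, ps, compute_pfi = FALSE)
  grid <- pdp_grid(tab, "x")
  curves <- lapply(res, project_pdp, table = tab, feature = "x", grid = grid)
  agg <- aggregate_pdp(curves)
  expect_equal(agg$n_projects[1], 3)
  expect_true(all(diff(agg$dependence) >= -1e-9))
  expect_true(all(agg$dependence >= 0 & agg$dependence <= 1))
})
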