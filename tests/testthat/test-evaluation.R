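test_that("stratified splits preserve class ratios and emit both orderings", {
  y <- rep(c(TRUE, FALSE), each = 4)
  sp <- stratified_2fold_splits(y, n_repetitions = 3, seed = 1)
  expect_length(sp, 6L)
  for (s in sp) {
    expect_identical(sum(y[s$train]), 2L)
    expect_identical(sum(y[s$test]), 2L)
    expect_identical(sort(c(s$train, s$test)), seq_along(y))
  }
  expect_identical(sp[[1]]$train, sp[[2]]$test)
  expect_identical(sp[[1]]$test, sp[[2]]$train)

  # the study's class sizes: 127/2415 split into 63/64 and 1207/1208
  y2 <- rep(c(TRUE, FALSE), c(127, 2415))
  sp2 <- stratified_2fold_splits(y2, n_repetitions = 1, seed = 9)
  expect_setequal(c(sum(y2[sp2[[1]]$train]), sum(y2[sp2[[1]]$test])), c(63, 64))
  expect_setequal(c(sum(!y2[sp2[[1]]$train]), sum(!y2[sp2[[1]]$test])),
                  c(1207, 1208))

  expect_identical(stratified_2fold_splits(y2, 2, seed = 5),
                   stratified_2fold_splits(y2, 2, seed = 5))
  expect_error(stratified_2fold_splits(c(TRUE, FALSE, FALSE), 1, 1),
               "at least 2")
})

test_that("the Mann-Whitney AUC matches enumeration and pROC", {
  expect_equal(as.numeric(auc_mw(c(3, 4, 1, 2), c(1, 1, 0, 0))), 1)
  expect_equal(as.numeric(auc_mw(rep(2, 6), rep(c(1, 0), 3))), 0.5)
  expect_equal(as.numeric(auc_mw(c(0.9, 0.4, 0.5, 0.1),
                                 c(TRUE, TRUE, FALSE, FALSE))), 0.75)

  s <- c(0.2, NA, 0.8, 0.5)
  a <- auc_mw(s, c(FALSE, TRUE, TRUE, FALSE))
  expect_identical(attr(a, "n_excluded"), 1L)
  expect_equal(as.numeric(a), 1)
  expect_warning(one_class <- auc_mw(c(NA, 1, 2), c(TRUE, FALSE, FALSE)),
                 "one class absent")
  expect_true(is.na(one_class))

  skip_if_not_installed("pROC")
  set.seed(31)
  for (i in 1:5) {
    y <- sample(c(TRUE, FALSE), 60, replace = TRUE, prob = c(0.3, 0.7))
    x <- round(rnorm(60) + y, 1) # rounding forces some ties
    ref <- as.numeric(pROC::auc(pROC::roc(y, x, quiet = TRUE,
                                          direction = "<", levels = c(FALSE, TRUE))))
    expect_equal(as.numeric(auc_mw(x, y)), ref)
  }
})

test_that("AUC is invariant under monotone transforms of the score", {
  set.seed(32)
  x <- rnorm(100)
  y <- runif(100) < 0.3
  expect_equal(as.numeric(auc_mw(exp(2 * x) + 1, y)),
               as.numeric(auc_mw(x, y)))
})

test_that("the corrected resampled t interval matches hand evaluation", {
  # k=2, r=1, values {0.7, 0.8}: s2=0.005, corrected var 1.5*0.005,
  # t(0.975, 1) = 12.7062
  ci <- corrected_resampled_ci(c(0.7, 0.8), k_folds = 2, n_repetitions = 1)
  expect_equal(ci$mean, 0.75)
  half <- qt(0.975, 1) * sqrt(0.005 * (1 / 2 + 1))
  expect_equal(ci$high - ci$mean, half)
  expect_equal(ci$low, 0.75 - half)
  expect_equal(half, 1.1004, tolerance = 1e-4)

  flat <- corrected_resampled_ci(rep(0.8, 20), k_folds = 2)
  expect_equal(flat$low, 0.8)
  expect_equal(flat$high, 0.8)

  expect_error(corrected_resampled_ci(0.5, 2), "at least 2")
  expect_error(corrected_resampled_ci(c(0.5, 0.6, 0.7), k_folds = 2,
                                      n_repetitions = 2),
               "must equal")
})

test_that("the corrected interval is conservative for an iid process", {
  # with independent draws the variance inflation makes coverage of the true
  # mean exceed the nominal level by a wide margin
  set.seed(33)
  covered <- replicate(200, {
    v <- rnorm(20, mean = 0.7, sd = 0.05)
    ci <- corrected_resampled_ci(v, k_folds = 2, n_repetitions = 10)
    ci$low <= 0.7 && 0.7 <= ci$high
  })
  expect_gte(mean(covered), 0.95)
})

test_that("comparing a result with itself is never significant", {
  co <- tiny_cohort(n = 300, seed = 41)
  lab <- label_cohort(co)
  res <- run_experiment(co, lab, experiment_spec("age", n_repetitions = 5, seed = 2))
  cmp <- compare_aucs(res, res)
  expect_equal(cmp$mean_diff, 0)
  expect_false(cmp$significant)

  other <- run_experiment(co, lab, experiment_spec("age", n_repetitions = 5, seed = 3))
  expect_error(compare_aucs(res, other), "split sequence")

  # far-apart per-split distributions are significant by construction
  fake <- function(values, seed) {
    structure(list(per_split_auc = values,
                   spec = experiment_spec("age", n_repetitions = length(values) / 2,
                                          seed = seed)),
              class = "cv_result")
  }
  cmp2 <- compare_aucs(fake(rep(c(0.9, 0.91), 10), 2),
                       fake(rep(c(0.5, 0.51), 10), 2))
  expect_true(cmp2$significant)
  expect_gt(cmp2$ci_low, 0)
})

test_that("an age-only experiment reproduces the raw age AUC per split", {
  co <- tiny_cohort(n = 400, seed = 42)
  lab <- label_cohort(co)
  spec <- experiment_spec("age", variant = 1, n_repetitions = 3, seed = 7)
  res <- run_experiment(co, lab, spec)
  expect_length(res$per_split_auc, 6L)
  expect_true(res$ci_low <= res$mean_auc && res$mean_auc <= res$ci_high)

  # recompute each split from the exported primitives: fit the single
  # fitness function on the training half, score the test half
  y <- lab$labels
  splits <- stratified_2fold_splits(y, 3, seed = 7)
  manual <- vapply(splits, function(s) {
    age_tr <- co$age[s$train]
    m <- fit_feature(age_tr[y[s$train]], age_tr[!y[s$train]])
    as.numeric(auc_mw(fitness(m, co$age[s$test]), y[s$test]))
  }, numeric(1))
  expect_equal(res$per_split_auc, manual)
})

test_that("variants drop or residualize age as specified", {
  co <- tiny_cohort(n = 600, seed = 43)
  lab <- label_cohort(co)
  feats <- co$feature_meta$feature
  # variant 2 must not use age: hierarchy relevances contain no age node
  res2 <- run_experiment(co, lab, experiment_spec(feats, variant = 2,
                                                  n_repetitions = 2, seed = 5))
  expect_false("age" %in% res2$relevances$node)
  res1 <- run_experiment(co, lab, experiment_spec(feats, variant = 1,
                                                  n_repetitions = 2, seed = 5))
  expect_true("age" %in% res1$relevances$node)
  expect_identical(nrow(res1$relevances),
                   4L * length(unique(res1$relevances$node)))
  # fold-scoped correction runs and stays in range
  res4 <- run_experiment(co, lab, experiment_spec(feats, variant = 4,
                                                  n_repetitions = 2, seed = 5,
                                                  correction_scope = "fold"))
  expect_true(all(res4$per_split_auc >= 0 & res4$per_split_auc <= 1))
})

test_that("cumulative feature sets are nested prefixes of the order", {
  co <- tiny_cohort(n = 100, seed = 44)
  order <- c("age", "cognitive_tests", "cardiovascular", "mri")
  specs <- cumulative_feature_sets(co, order, n_repetitions = 2, seed = 1)
  expect_length(specs, 4L)
  expect_identical(specs[[1]]$features, "age")
  for (i in 2:4) {
    expect_true(all(specs[[i - 1]]$features %in% specs[[i]]$features))
  }
  expect_identical(specs[[4]]$name, paste(order, collapse = "+"))
  expect_error(cumulative_feature_sets(co, c("age", "nope")), "unknown category")
})

test_that("a selection threshold of zero reproduces the unselected result", {
  co <- tiny_cohort(n = 500, seed = 45)
  lab <- label_cohort(co)
  feats <- co$feature_meta$feature
  plain <- run_experiment(co, lab, experiment_spec(feats, n_repetitions = 2, seed = 3))
  t0 <- run_experiment(co, lab, experiment_spec(feats, n_repetitions = 2, seed = 3,
                                                mri_threshold = 0))
  expect_equal(t0$per_split_auc, plain$per_split_auc)

  grid <- seq(0, 0.1, by = 0.01)
  sweep <- selection_sweep(co, lab, feature_sets = list(mri = features_in_category(co, "mri")),
                           grid = grid, n_repetitions = 2, seed = 3)
  expect_identical(nrow(sweep), length(grid))
  expect_true(0.07 %in% sweep$t)
})

test_that("noise features cannot drown a strong predictor", {
  co <- tiny_cohort(n = 1000, seed = 46,
                    biomarker_specs = default_biomarker_specs(n_noise_mri = 50))
  lab <- label_cohort(co)
  age_only <- run_experiment(co, lab, experiment_spec("age", n_repetitions = 3, seed = 6))
  noisy <- run_experiment(co, lab, experiment_spec(
    c("age", sprintf("noise_mri_%02d", 1:50)), n_repetitions = 3, seed = 6))
  expect_lt(age_only$mean_auc - noisy$mean_auc, 0.15)
})

test_that("extreme-subgroup restriction behaves at its limits", {
  dsi <- c(0.1, 0.9, 0.3, 0.7, NA)
  y <- c(FALSE, TRUE, FALSE, TRUE, TRUE)
  none <- extreme_subgroup_auc(dsi, y, low = 0, high = 1)
  expect_identical(none$n_retained, 0L)
  expect_true(is.na(none$auc))

  all_in <- extreme_subgroup_auc(dsi, y, low = 0.5, high = 0.5)
  expect_identical(all_in$n_retained, 4L)
  expect_equal(all_in$auc, as.numeric(auc_mw(dsi, y)))
  expect_equal(all_in$fraction_retained, 1)

  sub <- extreme_subgroup_auc(dsi, y, low = 0.2, high = 0.8)
  expect_identical(sub$n_retained, 2L)
  expect_equal(sub$auc, 1)
})
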