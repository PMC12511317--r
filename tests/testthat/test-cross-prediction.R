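test_that("balanced accuracy and macro metrics follow per-class arithmetic", {
  expect_equal(balanced_accuracy(diag(c(5, 9, 3))), 1)
  cm <- matrix(c(50, 20, 10, 20), 2, 2)  # rows = truth
  expect_equal(balanced_accuracy(cm), (50 / 60 + 20 / 40) / 2)
  expect_equal(round(balanced_accuracy(cm), 4), 0.6667)
  expect_error(balanced_accuracy(matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)),
               "non-empty")
  set.seed(19)
  truth <- rep(c(0, 1), each = 500)
  pred <- sample(c(0, 1), 1000, TRUE)
  expect_lt(abs(balanced_accuracy(confusion_matrix(truth, pred)) - 0.5), 0.06)
  prf <- macro_prf(cm)
  expect_equal(unname(prf["recall"]), (50 / 60 + 20 / 40) / 2)
  expect_equal(unname(prf["precision"]), (50 / 70 + 20 / 30) / 2)
})

test_that("target suite applies relatedness and name-pattern exclusions", {
  tab <- generate_cohort(generator_config(n_patients = 80, missing_rate = 0,
                                          seed = 23))
  specs <- build_target_suite(tab, gated = c("hospital_admission",
                                             "covid_test_positive"))
  expect_length(specs, 40)
  by_name <- stats::setNames(specs, vapply(specs, `[[`, "", "name"))
  expect_equal(by_name$irrigation_effect$excluded_predictors, "irrigation_use")
  expect_equal(by_name$irrigation_use$excluded_predictors, "irrigation_effect")
  expect_length(by_name$age$excluded_predictors, 0)  # no group-mates
  expect_true(by_name$hospital_admission$gated)
  expect_equal(sum(!vapply(specs, `[[`, FALSE, "gated")), 38)
  # name-pattern rule
  specs2 <- build_target_suite(tab, name_patterns = "^covid")
  by2 <- stats::setNames(specs2, vapply(specs2, `[[`, "", "name"))
  expect_setequal(by2$covid_infection$excluded_predictors,
                  setdiff(tab$schema$name[grepl("^covid", tab$schema$name)],
                          "covid_infection"))
  # classification/regression assignment by kind and level cap
  expect_equal(by_name$stool_type$task, "classification")   # 7 levels
  expect_equal(by_name$age$task, "regression")
})

test_that("grid bookkeeping multiplies folds by grid cardinality", {
  g <- grid_config(learning_rate = c(0.1, 0.3), n_estimators = c(50, 100),
                   max_depth = c(2, 3), subsample = 1, gamma = 0,
                   min_child_weight = 1)
  expect_equal(grid_fit_count(g), 5 * 8)
  expect_equal(nrow(phenonet:::grid_combos(g)), 8)
})

make_fit_fixture <- function(n = 300, seed = 29) {
  withr::with_seed(seed, {
    x <- sample(1:5, n, TRUE)
    v <- cbind(y = as.numeric(x), x = as.numeric(x), z = rnorm(n),
               w = rnorm(n))
    manual_table(v)
  })
}

test_that("a perfectly determined target is recovered with full importance on its driver", {
  tab <- make_fit_fixture()
  sp <- make_split(tab, 0.2, seed = 1)
  spec <- build_target_suite(tab)[[1]]
  grid <- grid_config(learning_rate = 0.3, n_estimators = 300, max_depth = 3,
                      subsample = 1, gamma = 0, min_child_weight = 1)
  res <- fit_target(tab, sp, spec, grid, seed = 7)
  expect_gt(res$test_metrics$r2, 1 - 1e-6)
  expect_equal(names(which.max(res$importance)), "x")
  expect_true(all(res$importance >= 0))
  expect_equal(sum(res$importance), 1)
})

test_that("a target independent of all predictors has near-zero test R2", {
  withr::with_seed(41, {
    v <- cbind(y = rnorm(1000), a = rnorm(1000), b = rnorm(1000))
  })
  tab <- manual_table(v)
  sp <- make_split(tab, 0.2, seed = 2)
  res <- fit_target(tab, sp, build_target_suite(tab)[[1]], grid_config(),
                    seed = 3)
  expect_lte(res$test_metrics$r2, 0.05)
})

test_that("attributions satisfy local accuracy against the raw model output", {
  tab <- generate_cohort(generator_config(n_patients = 250, missing_rate = 0,
                                          seed = 43))
  sp <- make_split(tab, 0.2, seed = 1)
  specs <- build_target_suite(tab)
  by_name <- stats::setNames(specs, vapply(specs, `[[`, "", "name"))
  grid <- grid_config(learning_rate = 0.3, n_estimators = 60, max_depth = 3)
  for (target in c("pain_severity", "abdominal_pain")) {
    res <- fit_target(tab, sp, by_name[[target]], grid, seed = 5)
    preds <- setdiff(colnames(tab$values),
                     c(target, res$target$excluded_predictors))
    margin <- predict(res$model, tab$values[sp$test_ids, preds, drop = FALSE],
                      outputmargin = TRUE)
    recon <- res$base_value + rowSums(res$attribution)
    expect_lt(max(abs(recon - margin)), 1e-5)
    expect_true(all(res$importance[res$target$excluded_predictors] == 0))
  }
})

test_that("training artefacts are bit-identical when test labels are replaced by noise", {
  tab <- make_fit_fixture(n = 200, seed = 47)
  sp <- make_split(tab, 0.2, seed = 4)
  spec <- build_target_suite(tab)[[3]]  # target "z"
  grid <- grid_config(learning_rate = c(0.1, 0.3), n_estimators = 50)
  res1 <- fit_target(tab, sp, spec, grid, seed = 11)
  tab2 <- tab
  withr::with_seed(99, {
    tab2$values[sp$test_ids, "z"] <- rnorm(length(sp$test_ids))
  })
  res2 <- fit_target(tab2, sp, spec, grid, seed = 11)
  expect_identical(res1$best_params, res2$best_params)
  expect_identical(res1$importance, res2$importance)
  expect_identical(res1$cv_score, res2$cv_score)
})

test_that("a one-point grid equals a direct single fit", {
  tab <- make_fit_fixture(n = 150, seed = 53)
  sp <- make_split(tab, 0.2, seed = 5)
  spec <- build_target_suite(tab)[[1]]
  grid <- grid_config(learning_rate = 0.2, n_estimators = 40, max_depth = 2,
                      subsample = 1, gamma = 0, min_child_weight = 1)
  res <- fit_target(tab, sp, spec, grid, seed = 13)
  expect_equal(res$best_params$learning_rate, 0.2)
  preds <- setdiff(colnames(tab$values), spec$name)
  mu <- mean(tab$values[sp$train_ids, "y"])
  sd_tr <- stats::sd(tab$values[sp$train_ids, "y"])
  direct <- xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = 0.2, max_depth = 2,
                  subsample = 1, gamma = 0, min_child_weight = 1,
                  nthread = 1, seed = 13, verbosity = 0),
    data = xgboost::xgb.DMatrix(
      tab$values[sp$train_ids, preds, drop = FALSE],
      label = (tab$values[sp$train_ids, "y"] - mu) / sd_tr),
    nrounds = 40)
  expect_equal(predict(res$model, tab$values[sp$test_ids, preds]),
               predict(direct, tab$values[sp$test_ids, preds]))
})

test_that("suite report separates structured from noise targets and tallies occurrences", {
  cfg <- tiny_config(n = 350, k = 2, per = 3, noise = 2, noise_sd = 0.5,
                     seed = 59)
  tab <- generate_cohort(cfg)
  sp <- make_split(tab, 0.2, seed = 6)
  specs <- build_target_suite(tab)
  grid <- grid_config(learning_rate = 0.3, n_estimators = 60, max_depth = 3)
  suite <- run_suite(tab, sp, specs, grid, seed = 17, top_k = 3)
  rep <- suite$report
  fitted <- rep[rep$status == "fitted", ]
  r2 <- stats::setNames(fitted$performance, fitted$target)
  structured <- paste0("f", 1:6)
  noise <- paste0("noise", 1:2)
  expect_gt(stats::median(r2[structured]), stats::median(r2[noise]))
  # counting identity: every model here has >= top_k positive importances
  expect_equal(sum(suite$occurrence), length(suite$results) * suite$top_k)
})

test_that("gated targets are reported as excluded and not fitted", {
  tab <- generate_cohort(generator_config(n_patients = 150, missing_rate = 0,
                                          seed = 61))
  sp <- make_split(tab, 0.2, seed = 7)
  gated <- gate_imbalanced_targets(tab, sp)
  expect_true("covid_test_positive" %in% gated)
  specs <- build_target_suite(tab, gated = gated)
  keep <- c("covid_test_positive", "age", "pain_severity")
  specs <- specs[vapply(specs, function(s) s$name %in% keep, TRUE)]
  suite <- run_suite(tab, sp, specs, grid_config(learning_rate = 0.3,
                                                 n_estimators = 30),
                     seed = 19)
  rep <- suite$report
  expect_equal(rep$status[rep$target == "covid_test_positive"], "excluded")
  expect_false("covid_test_positive" %in% names(suite$results))
})
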