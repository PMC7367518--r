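test_that("metrics match their closed forms", {
  expect_equal(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  y <- c(0, 0, 2, 2)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  expect_equal(r_squared(y, c(0, 1, 1, 2)), 0.5) # SS_res=2, SS_tot=4
  expect_lt(r_squared(y, c(2, 2, 0, 0)), 0)      # worse than the mean
  expect_true(is.na(r_squared(c(1, 1, 1), c(1, 2, 3))))
  expect_equal(rmse(c(0, 2), c(0, 0)), sqrt(2))
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  set.seed(1)
  a <- rnorm(20); b <- rnorm(20); p <- sample(20)
  expect_equal(rmse(a, b), rmse(a[p], b[p]))
  expect_error(rmse(1:3, 1:2))
  # identity R2 = 1 - rmse^2 * n / SS_tot on the same predictions
  expect_equal(r_squared(a, b),
               1 - rmse(a, b)^2 * 20 / sum((a - mean(a))^2))
})

test_that("leave-all-out folds partition each patient's own timeline", {
  d <- rbind(full_series(21, "P001"), full_series(21, "P002"))
  class(d) <- c("selfassessment", "data.frame")
  ds <- build_windows(d, w = 1, h = 1)
  plan <- make_leave_all_out_splits(ds, T = 3, partition_length = 7)
  expect_equal(plan$n_folds, 2L)
  f1 <- plan$folds[[1]]
  start <- min(d$date)
  # fold 1 trains on targets in days 1-7 and tests on days 8-14, both patients
  expect_true(all(ds$target_date[f1$train] <= start + 6))
  expect_true(all(ds$target_date[f1$test] >= start + 7 &
                    ds$target_date[f1$test] <= start + 13))
  expect_setequal(unique(ds$patient_id[f1$test]), c("P001", "P002"))
  # minimal case: T=2 gives exactly one fold
  expect_equal(make_leave_all_out_splits(ds, T = 2)$n_folds, 1L)
  expect_error(make_leave_all_out_splits(ds, T = 1), "T")
  validate_split_plan(plan, ds)
  # ordering invariant per patient in every fold
  for (f in plan$folds) {
    for (pid in unique(ds$patient_id[f$test])) {
      tr <- f$train[ds$patient_id[f$train] == pid]
      te <- f$test[ds$patient_id[f$test] == pid]
      if (length(tr) && length(te))
        expect_lt(max(as.numeric(ds$target_date[tr])),
                  min(as.numeric(ds$target_date[te])))
    }
  }
})

test_that("leave-one-out folds pool the population with a two-week head start", {
  d <- rbind(full_series(100, "P001"), full_series(100, "P002"),
             full_series(10, "P003"))
  class(d) <- c("selfassessment", "data.frame")
  ds <- build_windows(d, w = 1, h = 1)
  expect_message(
    plan <- make_leave_one_out_splits(ds, train_period = 14,
                                      test_period = 154),
    "excluded")
  # P003 has no examples after day 14 -> excluded and reported
  expect_equal(plan$excluded_patients, "P003")
  expect_equal(plan$n_folds, 2L)
  f <- plan$folds[[1]]
  held <- f$held_out
  own_train <- f$train[ds$patient_id[f$train] == held]
  start <- min(d$date)
  expect_true(all(ds$target_date[own_train] <= start + 13))
  expect_true(all(ds$target_date[f$test] > start + 13))
  expect_true(all(ds$patient_id[f$test] == held))
  # other patients contribute their entire data to training
  other <- setdiff(ds$patients, c(held, "P003"))
  expect_equal(sum(ds$patient_id[f$train] %in% other),
               sum(ds$patient_id %in% other))
  validate_split_plan(plan, ds)
})

test_that("run_cv rejects corrupted split plans", {
  cfg <- population_config(n_patients = 4, n_days = 40, seed = 44)
  ds <- build_windows(generate_population(cfg), w = 1, h = 1)
  plan <- make_leave_all_out_splits(ds, T = 3, partition_length = 7)
  # overlap corruption
  bad1 <- plan
  bad1$folds[[1]]$train <- c(bad1$folds[[1]]$train, bad1$folds[[1]]$test[1])
  expect_error(run_cv("pooled_mean", ds, bad1), "leakage")
  # future-training corruption: a late test example moved into training
  bad2 <- plan
  late <- bad2$folds[[1]]$test[which.max(ds$target_date[bad2$folds[[1]]$test])]
  bad2$folds[[1]]$train <- c(setdiff(bad2$folds[[1]]$train, late), late)
  bad2$folds[[1]]$test <- setdiff(bad2$folds[[1]]$test, late)
  expect_error(run_cv("pooled_mean", ds, bad2), "leakage")
})

test_that("pooled metrics behave across models on a common plan", {
  cfg <- population_config(n_patients = 6, n_days = 60, seed = 55)
  ds <- build_windows(generate_population(cfg), w = 1, h = 1)
  plan <- make_leave_all_out_splits(ds, T = 4, partition_length = 7)
  cv <- run_cv(list(oracle = list(kind = "oracle"),
                    pooled_mean = list(kind = "pooled_mean"),
                    last_observed = list(kind = "last_observed"),
                    separate_mean = list(kind = "separate_mean")),
               ds, plan, seed = 3)
  m <- cv$metrics
  # a perfect reference scores R2=1, RMSE=0 on any plan
  expect_equal(m$r2[m$model == "oracle"], 1)
  expect_equal(m$rmse[m$model == "oracle"], 0)
  # the pooled mean explains (almost) no variance out of sample
  expect_lt(m$r2[m$model == "pooled_mean"], 0.05)
  expect_gt(m$r2[m$model == "pooled_mean"], -0.3)
  # metrics computed once on pooled predictions, not averaged over folds
  d <- cv$predictions
  d <- d[d$model == "last_observed", ]
  expect_equal(m$rmse[m$model == "last_observed"], rmse(d$y_true, d$y_pred))
  expect_equal(m$n_test[m$model == "last_observed"], nrow(d))
  # determinism of the full table under a fixed seed
  cv2 <- run_cv(list(pooled_mean = list(kind = "pooled_mean"),
                     gbt = list(kind = "pooled_gbt")), ds, plan, seed = 3)
  cv3 <- run_cv(list(pooled_mean = list(kind = "pooled_mean"),
                     gbt = list(kind = "pooled_gbt")), ds, plan, seed = 3)
  expect_identical(cv2$metrics, cv3$metrics)
})

test_that("separate baselines are excluded pairwise for unseen patients", {
  # P003's first two weeks have no two consecutive observed days, so their
  # leave-one-out fold has no own training examples; separate kinds then
  # predict NA for that patient, excluded pairwise and counted
  d <- rbind(full_series(60, "P001"), full_series(60, "P002"),
             gappy_series(c(seq(1, 13, by = 2), 15:60), "P003"))
  class(d) <- c("selfassessment", "data.frame")
  ds <- build_windows(d, w = 2, h = 1)
  plan <- make_leave_one_out_splits(ds, train_period = 14, test_period = 60)
  cv <- run_cv(list(sm = list(kind = "separate_mean"),
                    pm = list(kind = "pooled_mean")), ds, plan, seed = 1)
  m <- cv$metrics
  expect_gt(m$n_excluded[m$model == "sm"], 0)
  expect_equal(m$n_excluded[m$model == "pm"], 0)
  expect_equal(m$n_test[m$model == "sm"] + m$n_excluded[m$model == "sm"],
               m$n_test[m$model == "pm"])
})

test_that("sweeps tabulate one row per model and swept value", {
  cfg <- population_config(n_patients = 5, n_days = 56, seed = 66)
  d <- generate_population(cfg)
  models <- list(pm = list(kind = "pooled_mean"),
                 lo = list(kind = "last_observed"))
  sw <- window_size_sweep(d, w_range = 1:3, h = 1, models = models,
                          T = 4, partition_length = 7, seed = 2)
  expect_equal(nrow(sw$table), 3 * 2)
  expect_true(all(c("r2", "rmse", "N") %in% names(sw$table)))
  # mean-model RMSE varies across w only through dataset composition
  pm_rmse <- sw$table$rmse[sw$table$model == "pm"]
  expect_lt(max(pm_rmse) / min(pm_rmse) - 1, 0.25)
  sh <- horizon_sweep(d, w = 1, h_range = 1:3, models = models,
                      T = 4, partition_length = 7, seed = 2)
  expect_equal(nrow(sh$table), 3 * 2)
  expect_true(all(is.finite(sh$table$mean_abs_dev_from_train_mean)))
})

test_that("feature importance is the mean absolute weight t-statistic", {
  post <- degenerate_linear_posterior(D = 6)
  # one weight with draws {1,1,1,3,3,3}: mean 2, sd 1.0954, |t| = 1.826
  post$beta[, 1, 1] <- c(1, 1, 1, 3, 3, 3)
  # a symmetric weight with mean zero has |t| = 0
  post$beta[, 1, 2] <- c(-1, 1, -1, 1, -1, 1)
  imp <- feature_importance(post)
  expect_s3_class(imp, "importance_table")
  expect_equal(imp$mean_abs_t[imp$item == "mood"], 2 / sd(c(1, 1, 1, 3, 3, 3)),
               tolerance = 1e-12)
  expect_equal(imp$mean_abs_t[imp$item == "activity"], 0)
  # degenerate zero-SD weights are not-applicable, not infinite
  expect_true(all(is.na(imp$mean_abs_t[imp$item == "alcohol"]) |
                    !is.infinite(imp$mean_abs_t[imp$item == "alcohol"])))
  # sorted by importance, descending
  expect_equal(imp$item[1], "mood")
  expect_true(all(diff(imp$mean_abs_t[!is.na(imp$mean_abs_t)]) <= 0))
})
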