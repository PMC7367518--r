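# First record day per patient, used to anchor that patient's partitions.
# Datasets built by build_windows carry it; otherwise fall back to the
# earliest window day.
patient_first_day <- function(data) {
  if (!is.null(data$first_record)) return(data$first_record)
  first_anchor <- tapply(as.numeric(data$anchor_date), data$patient_id, min)
  as.Date(first_anchor - (data$w - 1), origin = "1970-01-01")
}

#' Leave-all-out time-series cross-validation plan
#'
#' Cuts each patient's timeline into T consecutive calendar partitions of
#' \code{partition_length} days, anchored at that patient's first window
#' day. An example belongs to the partition of its target date. Fold k
#' (k = 2..T) tests on partition k pooled across patients and trains on all
#' earlier partitions pooled across patients; the first partition is never a
#' test set because it has no prior data, giving at most T-1 folds. Folds
#' with an empty training or test side are dropped with a notice. This
#' emulates a cohort that starts monitoring simultaneously with no prior
#' data.
#'
#' @param data A \code{forecast_dataset}.
#' @param T Number of partitions (>= 2).
#' @param partition_length Partition length in days (default one week).
#' @return An object of class \code{split_plan} with one
#'   \code{list(train, test)} of example indices per fold.
#' @export
make_leave_all_out_splits <- function(data, T, partition_length = 7) {
  if (!is.numeric(T) || T < 2) stop("T must be >= 2", call. = FALSE)
  stopifnot(inherits(data, "forecast_dataset"))
  first <- patient_first_day(data)
  offset <- as.numeric(data$target_date) -
    as.numeric(first[data$patient_id])
  part <- floor(offset / partition_length) + 1L
  folds <- list()
  dropped <- 0L
  for (k in 2:T) {
    test <- which(part == k)
    train <- which(part < k)
    if (!length(test) || !length(train)) {
      dropped <- dropped + 1L
      next
    }
    folds[[length(folds) + 1L]] <- list(train = train, test = test,
                                        partition = k)
  }
  if (dropped)
    message(sprintf("leave-all-out: dropped %d empty fold(s)", dropped))
  structure(list(scheme = "leave_all_out", folds = folds, T = as.integer(T),
                 partition_length = partition_length,
                 n_folds = length(folds), excluded_patients = character(0)),
            class = "split_plan")
}

#' Leave-one-out time-series cross-validation plan
#'
#' One fold per held-out patient: that patient's examples whose targets fall
#' in their first \code{train_period} days join all examples of every other
#' patient as training; their examples with targets in the following
#' \code{test_period} days form the test set. Patients without any
#' test-period example are excluded and reported. This emulates a patient
#' who starts monitoring when data from a population of similar individuals
#' is already available.
#'
#' @param data A \code{forecast_dataset}.
#' @param train_period Days of the held-out patient's own data available for
#'   training (default 14, i.e. two weeks).
#' @param test_period Days evaluated after the training period (default 154,
#'   i.e. 22 weeks).
#' @return A \code{split_plan}; excluded patients are listed in
#'   \code{$excluded_patients}.
#' @export
make_leave_one_out_splits <- function(data, train_period = 14,
                                      test_period = 154) {
  if (!is.numeric(train_period) || train_period < 1)
    stop("train_period must be >= 1", call. = FALSE)
  stopifnot(inherits(data, "forecast_dataset"))
  first <- patient_first_day(data)
  folds <- list()
  excluded <- character(0)
  for (pid in data$patients) {
    own <- which(data$patient_id == pid)
    cutoff <- first[[pid]] + train_period - 1
    own_train <- own[data$target_date[own] <= cutoff]
    test <- own[data$target_date[own] > cutoff &
                  data$target_date[own] <= cutoff + test_period]
    if (!length(test)) {
      excluded <- c(excluded, pid)
      next
    }
    train <- c(setdiff(seq_len(data$N), own), own_train)
    folds[[length(folds) + 1L]] <- list(train = train, test = test,
                                        held_out = pid, cutoff = cutoff)
  }
  if (length(excluded))
    message(sprintf("leave-one-out: excluded %d patient(s) with no test examples",
                    length(excluded)))
  structure(list(scheme = "leave_one_out", folds = folds,
                 train_period = train_period, test_period = test_period,
                 n_folds = length(folds), excluded_patients = excluded),
            class = "split_plan")
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("%s split plan: %d fold(s)\n", x$scheme, x$n_folds))
  if (length(x$excluded_patients))
    cat(sprintf("  excluded patients: %s\n",
                paste(x$excluded_patients, collapse = ", ")))
  invisible(x)
}

#' Assert that a split plan cannot leak future information
#'
#' Checks, for every fold, that train and test sets are disjoint and that
#' the temporal ordering of the scheme holds: under leave-all-out, every
#' patient's training targets predate all their test targets in that fold;
#' under leave-one-out, the held-out patient contributes no training example
#' beyond their training-period cutoff. Violations raise an error.
#'
#' @param plan A \code{split_plan}.
#' @param data The \code{forecast_dataset} the plan indexes into.
#' @return \code{TRUE} invisibly if the plan is sound.
#' @export
validate_split_plan <- function(plan, data) {
  stopifnot(inherits(plan, "split_plan"), inherits(data, "forecast_dataset"))
  for (f in plan$folds) {
    if (length(intersect(f$train, f$test)))
      stop("leakage: overlapping train and test examples", call. = FALSE)
    if (any(f$train > data$N) || any(f$test > data$N))
      stop("split plan indexes beyond the dataset", call. = FALSE)
    if (plan$scheme == "leave_all_out") {
      for (pid in unique(data$patient_id[f$test])) {
        tr <- f$train[data$patient_id[f$train] == pid]
        if (!length(tr)) next
        if (max(data$target_date[tr]) >= min(data$target_date[f$test[
          data$patient_id[f$test] == pid]]))
          stop(sprintf("leakage: training targets of %s overlap their test period",
                       pid), call. = FALSE)
      }
    } else if (plan$scheme == "leave_one_out") {
      own_tr <- f$train[data$patient_id[f$train] == f$held_out]
      if (length(own_tr) && any(data$target_date[own_tr] > f$cutoff))
        stop(sprintf("leakage: held-out patient %s has training data beyond the cutoff",
                     f$held_out), call. = FALSE)
      if (any(data$patient_id[f$test] != f$held_out))
        stop("leave-one-out test fold contains other patients", call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Predicted coefficient of determination
#'
#' R2 = 1 - sum((y - yhat)^2) / sum((y - mean(y))^2), with the reference
#' mean taken over the pooled test targets. Values below zero mean the
#' predictions are worse than the pooled test-mean predictor. Zero variance
#' in \code{y_true} makes the quantity undefined; NA is returned.
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return A value <= 1, or NA when undefined.
#' @export
r_squared <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) return(NA_real_)
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Root mean squared error
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return sqrt(mean((y_true - y_pred)^2)).
#' @export
rmse <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) > 0)
  sqrt(mean((y_true - y_pred)^2))
}

# Fit one model spec on a training subset and predict a test subset.
fit_and_predict <- function(spec, train, test, seed) {
  kind <- spec$kind
  if (kind == "oracle") {
    # identity reference returning the true targets; audit tool only
    return(list(pred = test$y, fit = NULL, train_mean = mean(train$y)))
  }
  if (kind %in% c("hier_linear", "hier_ordinal")) {
    mcmc <- spec$mcmc
    mcmc$seed <- (mcmc$seed + seed) %% .Machine$integer.max
    fit <- if (kind == "hier_linear")
      fit_hier_linear(train, mcmc = mcmc)
    else fit_hier_ordinal(train, mcmc = mcmc)
    list(pred = predict(fit, test, seed = seed)$mean, fit = fit,
         train_mean = mean(train$y))
  } else {
    fit <- fit_baseline(kind, train, seed = seed,
                        config = spec$config %||% list(
                          lambda = 1, nrounds = 100, max_depth = 3,
                          eta = 0.1))
    list(pred = predict(fit, test, unseen = "na"), fit = fit,
         train_mean = mean(train$y))
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run time-series cross-validation for a set of models
#'
#' Fits every model on each fold's training examples, predicts the fold's
#' test examples, pools all test predictions per model across folds, and
#' computes predicted R2 and RMSE once on the pooled predictions. The plan
#' is re-validated against the data before anything is fitted (leakage
#' guard). Separate-kind baselines yield NA predictions for patients unseen
#' in a fold's training data; those pairs are excluded from the metrics and
#' counted.
#'
#' @param models Named list of model specs; each spec is a list with
#'   \code{kind} (one of \code{baseline_kinds()}, \code{"hier_linear"},
#'   \code{"hier_ordinal"}) and optionally \code{mcmc} (an
#'   \code{\link{mcmc_config}} for the hierarchical kinds) or \code{config}
#'   (baseline hyperparameters). A bare character vector of kinds is also
#'   accepted.
#' @param data A \code{forecast_dataset}.
#' @param plan A \code{split_plan} built from the same dataset.
#' @param seed Integer seed; per-fold fitting seeds are derived from it.
#' @return An object of class \code{cv_result}: \code{$metrics} (one row
#'   per model: scheme, w, h, r2, rmse, n_test, n_folds, n_excluded) and
#'   \code{$predictions} (pooled per-example predictions for audit).
#' @export
run_cv <- function(models, data, plan, seed = 1L) {
  validate_split_plan(plan, data)
  if (is.character(models))
    models <- stats::setNames(lapply(models, function(k) list(kind = k)),
                              models)
  for (nm in names(models)) {
    if (is.null(models[[nm]]$mcmc) &&
        models[[nm]]$kind %in% c("hier_linear", "hier_ordinal"))
      models[[nm]]$mcmc <- mcmc_config()
  }
  preds <- list()
  for (fi in seq_along(plan$folds)) {
    f <- plan$folds[[fi]]
    train <- subset_dataset(data, f$train)
    test <- subset_dataset(data, f$test)
    for (nm in names(models)) {
      res <- fit_and_predict(models[[nm]], train, test,
                             seed = seed * 1000L + fi)
      preds[[length(preds) + 1L]] <- data.frame(
        model = nm, fold = fi, patient_id = test$patient_id,
        target_date = test$target_date, y_true = test$y,
        y_pred = res$pred, train_mean = res$train_mean,
        stringsAsFactors = FALSE)
    }
  }
  preds <- do.call(rbind, preds)
  metrics <- do.call(rbind, lapply(names(models), function(nm) {
    d <- preds[preds$model == nm, ]
    ok <- !is.na(d$y_pred)
    data.frame(model = nm, scheme = plan$scheme, w = data$w, h = data$h,
               r2 = if (any(ok)) r_squared(d$y_true[ok], d$y_pred[ok]) else NA_real_,
               rmse = if (any(ok)) rmse(d$y_true[ok], d$y_pred[ok]) else NA_real_,
               mean_abs_dev_from_train_mean =
                 if (any(ok)) mean(abs(d$y_pred[ok] - d$train_mean[ok])) else NA_real_,
               n_test = sum(ok), n_folds = plan$n_folds,
               n_excluded = sum(!ok), stringsAsFactors = FALSE)
  }))
  structure(list(metrics = metrics, predictions = preds,
                 scheme = plan$scheme, seed = seed),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("Time-series cross-validation (%s)\n", x$scheme))
  print(x$metrics[c("model", "r2", "rmse", "n_test", "n_folds",
                    "n_excluded")], digits = 3, row.names = FALSE)
  invisible(x)
}

#' Window-size sweep
#'
#' Rebuilds the windowed dataset for each window size w (dataset sizes
#' differ across w because longer complete histories are rarer), runs the
#' cross-validation scheme, and collects the metrics. Mean-model errors vary
#' across w only because of the differing datasets.
#'
#' @param data A raw \code{selfassessment} data frame.
#' @param w_range Window sizes to evaluate (default 1..7).
#' @param h Forecast horizon (default 1 day).
#' @param models Model specs as in \code{\link{run_cv}}.
#' @param scheme \code{"leave_all_out"} (with \code{T},
#'   \code{partition_length}) or \code{"leave_one_out"} (with
#'   \code{train_period}, \code{test_period}).
#' @param T,partition_length,train_period,test_period Scheme parameters.
#' @param seed Seed forwarded to \code{\link{run_cv}}.
#' @return An object of class \code{sweep_result}; \code{$table} has one row
#'   per model and swept value, including the per-sweep dataset size N.
#' @export
window_size_sweep <- function(data, w_range = 1:7, h = 1, models,
                              scheme = c("leave_all_out", "leave_one_out"),
                              T = 24, partition_length = 7,
                              train_period = 14, test_period = 154,
                              seed = 1L) {
  scheme <- match.arg(scheme)
  rows <- list()
  for (w in w_range) {
    ds <- build_windows(data, w = w, h = h)
    plan <- if (scheme == "leave_all_out")
      make_leave_all_out_splits(ds, T = T, partition_length = partition_length)
    else make_leave_one_out_splits(ds, train_period = train_period,
                                   test_period = test_period)
    cv <- run_cv(models, ds, plan, seed = seed)
    m <- cv$metrics
    m$N <- ds$N
    rows[[length(rows) + 1L]] <- m
  }
  structure(list(table = do.call(rbind, rows), sweep = "w",
                 values = w_range, scheme = scheme),
            class = "sweep_result")
}

#' Horizon sweep
#'
#' As \code{\link{window_size_sweep}} but holding w fixed and varying the
#' forecast horizon h. Alongside R2 and RMSE, the pooled mean absolute
#' deviation of each model's predictions from the fold training-target mean
#' is reported, which exposes how forecasts regress toward the mean of the
#' data as the horizon grows and the predictable signal shrinks.
#'
#' @inheritParams window_size_sweep
#' @param w Window size (default 4 days).
#' @param h_range Horizons to evaluate (default 1..7).
#' @export
horizon_sweep <- function(data, w = 4, h_range = 1:7, models,
                          scheme = c("leave_all_out", "leave_one_out"),
                          T = 24, partition_length = 7,
                          train_period = 14, test_period = 154,
                          seed = 1L) {
  scheme <- match.arg(scheme)
  rows <- list()
  for (h in h_range) {
    ds <- build_windows(data, w = w, h = h)
    plan <- if (scheme == "leave_all_out")
      make_leave_all_out_splits(ds, T = T, partition_length = partition_length)
    else make_leave_one_out_splits(ds, train_period = train_period,
                                   test_period = test_period)
    cv <- run_cv(models, ds, plan, seed = seed)
    m <- cv$metrics
    m$N <- ds$N
    rows[[length(rows) + 1L]] <- m
  }
  structure(list(table = do.call(rbind, rows), sweep = "h",
                 values = h_range, scheme = scheme),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("%s sweep over %s = %s (%s)\n", x$sweep, x$sweep,
              paste(range(x$values), collapse = ".."), x$scheme))
  print(x$table[c("model", x$sweep, "r2", "rmse", "N")], digits = 3,
        row.names = FALSE)
  invisible(x)
}

#' RMSE curves for a sweep
#'
#' @param x A \code{sweep_result}.
#' @param metric Column to plot (default \code{"rmse"}).
#' @param ... Passed to \code{matplot}.
#' @export
plot.sweep_result <- function(x, metric = "rmse", ...) {
  tab <- x$table
  models <- unique(tab$model)
  m <- sapply(models, function(nm) tab[tab$model == nm, metric])
  graphics::matplot(x$values, m, type = "b", pch = 16, lty = 1,
                    xlab = x$sweep, ylab = toupper(metric), ...)
  graphics::legend("topleft", legend = models, col = seq_along(models),
                   lty = 1, pch = 16, cex = 0.8)
  invisible(x)
}

#' Feature importance from individual-level regression weights
#'
#' For each patient-level weight the t-statistic t = posterior mean /
#' posterior SD is computed; the table reports the mean and SD over patients
#' of |t| for every (item, lag) pair, sorted by overall mean |t|
#' descending. Large |t| marks predictors whose individual weights are
#' consistently distinguishable from zero. A degenerate weight (zero
#' posterior SD) yields NA for that patient.
#'
#' @param posterior A fitted \code{hier_linear} model.
#' @return A data.frame of class \code{importance_table} with columns
#'   \code{item}, \code{lag}, \code{mean_abs_t}, \code{sd_abs_t}.
#' @export
feature_importance <- function(posterior) {
  stopifnot(inherits(posterior, "hier_linear"))
  J <- length(posterior$patients)
  P <- length(posterior$feature_names)
  tmat <- matrix(NA_real_, J, P)
  for (j in seq_len(J)) {
    b <- posterior$beta[, j, , drop = TRUE]
    if (is.null(dim(b))) b <- matrix(b, posterior$n_draws, P)
    mu <- colMeans(b)
    sdv <- apply(b, 2, stats::sd)
    tmat[j, ] <- ifelse(sdv > 0, mu / sdv, NA_real_)
  }
  parts <- strsplit(posterior$feature_names, "@", fixed = TRUE)
  out <- data.frame(
    item = vapply(parts, `[`, character(1), 1),
    lag = as.integer(vapply(parts, `[`, character(1), 2)),
    mean_abs_t = colMeans(abs(tmat), na.rm = TRUE),
    sd_abs_t = apply(abs(tmat), 2, stats::sd, na.rm = TRUE),
    row.names = NULL)
  out <- out[order(-out$mean_abs_t), ]
  rownames(out) <- NULL
  class(out) <- c("importance_table", "data.frame")
  out
}
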