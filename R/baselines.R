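baseline_kinds <- function() {
  c("last_observed", "pooled_mean", "separate_mean",
    "pooled_ridge", "separate_ridge", "pooled_gbt", "separate_gbt")
}

# Closed-form ridge with unpenalized intercept:
# minimise ||y - b0 - X b||^2 + lambda ||b||^2.
ridge_fit <- function(X, y, lambda) {
  Xc <- scale(X, center = TRUE, scale = FALSE)
  yc <- y - mean(y)
  A <- crossprod(Xc) + diag(lambda, ncol(X))
  b <- solve(A, crossprod(Xc, yc))
  list(b = as.vector(b), b0 = mean(y) - sum(attr(Xc, "scaled:center") * b),
       lambda = lambda)
}

ridge_predict <- function(fit, X) as.vector(X %*% fit$b) + fit$b0

gbt_fit <- function(X, y, config, seed) {
  xgboost::xgboost(X, y, objective = "reg:squarederror",
                   nrounds = config$nrounds, max_depth = config$max_depth,
                   learning_rate = config$eta, nthreads = 1,
                   seed = seed, verbosity = 0)
}

#' Fit a naive or machine-learning baseline forecaster
#'
#' The comparison suite around the hierarchical models:
#' \itemize{
#'   \item \code{last_observed}: repeats the newest observed mood in the
#'     window (the lag-0 mood feature mapped back to the -3..3 scale),
#'     regardless of the horizon.
#'   \item \code{pooled_mean} / \code{separate_mean}: the mean of the
#'     training targets, globally or per patient.
#'   \item \code{pooled_ridge} / \code{separate_ridge}: ridge regression of
#'     the target on the flattened window features (fixed penalty
#'     lambda = 1 on the normalized features, intercept unpenalized),
#'     pooled or one model per patient.
#'   \item \code{pooled_gbt} / \code{separate_gbt}: gradient-boosted trees
#'     (100 rounds, depth 3, learning rate 0.1), pooled or per patient.
#' }
#' Separate kinds hold one sub-model per training patient and cannot predict
#' for patients absent from training.
#'
#' @param kind One of \code{baseline_kinds()}.
#' @param data Training \code{forecast_dataset}.
#' @param seed Seed for the stochastic learners.
#' @param config Hyperparameters recorded in the fitted object; defaults:
#'   \code{lambda = 1}, \code{nrounds = 100}, \code{max_depth = 3},
#'   \code{eta = 0.1}.
#' @return An object of class \code{baseline_model}.
#' @export
fit_baseline <- function(kind, data, seed = 1L,
                         config = list(lambda = 1, nrounds = 100,
                                       max_depth = 3, eta = 0.1)) {
  kind <- match.arg(kind, baseline_kinds())
  stopifnot(inherits(data, "forecast_dataset"), data$N >= 1)
  fitted <- switch(kind,
    last_observed = list(),
    pooled_mean = list(mean = mean(data$y)),
    separate_mean = list(
      means = tapply(data$y, data$patient_id, mean),
      pooled = mean(data$y)),
    pooled_ridge = list(fit = ridge_fit(data$X, data$y, config$lambda)),
    separate_ridge = list(fits = lapply(
      split(seq_len(data$N), data$patient_id),
      function(i) ridge_fit(data$X[i, , drop = FALSE], data$y[i],
                            config$lambda))),
    pooled_gbt = list(fit = gbt_fit(data$X, data$y, config, seed)),
    separate_gbt = list(fits = lapply(
      split(seq_len(data$N), data$patient_id),
      function(i) gbt_fit(data$X[i, , drop = FALSE], data$y[i], config,
                          seed)))
  )
  structure(list(kind = kind, fitted = fitted, config = config,
                 feature_names = data$feature_names,
                 patients = data$patients, w = data$w, h = data$h),
            class = "baseline_model")
}

#' Predict from a baseline forecaster
#'
#' @param object A \code{baseline_model}.
#' @param newdata A \code{forecast_dataset} (or feature matrix with
#'   \code{patient_id} supplied for the separate kinds).
#' @param patient_id Optional patient ids per row.
#' @param unseen For separate kinds, what to do with patients absent from
#'   training: \code{"error"} (cold start unsupported) or \code{"na"}
#'   (return NA; callers may exclude pairwise).
#' @param ... Unused.
#' @return Numeric vector of point predictions on the -3..3 mood scale.
#' @export
predict.baseline_model <- function(object, newdata, patient_id = NULL,
                                   unseen = c("error", "na"), ...) {
  unseen <- match.arg(unseen)
  if (inherits(newdata, "forecast_dataset")) {
    X <- newdata$X
    if (is.null(patient_id)) patient_id <- newdata$patient_id
  } else {
    X <- as.matrix(newdata)
  }
  if (ncol(X) != length(object$feature_names))
    stop("feature length mismatch", call. = FALSE)
  n <- nrow(X)
  separate <- grepl("^separate_", object$kind)
  if (separate) {
    if (is.null(patient_id))
      stop("separate baselines need patient_id", call. = FALSE)
    new_pat <- setdiff(unique(patient_id), object$patients)
    if (length(new_pat) && unseen == "error")
      stop(sprintf("cold-start unsupported for %s: unseen patient(s) %s",
                   object$kind, paste(new_pat, collapse = ", ")),
           call. = FALSE)
  }
  switch(object$kind,
    last_observed = {
      # lag-0 mood feature, mapped back from [0,1] to the -3..3 scale
      col <- match("mood@0", object$feature_names)
      X[, col] * 6 - 3
    },
    pooled_mean = rep(object$fitted$mean, n),
    separate_mean = {
      out <- unname(object$fitted$means[as.character(patient_id)])
      as.vector(out)
    },
    pooled_ridge = ridge_predict(object$fitted$fit, X),
    separate_ridge = {
      out <- rep(NA_real_, n)
      for (pid in intersect(unique(patient_id), object$patients)) {
        i <- which(patient_id == pid)
        out[i] <- ridge_predict(object$fitted$fits[[pid]],
                                X[i, , drop = FALSE])
      }
      out
    },
    pooled_gbt = as.vector(stats::predict(object$fitted$fit, X)),
    separate_gbt = {
      out <- rep(NA_real_, n)
      for (pid in intersect(unique(patient_id), object$patients)) {
        i <- which(patient_id == pid)
        out[i] <- as.vector(stats::predict(object$fitted$fits[[pid]],
                                           X[i, , drop = FALSE]))
      }
      out
    })
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf("Baseline forecaster: %s (%d training patients, w=%d, h=%d)\n",
              x$kind, length(x$patients), x$w, x$h))
  invisible(x)
}
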