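# Resolve newdata into a feature matrix + patient ids aligned with a fit.
resolve_newdata <- function(object, newdata, patient_id) {
  if (inherits(newdata, "forecast_dataset")) {
    X <- newdata$X
    if (is.null(patient_id)) patient_id <- newdata$patient_id
  } else {
    X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  }
  if (ncol(X) != length(object$feature_names))
    stop(sprintf("feature length mismatch: got %d, expected %d",
                 ncol(X), length(object$feature_names)), call. = FALSE)
  if (is.null(patient_id)) patient_id <- rep(NA_character_, nrow(X))
  if (length(patient_id) == 1) patient_id <- rep(patient_id, nrow(X))
  stopifnot(length(patient_id) == nrow(X))
  list(X = X, patient_id = as.character(patient_id))
}

# Per-draw linear predictor matrix (D x n) for rows of X belonging to one
# patient index j; j = NA draws new individual parameters from the
# population distributions (cold start), one fresh individual per row.
linear_eta_draws <- function(object, X, j) {
  D <- object$n_draws
  if (!is.na(j)) {
    b <- object$beta[, j, , drop = TRUE]
    if (is.null(dim(b))) b <- matrix(b, D, dim(object$beta)[3])
    object$alpha[, j] + b %*% t(X)
  } else {
    eta <- matrix(NA_real_, D, nrow(X))
    for (r in seq_len(nrow(X))) {
      alpha_new <- object$mu_alpha + object$tau_alpha * stats::rnorm(D)
      beta_new <- object$mu_beta + object$tau_beta *
        matrix(stats::rnorm(D * ncol(X)), D, ncol(X))
      eta[, r] <- alpha_new + beta_new %*% X[r, ]
    }
    eta
  }
}

#' Predict future mood from a fitted hierarchical linear model
#'
#' For a patient seen in training, predictions use that patient's posterior
#' draws of (alpha_j, beta_j); for an unseen (or NA) patient id, individual
#' parameters are drawn from the fitted population distributions per
#' retained draw, which is how the model handles the cold-start situation.
#' The reported mean is the posterior mean of the linear predictor; the SD
#' and central 95% interval describe the full predictive distribution
#' (including the observation noise sigma).
#'
#' @param object A fitted \code{hier_linear} model.
#' @param newdata A \code{forecast_dataset}, a feature matrix, or a single
#'   feature vector in the fitted feature order.
#' @param patient_id Patient id per row (defaults to the ids in
#'   \code{newdata} when it is a \code{forecast_dataset}; NA = new patient).
#' @param seed Seed for the predictive noise draws.
#' @param ... Unused.
#' @return A data.frame with columns \code{mean}, \code{sd}, \code{lwr},
#'   \code{upr} (central 95% predictive interval), one row per example.
#' @export
predict.hier_linear <- function(object, newdata, patient_id = NULL,
                                seed = 1L, ...) {
  nd <- resolve_newdata(object, newdata, patient_id)
  set.seed(seed)
  n <- nrow(nd$X)
  D <- object$n_draws
  out <- data.frame(mean = numeric(n), sd = numeric(n),
                    lwr = numeric(n), upr = numeric(n))
  jmap <- match(nd$patient_id, object$patients)
  for (grp in split(seq_len(n), jmap, drop = FALSE)) {
    if (!length(grp)) next
    j <- jmap[grp[1]]
    eta <- linear_eta_draws(object, nd$X[grp, , drop = FALSE], j)
    noise <- matrix(stats::rnorm(D * length(grp), 0, object$sigma),
                    D, length(grp))
    pred <- eta + noise
    out$mean[grp] <- colMeans(eta)
    out$sd[grp] <- apply(pred, 2, stats::sd)
    qs <- apply(pred, 2, stats::quantile, probs = c(0.025, 0.975))
    out$lwr[grp] <- qs[1, ]
    out$upr[grp] <- qs[2, ]
  }
  # NA patients are dropped by split(); handle them explicitly
  nas <- which(is.na(jmap))
  if (length(nas)) {
    eta <- linear_eta_draws(object, nd$X[nas, , drop = FALSE], NA)
    noise <- matrix(stats::rnorm(D * length(nas), 0, object$sigma),
                    D, length(nas))
    pred <- eta + noise
    out$mean[nas] <- colMeans(eta)
    out$sd[nas] <- apply(pred, 2, stats::sd)
    qs <- apply(pred, 2, stats::quantile, probs = c(0.025, 0.975))
    out$lwr[nas] <- qs[1, ]
    out$upr[nas] <- qs[2, ]
  }
  out
}

# Per-draw latent score and replicated ordinal levels for one patient.
ordinal_level_draws <- function(object, X, j) {
  D <- object$n_draws
  K <- length(object$levels)
  n <- nrow(X)
  if (!is.na(j)) {
    b <- object$beta[, j, , drop = TRUE]
    if (is.null(dim(b))) b <- matrix(b, D, dim(object$beta)[3])
    z <- b %*% t(X)
    cmat <- object$cutpoints[, j, , drop = TRUE]
    if (is.null(dim(cmat))) cmat <- matrix(cmat, D, K - 1)
  } else {
    beta_new <- object$mu_beta + object$tau_beta *
      matrix(stats::rnorm(D * ncol(X)), D, ncol(X))
    z <- beta_new %*% t(X)
    # new-patient cutpoints: population location plus scale noise, sorted to
    # respect the ordering constraint
    cmat <- object$mu_c + object$tau_c *
      matrix(stats::rnorm(D * (K - 1)), D, K - 1)
    cmat <- t(apply(cmat, 1, sort))
  }
  probs <- array(NA_real_, c(D, n, K))
  for (d in seq_len(D)) {
    cdf <- cbind(1, stats::plogis(outer(z[d, ], cmat[d, ], `-`)), 0)
    probs[d, , ] <- cdf[, -ncol(cdf), drop = FALSE] - cdf[, -1, drop = FALSE]
  }
  # the ordinal forecaster never leaves the range of the training targets:
  # predictive mass is restricted to the observed level range and
  # renormalized (levels between the observed extremes keep their mass)
  if (!is.null(object$y_range)) {
    keep <- object$levels >= object$y_range[1] &
      object$levels <= object$y_range[2]
    if (!all(keep)) {
      probs[, , !keep] <- 0
      tot <- apply(probs, c(1, 2), sum)
      tot[tot == 0] <- 1
      probs <- probs / array(tot, c(D, n, K))
    }
  }
  probs
}

#' Predict future mood from a fitted hierarchical ordinal model
#'
#' Produces the posterior predictive distribution over the nine mood levels,
#' restricted to the level range observed in training (the defining
#' guarantee of the ordinal forecaster: neither predictions nor their
#' uncertainty bands can leave the range of the training data). The point
#' forecast is the probability-weighted mean of the level values under the
#' averaged predictive pmf; the 95% interval endpoints are quantiles of
#' replicated level draws and therefore always actual scale levels. Unseen
#' patients receive population-drawn weights and cutpoints.
#'
#' @inheritParams predict.hier_linear
#' @param object A fitted \code{hier_ordinal} model.
#' @return A data.frame with columns \code{mean}, \code{sd}, \code{lwr},
#'   \code{upr}; the averaged category-probability matrix (n x 9) is
#'   attached as attribute \code{"class_probs"}.
#' @export
predict.hier_ordinal <- function(object, newdata, patient_id = NULL,
                                 seed = 1L, ...) {
  nd <- resolve_newdata(object, newdata, patient_id)
  set.seed(seed)
  n <- nrow(nd$X)
  D <- object$n_draws
  K <- length(object$levels)
  jmap <- match(nd$patient_id, object$patients)
  out <- data.frame(mean = numeric(n), sd = numeric(n),
                    lwr = numeric(n), upr = numeric(n))
  class_probs <- matrix(NA_real_, n, K,
                        dimnames = list(NULL, object$levels))
  groups <- c(split(seq_len(n), jmap, drop = FALSE),
              if (anyNA(jmap)) list(na = which(is.na(jmap))))
  for (grp in groups) {
    if (!length(grp)) next
    j <- jmap[grp[1]]
    probs <- ordinal_level_draws(object, nd$X[grp, , drop = FALSE], j)
    for (r in seq_along(grp)) {
      pm <- probs[, r, , drop = TRUE]
      if (is.null(dim(pm))) pm <- matrix(pm, D, K)
      avg <- colMeans(pm)
      class_probs[grp[r], ] <- avg
      out$mean[grp[r]] <- sum(avg * object$levels)
      # replicated level draws: one category per retained draw
      u <- stats::runif(D)
      cum <- t(apply(pm, 1, cumsum))
      ks <- rowSums(u > cum) + 1L
      lev <- object$levels[pmin(ks, K)]
      out$sd[grp[r]] <- stats::sd(lev)
      qq <- stats::quantile(lev, c(0.025, 0.975), type = 1)
      out$lwr[grp[r]] <- qq[1]
      out$upr[grp[r]] <- qq[2]
    }
  }
  attr(out, "class_probs") <- class_probs
  out
}

#' Posterior predictive replication and tail check
#'
#' Draws one replicated target per (example, retained draw) from the fitted
#' model and compares the tails of the replicated mood distribution with the
#' observed one: the fractions of values below -0.75 (depressive) and above
#' 0.75 (manic), with the replicated tail mass expressed as a percentage of
#' the observed tail mass. A model that underestimates extremes replicates
#' well below 100%. When an observed tail is empty the ratio is undefined
#' and reported as NA, never a division error.
#'
#' @param object A fitted \code{hier_linear} or \code{hier_ordinal} model.
#' @param data A \code{forecast_dataset} with the same feature layout
#'   (default: the training data).
#' @param ndraws Number of retained draws to use (capped at the posterior
#'   size; replication cost is N x ndraws).
#' @param seed Seed for replication noise.
#' @return A list with \code{yrep} (ndraws x N matrix of replicated
#'   targets) and \code{tail_report}, a data.frame with one row per tail
#'   (observed fraction, replicated fraction, replicated as % of observed).
#' @export
posterior_predictive_replicate <- function(object, data = object$data,
                                           ndraws = 200, seed = 1L) {
  stopifnot(inherits(object, "hiermood"))
  if (!identical(data$feature_names, object$feature_names))
    stop("dataset feature layout does not match the fitted model",
         call. = FALSE)
  set.seed(seed)
  D <- object$n_draws
  use <- if (ndraws >= D) seq_len(D) else
    round(seq(1, D, length.out = ndraws))
  n <- data$N
  jmap <- match(data$patient_id, object$patients)
  yrep <- matrix(NA_real_, length(use), n)
  if (inherits(object, "hier_linear")) {
    for (grp in split(seq_len(n), jmap, drop = FALSE)) {
      if (!length(grp)) next
      eta <- linear_eta_draws(object, data$X[grp, , drop = FALSE],
                              jmap[grp[1]])[use, , drop = FALSE]
      yrep[, grp] <- eta + stats::rnorm(length(eta), 0, object$sigma[use])
    }
  } else {
    K <- length(object$levels)
    for (grp in split(seq_len(n), jmap, drop = FALSE)) {
      if (!length(grp)) next
      probs <- ordinal_level_draws(object, data$X[grp, , drop = FALSE],
                                   jmap[grp[1]])[use, , , drop = FALSE]
      for (r in seq_along(grp)) {
        pm <- matrix(probs[, r, ], length(use), K)
        u <- stats::runif(length(use))
        ks <- rowSums(u > t(apply(pm, 1, cumsum))) + 1L
        yrep[, grp[r]] <- object$levels[pmin(ks, K)]
      }
    }
  }
  obs_low <- mean(data$y < -0.75)
  obs_high <- mean(data$y > 0.75)
  rep_low <- mean(yrep < -0.75)
  rep_high <- mean(yrep > 0.75)
  tail_report <- data.frame(
    tail = c("below_-0.75", "above_0.75"),
    observed_fraction = c(obs_low, obs_high),
    replicated_fraction = c(rep_low, rep_high),
    replicated_pct_of_observed = c(
      if (obs_low > 0) 100 * rep_low / obs_low else NA_real_,
      if (obs_high > 0) 100 * rep_high / obs_high else NA_real_)
  )
  list(yrep = yrep, tail_report = tail_report)
}

#' @export
print.hiermood <- function(x, ...) {
  kind <- if (inherits(x, "hier_linear")) "linear" else "ordinal"
  cat(sprintf("Hierarchical Bayesian %s mood forecaster\n", kind))
  cat(sprintf("  %d patients, %s training examples, w=%d, h=%d\n",
              length(x$patients),
              if (is.null(x$data)) "(not serialized)" else x$data$N,
              x$w, x$h))
  cat(sprintf("  %d retained draws (%d chains x %d iterations, %.0f%% warm-up)\n",
              x$n_draws, x$mcmc$chains, x$mcmc$iterations,
              100 * x$mcmc$warmup_fraction))
  cat(sprintf("  converged (split-Rhat <= 1.05 on population parameters): %s\n",
              x$converged))
  invisible(x)
}

#' @export
summary.hiermood <- function(object, ...) {
  pop <- if (inherits(object, "hier_linear")) {
    rbind(
      data.frame(parameter = "mu_alpha", mean = mean(object$mu_alpha),
                 sd = stats::sd(object$mu_alpha)),
      data.frame(parameter = paste0("mu_beta[", object$feature_names, "]"),
                 mean = colMeans(object$mu_beta),
                 sd = apply(object$mu_beta, 2, stats::sd)),
      data.frame(parameter = "sigma", mean = mean(object$sigma),
                 sd = stats::sd(object$sigma)))
  } else {
    rbind(
      data.frame(parameter = paste0("mu_beta[", object$feature_names, "]"),
                 mean = colMeans(object$mu_beta),
                 sd = apply(object$mu_beta, 2, stats::sd)),
      data.frame(parameter = paste0("mu_c[", seq_len(ncol(object$mu_c)), "]"),
                 mean = colMeans(object$mu_c),
                 sd = apply(object$mu_c, 2, stats::sd)))
  }
  rownames(pop) <- NULL
  res <- list(population = pop, diagnostics = object$diagnostics,
              converged = object$converged)
  class(res) <- "summary.hiermood"
  res
}

#' @export
print.summary.hiermood <- function(x, ...) {
  cat("Population-level posterior summary:\n")
  print(x$population, digits = 3)
  cat(sprintf("\nConverged: %s (max split-Rhat %.3f)\n", x$converged,
              suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE))))
  invisible(x)
}

#' @export
coef.hier_linear <- function(object, ...) {
  J <- length(object$patients)
  b <- t(vapply(seq_len(J), function(j) colMeans(object$beta[, j, , drop = FALSE][, 1, ]),
                numeric(length(object$feature_names))))
  dimnames(b) <- list(object$patients, object$feature_names)
  list(alpha = stats::setNames(colMeans(object$alpha), object$patients),
       beta = b,
       mu_alpha = mean(object$mu_alpha),
       mu_beta = stats::setNames(colMeans(object$mu_beta),
                                 object$feature_names))
}

#' @export
coef.hier_ordinal <- function(object, ...) {
  J <- length(object$patients)
  b <- t(vapply(seq_len(J), function(j) colMeans(object$beta[, j, , drop = FALSE][, 1, ]),
                numeric(length(object$feature_names))))
  dimnames(b) <- list(object$patients, object$feature_names)
  list(beta = b,
       mu_beta = stats::setNames(colMeans(object$mu_beta),
                                 object$feature_names),
       mu_c = colMeans(object$mu_c))
}

#' @export
residuals.hiermood <- function(object, ...) {
  object$data$y - predict(object, object$data)$mean
}

#' @export
fitted.hiermood <- function(object, ...) {
  predict(object, object$data)$mean
}

#' @export
simulate.hiermood <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  rep <- posterior_predictive_replicate(object, object$data, ndraws = nsim,
                                        seed = if (is.null(seed)) 1L else seed)
  out <- as.data.frame(t(rep$yrep))
  names(out) <- paste0("sim_", seq_len(ncol(out)))
  out
}

#' Forecast fan plot
#'
#' Plots a patient's observed mood trajectory together with model forecasts
#' and their 95% predictive intervals.
#'
#' @param x A fitted \code{hiermood} model.
#' @param patient Patient id to display (default: the patient with most
#'   training examples).
#' @param ... Passed to \code{plot}.
#' @export
plot.hiermood <- function(x, patient = NULL, ...) {
  d <- x$data
  if (is.null(patient))
    patient <- names(which.max(table(d$patient_id)))
  idx <- which(d$patient_id == patient)
  pr <- predict(x, subset_dataset(d, idx))
  ord <- order(d$target_date[idx])
  dates <- d$target_date[idx][ord]
  graphics::plot(dates, d$y[idx][ord], type = "p", pch = 16,
                 ylim = range(c(-3, 3)), xlab = "date", ylab = "mood",
                 main = sprintf("Observed vs forecast mood (%s, h=%d)",
                                patient, d$h), ...)
  graphics::polygon(c(dates, rev(dates)),
                    c(pr$lwr[ord], rev(pr$upr[ord])),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(dates, pr$mean[ord], col = "steelblue", lwd = 2)
  invisible(x)
}

#' Serialize / restore a fitted posterior
#'
#' Writes the retained draws as flat CSV files plus a JSON metadata file
#' (model kind, feature order, patient map, MCMC configuration, priors) into
#' a directory, and restores a predictable model object from such a
#' directory.
#'
#' @param object A fitted \code{hiermood} model.
#' @param dir Output directory (created if needed).
#' @return \code{write_posterior} returns \code{dir} invisibly;
#'   \code{read_posterior} returns a \code{hiermood} object (without the
#'   training data, which is not serialized).
#' @export
write_posterior <- function(object, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  kind <- if (inherits(object, "hier_linear")) "linear" else "ordinal"
  flat <- function(a) {
    d <- dim(a)
    m <- matrix(a, d[1], d[2] * d[3])
    colnames(m) <- as.vector(outer(seq_len(d[2]), seq_len(d[3]),
                                   function(j, p) sprintf("j%d_p%d", j, p)))
    m
  }
  draws <- if (kind == "linear") {
    cbind(mu_alpha = object$mu_alpha, object$mu_beta, tau_alpha = object$tau_alpha,
          object$tau_beta, sigma = object$sigma, object$alpha, flat(object$beta))
  } else {
    cbind(object$mu_beta, object$tau_beta, object$mu_c, tau_c = object$tau_c,
          flat(object$beta), flat(object$cutpoints))
  }
  utils::write.csv(draws, file.path(dir, "draws.csv"), row.names = FALSE)
  jsonlite::write_json(list(
    kind = kind, feature_names = object$feature_names,
    patients = object$patients, w = object$w, h = object$h,
    n_draws = object$n_draws,
    mcmc = unclass(object$mcmc), priors = object$priors,
    levels = if (kind == "ordinal") object$levels,
    y_range = if (kind == "ordinal") object$y_range,
    converged = object$converged),
    file.path(dir, "metadata.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(dir)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  draws <- as.matrix(utils::read.csv(file.path(dir, "draws.csv")))
  D <- nrow(draws)
  J <- length(meta$patients)
  P <- length(meta$feature_names)
  unflat <- function(cols, n3) {
    a <- array(NA_real_, c(D, J, n3))
    for (j in seq_len(J)) for (p in seq_len(n3))
      a[, j, p] <- draws[, sprintf("%s%d_p%d", cols, j, p)]
    a
  }
  # column names are mangled by read.csv; rebuild by position
  obj <- if (meta$kind == "linear") {
    off <- 0
    grab <- function(n) {
      out <- draws[, off + seq_len(n), drop = FALSE]
      off <<- off + n
      out
    }
    list(mu_alpha = as.vector(grab(1)), mu_beta = grab(P),
         tau_alpha = as.vector(grab(1)), tau_beta = grab(P),
         sigma = as.vector(grab(1)), alpha = grab(J),
         beta = array(grab(J * P), c(D, J, P)))
  } else {
    K <- length(meta$levels)
    off <- 0
    grab <- function(n) {
      out <- draws[, off + seq_len(n), drop = FALSE]
      off <<- off + n
      out
    }
    list(mu_beta = grab(P), tau_beta = grab(P), mu_c = grab(K - 1),
         tau_c = as.vector(grab(1)), beta = array(grab(J * P), c(D, J, P)),
         cutpoints = array(grab(J * (K - 1)), c(D, J, K - 1)))
  }
  obj$patients <- meta$patients
  obj$feature_names <- meta$feature_names
  obj$w <- meta$w; obj$h <- meta$h
  obj$n_draws <- D
  obj$mcmc <- do.call(mcmc_config, meta$mcmc[c("chains", "iterations",
                                               "warmup_fraction", "seed")])
  obj$priors <- meta$priors
  obj$converged <- meta$converged
  obj$diagnostics <- NULL
  if (meta$kind == "ordinal") {
    obj$levels <- meta$levels
    obj$y_range <- meta$y_range
  }
  class(obj) <- c(if (meta$kind == "linear") "hier_linear" else "hier_ordinal",
                  "hiermood")
  obj
}
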