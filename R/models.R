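#' MCMC sampler configuration
#'
#' Defaults follow common practice for these models: four chains of 5,000
#' iterations each with the first half used for adaptation and warm-up,
#' retaining 10,000 posterior draws. Tests and sweeps use fewer iterations.
#'
#' @param chains Number of chains (>= 1).
#' @param iterations Iterations per chain (even; the first
#'   \code{warmup_fraction} are discarded as adaptation + burn-in).
#' @param warmup_fraction Fraction of iterations used for warm-up, in (0, 1).
#' @param seed Integer seed; chain RNGs are derived from it, so identical
#'   config + data give identical draws.
#' @return An object of class \code{mcmc_config}.
#' @export
mcmc_config <- function(chains = 4, iterations = 5000,
                        warmup_fraction = 0.5, seed = 1L) {
  stopifnot(chains >= 1, iterations >= 2, iterations %% 2 == 0,
            warmup_fraction > 0, warmup_fraction < 1)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 warmup_fraction = warmup_fraction,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

# Prior scales (normalized-feature scale). Population parameters tied to the
# mood predictors get wider ("less restrictive") priors than the remaining
# items, which are regularized more strongly. `wide` is applied to the w
# mood-lag weights, `narrow` to everything else; the ordinal model works on
# the logistic latent scale and uses proportionally wider values.
prior_scales <- function(feature_names, wide, narrow) {
  is_mood <- grepl("^mood@", feature_names)
  ifelse(is_mood, wide, narrow)
}

jags_linear_model <- function(fix_sigma, fix_tau) {
  paste0("
model {
  for (i in 1:N) {
    mu[i] <- alpha[pid[i]] + inprod(beta[pid[i], ], X[i, ])
    y[i] ~ dnorm(mu[i], prec_y)
  }
  for (j in 1:J) {
    alpha_raw[j] ~ dnorm(0, 1)
    alpha[j] <- mu_alpha + tau_alpha * alpha_raw[j]
    for (p in 1:P) {
      beta_raw[j, p] ~ dnorm(0, 1)
      beta[j, p] <- mu_beta[p] + tau_beta[p] * beta_raw[j, p]
    }
  }
  mu_alpha ~ dnorm(0, 1)
  for (p in 1:P) {
    mu_beta[p] ~ dnorm(0, 1 / (prior_sd_mu[p] * prior_sd_mu[p]))
  }
",
if (fix_tau) "" else "
  tau_alpha ~ dnorm(0, 1) T(0,)
  for (p in 1:P) {
    tau_beta[p] ~ dnorm(0, 1 / (prior_sd_tau[p] * prior_sd_tau[p])) T(0,)
  }
",
if (fix_sigma) "" else "
  sigma ~ dnorm(0, 1) T(0,)
",
"
  prec_y <- 1 / (sigma * sigma)
}
")
}

jags_ordinal_model <- function() {
  "
model {
  for (i in 1:N) {
    z[i] <- inprod(beta[pid[i], ], X[i, ])
    Q[i, 1] <- ilogit(z[i] - c[pid[i], 1])
    prob[i, 1] <- 1 - Q[i, 1]
    for (k in 2:(K - 1)) {
      Q[i, k] <- ilogit(z[i] - c[pid[i], k])
      prob[i, k] <- Q[i, k - 1] - Q[i, k]
    }
    prob[i, K] <- Q[i, K - 1]
    y[i] ~ dcat(prob[i, 1:K])
  }
  for (j in 1:J) {
    for (p in 1:P) {
      beta_raw[j, p] ~ dnorm(0, 1)
      beta[j, p] <- mu_beta[p] + tau_beta[p] * beta_raw[j, p]
    }
    c[j, 1] ~ dnorm(mu_c[1], prec_c)
    for (k in 2:(K - 1)) {
      c[j, k] ~ dnorm(mu_c[k], prec_c) T(c[j, k - 1], )
    }
  }
  mu_c[1] ~ dnorm(0, 0.04)
  for (k in 2:(K - 1)) {
    mu_c[k] ~ dnorm(0, 0.04) T(mu_c[k - 1], )
  }
  tau_c ~ dnorm(0, 1) T(0,)
  prec_c <- 1 / (tau_c * tau_c)
  for (p in 1:P) {
    mu_beta[p] ~ dnorm(0, 1 / (prior_sd_mu[p] * prior_sd_mu[p]))
    tau_beta[p] ~ dnorm(0, 1 / (prior_sd_tau[p] * prior_sd_tau[p])) T(0,)
  }
}
"
}

# Extract an indexed family of columns as an unnamed D x n draw matrix.
# coda drops the index on length-1 nodes ("alpha" rather than "alpha[1]").
draw_matrix <- function(m, prefix, n) {
  cols <- sprintf("%s[%d]", prefix, seq_len(n))
  if (n == 1 && !cols %in% colnames(m) && prefix %in% colnames(m))
    cols <- prefix
  out <- m[, cols, drop = FALSE]
  dimnames(out) <- NULL
  out
}

chain_inits <- function(mcmc, extra = NULL) {
  lapply(seq_len(mcmc$chains), function(k) {
    c(list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = (mcmc$seed %% 100000L) * 10L + k),
      extra)
  })
}

run_jags <- function(model_string, dat, monitor, mcmc, inits_extra = NULL) {
  warm <- as.integer(round(mcmc$iterations * mcmc$warmup_fraction))
  n_adapt <- max(100L, warm %/% 2L)
  n_burn <- warm - n_adapt
  jm <- rjags::jags.model(textConnection(model_string), data = dat,
                          inits = chain_inits(mcmc, inits_extra),
                          n.chains = mcmc$chains, n.adapt = n_adapt,
                          quiet = TRUE)
  if (n_burn > 0) update(jm, n_burn, progress.bar = "none")
  rjags::coda.samples(jm, monitor, n.iter = mcmc$iterations - warm,
                      progress.bar = "none")
}

# Split-Rhat and effective sample size on selected parameters; returns a
# data.frame. Non-convergence is recorded and warned about, never fatal.
mcmc_diagnostics <- function(samples, pars) {
  m <- as.matrix(samples[[1]])
  keep <- intersect(pars, colnames(m))
  sub <- lapply(samples, function(s) s[, keep, drop = FALSE])
  rhat <- tryCatch({
    if (length(samples) > 1)
      coda::gelman.diag(coda::as.mcmc.list(sub), autoburnin = FALSE,
                        multivariate = FALSE)$psrf[, 1]
    else stats::setNames(rep(NA_real_, length(keep)), keep)
  }, error = function(e) stats::setNames(rep(NA_real_, length(keep)), keep))
  ess <- tryCatch(coda::effectiveSize(coda::as.mcmc.list(sub)),
                  error = function(e) stats::setNames(rep(NA_real_, length(keep)), keep))
  data.frame(parameter = keep, rhat = unname(rhat[keep]),
             ess = unname(ess[keep]), row.names = NULL)
}

#' Fit the hierarchical Bayesian linear mood forecaster
#'
#' The model is y_ji = Normal(alpha_j + beta_j' x_ji, sigma) for patient j
#' and example i, with partial pooling: alpha_j ~ Normal(mu_alpha,
#' tau_alpha) and beta_j ~ Normal(mu_beta, tau_beta) component-wise.
#' Population means have normal priors and the scale parameters (tau_alpha,
#' tau_beta, sigma) half-normal priors; the mood-lag weight priors are wider
#' than those of the other items (mood is expected to be the dominant
#' predictor), which regularizes the rest. Individual-level parameters use
#' the non-centered parameterization for efficient sampling.
#'
#' @param data A \code{forecast_dataset} (see \code{\link{build_windows}}).
#' @param mcmc An \code{\link{mcmc_config}}.
#' @param prior_sd_wide,prior_sd_narrow Prior SDs for mood-lag /
#'   other-population weight means; the same scales are used for the
#'   half-normal priors on the corresponding tau components.
#' @param sigma_fixed Optional known observation SD (then sigma gets no
#'   prior; used for closed-form cross-checks).
#' @param tau_fixed Optional known value for all population SDs
#'   (tau_alpha and every tau_beta component); \code{tau_fixed = 0} is
#'   replaced by 1e-6 to keep the model proper.
#' @return An object of class \code{c("hier_linear", "hiermood")} holding
#'   posterior draw matrices/arrays (\code{alpha}: D x J, \code{beta}:
#'   D x J x P, \code{sigma}, \code{mu_alpha}, \code{mu_beta}: D x P,
#'   \code{tau_alpha}, \code{tau_beta}), the training data, convergence
#'   diagnostics (\code{$diagnostics}, with \code{$converged} flag at
#'   split-Rhat <= 1.05 on population parameters), and the configuration.
#' @export
fit_hier_linear <- function(data, mcmc = mcmc_config(),
                            prior_sd_wide = 1, prior_sd_narrow = 0.25,
                            sigma_fixed = NULL, tau_fixed = NULL) {
  stopifnot(inherits(data, "forecast_dataset"))
  if (data$N < 1) stop("empty dataset", call. = FALSE)
  P <- ncol(data$X)
  dat <- list(N = data$N, J = data$J, P = P, pid = data$patient_index,
              X = data$X, y = data$y,
              prior_sd_mu = prior_scales(data$feature_names, prior_sd_wide,
                                         prior_sd_narrow))
  fix_tau <- !is.null(tau_fixed)
  fix_sigma <- !is.null(sigma_fixed)
  if (fix_tau) {
    tf <- max(tau_fixed, 1e-6)
    dat$tau_alpha <- tf
    dat$tau_beta <- rep(tf, P)
  } else {
    dat$prior_sd_tau <- prior_scales(data$feature_names, prior_sd_wide,
                                     prior_sd_narrow)
  }
  if (fix_sigma) dat$sigma <- sigma_fixed

  monitor <- c("alpha", "beta", "mu_alpha", "mu_beta",
               if (!fix_tau) c("tau_alpha", "tau_beta"),
               if (!fix_sigma) "sigma")
  samples <- run_jags(jags_linear_model(fix_sigma, fix_tau), dat, monitor,
                      mcmc)
  m <- as.matrix(do.call(rbind, lapply(samples, as.matrix)))
  D <- nrow(m)
  J <- data$J
  get <- function(nm) m[, nm, drop = TRUE]
  beta <- array(NA_real_, c(D, J, P))
  for (j in seq_len(J)) for (p in seq_len(P))
    beta[, j, p] <- get(sprintf("beta[%d,%d]", j, p))
  pop_pars <- c("mu_alpha", paste0("mu_beta[", seq_len(P), "]"),
                if (!fix_tau) c("tau_alpha", paste0("tau_beta[", seq_len(P), "]")),
                if (!fix_sigma) "sigma")
  diag_df <- mcmc_diagnostics(samples, pop_pars)
  converged <- all(is.na(diag_df$rhat)) || max(diag_df$rhat, na.rm = TRUE) <= 1.05
  if (!converged)
    warning(sprintf("possible non-convergence: max split-Rhat = %.3f",
                    max(diag_df$rhat, na.rm = TRUE)), call. = FALSE)
  structure(list(
    alpha = draw_matrix(m, "alpha", J),
    beta = beta,
    sigma = if (fix_sigma) rep(sigma_fixed, D) else get("sigma"),
    mu_alpha = get("mu_alpha"),
    mu_beta = draw_matrix(m, "mu_beta", P),
    tau_alpha = if (fix_tau) rep(max(tau_fixed, 1e-6), D) else get("tau_alpha"),
    tau_beta = if (fix_tau) matrix(max(tau_fixed, 1e-6), D, P)
               else draw_matrix(m, "tau_beta", P),
    patients = data$patients, feature_names = data$feature_names,
    w = data$w, h = data$h, data = data, mcmc = mcmc,
    priors = list(wide = prior_sd_wide, narrow = prior_sd_narrow,
                  sigma_fixed = sigma_fixed, tau_fixed = tau_fixed),
    diagnostics = diag_df, converged = converged, n_draws = D),
    class = c("hier_linear", "hiermood"))
}

#' Fit the hierarchical Bayesian ordered-logistic mood forecaster
#'
#' Treats the nine-level mood score as an ordinal outcome: a latent score
#' z_ji = beta_j' x_ji together with a patient-specific strictly increasing
#' sequence of K-1 interior cutpoints c_j determines the category
#' probabilities through the logistic CDF (see
#' \code{\link{ordered_logistic_pmf}}). Weights are partially pooled as in
#' the linear model; cutpoints are partially pooled around an ordered
#' population location mu_c with scale tau_c (ordering enforced by
#' truncation in the hierarchy). The model has no intercept: location is
#' absorbed by the cutpoints. Because predictions are distributions over the
#' nine levels, forecasts and their uncertainty bands can never leave the
#' observed scale.
#'
#' @inheritParams fit_hier_linear
#' @param prior_sd_wide,prior_sd_narrow Prior SDs on the logistic latent
#'   scale for mood-lag / other weight population means.
#' @return An object of class \code{c("hier_ordinal", "hiermood")} with draw
#'   arrays \code{beta} (D x J x P), \code{cutpoints} (D x J x (K-1)),
#'   \code{mu_beta}, \code{tau_beta}, \code{mu_c} (D x (K-1)), \code{tau_c},
#'   the level values, training data, and convergence diagnostics.
#' @export
fit_hier_ordinal <- function(data, mcmc = mcmc_config(),
                             prior_sd_wide = 10, prior_sd_narrow = 2.5) {
  stopifnot(inherits(data, "forecast_dataset"))
  if (data$N < 1) stop("empty dataset", call. = FALSE)
  levels <- mood_levels()
  if (!all(data$y %in% levels))
    stop("targets must lie on the nine-level mood scale", call. = FALSE)
  K <- length(levels)
  P <- ncol(data$X)
  ycat <- match(data$y, levels)
  dat <- list(N = data$N, J = data$J, P = P, K = K,
              pid = data$patient_index, X = data$X, y = ycat,
              prior_sd_mu = prior_scales(data$feature_names, prior_sd_wide,
                                         prior_sd_narrow),
              prior_sd_tau = prior_scales(data$feature_names,
                                          prior_sd_wide / 2,
                                          prior_sd_narrow / 2))
  # initialize cutpoints at the pooled empirical logit quantiles (smoothed)
  counts <- tabulate(ycat, nbins = K) + 0.5
  cum <- cumsum(counts / sum(counts))
  c_init <- stats::qlogis(pmin(pmax(cum[-K], 1e-4), 1 - 1e-4))
  c_init <- cummax(c_init + seq(0, 1e-3, length.out = K - 1))
  inits_extra <- list(mu_c = c_init,
                      c = matrix(rep(c_init, each = data$J), data$J, K - 1))
  samples <- run_jags(jags_ordinal_model(), dat,
                      c("beta", "c", "mu_beta", "tau_beta", "mu_c", "tau_c"),
                      mcmc, inits_extra)
  m <- as.matrix(do.call(rbind, lapply(samples, as.matrix)))
  D <- nrow(m); J <- data$J
  get <- function(nm) m[, nm, drop = TRUE]
  beta <- array(NA_real_, c(D, J, P))
  for (j in seq_len(J)) for (p in seq_len(P))
    beta[, j, p] <- get(sprintf("beta[%d,%d]", j, p))
  cutp <- array(NA_real_, c(D, J, K - 1))
  for (j in seq_len(J)) for (k in seq_len(K - 1))
    cutp[, j, k] <- get(sprintf("c[%d,%d]", j, k))
  pop_pars <- c(paste0("mu_beta[", seq_len(P), "]"),
                paste0("mu_c[", seq_len(K - 1), "]"), "tau_c")
  diag_df <- mcmc_diagnostics(samples, pop_pars)
  converged <- all(is.na(diag_df$rhat)) || max(diag_df$rhat, na.rm = TRUE) <= 1.05
  if (!converged)
    warning(sprintf("possible non-convergence: max split-Rhat = %.3f",
                    max(diag_df$rhat, na.rm = TRUE)), call. = FALSE)
  structure(list(
    beta = beta, cutpoints = cutp,
    y_range = range(data$y),
    mu_beta = draw_matrix(m, "mu_beta", P),
    tau_beta = draw_matrix(m, "tau_beta", P),
    mu_c = draw_matrix(m, "mu_c", K - 1),
    tau_c = get("tau_c"),
    levels = levels, patients = data$patients,
    feature_names = data$feature_names, w = data$w, h = data$h,
    data = data, mcmc = mcmc,
    priors = list(wide = prior_sd_wide, narrow = prior_sd_narrow),
    diagnostics = diag_df, converged = converged, n_draws = D),
    class = c("hier_ordinal", "hiermood"))
}

#' Ordered-logistic category probabilities
#'
#' Probability of each of K categories for latent score z and K-1 strictly
#' increasing cutpoints: P(y = k) = logisticCDF(z - c_{k-1}) -
#' logisticCDF(z - c_k), with c_0 = -Inf and c_K = +Inf, so the vector sums
#' to 1.
#'
#' @param z Latent score (scalar or vector).
#' @param cutpoints Strictly increasing numeric vector of K-1 cutpoints.
#' @return For scalar z a probability vector of length K; for vector z a
#'   matrix with one row per score.
#' @export
ordered_logistic_pmf <- function(z, cutpoints) {
  if (length(cutpoints) < 1 || any(diff(cutpoints) <= 0) ||
      any(!is.finite(cutpoints)))
    stop("cutpoints must be finite and strictly increasing", call. = FALSE)
  cdf <- cbind(1, stats::plogis(outer(z, cutpoints, `-`)), 0)
  p <- cdf[, -ncol(cdf), drop = FALSE] - cdf[, -1, drop = FALSE]
  if (length(z) == 1) as.vector(p) else p
}
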