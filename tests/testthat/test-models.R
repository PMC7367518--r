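test_that("ordered-logistic pmf matches the logistic-CDF closed form", {
  expect_equal(ordered_logistic_pmf(0, 0), c(0.5, 0.5))
  expect_equal(ordered_logistic_pmf(log(3), 0), c(0.25, 0.75),
               tolerance = 1e-12)
  expect_error(ordered_logistic_pmf(0, c(1, 1)), "increasing")
  expect_error(ordered_logistic_pmf(0, c(2, 1)), "increasing")
  set.seed(42)
  for (rep in 1:50) {
    K <- sample(2:9, 1)
    cuts <- sort(rnorm(K - 1, 0, 3))
    if (any(diff(cuts) == 0)) next
    z <- rnorm(1, 0, 3)
    p <- ordered_logistic_pmf(z, cuts)
    expect_equal(sum(p), 1, tolerance = 1e-12)
    expect_true(all(p >= 0))
    # independent closed form: successive differences of the latent CDF
    cdf <- c(1, plogis(z - cuts), 0)
    expect_equal(p, cdf[-length(cdf)] - cdf[-1], tolerance = 1e-12)
  }
})

test_that("the hierarchical linear model recovers known parameters", {
  mu_beta <- c(2, rep(0, 11))
  ds <- simulate_from_hier_linear(J = 10, n_per = 50, mu_beta = mu_beta,
                                  tau_beta = 0.01, tau_alpha = 0.01,
                                  mu_alpha = 0, sigma = 0.10, seed = 42)
  fit <- quiet_fit_linear(ds, mcmc = fast_mcmc(seed = 7, iterations = 800))
  expect_gt(mean(fit$sigma), 0.07)
  expect_lt(mean(fit$sigma), 0.13)
  expect_lt(abs(mean(fit$mu_beta[, 1]) - 2), 0.2)
  # retained draw count honours the warm-up contract
  expect_equal(fit$n_draws, 2 * 800 * 0.5)
  # scale draws respect positivity in every draw
  expect_true(all(fit$sigma > 0))
  expect_true(all(fit$tau_alpha > 0))
  expect_true(all(fit$tau_beta > 0))
})

test_that("null data give a null intercept", {
  X <- matrix(0, 30, 12)
  ds <- manual_dataset(X, rep(0, 30), rep("P001", 30))
  # exactly constant targets leave sigma unidentified at the boundary, so it
  # is held at a known small value for this symmetry check
  fit <- quiet_fit_linear(ds, mcmc = fast_mcmc(seed = 2, iterations = 400),
                          sigma_fixed = 0.1)
  a <- fit$alpha[, 1]
  expect_lt(abs(mean(a)), 2 * sd(a))
})

test_that("sampling is deterministic under a fixed seed", {
  ds <- simulate_from_hier_linear(J = 4, n_per = 10,
                                  mu_beta = c(1, rep(0, 11)), seed = 5)
  f1 <- quiet_fit_linear(ds, mcmc = fast_mcmc(seed = 31, iterations = 200))
  f2 <- quiet_fit_linear(ds, mcmc = fast_mcmc(seed = 31, iterations = 200))
  expect_identical(f1$sigma, f2$sigma)
  expect_identical(f1$mu_beta, f2$mu_beta)
  f3 <- quiet_fit_linear(ds, mcmc = fast_mcmc(seed = 32, iterations = 200))
  expect_false(identical(f1$sigma, f3$sigma))
})

test_that("degenerate posterior predicts the exact linear combination", {
  post <- degenerate_linear_posterior(alpha = 1, beta1 = 2, sigma = 0.1)
  x <- c(0.5, rep(0, 11))
  pr <- predict(post, x, patient_id = "P001", seed = 1)
  expect_equal(pr$mean, 2.0, tolerance = 1e-12) # 1 + 2 * 0.5
  # predictive spread is sigma-driven
  expect_lt(abs(pr$sd - 0.1), 0.03)
  expect_error(predict(post, c(0.5, 0)), "mismatch")
})

test_that("cold-start predictions collapse to the population mean when tau ~ 0", {
  post <- degenerate_linear_posterior(alpha = 0.7, beta1 = 1.5, tau = 1e-9)
  x <- c(0.4, rep(0, 11))
  seen <- predict(post, x, patient_id = "P001", seed = 3)
  unseen <- predict(post, x, patient_id = "P999", seed = 3)
  expect_lt(abs(unseen$mean - seen$mean), 1e-6)
  na_pat <- predict(post, x, patient_id = NA, seed = 3)
  expect_lt(abs(na_pat$mean - seen$mean), 1e-6)
})

test_that("pooling shrinks scarce patients toward the population weights", {
  # patient A: abundant data; patient B: 3 examples only
  set.seed(77)
  P <- 12
  mu <- c(1.5, rep(0, P - 1))
  XA <- matrix(runif(120 * P), 120, P)
  XB <- matrix(runif(3 * P), 3, P)
  beta_A <- mu + rnorm(P, 0, 0.05)
  beta_B <- mu + rnorm(P, 0, 0.05)
  yA <- 0.1 + XA %*% beta_A + rnorm(120, 0, 0.2)
  yB <- 0.1 + XB %*% beta_B + rnorm(3, 0, 0.2)
  ds <- manual_dataset(rbind(XA, XB), c(yA, yB),
                       c(rep("P001", 120), rep("P002", 3)))
  fit <- quiet_fit_linear(ds, mcmc = fast_mcmc(seed = 6, iterations = 600))
  b_hat <- coef(fit)$beta
  mu_hat <- coef(fit)$mu_beta
  # separate estimates: least squares (minimum-norm for the scarce patient)
  ls_fit <- function(X, y) {
    s <- svd(cbind(1, X))
    dinv <- ifelse(s$d > 1e-8, 1 / s$d, 0)
    (s$v %*% (dinv * crossprod(s$u, y)))[-1]
  }
  ls_A <- ls_fit(XA, yA)
  ls_B <- ls_fit(XB, yB)
  # abundant patient: hierarchical estimate close to separate least squares
  expect_lt(sqrt(sum((b_hat["P001", ] - ls_A)^2)),
            sqrt(sum((mu_hat - ls_A)^2)) + 0.5)
  # scarce patient: hierarchical estimate nearer the population mean than
  # the separate estimate is
  expect_lt(sqrt(sum((b_hat["P002", ] - mu_hat)^2)),
            sqrt(sum((ls_B - mu_hat)^2)))
})

test_that("ordinal fit validates targets and keeps cutpoints ordered", {
  ds <- simulate_from_hier_linear(J = 4, n_per = 15,
                                  mu_beta = c(1, rep(0, 11)), seed = 9)
  bad <- ds; bad$y <- ds$y # continuous values, not on the scale
  expect_error(fit_hier_ordinal(bad), "scale")
  ds$y <- discretize_mood(ds$y)
  fit <- quiet_fit_ordinal(ds, mcmc = fast_mcmc(seed = 4, iterations = 400))
  # ordering constraint holds in 100% of retained draws
  expect_true(all(apply(fit$cutpoints, c(1, 2), function(cc) all(diff(cc) > 0))))
  expect_true(all(t(apply(fit$mu_c, 1, diff)) > 0))
})

test_that("ordinal predictive mass concentrates on dominant observed levels", {
  set.seed(10)
  n <- 60
  X <- matrix(runif(n * 12), n, 12)
  y <- sample(c(0, 0.5), n, replace = TRUE)
  ds <- manual_dataset(X, y, rep("P001", n))
  fit <- quiet_fit_ordinal(ds, mcmc = fast_mcmc(seed = 8, iterations = 400))
  rep <- posterior_predictive_replicate(fit, ds, ndraws = 100, seed = 2)
  expect_gt(mean(rep$yrep %in% c(0, 0.5)), 0.9)
})

test_that("balanced null-feature targets give near-symmetric cutpoints", {
  set.seed(11)
  lv <- mood_levels()
  y <- rep(lv, each = 8)
  X <- matrix(0, length(y), 12)
  ds <- manual_dataset(X, y, rep("P001", length(y)))
  fit <- quiet_fit_ordinal(ds, mcmc = fast_mcmc(seed = 12, iterations = 400))
  cm <- colMeans(fit$mu_c)
  cs <- apply(fit$mu_c, 2, sd)
  K1 <- length(cm)
  for (k in seq_len(K1 %/% 2))
    expect_lt(abs(cm[k] + cm[K1 + 1 - k]), 2 * (cs[k] + cs[K1 + 1 - k]))
})

test_that("posterior predictive tail report handles perfect and empty tails", {
  post <- degenerate_linear_posterior(alpha = 0, beta1 = 0, sigma = 1e-6)
  n <- 40
  X <- matrix(0, n, 12)
  y <- rep(0, n) # all euthymic -> empty observed tails
  ds <- manual_dataset(X, y, rep("P001", n))
  rep <- posterior_predictive_replicate(post, ds, ndraws = 50, seed = 1)
  expect_true(all(is.na(rep$tail_report$replicated_pct_of_observed)))
  # when replication equals observation, both ratios are 100%
  y2 <- rep(c(-1, 1), n / 2)
  obs_frac <- c(mean(y2 < -0.75), mean(y2 > 0.75))
  expect_equal(obs_frac, c(0.5, 0.5))
  fake_rep <- list(yrep = matrix(rep(y2, each = 10), 10, n))
  ratio <- 100 * c(mean(fake_rep$yrep < -0.75), mean(fake_rep$yrep > 0.75)) /
    obs_frac
  expect_equal(ratio, c(100, 100))
})

test_that("posterior serialization round-trips predictions", {
  ds <- simulate_from_hier_linear(J = 3, n_per = 12,
                                  mu_beta = c(1, rep(0, 11)), seed = 13)
  fit <- quiet_fit_linear(ds, mcmc = fast_mcmc(seed = 14, iterations = 200))
  dir <- file.path(tempdir(), "post")
  write_posterior(fit, dir)
  back <- read_posterior(dir)
  x <- runif(12)
  expect_equal(predict(back, x, patient_id = "P002", seed = 5)$mean,
               predict(fit, x, patient_id = "P002", seed = 5)$mean,
               tolerance = 1e-10)
  dso <- ds; dso$y <- discretize_mood(ds$y)
  fito <- quiet_fit_ordinal(dso, mcmc = fast_mcmc(seed = 15, iterations = 200))
  diro <- file.path(tempdir(), "post_ord")
  write_posterior(fito, diro)
  backo <- read_posterior(diro)
  expect_equal(predict(backo, x, patient_id = "P002", seed = 5)$mean,
               predict(fito, x, patient_id = "P002", seed = 5)$mean,
               tolerance = 1e-10)
})

test_that("baseline forecasters implement their definitions", {
  set.seed(20)
  n <- 12
  X <- matrix(runif(n * 12), n, 12)
  pid <- rep(c("P001", "P002"), each = n / 2)
  y <- c(rep(c(-1, 0, 1), 2), c(1, 2, 1, 2, 1, 2))
  ds <- manual_dataset(X, y, pid)

  lo <- fit_baseline("last_observed", ds)
  x1 <- X[1, ]; x1[1] <- normalize_items(0.5, "mood")
  expect_equal(predict(lo, matrix(x1, 1)), 0.5)

  pm <- fit_baseline("pooled_mean", subset_dataset(ds, 1:6))
  expect_equal(predict(pm, ds)[1:3], rep(0, 3))

  sm <- fit_baseline("separate_mean", ds)
  ds2 <- manual_dataset(X[7:8, , drop = FALSE], y[7:8], c("P002", "P002"))
  expect_equal(unique(predict(sm, ds2)), mean(c(1, 2, 1, 2, 1, 2)))

  # cold start unsupported for separate kinds
  ds3 <- manual_dataset(X[1:2, , drop = FALSE], y[1:2], c("P999", "P999"))
  expect_error(predict(sm, ds3), "cold-start")
  expect_true(all(is.na(predict(sm, ds3, unseen = "na"))))

  # ridge with a huge penalty approaches the training mean
  pr <- fit_baseline("pooled_ridge", ds, config = list(lambda = 1e9))
  expect_equal(unique(round(predict(pr, ds), 6)), round(mean(y), 6))

  # gradient boosting is deterministic given a seed and fits the data
  g1 <- fit_baseline("pooled_gbt", ds, seed = 3)
  g2 <- fit_baseline("pooled_gbt", ds, seed = 3)
  expect_equal(predict(g1, ds), predict(g2, ds))
})
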