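# Shared fixtures: all data are built in code, no files.

# A fully observed single-patient series of n consecutive days. Alcohol
# encodes the day index (capped at 10) so window contents are auditable.
full_series <- function(n = 10, patient_id = "P001",
                        start = as.Date("2021-03-01"), mood = NULL) {
  d <- data.frame(
    patient_id = patient_id,
    date = start + 0:(n - 1),
    activity = 0, alcohol = pmin(0:(n - 1), 10), anxiety = 0,
    irritable = 0, cognitive_difficulty = 0, medicine = "taken",
    mixed_mood = 0,
    mood = if (is.null(mood)) rep(c(0, 0.5, -0.5), length.out = n) else mood,
    sleep = 7, stress = 0, stringsAsFactors = FALSE)
  class(d) <- c("selfassessment", "data.frame")
  d
}

# Series observed only on the given day offsets (day 1 = start date).
gappy_series <- function(days, patient_id = "P001",
                         start = as.Date("2021-03-01")) {
  d <- full_series(max(days), patient_id = patient_id, start = start)
  d[d$date %in% (start + days - 1), , drop = FALSE]
}

# Wrap plain matrices into a forecast_dataset (w = 1) for direct model tests.
manual_dataset <- function(X, y, patient_id, h = 1,
                           start = as.Date("2021-01-01")) {
  patients <- sort(unique(patient_id))
  feature_names <- paste0(moodcast::predictor_items(), "@0")
  stopifnot(ncol(X) == length(feature_names))
  colnames(X) <- feature_names
  anchor <- start + unlist(lapply(table(patient_id)[patients], seq_len)) - 1
  structure(list(
    X = X, y = y, patient_id = patient_id,
    patient_index = match(patient_id, patients),
    anchor_date = as.Date(anchor, origin = "1970-01-01"),
    target_date = as.Date(anchor + h, origin = "1970-01-01"),
    patients = patients, feature_names = feature_names,
    w = 1L, h = as.integer(h), J = length(patients),
    N = length(y)), class = "forecast_dataset")
}

# Short-chain sampler configuration for unit tests.
fast_mcmc <- function(seed = 1L, chains = 2, iterations = 600) {
  moodcast::mcmc_config(chains = chains, iterations = iterations,
                        warmup_fraction = 0.5, seed = seed)
}

# Fit helpers that silence the (expected) short-chain convergence warnings.
quiet_fit_linear <- function(...) suppressWarnings(fit_hier_linear(...))
quiet_fit_ordinal <- function(...) suppressWarnings(fit_hier_ordinal(...))

# A degenerate linear posterior with point-mass draws, for exact checks.
degenerate_linear_posterior <- function(alpha = 1, beta1 = 2, sigma = 0.1,
                                        D = 400, P = 12,
                                        tau = 1e-8) {
  feature_names <- paste0(moodcast::predictor_items(), "@0")
  beta_mean <- c(beta1, rep(0, P - 1))
  beta <- array(rep(beta_mean, each = D), c(D, 1, P))
  structure(list(
    alpha = matrix(alpha, D, 1),
    beta = beta,
    sigma = rep(sigma, D),
    mu_alpha = rep(alpha, D),
    mu_beta = matrix(rep(beta_mean, each = D), D, P),
    tau_alpha = rep(tau, D),
    tau_beta = matrix(tau, D, P),
    patients = "P001", feature_names = feature_names,
    w = 1L, h = 1L, data = NULL, mcmc = fast_mcmc(),
    priors = list(), diagnostics = NULL, converged = TRUE,
    n_draws = D), class = c("hier_linear", "hiermood"))
}

# Generate a dataset directly from the hierarchical linear model.
simulate_from_hier_linear <- function(J, n_per, mu_beta, tau_beta = 0.05,
                                      mu_alpha = 0.2, tau_alpha = 0.1,
                                      sigma = 0.3, seed = 1) {
  set.seed(seed)
  P <- length(mu_beta)
  N <- J * n_per
  pid <- sprintf("P%03d", rep(seq_len(J), each = n_per))
  X <- matrix(stats::runif(N * P), N, P)
  alpha_j <- stats::rnorm(J, mu_alpha, tau_alpha)
  beta_j <- sapply(seq_len(P), function(p) stats::rnorm(J, mu_beta[p], tau_beta))
  j <- rep(seq_len(J), each = n_per)
  y <- alpha_j[j] + rowSums(X * beta_j[j, , drop = FALSE]) +
    stats::rnorm(N, 0, sigma)
  manual_dataset(X, y, pid)
}
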