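#' The nine-level daily mood scale
#'
#' Self-reported mood is scored on an ordinal scale with finer resolution
#' around euthymia (neutral mood): -3, -2, -1, -0.5, 0, 0.5, 1, 2, 3.
#' Negative values indicate degrees of depression, positive values degrees of
#' mania, zero neutral mood.
#'
#' @return Numeric vector of the nine allowed mood levels, ascending.
#' @export
mood_levels <- function() {
  c(-3, -2, -1, -0.5, 0, 0.5, 1, 2, 3)
}

# Allowed raw ranges of the daily questionnaire items.
# Alcohol is recorded as "0 to 10+"; the open-ended category is capped at 10.
item_ranges <- function() {
  list(
    activity = c(-3, 3), alcohol = c(0, 10), anxiety = c(0, 2),
    irritable = c(0, 2), cognitive_difficulty = c(0, 2),
    mixed_mood = c(0, 1), mood = c(-3, 3), sleep = c(0, 24), stress = c(0, 2)
  )
}

medicine_categories <- function() c("taken", "not_taken", "taken_with_changes")

#' Configuration of the synthetic self-assessment cohort generator
#'
#' Describes a cohort of patients answering a daily questionnaire. Each
#' patient has a latent mood trajectory following a stationary AR(1) process
#' around an individual baseline; the baseline is drawn from a population
#' distribution. Observed mood is the latent mood snapped to the nine-level
#' ordinal scale, the other items are noisy monotone functions of the
#' same-day latent mood, and each day is independently observed with the
#' configured adherence probability (missing days are absent rows).
#'
#' The defaults are calibrated so that pooled generated mood reproduces the
#' distribution typical of monitored bipolar-disorder cohorts: mean near
#' -0.14, SD near 0.48, the large majority of scores in the euthymic band
#' (-0.75, 0.75), depressive tail a few times heavier than the manic tail,
#' positive day-to-day autocorrelation, and an adherence of 82.8%.
#'
#' @param n_patients Number of patients J (>= 1).
#' @param n_days Number of calendar days per patient (>= 1).
#' @param mood_pop_mean Population mean of individual latent baselines
#'   (mood units).
#' @param mood_pop_sd Between-patient SD of individual baselines.
#' @param ar_coefficient Day-to-day autoregression of latent mood, in [0, 1).
#' @param innovation_sd SD of daily latent innovations.
#' @param covariate_effects Named numeric vector: effect of same-day latent
#'   mood on each generated covariate, on that covariate's latent scale.
#'   Signs follow clinical direction (e.g. anxiety loads negatively on mood).
#' @param adherence Probability that a day is observed, in (0, 1].
#' @param medicine_probs Probabilities of medicine taken / not taken / taken
#'   with changes (summing to 1).
#' @param start_date First calendar day of every series.
#' @param seed Integer RNG seed; identical config + seed gives identical data.
#'
#' @return An object of class \code{population_config}.
#' @export
population_config <- function(n_patients = 50,
                              n_days = 200,
                              mood_pop_mean = -0.14,
                              mood_pop_sd = 0.25,
                              ar_coefficient = 0.5,
                              innovation_sd = 0.355,
                              covariate_effects = c(
                                activity = 0.9, alcohol = 0.15,
                                anxiety = -0.9, irritable = -0.7,
                                cognitive_difficulty = -0.8,
                                mixed_mood = -0.5, sleep = -0.8, stress = -0.9
                              ),
                              adherence = 0.828,
                              medicine_probs = c(taken = 0.85, not_taken = 0.10,
                                                 taken_with_changes = 0.05),
                              start_date = as.Date("2020-01-01"),
                              seed = 1L) {
  chk <- function(ok, field, msg) {
    if (!ok) stop(sprintf("invalid '%s': %s", field, msg), call. = FALSE)
  }
  chk(is.numeric(n_patients) && length(n_patients) == 1 && n_patients >= 1,
      "n_patients", "must be a single count >= 1")
  chk(is.numeric(n_days) && length(n_days) == 1 && n_days >= 1,
      "n_days", "must be a single count >= 1")
  chk(is.numeric(ar_coefficient) && ar_coefficient >= 0 && ar_coefficient < 1,
      "ar_coefficient", "must lie in [0, 1)")
  chk(is.numeric(innovation_sd) && innovation_sd >= 0,
      "innovation_sd", "must be >= 0")
  chk(is.numeric(mood_pop_sd) && mood_pop_sd >= 0,
      "mood_pop_sd", "must be >= 0")
  chk(is.numeric(adherence) && adherence > 0 && adherence <= 1,
      "adherence", "must lie in (0, 1]")
  chk(is.numeric(medicine_probs) && length(medicine_probs) == 3 &&
        all(medicine_probs >= 0) && abs(sum(medicine_probs) - 1) < 1e-8,
      "medicine_probs", "must be 3 non-negative probabilities summing to 1")
  chk(is.numeric(covariate_effects) && !is.null(names(covariate_effects)),
      "covariate_effects", "must be a named numeric vector")
  structure(
    list(n_patients = as.integer(n_patients), n_days = as.integer(n_days),
         mood_pop_mean = mood_pop_mean, mood_pop_sd = mood_pop_sd,
         ar_coefficient = ar_coefficient, innovation_sd = innovation_sd,
         covariate_effects = covariate_effects, adherence = adherence,
         medicine_probs = medicine_probs, start_date = as.Date(start_date),
         seed = as.integer(seed)),
    class = "population_config"
  )
}

#' Snap a continuous mood value to the nine-level ordinal scale
#'
#' Maps each value to the nearest allowed mood level; a value exactly halfway
#' between two adjacent levels goes to the level nearer zero. Values beyond
#' the scale are clamped to -3 or 3.
#'
#' @param latent Numeric vector of finite latent mood values.
#' @return Numeric vector of the same length with values in
#'   \code{mood_levels()}.
#' @export
discretize_mood <- function(latent) {
  if (!is.numeric(latent) || any(!is.finite(latent)))
    stop("discretize_mood: input must be finite numeric", call. = FALSE)
  lv <- mood_levels()
  vapply(latent, function(v) {
    d <- abs(lv - v)
    cand <- which(d == min(d))
    if (length(cand) > 1L) cand <- cand[which.min(abs(lv[cand]))]
    lv[cand]
  }, numeric(1))
}

# Threshold a latent score into an integer 0..k_max (monotone in score).
# Cut offsets position most mass at low grades, matching the mild symptom
# profile of a monitored cohort.
threshold_grade <- function(score, k_max, cuts) {
  pmin(pmax(findInterval(score, cuts), 0L), k_max)
}

#' Generate a synthetic cohort of daily self-assessment series
#'
#' Simulates, for each patient, an individual baseline drawn from
#' Normal(mood_pop_mean, mood_pop_sd), a latent AR(1) mood trajectory around
#' that baseline (started at stationarity), observed mood via
#' \code{\link{discretize_mood}}, questionnaire covariates as noisy monotone
#' functions of the same-day latent mood, and day-level dropout with the
#' configured adherence. The result is the long-format dataset the rest of
#' the pipeline consumes.
#'
#' @param config A \code{\link{population_config}}.
#' @return A \code{data.frame} of class \code{selfassessment}, one row per
#'   observed patient-day, ordered by patient and date, with columns
#'   \code{patient_id}, \code{date}, \code{activity}, \code{alcohol},
#'   \code{anxiety}, \code{irritable}, \code{cognitive_difficulty},
#'   \code{medicine}, \code{mixed_mood}, \code{mood}, \code{sleep},
#'   \code{stress}.
#' @export
generate_population <- function(config) {
  if (!inherits(config, "population_config"))
    stop("generate_population expects a population_config", call. = FALSE)
  set.seed(config$seed)
  J <- config$n_patients
  n <- config$n_days
  eff <- config$covariate_effects
  e <- function(nm) if (nm %in% names(eff)) eff[[nm]] else 0
  ar <- config$ar_coefficient
  stat_sd <- if (ar > 0) config$innovation_sd / sqrt(1 - ar^2) else config$innovation_sd

  out <- vector("list", J)
  for (j in seq_len(J)) {
    b <- stats::rnorm(1, config$mood_pop_mean, config$mood_pop_sd)
    m <- numeric(n)
    m[1] <- b + stats::rnorm(1, 0, stat_sd)
    if (n > 1) {
      innov <- stats::rnorm(n - 1, 0, config$innovation_sd)
      for (t in 2:n) m[t] <- b + ar * (m[t - 1] - b) + innov[t - 1]
    }
    dates <- config$start_date + 0:(n - 1)
    activity <- pmin(pmax(round(e("activity") * m + stats::rnorm(n, 0, 0.9)), -3), 3)
    alcohol <- pmin(stats::rpois(n, lambda = exp(-0.5 + e("alcohol") * m)), 10)
    grade <- function(nm) {
      threshold_grade(e(nm) * m + stats::rnorm(n, 0, 1), 2L, c(1.0, 2.2))
    }
    anxiety <- grade("anxiety")
    irritable <- grade("irritable")
    cognitive_difficulty <- grade("cognitive_difficulty")
    stress <- grade("stress")
    mixed_mood <- stats::rbinom(n, 1, stats::plogis(-2.5 + e("mixed_mood") * m))
    sleep <- round(pmin(pmax(7.2 + e("sleep") * m + stats::rnorm(n, 0, 1.1), 0), 24) * 2) / 2
    medicine <- sample(medicine_categories(), n, replace = TRUE,
                       prob = config$medicine_probs)
    keep <- stats::runif(n) < config$adherence
    out[[j]] <- data.frame(
      patient_id = sprintf("P%03d", j),
      date = dates,
      activity = as.numeric(activity),
      alcohol = as.numeric(alcohol),
      anxiety = as.numeric(anxiety),
      irritable = as.numeric(irritable),
      cognitive_difficulty = as.numeric(cognitive_difficulty),
      medicine = medicine,
      mixed_mood = as.numeric(mixed_mood),
      mood = discretize_mood(m),
      sleep = sleep,
      stress = as.numeric(stress),
      stringsAsFactors = FALSE
    )[keep, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("selfassessment", "data.frame")
  attr(res, "n_days") <- n
  res
}

#' Summary statistics of a self-assessment dataset
#'
#' Computes the pooled mood mean and SD, the fractions of mood scores in the
#' depressive (mood < -0.75) and manic (mood > 0.75) tails (strict
#' inequalities, the complement of the euthymic band), mean per-patient mood
#' autocorrelation at lags 1..7 (computed on each patient's daily grid, using
#' complete lagged pairs only), and the observed adherence (observed rows
#' over patient-days spanned between each patient's first and last record).
#'
#' @param data A \code{selfassessment} data frame (see
#'   \code{\link{generate_population}}).
#' @return A list with components \code{mood_mean}, \code{mood_sd},
#'   \code{frac_below}, \code{frac_above}, \code{autocorrelation} (named
#'   vector, lags 1..7), \code{adherence}, \code{n_patients}, \code{n_records}.
#' @export
summarize_population <- function(data) {
  if (!is.data.frame(data) || nrow(data) == 0)
    stop("summarize_population: empty data", call. = FALSE)
  mood <- data$mood
  per_patient <- split(data, data$patient_id)
  acf_k <- function(k) {
    vals <- vapply(per_patient, function(d) {
      if (nrow(d) < 3) return(NA_real_)
      days <- as.integer(d$date - min(d$date))
      grid <- rep(NA_real_, max(days) + 1L)
      grid[days + 1L] <- d$mood
      if (length(grid) <= k + 2L) return(NA_real_)
      x <- grid[seq_len(length(grid) - k)]
      y <- grid[(k + 1):length(grid)]
      ok <- !is.na(x) & !is.na(y)
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        return(NA_real_)
      stats::cor(x[ok], y[ok])
    }, numeric(1))
    mean(vals, na.rm = TRUE)
  }
  span <- vapply(per_patient, function(d)
    as.numeric(max(d$date) - min(d$date)) + 1, numeric(1))
  list(
    mood_mean = mean(mood),
    mood_sd = stats::sd(mood),
    frac_below = mean(mood < -0.75),
    frac_above = mean(mood > 0.75),
    autocorrelation = stats::setNames(vapply(1:7, acf_k, numeric(1)),
                                      paste0("lag", 1:7)),
    adherence = nrow(data) / sum(span),
    n_patients = length(per_patient),
    n_records = nrow(data)
  )
}

#' Write / read the self-assessment CSV dialect
#'
#' One row per patient-day; header columns are \code{patient_id}, ISO-8601
#' \code{date}, then the questionnaire items by name. UTF-8,
#' comma-separated, "." decimal.
#'
#' @param data A \code{selfassessment} data frame.
#' @param path Output CSV path.
#' @return \code{write_selfassessment_csv} returns \code{path} invisibly;
#'   \code{read_selfassessment_csv} returns a \code{selfassessment} data
#'   frame.
#' @export
write_selfassessment_csv <- function(data, path) {
  cols <- c("patient_id", "date", "activity", "alcohol", "anxiety",
            "irritable", "cognitive_difficulty", "medicine", "mixed_mood",
            "mood", "sleep", "stress")
  stopifnot(all(cols %in% names(data)))
  out <- data[cols]
  out$date <- format(as.Date(out$date), "%Y-%m-%d")
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_selfassessment_csv
#' @export
read_selfassessment_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  d$date <- as.Date(d$date)
  validate_selfassessment(d)
  d <- d[order(d$patient_id, d$date), , drop = FALSE]
  rownames(d) <- NULL
  class(d) <- c("selfassessment", "data.frame")
  d
}

# Range validation against the questionnaire's allowed values.
validate_selfassessment <- function(d) {
  rng <- item_ranges()
  for (nm in names(rng)) {
    v <- d[[nm]]
    if (is.null(v)) stop(sprintf("missing column '%s'", nm), call. = FALSE)
    bad <- !is.na(v) & (v < rng[[nm]][1] | v > rng[[nm]][2])
    if (any(bad))
      stop(sprintf("column '%s' outside allowed range [%g, %g]",
                   nm, rng[[nm]][1], rng[[nm]][2]), call. = FALSE)
  }
  if (!all(d$mood %in% mood_levels()))
    stop("mood contains values not on the nine-level scale", call. = FALSE)
  if (!all(d$medicine %in% medicine_categories()))
    stop(sprintf("unknown medicine category: %s",
                 paste(unique(setdiff(d$medicine, medicine_categories())),
                       collapse = ", ")), call. = FALSE)
  if (anyDuplicated(d[c("patient_id", "date")]))
    stop("duplicate (patient_id, date) rows", call. = FALSE)
  invisible(TRUE)
}
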