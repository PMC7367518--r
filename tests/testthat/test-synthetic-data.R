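test_that("mood discretization snaps to the nearest level, ties toward zero", {
  expect_identical(discretize_mood(0), 0)
  expect_identical(discretize_mood(10), 3)
  expect_identical(discretize_mood(-10), -3)
  # midpoint boundaries between adjacent levels
  expect_identical(discretize_mood(0.74), 0.5)
  expect_identical(discretize_mood(0.76), 1)
  # exact midpoints resolve toward the level nearer zero
  expect_identical(discretize_mood(0.75), 0.5)
  expect_identical(discretize_mood(-0.75), -0.5)
  expect_identical(discretize_mood(c(-2.5, 2.5)), c(-2, 2))
  expect_error(discretize_mood(NaN), "finite")
  expect_error(discretize_mood(Inf), "finite")
  # every output lies on the scale
  set.seed(1)
  expect_true(all(discretize_mood(rnorm(500, 0, 2)) %in% mood_levels()))
})

test_that("configuration validation names the offending field", {
  expect_error(population_config(n_patients = 0), "n_patients")
  expect_error(population_config(ar_coefficient = 1), "ar_coefficient")
  expect_error(population_config(adherence = 0), "adherence")
  expect_error(population_config(adherence = 1.2), "adherence")
  expect_error(population_config(medicine_probs = c(1, 1, 1)),
               "medicine_probs")
  expect_error(generate_population(list()), "population_config")
})

test_that("full adherence yields complete series; values stay in range", {
  cfg <- population_config(n_patients = 5, n_days = 30, adherence = 1,
                           seed = 11)
  d <- generate_population(cfg)
  expect_equal(unname(table(d$patient_id)), rep(30L, 5),
               ignore_attr = TRUE)
  expect_true(all(d$mood %in% mood_levels()))
  rng <- moodcast:::item_ranges()
  for (nm in names(rng))
    expect_true(all(d[[nm]] >= rng[[nm]][1] & d[[nm]] <= rng[[nm]][2]),
                label = nm)
  expect_false(anyDuplicated(d[c("patient_id", "date")]) > 0)
})

test_that("generation is byte-identical under a fixed seed", {
  cfg <- population_config(n_patients = 4, n_days = 40, seed = 99)
  f1 <- tempfile(fileext = ".csv"); f2 <- tempfile(fileext = ".csv")
  write_selfassessment_csv(generate_population(cfg), f1)
  write_selfassessment_csv(generate_population(cfg), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  # and a different seed gives different data
  cfg2 <- population_config(n_patients = 4, n_days = 40, seed = 100)
  d2 <- generate_population(cfg2)
  expect_false(identical(generate_population(cfg)$mood, d2$mood))
})

test_that("white-noise limit has no lag-1 autocorrelation", {
  cfg <- population_config(n_patients = 1, n_days = 2000,
                           ar_coefficient = 0, adherence = 1,
                           covariate_effects = c(activity = 0), seed = 5)
  d <- generate_population(cfg)
  r <- cor(d$mood[-nrow(d)], d$mood[-1])
  expect_lt(abs(r), 0.1)
})

test_that("default calibration reproduces the pooled mood moments", {
  cfg <- population_config(n_patients = 50, n_days = 200, seed = 2024)
  s <- summarize_population(generate_population(cfg))
  expect_gt(s$mood_mean, -0.14 - 0.05)
  expect_lt(s$mood_mean, -0.14 + 0.05)
  expect_gt(s$mood_sd, 0.48 - 0.05)
  expect_lt(s$mood_sd, 0.48 + 0.05)
  # depressive tail heavier than manic tail, most mass euthymic
  expect_gt(s$frac_below, s$frac_above)
  expect_gt(1 - s$frac_below - s$frac_above, 0.8)
})

test_that("positive autocorrelation decays over lags 1..7", {
  # persistence high enough that the lag-7 signal clears Monte-Carlo noise
  cfg <- population_config(n_patients = 4, n_days = 1500, adherence = 1,
                           ar_coefficient = 0.8, innovation_sd = 0.25,
                           seed = 31)
  s <- summarize_population(generate_population(cfg))
  ac <- s$autocorrelation
  expect_true(all(ac > 0))
  # non-increasing within Monte-Carlo tolerance
  expect_true(all(diff(ac) < 0.05))
})

test_that("empirical adherence matches the configured rate", {
  cfg <- population_config(n_patients = 20, n_days = 150, adherence = 0.828,
                           seed = 17)
  d <- generate_population(cfg)
  n <- 20 * 150
  # binomial 99% band around the configured adherence
  half <- 2.58 * sqrt(0.828 * (1 - 0.828) / n)
  # observed adherence uses first-to-last span, which trims unobserved edges
  expect_gt(summarize_population(d)$adherence, 0.828 - half - 0.02)
  expect_lt(summarize_population(d)$adherence, 0.828 + half + 0.02)
})

test_that("population summary counts tails with strict inequalities", {
  d <- full_series(4, mood = c(-1, 0, 0, 1))
  s <- summarize_population(d)
  expect_equal(s$frac_below, 0.25)
  expect_equal(s$frac_above, 0.25)
  d0 <- full_series(5, mood = rep(0, 5))
  s0 <- summarize_population(d0)
  expect_equal(s0$frac_below, 0)
  expect_equal(s0$frac_above, 0)
  expect_equal(s0$mood_mean, 0)
  expect_equal(s0$mood_sd, 0)
  # band edges are excluded from the tails (strict comparison)
  dedge <- full_series(4, mood = c(-0.5, -0.5, 0.5, 0.5))
  sedge <- summarize_population(dedge)
  expect_equal(sedge$frac_below, 0)
  expect_equal(sedge$frac_above, 0)
  expect_error(summarize_population(data.frame()), "empty")
})

test_that("self-assessment CSV round-trips and validates", {
  cfg <- population_config(n_patients = 3, n_days = 25, seed = 8)
  d <- generate_population(cfg)
  f <- tempfile(fileext = ".csv")
  write_selfassessment_csv(d, f)
  d2 <- read_selfassessment_csv(f)
  expect_equal(d2$mood, d$mood)
  expect_equal(d2$date, d$date)
  expect_s3_class(d2, "selfassessment")
  # corrupt a value out of range -> validation error naming the column
  bad <- d; bad$anxiety[1] <- 5
  fbad <- tempfile(fileext = ".csv")
  write_selfassessment_csv(bad, fbad)
  expect_error(read_selfassessment_csv(fbad), "anxiety")
})
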