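test_that("generator configs are validated", {
  badC <- matrix(c(1, .9, -.9, .9, 1, .9, -.9, .9, 1), 3)
  expect_error(generator_config(behaviour_residual_correlations = badC),
               "positive-definite")
  expect_error(generator_config(icc_targets = c(entry = 1.2, distance = .3,
                                                exploration = .3, rmr = .3,
                                                stress_max = .1,
                                                stress_integral = .1)),
               "\\[0, 1\\)")
  expect_error(generator_config(sessions_per_individual = 5), "1..4")
  expect_error(generator_config(temperature_sd = -1), "positive")
})

test_that("same seed reproduces the same cohort and bundle", {
  cfg <- generator_config(n_individuals = 15, rng_seed = 61)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
  b1 <- generate_dataset(generator_config(n_individuals = 4, rng_seed = 62))
  b2 <- generate_dataset(generator_config(n_individuals = 4, rng_seed = 62))
  expect_identical(b1$cohort, b2$cohort)
  expect_identical(b1$traces, b2$traces)
})

test_that("session counts respect the design bound", {
  co <- generate_cohort(generator_config(n_individuals = 75, rng_seed = 63))
  expect_lte(nrow(co), 75 * 4)
  expect_true(all(table(co$id) <= 4))
  ## session 1 always present; later sessions only after earlier ones
  expect_true(all(tapply(co$session, co$id, function(s)
    identical(sort(s), seq_along(s)))))
})

test_that("a bundle round-trips through plain-text files", {
  b <- generate_dataset(generator_config(n_individuals = 3, rng_seed = 64))
  dir <- tempfile()
  write_bundle(b, dir)
  b2 <- read_bundle(dir)
  expect_equal(nrow(b2$cohort), nrow(b$cohort))
  expect_equal(b2$cohort$rmr, b$cohort$rmr, tolerance = 1e-9)
  expect_equal(b2$cohort$test_date, b$cohort$test_date)
  expect_setequal(names(b2$traces), names(b$traces))
  k <- names(b$traces)[1]
  expect_equal(b2$traces[[k]]$FeO2, b$traces[[k]]$FeO2, tolerance = 1e-12)
  expect_equal(b2$true_parameters$rng_seed, 64)
  unlink(dir, recursive = TRUE)
})

test_that("generated ICCs match their targets (balanced ANOVA oracle)", {
  cfg <- null_generator_config(
    n_individuals = 500, sessions_per_individual = 2, survival_prob = 1,
    icc_targets = c(entry = 0.5, distance = 0.3, exploration = 0.6,
                    rmr = 0.8, stress_max = 0.2, stress_integral = 0.4),
    rng_seed = 65)
  co <- generate_cohort(cfg)
  ## with every causal path off, the raw-scale ANOVA ICC must match; rmr
  ## and distance are affine in the latent scale so the ICC carries over
  expect_lt(abs(anova_icc(co$rmr, co$id)$icc - 0.8), 0.05)
  expect_lt(abs(anova_icc(co$distance, co$id)$icc - 0.3), 0.05)
  expect_lt(abs(anova_icc(co$exploration, co$id)$icc - 0.6), 0.07)
})

test_that("null configuration produces no birth-date associations", {
  set.seed(66)
  cors <- sapply(1:60, function(i) {
    co <- generate_cohort(null_generator_config(n_individuals = 80,
                                                sessions_per_individual = 1,
                                                rng_seed = 800 + i))
    c(cor(co$birth_day_true, co$distance),
      cor(co$birth_day_true, co$exploration),
      cor(co$birth_day_true, co$rmr))
  })
  ## Monte-Carlo error around zero: SE = 1/sqrt(60 * 80) ~ 0.014
  expect_true(all(abs(rowMeans(cors)) < 0.045))
})

test_that("washout steady state recovers a constant metabolic rate", {
  cfg <- generator_config(rng_seed = 67, noise_sd_o2 = 0, noise_sd_co2 = 0,
                          analyzer_offset_o2 = 0)
  tr <- generate_trace(list(v_rest = 1.4), cfg)
  s <- summarize_session(tr, 100)
  expect_equal(s$rmr_raw, 84, tolerance = 0.01 * 84)
  ## empty chamber: excurrent equals incurrent up to noise
  tr0 <- generate_trace(list(v_rest = 0), generator_config(rng_seed = 68,
                                                           analyzer_offset_o2 = 0))
  expect_lt(max(abs(tr0$FeO2 - tr0$FiO2)), 6 * 2e-5)
})

test_that("a step in animal VO2 washes out with time constant V/flow", {
  cfg <- generator_config(rng_seed = 69, noise_sd_o2 = 0, noise_sd_co2 = 0,
                          analyzer_offset_o2 = 0)
  step_at <- 1500
  tr <- generate_trace(list(
    v_rest = 1.4, alarm_times = numeric(),
    duration_s = 2600,
    activity_bouts = data.frame(start = step_at, duration = 1100,
                                amp = 0.5)), cfg)
  v <- compute_vo2(tr)
  tau <- 1000 / 700 * 60  # 85.7 s
  v0 <- v$vo2[v$t == step_at - 1]
  vinf <- 1.4 * 1.5 * 60
  at_tau <- v$vo2[which.min(abs(v$t - (step_at + tau)))]
  expect_equal((at_tau - v0) / (vinf - v0), 1 - exp(-1), tolerance = 0.05)
  at_5tau <- v$vo2[which.min(abs(v$t - (step_at + 5 * tau)))]
  expect_equal(at_5tau, vinf, tolerance = 0.01)
})

test_that("traces reproduce the session's stress metrics after washout", {
  cfg <- generator_config(rng_seed = 70, noise_sd_o2 = 0, noise_sd_co2 = 0,
                          analyzer_offset_o2 = 0)
  basis <- paceline:::.alarm_basis(cfg)
  for (tgt in list(c(30, 12), c(60, 25), c(15, 8))) {
    sol <- paceline:::.solve_alarm_shape(tgt[1], tgt[2], basis)
    tr <- generate_trace(list(v_rest = 1.4, alarm_amp_fast = sol$amp_fast,
                              alarm_amp_slow = sol$amp_slow), cfg)
    s <- summarize_session(tr, 100)
    expect_equal(s$rmr_raw, 84, tolerance = 0.01 * 84)
    expect_lt(abs(s$stress_max - tgt[1]), 0.05 * max(tgt[1], 20))
    expect_lt(abs(s$stress_integral - tgt[2]), 0.05 * max(tgt[2], 20))
  }
})

test_that("a sustained stress response's peak survives the washout", {
  ## peak recovery through the chamber lag requires the response to hold
  ## near its peak for several washout time constants
  cfg <- generator_config(rng_seed = 71, noise_sd_o2 = 0, noise_sd_co2 = 0,
                          analyzer_offset_o2 = 0)
  tr <- generate_trace(list(v_rest = 1.4, alarm_amp_fast = 0,
                            alarm_amp_slow = 0.5, decay_slow_s = 3000,
                            alarm_times = 1620, duration_s = 2000), cfg)
  s <- summarize_session(tr, 100)
  ## within the 1-min metric window the chamber lag caps the observable
  ## peak at amp * (1 - exp(-60 / tau)); a near-sustained response reaches it
  cap <- 50 * (1 - exp(-60 / (1000 / 700 * 60)))
  expect_equal(s$stress_max, cap, tolerance = 0.15)
  ## whereas a fast-decaying response is strongly attenuated
  tr2 <- generate_trace(list(v_rest = 1.4, alarm_amp_fast = 0.5,
                             alarm_amp_slow = 0, decay_fast_s = 10,
                             alarm_times = 1620, duration_s = 2000), cfg)
  s2 <- summarize_session(tr2, 100)
  expect_lt(s2$stress_max, 15)
})

test_that("alarms inside the equilibration window are rejected", {
  cfg <- generator_config(rng_seed = 72)
  expect_error(generate_trace(list(v_rest = 1.4, alarm_times = 600), cfg),
               "discard window")
})

test_that("missing-data flags and the session filter conserve rows", {
  cfg <- generator_config(n_individuals = 120, rng_seed = 73,
                          missing_behaviour_prob = 0.1, missing_mr_prob = 0.1)
  co <- generate_cohort(cfg)
  fl <- filter_complete_sessions(co)
  expect_equal(nrow(fl$data) + sum(fl$excluded), nrow(co))
  expect_gt(fl$excluded[["missing_behaviour"]], 0)
  expect_gt(fl$excluded[["missing_mr"]], 0)
  expect_false(anyNA(fl$data$rmr))
})
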