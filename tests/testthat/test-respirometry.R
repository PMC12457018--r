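const_trace <- function(feo2 = 0.2075, feco2 = 0.0024, n = 2000, flow = 700,
                        wvp = 0, events = 1500) {
  resp_trace(t = seq_len(n) - 1, FeO2 = feo2, FeCO2 = feco2, WVP = wvp,
             flow = flow, events = events)
}

vo2_series <- function(t, vo2, events = numeric()) {
  structure(list(t = t, vo2 = vo2, events = events), class = "vo2_series")
}

test_that("pull-system VO2: no consumer, worked value, flow linearity", {
  tr0 <- const_trace(feo2 = 0.2095, feco2 = 0.0004)
  expect_equal(compute_vo2(tr0)$vo2, rep(0, 2000))
  ## FiO2 0.2095 -> FeO2 0.2075 with dCO2 = 0.0020 at 700 ml/min dry:
  ## 1.4 ml/min = 84 ml/h, the dilution terms cancel at RQ = 1
  v <- compute_vo2(const_trace())
  expect_equal(v$vo2[1], 84, tolerance = 1e-9)
  v_half <- compute_vo2(const_trace(flow = 350))
  expect_equal(v_half$vo2, v$vo2 / 2)
})

test_that("VO2 honours dry-flow correction and the RQ-assumption variant", {
  tr <- const_trace(wvp = 2)
  expect_equal(compute_vo2(tr)$vo2[1], 84 * (101.325 - 2) / 101.325,
               tolerance = 1e-9)
  ## without the CO2 channel an RQ must be supplied
  expect_error(compute_vo2(const_trace(), use_co2 = FALSE), "respiratory quotient")
  v_rq <- compute_vo2(const_trace(), use_co2 = FALSE, rq_assumption = 1)
  expect_equal(v_rq$vo2[1], 700 * 0.0020 / (1 - 0) * 60 *
                 (1 - 0) / 1, tolerance = 1e-6)
})

test_that("baseline correction removes analyser offsets", {
  n <- 1200
  ch <- rep(c("baseline", "test"), c(300, n - 300))
  tr_clean <- resp_trace(t = seq_len(n) - 1,
                         FeO2 = ifelse(ch == "baseline", 0.2095, 0.2075),
                         FeCO2 = ifelse(ch == "baseline", 0.0004, 0.0024),
                         channel = ch, events = 1100)
  ## already on target: correction is the identity
  expect_equal(correct_baseline(tr_clean)$FeO2,
               tr_clean$FeO2, tolerance = 1e-12)
  ## constant +5e-4 offset on both channels is removed exactly
  tr_off <- tr_clean
  tr_off$FeO2 <- tr_off$FeO2 + 5e-4
  ## the baseline channel shows incurrent air + offset
  tr_off$FeO2[ch == "baseline"] <- 0.2095 + 5e-4
  fixed <- correct_baseline(tr_off)
  expect_equal(compute_vo2(fixed)$vo2, compute_vo2(correct_baseline(tr_clean))$vo2,
               tolerance = 1e-6)
  expect_error(correct_baseline(const_trace()), "no baseline")
})

test_that("two baseline segments interpolate the offset linearly", {
  n <- 2000
  ch <- rep("test", n)
  ch[1:200] <- "baseline"; ch[1801:2000] <- "baseline"
  a <- 4e-4; b <- 8e-4
  fe <- rep(0.2075, n)
  fe[1:200] <- 0.2095 + a
  fe[1801:2000] <- 0.2095 + b
  tr <- resp_trace(t = seq_len(n) - 1, FeO2 = fe, FeCO2 = 0.0024,
                   channel = ch, events = 1500)
  fixed <- correct_baseline(tr)
  mid <- which.min(abs(tr$t - mean(c(mean(tr$t[1:200]), mean(tr$t[1801:2000])))))
  applied <- tr$FeO2[mid] - fixed$FeO2[mid]
  expect_equal(applied, (a + b) / 2, tolerance = 1e-3)
})

test_that("RMR is the lowest 30-s window before the first alarm", {
  t <- 0:1500
  v <- rep(84, length(t))
  expect_equal(extract_rmr(vo2_series(t, v, 1400)), 84)
  ## a single 30-s dip inside the legal span is found
  v2 <- v; v2[t >= 1000 & t < 1030] <- 60
  expect_equal(extract_rmr(vo2_series(t, v2, 1400)), 60)
  ## a dip before the 10-min discard boundary is ignored
  v3 <- v; v3[t >= 200 & t < 230] <- 40
  expect_equal(extract_rmr(vo2_series(t, v3, 1400)), 84)
  expect_error(extract_rmr(vo2_series(0:100, rep(84, 101), 90)),
               "insufficient")
})

test_that("sliding-window RMR equals the brute-force minimum on random traces", {
  set.seed(71)
  for (i in 1:200) {
    n <- sample(200:500, 1)
    t <- seq_len(n) - 1
    v <- 60 + 30 * runif(n)
    alarm <- sample(150:(n - 1), 1)
    vs <- vo2_series(t, v, alarm)
    disc <- runif(1, 0.5, 2); srch <- runif(1, 1, 3); win <- sample(10:40, 1)
    got <- tryCatch(extract_rmr(vs, discard_minutes = disc,
                                window_seconds = win, search_minutes = srch),
                    error = function(e) NA_real_)
    want <- brute_min_window(t, v, max(disc * 60, alarm - srch * 60),
                             alarm, win)
    if (is.finite(want) && is.na(got)) fail("implementation refused a legal span")
    if (is.na(got)) next
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("stress metrics match the flat, step and triangle closed forms", {
  t <- 0:200; r <- 84; a <- 100
  flat <- vo2_series(t, rep(r, length(t)))
  expect_equal(unname(stress_response(flat, a, r)), c(0, 0))
  step <- vo2_series(t, ifelse(t >= a, 1.5 * r, r))
  expect_equal(unname(stress_response(step, a, r)), c(50, 50))
  tri <- rep(r, length(t))
  sel <- t >= a & t <= a + 60
  tri[sel] <- 2 * r - (t[sel] - a) / 60 * r
  expect_equal(unname(stress_response(vo2_series(t, tri), a, r)), c(100, 50))
})

test_that("stress metrics are ratios: invariant to rescaling the series", {
  set.seed(5)
  t <- 0:200
  v <- 80 + cumsum(rnorm(length(t)))
  v <- v - min(v) + 50
  s1 <- stress_response(vo2_series(t, v), 100, 70)
  s2 <- stress_response(vo2_series(t, 3.7 * v), 100, 3.7 * 70)
  expect_equal(s1, s2, tolerance = 1e-10)
  expect_error(stress_response(vo2_series(t, v), 170, 70), "truncated")
  expect_error(stress_response(vo2_series(t, v), 100, 0), "positive")
})

test_that("session summaries average stress metrics over at most two alarms", {
  ## two alarms with different responses: the summary is their mean
  t <- 0:2400
  r <- 84
  v <- rep(r, length(t))
  v[t >= 1500 & t <= 1560] <- 1.4 * r   # +40% flat
  v[t >= 2100 & t <= 2160] <- 1.6 * r   # +60% flat
  ch <- rep(c("baseline", "test"), c(300, length(t) - 300))
  fe_o2 <- ifelse(ch == "baseline", 0.2095, 0.2095 - (v / 60) / 700)
  fe_co2 <- ifelse(ch == "baseline", 0.0004, 0.0004 + (v / 60) / 700)
  tr <- resp_trace(t = t, FeO2 = fe_o2, FeCO2 = fe_co2,
                   channel = ch, events = c(1500, 2100))
  s <- summarize_session(tr, 100)
  expect_equal(s$n_alarms_used, 2)
  expect_equal(s$stress_max, 50, tolerance = 0.5)
  ## one alarm only
  tr1 <- tr; tr1$events <- 1500
  s1 <- summarize_session(tr1, 100)
  expect_equal(s1$n_alarms_used, 1)
  expect_equal(s1$stress_max, 40, tolerance = 0.5)
  ## no alarms: stress missing, RMR still computed
  tr0 <- tr; tr0$events <- numeric()
  s0 <- summarize_session(tr0, 100)
  expect_true(is.na(s0$stress_max) && is.na(s0$stress_integral))
  expect_equal(s0$rmr_raw, 84, tolerance = 1)
  expect_equal(s0$rmr, s0$rmr_raw / 100^0.75)
})

test_that("Kleiber mass correction follows the 3/4-power law", {
  expect_equal(mass_correct(84, 100), 84 / 100^0.75)
  expect_equal(mass_correct(5, 1), 5)
  expect_equal(mass_correct(10, 80) / mass_correct(10, 160), 2^0.75)
  expect_error(mass_correct(10, 0), "positive")
})
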