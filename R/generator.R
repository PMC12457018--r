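## Synthetic-data generator: cohort/session tables with the causal
## structure linking date of birth, personality and metabolic rate, and
## pull-mode respirometry traces with first-order chamber washout.

#' Default generating path coefficients
#'
#' Standardized slopes used as generating values by [generate_cohort()]:
#' later-born individuals are more exploratory, travel further, enter the
#' arena with higher probability (latent scale), have higher RMR and a
#' lower integral (and, as a tendency, maximum) metabolic stress response;
#' RMR additionally decreases with ambient temperature and differs between
#' study years. Edges not listed (age class, food abundance, body mass,
#' and all direct behaviour-to-metabolism paths) generate with slope 0.
#'
#' @return Named numeric vector, names of the form `"from->to"`.
#' @export
default_path_coefficients <- function() {
  c("birth->exploration" = 0.365,
    "birth->distance" = 0.267,
    "birth->entry" = 0.448,
    "birth->rmr" = 0.240,
    "birth->stress_max" = -0.274,
    "birth->stress_integral" = -0.316,
    "temperature->rmr" = -0.234,
    "year->rmr" = 0.723)
}

.pc <- function(coefs, from, to) {
  v <- coefs[paste0(from, "->", to)]
  if (is.na(v)) 0 else unname(v)
}

#' Configuration of the synthetic-data generator
#'
#' Defines the study conditions the generator emulates: cohort size and
#' repeated-test design, the seasonal birth-date distribution, the
#' generating standardized path coefficients, the behavioural-syndrome
#' residual correlations, per-variable repeatability (intraclass
#' correlation) targets, and the respirometry hardware settings (flow
#' rate, chamber volume, sampling rate, alarm protocol).
#'
#' @param n_individuals Number of individuals (females).
#' @param sessions_per_individual Maximum repeated test sessions (1-4).
#' @param season_start Calendar date of the season origin (1 July).
#' @param birth_date_mean_day,birth_date_sd Mean and SD (days since season
#'   start) of the truncated-normal birth-date distribution over the
#'   breeding window.
#' @param birth_window Truncation bounds (days since season start) of the
#'   breeding window, mid-July to late November by default.
#' @param path_coefficients Named vector of generating standardized slopes
#'   (see [default_path_coefficients()]).
#' @param behaviour_residual_correlations 3x3 correlation matrix of the
#'   non-birth-date components of (entry latent, distance, exploration).
#' @param icc_targets Named vector of intraclass correlations in `[0, 1)`
#'   for `entry` (latent scale), `distance`, `exploration`, `rmr`,
#'   `stress_max`, `stress_integral`.
#' @param survival_prob Per-session Bernoulli survival probability after
#'   the first test (mortality/disappearance dropout).
#' @param missing_behaviour_prob,missing_mr_prob Probability that a session
#'   yields no behavioural / no metabolic data (recorded as `NA`).
#' @param trace_sampling_rate Trace sampling rate (Hz).
#' @param flow_rate Pull-system flow rate (ml min^-1).
#' @param chamber_volume Test-chamber volume (ml); the washout time
#'   constant is `chamber_volume / flow_rate` minutes.
#' @param baseline_minutes Initial baseline-channel recording (min).
#' @param pre_alarm_minutes Test-channel recording before the first alarm
#'   (min, >= 20: 10 discarded + 10 searched for RMR).
#' @param alarm_spacing_seconds Spacing between the two alarms (s).
#' @param FiO2,FiCO2 Incurrent gas fractions.
#' @param BP,WVP Barometric and water-vapour pressure (kPa).
#' @param noise_sd_o2,noise_sd_co2 SD of additive Gaussian sensor noise on
#'   the gas fractions.
#' @param analyzer_offset_o2 Constant analyser offset on fractional O2
#'   (removed downstream by baseline correction).
#' @param temperature_mean,temperature_sd Ambient temperature (deg C).
#' @param food_mean,food_sd Food abundance (food plants per 4 m^2).
#' @param mass_test_mean,mass_test_sd Body mass at testing (g).
#' @param entry_intercept Intercept of the latent logit for entering the
#'   arena.
#' @param rng_seed Integer seed; every draw is reproducible from it.
#' @return A `generator_config` (validated list).
#' @export
generator_config <- function(n_individuals = 75,
                             sessions_per_individual = 4,
                             season_start = "2022-07-01",
                             birth_date_mean_day = 80,
                             birth_date_sd = 30,
                             birth_window = c(14, 147),
                             path_coefficients = default_path_coefficients(),
                             behaviour_residual_correlations =
                               matrix(c(1, .4, .4, .4, 1, .4, .4, .4, 1), 3),
                             icc_targets = c(entry = 0.512, distance = 0.323,
                                             exploration = 0.378, rmr = 0.393,
                                             stress_max = 0.097,
                                             stress_integral = 0.013),
                             survival_prob = 0.55,
                             missing_behaviour_prob = 0.02,
                             missing_mr_prob = 0.02,
                             trace_sampling_rate = 1,
                             flow_rate = 700, chamber_volume = 1000,
                             baseline_minutes = 5, pre_alarm_minutes = 22,
                             alarm_spacing_seconds = 900,
                             FiO2 = 0.2095, FiCO2 = 0.0004,
                             BP = 101.325, WVP = 1.0,
                             noise_sd_o2 = 2e-5, noise_sd_co2 = 1e-5,
                             analyzer_offset_o2 = 1e-4,
                             temperature_mean = 25, temperature_sd = 3,
                             food_mean = 10, food_sd = 3,
                             mass_test_mean = 80, mass_test_sd = 8,
                             entry_intercept = 1.0,
                             rng_seed = 1L) {
  cfg <- as.list(environment())
  if (sessions_per_individual < 1 || sessions_per_individual > 4)
    stop("`sessions_per_individual` must be in 1..4")
  C <- behaviour_residual_correlations
  if (!isTRUE(all.equal(C, t(C))) ||
      inherits(tryCatch(chol(C), error = identity), "error"))
    stop("behaviour_residual_correlations must be a symmetric positive-definite correlation matrix")
  need <- c("entry", "distance", "exploration", "rmr", "stress_max",
            "stress_integral")
  if (!all(need %in% names(icc_targets)))
    stop("icc_targets must name: ", paste(need, collapse = ", "))
  if (any(icc_targets < 0 | icc_targets >= 1))
    stop("icc_targets must lie in [0, 1)")
  if (any(c(birth_date_sd, temperature_sd, food_sd, mass_test_sd,
            flow_rate, chamber_volume) <= 0))
    stop("scale parameters and hardware settings must be positive")
  if (pre_alarm_minutes < 20)
    stop("`pre_alarm_minutes` must be >= 20 (10 min discard + 10 min RMR search)")
  class(cfg) <- "generator_config"
  cfg
}

## Raw-unit mappings for the analysis-scale (standardized / transformed)
## latent variables. The stress mappings are the exact inverses of the
## variance-stabilising transforms used downstream (sqrt with offset 9.76,
## log with offset 25.07), so the forward transform is affine in the
## latent and standardized slopes survive the round trip.
.raw_maps <- list(
  distance = function(z) 1500 + 600 * z,           # cm
  exploration = function(z) pmin(100, pmax(0, 30 + 12 * z)),  # % time
  rmr = function(z) 2.6 + 0.3 * z,                 # ml O2 / h / g^0.75
  stress_max = function(z) (1.2 * z + 6)^2 - 9.76, # %
  stress_integral = function(z) exp(0.3 * z + 3.51) - 25.07)  # %

#' Generate a synthetic cohort/session table
#'
#' Draws a cohort of individuals with seasonal birth dates and builds, per
#' test session, the three personality traits, the three metabolic
#' variables and the environmental covariates from the configured causal
#' structure: standardized latent variables receive the generating path
#' coefficients on the (empirically standardized) birth date, individual
#' random intercepts sized to the repeatability targets, correlated
#' behavioural residuals, and are then mapped to raw measurement units.
#' The binary entry trait arises from a latent logit threshold whose
#' slope is chosen so the configured latent-scale standardized
#' coefficient holds. First-capture mass follows the forward Gompertz
#' growth curve, so downstream growth-curve ageing recovers the true
#' birth dates.
#'
#' @param config A [generator_config()].
#' @return Data frame, one row per individual x session, with identifiers,
#'   covariates, behaviours, metabolic variables (raw units) and the true
#'   generating birth day in `birth_day_true`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  if (!is.null(config$rng_seed)) set.seed(config$rng_seed)
  n <- config$n_individuals
  pcs <- config$path_coefficients
  icc <- config$icc_targets

  ## individuals
  bd <- numeric(0)
  while (length(bd) < n) {
    cand <- stats::rnorm(n, config$birth_date_mean_day, config$birth_date_sd)
    bd <- c(bd, cand[cand >= config$birth_window[1] &
                       cand <= config$birth_window[2]])
  }
  bd <- bd[seq_len(n)]
  year_code_i <- sample(c(-1, 1), n, replace = TRUE)
  capture_age <- stats::runif(n, 20, 37.5)
  mass_first <- gompertz_mass(capture_age, gompertz_params())
  season0 <- as.Date(config$season_start)
  season_i <- season0 + ifelse(year_code_i > 0, 365, 0)
  first_capture <- season_i + round(bd + capture_age)

  ## session skeleton with dropout after the first test
  S <- config$sessions_per_individual
  alive <- matrix(TRUE, n, S)
  if (S > 1) for (s in 2:S)
    alive[, s] <- alive[, s - 1] & (stats::runif(n) < config$survival_prob)
  keep <- which(t(alive), arr.ind = FALSE)
  id <- rep(seq_len(n), each = S)[keep]
  session <- rep(seq_len(S), n)[keep]
  m <- length(id)
  offs <- c(42, 56, 140, 154)

  d <- data.frame(
    id = factor(sprintf("F%03d", id)),
    session = session,
    prior_tests = session - 1L,
    year = ifelse(year_code_i[id] > 0, 2023L, 2022L),
    year_code = year_code_i[id],
    age_class = ifelse(session <= 2, "young", "old"),
    age_code = ifelse(session <= 2, -1, 1),
    season_start = season_i[id],
    test_date = season_i[id] + round(bd[id]) + offs[session],
    first_capture_date = first_capture[id],
    mass_first_capture = mass_first[id],
    birth_day_true = bd[id],
    temperature = stats::rnorm(m, config$temperature_mean, config$temperature_sd),
    food = stats::rnorm(m, config$food_mean, config$food_sd),
    body_mass = stats::rnorm(m, config$mass_test_mean, config$mass_test_sd))

  ## standardized (session-row) exogenous drivers
  zb <- as.numeric(scale(d$birth_day_true))
  zt <- as.numeric(scale(d$temperature))
  zf <- as.numeric(scale(d$food))
  zm <- as.numeric(scale(d$body_mass))
  zyear <- d$year_code
  zage <- d$age_code

  ## --- behaviours -------------------------------------------------------
  C <- config$behaviour_residual_correlations
  b_ent <- .pc(pcs, "birth", "entry")
  s2u_ent <- icc["entry"] / (1 - icc["entry"]) * pi^2 / 3
  lat_tot <- (s2u_ent + pi^2 / 3) / (1 - b_ent^2)
  slope_ent <- b_ent * sqrt(lat_tot)

  b_dis <- .pc(pcs, "birth", "distance")
  b_exp <- .pc(pcs, "birth", "exploration")
  res_dis <- 1 - b_dis^2; res_exp <- 1 - b_exp^2
  sdu <- sqrt(c(s2u_ent, icc["distance"] * res_dis, icc["exploration"] * res_exp))
  sde <- sqrt(c((1 - icc["distance"]) * res_dis,
                (1 - icc["exploration"]) * res_exp))
  u_beh <- MASS::mvrnorm(n, c(0, 0, 0), diag(sdu) %*% C %*% diag(sdu))
  Ce <- C[2:3, 2:3]
  e_beh <- MASS::mvrnorm(m, c(0, 0), diag(sde) %*% Ce %*% diag(sde))

  eta_entry <- config$entry_intercept + slope_ent * zb + u_beh[id, 1]
  d$entry <- stats::rbinom(m, 1, stats::plogis(eta_entry))
  dist_std <- b_dis * zb + u_beh[id, 2] + e_beh[, 1]
  expl_std <- b_exp * zb + u_beh[id, 3] + e_beh[, 2]
  d$distance <- .raw_maps$distance(dist_std)
  d$exploration <- .raw_maps$exploration(expl_std)

  ## --- metabolic variables ---------------------------------------------
  beh_std <- cbind(entry = as.numeric(scale(eta_entry)),
                   distance = dist_std, exploration = expl_std)
  for (v in c("rmr", "stress_max", "stress_integral")) {
    fixed <- .pc(pcs, "birth", v) * zb +
      .pc(pcs, "temperature", v) * zt +
      .pc(pcs, "year", v) * zyear +
      .pc(pcs, "age", v) * zage +
      .pc(pcs, "food", v) * zf +
      .pc(pcs, "mass", v) * zm +
      .pc(pcs, "entry", v) * beh_std[, "entry"] +
      .pc(pcs, "distance", v) * beh_std[, "distance"] +
      .pc(pcs, "exploration", v) * beh_std[, "exploration"]
    v_f <- .pc(pcs, "birth", v)^2 + .pc(pcs, "temperature", v)^2 +
      .pc(pcs, "year", v)^2 + .pc(pcs, "age", v)^2 + .pc(pcs, "food", v)^2 +
      .pc(pcs, "mass", v)^2 + .pc(pcs, "entry", v)^2 +
      .pc(pcs, "distance", v)^2 + .pc(pcs, "exploration", v)^2
    res <- max(1 - v_f, 0.05)
    s2u <- icc[v] * res; s2e <- (1 - icc[v]) * res
    lat <- fixed + stats::rnorm(n, 0, sqrt(s2u))[id] +
      stats::rnorm(m, 0, sqrt(s2e))
    d[[v]] <- .raw_maps[[v]](lat)
  }
  d$rmr_raw <- d$rmr * d$body_mass^0.75

  ## missing-data flags (failed behaviour tests / failed MR measurements)
  beh_na <- stats::runif(m) < config$missing_behaviour_prob
  mr_na <- stats::runif(m) < config$missing_mr_prob
  d$entry[beh_na] <- NA
  d$distance[beh_na] <- NA
  d$exploration[beh_na] <- NA
  d$rmr[mr_na] <- NA
  d$stress_max[mr_na] <- NA
  d$stress_integral[mr_na] <- NA
  d$rmr_raw[mr_na] <- NA
  attr(d, "generator") <- list(slope_entry = slope_ent,
                               entry_latent_total = lat_tot)
  d
}

#' Keep only sessions with both behavioural and metabolic data
#'
#' @param cohort A session table from [generate_cohort()] (or ingested).
#' @return List with `data` (complete sessions), and `excluded`, a named
#'   count per exclusion reason. Row counts are conserved:
#'   `nrow(data) + sum(excluded) = nrow(cohort)`.
#' @export
filter_complete_sessions <- function(cohort) {
  beh_na <- is.na(cohort$entry) | is.na(cohort$distance) |
    is.na(cohort$exploration)
  mr_na <- is.na(cohort$rmr) | is.na(cohort$stress_max) |
    is.na(cohort$stress_integral)
  list(data = cohort[!(beh_na | mr_na), , drop = FALSE],
       excluded = c(missing_behaviour = sum(beh_na & !mr_na),
                    missing_mr = sum(mr_na & !beh_na),
                    missing_both = sum(beh_na & mr_na)))
}

#' Transform a session table for analysis
#'
#' Applies the session filter and the variance-stabilising transforms to
#' the stress responses (square root after adding 9.76 for the maximum
#' response; natural log after adding 25.07 for the integral response --
#' or data-derived `|min| + 0.01` offsets). Scaling to standardized slopes
#' happens inside the model fits; this function only makes the table
#' analysis-ready.
#'
#' @param cohort Session table with raw-unit columns.
#' @param offsets `"paper"` (fixed constants) or `"data"`.
#' @return The filtered table with `stress_max` / `stress_integral`
#'   replaced by their transformed versions; exclusion counts and the
#'   offsets used are attached as attributes.
#' @export
prepare_analysis_data <- function(cohort, offsets = c("paper", "data")) {
  offsets <- match.arg(offsets)
  fl <- filter_complete_sessions(cohort)
  d <- fl$data
  o1 <- if (offsets == "paper") 9.76 else NULL
  o2 <- if (offsets == "paper") 25.07 else NULL
  t1 <- .apply_transform(d$stress_max, "sqrt_offset", o1)
  t2 <- .apply_transform(d$stress_integral, "log_offset", o2)
  d$stress_max <- t1$y
  d$stress_integral <- t2$y
  attr(d, "excluded") <- fl$excluded
  attr(d, "offsets") <- c(stress_max = t1$offset, stress_integral = t2$offset)
  d
}
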