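## Respirometry trace synthesis: a piecewise animal-VO2 profile passed
## through a first-order chamber washout, plus sensor noise and analyser
## offset, producing traces the respirometry module can process.

## Exact discrete first-order lag with time constant tau (s) on grid dt:
## y[k] = y_ss[k] + (y[k-1] - y_ss[k]) * exp(-dt / tau).
.washout <- function(y_ss, y0, tau, dt) {
  a <- exp(-dt / tau)
  as.numeric(stats::filter((1 - a) * y_ss, a, method = "recursive",
                           init = y0))
}

#' Generate one synthetic respirometry trace
#'
#' Builds the animal's instantaneous oxygen-consumption profile (resting
#' level, optional activity bouts, and per-alarm responses that rise
#' instantaneously and decay as the sum of a fast and a slow exponential),
#' converts it to instantaneous excurrent gas fractions by the pull-system
#' mass balance, passes those through the first-order chamber washout with
#' time constant `chamber_volume / flow_rate`, and adds analyser offset
#' and Gaussian sensor noise. The recording starts with a baseline-channel
#' segment (empty reference channel) while the chamber equilibrates with
#' the animal inside.
#'
#' @param session_params List with `v_rest` (resting VO2, ml O2 min^-1),
#'   and optionally `alarm_amp_fast`, `alarm_amp_slow` (response
#'   amplitudes as fractions of resting; scalars or one per alarm),
#'   `decay_fast_s`, `decay_slow_s` (decay time constants, default 20 and
#'   120 s), `alarm_times` (s; default from the config protocol),
#'   `duration_s`, `activity_bouts` (data frame `start`, `duration`,
#'   `amp`).
#' @param config A [generator_config()] providing hardware settings and
#'   noise levels.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return A [resp_trace()] with alarm events marked.
#' @export
generate_trace <- function(session_params, config = generator_config(),
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- session_params
  dt <- 1 / config$trace_sampling_rate
  base_s <- config$baseline_minutes * 60
  alarms <- p$alarm_times
  if (is.null(alarms))
    alarms <- base_s + config$pre_alarm_minutes * 60 +
      c(0, config$alarm_spacing_seconds)
  if (length(alarms) && any(alarms <= base_s + 600))
    stop("alarm before the end of the equilibration discard window")
  dur <- p$duration_s
  if (is.null(dur)) dur <- max(alarms, base_s + 1200) + 180
  t <- seq(0, dur, by = dt)
  n <- length(t)

  ## animal VO2 profile (ml/min)
  v <- rep(p$v_rest, n)
  af <- rep(p$alarm_amp_fast %||% 0, length.out = length(alarms))
  as_ <- rep(p$alarm_amp_slow %||% 0, length.out = length(alarms))
  tf <- p$decay_fast_s %||% 20
  ts <- p$decay_slow_s %||% 120
  for (k in seq_along(alarms)) {
    post <- t >= alarms[k]
    dtk <- t[post] - alarms[k]
    v[post] <- v[post] + p$v_rest *
      (af[k] * exp(-dtk / tf) + as_[k] * exp(-dtk / ts))
  }
  if (!is.null(p$activity_bouts) && nrow(p$activity_bouts)) {
    for (k in seq_len(nrow(p$activity_bouts))) {
      b <- p$activity_bouts[k, ]
      v[t >= b$start & t < b$start + b$duration] <-
        v[t >= b$start & t < b$start + b$duration] + p$v_rest * b$amp
    }
  }

  fr_dry <- config$flow_rate * (config$BP - config$WVP) / config$BP
  tau <- config$chamber_volume / config$flow_rate * 60  # seconds
  o2_ss <- config$FiO2 - v / fr_dry
  co2_ss <- config$FiCO2 + v / fr_dry  # RQ = 1 simulation
  o2_ch <- .washout(o2_ss, config$FiO2, tau, dt)
  co2_ch <- .washout(co2_ss, config$FiCO2, tau, dt)

  baseline <- t < base_s
  feo2 <- ifelse(baseline, config$FiO2, o2_ch) + config$analyzer_offset_o2 +
    stats::rnorm(n, 0, config$noise_sd_o2)
  feco2 <- ifelse(baseline, config$FiCO2, co2_ch) +
    stats::rnorm(n, 0, config$noise_sd_co2)
  resp_trace(t = t, FeO2 = feo2, FeCO2 = pmax(feco2, 1e-6),
             FiO2 = config$FiO2, FiCO2 = config$FiCO2,
             WVP = config$WVP, BP = config$BP, flow = config$flow_rate,
             channel = ifelse(baseline, "baseline", "test"),
             events = alarms)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

## Washed alarm-response basis shapes over the 1-min response window,
## computed with the same discrete recursion as generate_trace, and the
## resulting (max, trapezoidal mean) of each basis.
.alarm_basis <- function(config) {
  dt <- 1 / config$trace_sampling_rate
  tau <- config$chamber_volume / config$flow_rate * 60
  tt <- seq(0, 180, by = dt)
  shape <- function(td) .washout(exp(-tt / td), 0, tau, dt)
  w <- tt <= 60 + 1e-9
  metr <- function(s) {
    sw <- s[w]
    trap <- (sum(sw) - (sw[1] + sw[length(sw)]) / 2) / 60 * dt
    c(max = max(sw), mean = trap)
  }
  s1 <- shape(20); s2 <- shape(120)
  list(s1 = s1[w], s2 = s2[w], m1 = metr(s1), m2 = metr(s2))
}

## Solve fast/slow amplitudes so the washed trace's observed stress
## metrics approximate the target (max%, integral%) pair.
.solve_alarm_shape <- function(target_max, target_int, basis) {
  A <- rbind(c(basis$m1[["max"]], basis$m2[["max"]]),
             c(basis$m1[["mean"]], basis$m2[["mean"]]))
  init <- tryCatch(solve(A, c(target_max, target_int) / 100),
                   error = function(e) c(0, 0))
  obj <- function(x) {
    comb <- x[1] * basis$s1 + x[2] * basis$s2
    trap <- (sum(comb) - (comb[1] + comb[length(comb)]) / 2) / 60
    (100 * max(comb) - target_max)^2 + (100 * trap - target_int)^2
  }
  fit <- stats::optim(init, obj, method = "Nelder-Mead",
                      control = list(maxit = 200, reltol = 1e-8))
  comb <- fit$par[1] * basis$s1 + fit$par[2] * basis$s2
  trap <- (sum(comb) - (comb[1] + comb[length(comb)]) / 2) / 60
  list(amp_fast = fit$par[1], amp_slow = fit$par[2],
       achieved_max = 100 * max(comb), achieved_int = 100 * trap)
}

#' Generate a complete synthetic dataset (cohort + respirometry traces)
#'
#' Runs [generate_cohort()] and then synthesises one respirometry trace
#' per session with metabolic data: the resting level encodes the
#' session's whole-animal RMR, and the alarm-response amplitudes are
#' solved so the washed-out (observed) trace reproduces the session's
#' stress metrics as closely as the peak-decay response family allows.
#' Sessions whose metabolic measurement failed (`NA`) get no trace.
#'
#' @param config A [generator_config()].
#' @return A `synthetic_bundle`: list with `cohort`, `traces` (named
#'   `"<id>_<session>"`), and `true_parameters` (generating values,
#'   including per-session achieved trace-level stress metrics).
#' @export
generate_dataset <- function(config) {
  cohort <- generate_cohort(config)
  basis <- .alarm_basis(config)
  traces <- list()
  ach <- data.frame(key = character(), target_max = numeric(),
                    target_int = numeric(), achieved_max = numeric(),
                    achieved_int = numeric())
  for (i in seq_len(nrow(cohort))) {
    if (is.na(cohort$rmr_raw[i])) next
    key <- sprintf("%s_%d", cohort$id[i], cohort$session[i])
    sol <- .solve_alarm_shape(cohort$stress_max[i],
                              cohort$stress_integral[i], basis)
    traces[[key]] <- generate_trace(
      list(v_rest = cohort$rmr_raw[i] / 60,
           alarm_amp_fast = sol$amp_fast, alarm_amp_slow = sol$amp_slow),
      config)
    ach <- rbind(ach, data.frame(
      key = key, target_max = cohort$stress_max[i],
      target_int = cohort$stress_integral[i],
      achieved_max = sol$achieved_max, achieved_int = sol$achieved_int))
  }
  structure(list(cohort = cohort, traces = traces,
                 true_parameters = list(
                   path_coefficients = as.list(config$path_coefficients),
                   icc_targets = as.list(config$icc_targets),
                   entry_slope_latent = attr(cohort, "generator")$slope_entry,
                   rng_seed = config$rng_seed,
                   trace_targets = ach)),
            class = "synthetic_bundle")
}

#' @export
print.synthetic_bundle <- function(x, ...) {
  cat("<synthetic_bundle> ", nrow(x$cohort), " session rows, ",
      length(x$traces), " trace(s)\n", sep = "")
  invisible(x)
}

#' Write / read a synthetic bundle as plain-text files
#'
#' Writes `cohort.csv`, one trace CSV per session under `traces/`, and
#' `true_parameters.json`.
#'
#' @param bundle A `synthetic_bundle`.
#' @param dir Output directory (created if needed).
#' @return `write_bundle` returns `dir` invisibly; `read_bundle` the
#'   bundle.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  co <- bundle$cohort
  for (v in names(co)) if (inherits(co[[v]], "Date"))
    co[[v]] <- format(co[[v]])
  utils::write.csv(co, file.path(dir, "cohort.csv"), row.names = FALSE)
  for (k in names(bundle$traces))
    write_resp_trace(bundle$traces[[k]],
                     file.path(dir, "traces", paste0(k, ".csv")))
  jsonlite::write_json(bundle$true_parameters,
                       file.path(dir, "true_parameters.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  co <- utils::read.csv(file.path(dir, "cohort.csv"))
  for (v in intersect(c("season_start", "test_date", "first_capture_date"),
                      names(co)))
    co[[v]] <- as.Date(co[[v]])
  co$id <- factor(co$id)
  files <- list.files(file.path(dir, "traces"), full.names = TRUE)
  traces <- lapply(files, read_resp_trace)
  names(traces) <- sub("\\.csv$", "", basename(files))
  tp <- jsonlite::read_json(file.path(dir, "true_parameters.json"),
                            simplifyVector = TRUE)
  structure(list(cohort = co, traces = traces, true_parameters = tp),
            class = "synthetic_bundle")
}
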