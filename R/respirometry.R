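## Respirometry trace processing: pull-system VO2, baseline drift
## correction, sliding-window RMR extraction and acute-stress metrics.

#' Per-sample oxygen consumption from a pull-mode respirometry trace
#'
#' Applies the classical flow-through mass-balance for an excurrent-flow
#' (pull) system with both gases measured downstream and no scrubbing:
#' \deqn{VO_2 = FR_{dry} \frac{(FiO_2 - FeO_2) - FeO_2 (FeCO_2 - FiCO_2)}
#'   {1 - FeO_2}}
#' with the wet excurrent flow dry-corrected as
#' `FR_dry = flow * (BP - WVP) / BP`. When the CO2 channel is unavailable
#' (`use_co2 = FALSE`) a fixed respiratory quotient must be supplied and
#' the variant `FR_dry (FiO2 - FeO2) / (1 - FeO2 (1 - RQ))` is used.
#' Baseline-channel samples are excluded from the animal series.
#'
#' @param trace A [resp_trace()].
#' @param rq_assumption Fixed respiratory quotient, required when
#'   `use_co2 = FALSE`.
#' @param use_co2 Use the measured CO2 channel (default) or an RQ
#'   assumption.
#' @param negative_tolerance Negative VO2 values below `-negative_tolerance`
#'   (ml O2 h^-1) trigger a warning reporting their count.
#' @return A `vo2_series`: list with `t` (s), `vo2` (ml O2 h^-1,
#'   whole-animal, dry-corrected) and the trace's alarm `events`.
#' @export
compute_vo2 <- function(trace, rq_assumption = NULL, use_co2 = TRUE,
                        negative_tolerance = 5) {
  stopifnot(inherits(trace, "resp_trace"))
  keep <- trace$channel == "test"
  fr_dry <- trace$flow[keep] * (trace$BP - trace$WVP[keep]) / trace$BP
  feo2 <- trace$FeO2[keep]; fio2 <- trace$FiO2[keep]
  if (any(1 - feo2 <= 0)) stop("corrupt trace: excurrent O2 fraction >= 1")
  if (use_co2) {
    num <- (fio2 - feo2) - feo2 * (trace$FeCO2[keep] - trace$FiCO2[keep])
    vo2 <- fr_dry * num / (1 - feo2)
  } else {
    if (is.null(rq_assumption))
      stop("`rq_assumption` must supply a respiratory quotient when use_co2 = FALSE")
    vo2 <- fr_dry * (fio2 - feo2) / (1 - feo2 * (1 - rq_assumption))
  }
  vo2 <- vo2 * 60  # ml min^-1 -> ml h^-1
  nneg <- sum(vo2 < -negative_tolerance)
  if (nneg > 0)
    warning(nneg, " sample(s) with VO2 below -", negative_tolerance,
            " ml/h; check baseline correction")
  structure(list(t = trace$t[keep], vo2 = vo2, events = trace$events),
            class = "vo2_series")
}

#' @export
print.vo2_series <- function(x, ...) {
  cat("<vo2_series> ", length(x$t), " samples; median VO2 ",
      round(stats::median(x$vo2), 2), " ml O2/h\n", sep = "")
  invisible(x)
}

#' Correct analyser drift against baseline-channel segments
#'
#' Offsets the excurrent gas fractions so that the mean of each
#' baseline-channel segment (empty reference channel) matches the incurrent
#' fractions. With a single baseline segment the offset is constant; with
#' two or more, the offset is interpolated linearly in time between the
#' segment means (and held constant beyond the outermost segments).
#'
#' @param trace A [resp_trace()] with at least one baseline-channel sample.
#' @return The corrected `resp_trace`.
#' @export
correct_baseline <- function(trace) {
  stopifnot(inherits(trace, "resp_trace"))
  bl <- trace$channel == "baseline"
  if (!any(bl))
    stop("no baseline samples in trace; cannot correct analyser drift")
  ## segment id per baseline sample: runs of TRUE in `bl`
  r <- rle(bl)
  seg_id <- rep(cumsum(r$values), r$lengths)  # 0 for leading test run
  seg_id[!bl] <- NA
  segs <- unique(stats::na.omit(seg_id))
  mid_t <- off_o2 <- off_co2 <- numeric(length(segs))
  for (k in seq_along(segs)) {
    i <- which(seg_id == segs[k])
    mid_t[k] <- mean(trace$t[i])
    off_o2[k] <- mean(trace$FeO2[i] - trace$FiO2[i])
    off_co2[k] <- mean(trace$FeCO2[i] - trace$FiCO2[i])
  }
  if (length(segs) == 1L) {
    o2 <- rep(off_o2, length(trace$t)); co2 <- rep(off_co2, length(trace$t))
  } else {
    o2 <- stats::approx(mid_t, off_o2, xout = trace$t, rule = 2)$y
    co2 <- stats::approx(mid_t, off_co2, xout = trace$t, rule = 2)$y
  }
  trace$FeO2 <- trace$FeO2 - o2
  trace$FeCO2 <- trace$FeCO2 - co2
  trace
}

## Mean of vo2 over all sliding windows [t_i, t_i + window) whose start
## lies in [from, to - window]; returns start times and window means.
.window_means <- function(t, vo2, from, to, window) {
  starts <- which(t >= from & t + window <= to + 1e-9)
  if (!length(starts)) return(NULL)
  cs <- cumsum(c(0, vo2))
  ends <- findInterval(t[starts] + window - 1e-9, t)
  m <- (cs[ends + 1] - cs[starts]) / (ends - starts + 1)
  list(start = t[starts], mean = m)
}

#' Extract resting metabolic rate from a VO2 series
#'
#' RMR is the lowest mean oxygen consumption over any contiguous sliding
#' window (default 30 s, stepping one sample) whose start lies within the
#' last `search_minutes` before the first alarm, after discarding the first
#' `discard_minutes` of the test recording (airflow equilibration). Ties are
#' broken in favour of the earliest window.
#'
#' @param vo2 A `vo2_series` from [compute_vo2()].
#' @param events Alarm onset times (s); defaults to the series' own events.
#'   With no alarms the end of the recording bounds the search.
#' @param discard_minutes Initial span to discard (min).
#' @param window_seconds Window length (s).
#' @param search_minutes Span before the first alarm to search (min).
#' @return RMR in ml O2 h^-1 (whole animal, not mass-corrected).
#' @export
extract_rmr <- function(vo2, events = NULL, discard_minutes = 10,
                        window_seconds = 30, search_minutes = 10) {
  stopifnot(inherits(vo2, "vo2_series"))
  if (is.null(events)) events <- vo2$events
  bound <- if (length(events)) min(events) else max(vo2$t)
  from <- max(vo2$t[1] + discard_minutes * 60, bound - search_minutes * 60)
  wm <- .window_means(vo2$t, vo2$vo2, from, bound, window_seconds)
  if (is.null(wm))
    stop(sprintf(
      "insufficient pre-alarm data: need a %gs window in [%.0f, %.0f] s",
      window_seconds, from, bound))
  wm$mean[which.min(wm$mean)]
}

#' Mass-correct a resting metabolic rate (Kleiber allometry)
#'
#' @param rmr_raw Whole-animal RMR (ml O2 h^-1).
#' @param mass Body mass (g), positive.
#' @return RMR in ml O2 h^-1 g^-0.75.
#' @export
mass_correct <- function(rmr_raw, mass) {
  if (any(mass <= 0)) stop("`mass` must be positive")
  rmr_raw / mass^0.75
}

#' Acute-stress metabolic response relative to resting rate
#'
#' Computes, over the minute following an alarm, (i) the maximum metabolic
#' stress response, `(max VO2 / RMR - 1) * 100`, and (ii) the integral
#' metabolic stress response, the trapezoidal integral of VO2 over the
#' window divided by the resting total (`RMR * window`), minus one, in
#' percent. Both are ratios to the resting state, so any mass correction
#' cancels. The window is the closed interval `[alarm_t, alarm_t + window]`;
#' the series is linearly interpolated at the window endpoints for the
#' integral.
#'
#' @param vo2 A `vo2_series`.
#' @param alarm_t Alarm onset time (s).
#' @param rmr_resting Resting rate (ml O2 h^-1), positive.
#' @param window_seconds Response window (s), default 60.
#' @return Named vector `c(stress_max = %, stress_integral = %)`.
#' @export
stress_response <- function(vo2, alarm_t, rmr_resting, window_seconds = 60) {
  stopifnot(inherits(vo2, "vo2_series"))
  if (rmr_resting <= 0) stop("`rmr_resting` must be positive")
  hi <- alarm_t + window_seconds
  if (max(vo2$t) < hi - 1e-9)
    stop(sprintf("window truncated: need data to %.0f s, have %.0f s",
                 hi, max(vo2$t)))
  inside <- vo2$t >= alarm_t & vo2$t <= hi + 1e-9
  tt <- vo2$t[inside]; vv <- vo2$vo2[inside]
  ## ensure exact endpoints by interpolation
  if (!length(tt) || tt[1] > alarm_t + 1e-9) {
    tt <- c(alarm_t, tt)
    vv <- c(stats::approx(vo2$t, vo2$vo2, alarm_t, rule = 2)$y, vv)
  }
  if (tt[length(tt)] < hi - 1e-9) {
    tt <- c(tt, hi)
    vv <- c(vv, stats::approx(vo2$t, vo2$vo2, hi, rule = 2)$y)
  }
  integ <- sum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2)
  c(stress_max = (max(vv) / rmr_resting - 1) * 100,
    stress_integral = (integ / (rmr_resting * window_seconds) - 1) * 100)
}

#' Summarise one respirometry session
#'
#' Full per-session processing: baseline drift correction, pull-system VO2
#' computation, sliding-window RMR extraction, Kleiber mass correction and
#' per-alarm stress metrics averaged over the (at most two) alarms with a
#' complete one-minute response window.
#'
#' @param trace A [resp_trace()].
#' @param mass Body mass at testing (g).
#' @param ... Passed on to [extract_rmr()] / [stress_response()].
#' @param rq_assumption,use_co2 Passed to [compute_vo2()].
#' @return A `metabolic_summary`: list with `rmr_raw` (ml O2 h^-1), `rmr`
#'   (ml O2 h^-1 g^-0.75), `stress_max` and `stress_integral` (%, `NA` when
#'   no usable alarm), `n_alarms_used` and `body_mass`.
#' @export
summarize_session <- function(trace, mass, rq_assumption = NULL,
                              use_co2 = TRUE, ...) {
  trace <- correct_baseline(trace)
  vo2 <- compute_vo2(trace, rq_assumption = rq_assumption, use_co2 = use_co2)
  rmr_raw <- extract_rmr(vo2, ...)
  alarms <- utils::head(trace$events, 2L)
  alarms <- alarms[alarms + 60 <= max(vo2$t) + 1e-9]
  if (length(alarms)) {
    sm <- vapply(alarms, function(a) stress_response(vo2, a, rmr_raw),
                 numeric(2))
    stress <- rowMeans(sm)
  } else stress <- c(stress_max = NA_real_, stress_integral = NA_real_)
  structure(list(rmr_raw = rmr_raw, rmr = mass_correct(rmr_raw, mass),
                 stress_max = unname(stress[1]),
                 stress_integral = unname(stress[2]),
                 n_alarms_used = length(alarms), body_mass = mass),
            class = "metabolic_summary")
}

#' @export
print.metabolic_summary <- function(x, ...) {
  cat(sprintf(
    "<metabolic_summary> RMR %.2f ml O2/h (%.3f ml/h/g^0.75 at %.1f g); max stress %+.1f%%, integral %+.1f%% (%d alarm(s))\n",
    x$rmr_raw, x$rmr, x$body_mass,
    x$stress_max, x$stress_integral, x$n_alarms_used))
  invisible(x)
}
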