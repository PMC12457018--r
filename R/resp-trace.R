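#' Construct a flow-through respirometry trace
#'
#' A `resp_trace` holds one pull-mode respirometry recording: excurrent and
#' incurrent gas fractions, water-vapour pressure, barometric pressure,
#' flow rate, a per-sample channel flag (`"baseline"` for the empty
#' reference channel, `"test"` for the animal chamber) and the onset times
#' of acoustic alarm events.
#'
#' @param t Sample times in seconds since recording start (strictly
#'   increasing).
#' @param FeO2,FeCO2 Excurrent fractional O2 / CO2 concentrations.
#' @param FiO2,FiCO2 Incurrent fractional concentrations (scalar or
#'   per-sample).
#' @param WVP Water-vapour pressure (kPa), scalar or per-sample.
#' @param BP Barometric pressure (kPa).
#' @param flow Flow rate (ml min^-1, wet, excurrent), scalar or per-sample.
#' @param channel Character vector, `"baseline"` or `"test"` per sample.
#' @param events Alarm onset times (seconds), sorted.
#' @return An object of class `resp_trace`.
#' @export
resp_trace <- function(t, FeO2, FeCO2, FiO2 = 0.2095, FiCO2 = 0.0004,
                       WVP = 0, BP = 101.325, flow = 700,
                       channel = rep("test", length(t)), events = numeric()) {
  n <- length(t)
  rec <- function(x) if (length(x) == 1L) rep(x, n) else x
  FeO2 <- rec(FeO2); FeCO2 <- rec(FeCO2); FiO2 <- rec(FiO2)
  FiCO2 <- rec(FiCO2); WVP <- rec(WVP); flow <- rec(flow); channel <- rec(channel)
  lens <- lengths(list(FeO2, FeCO2, FiO2, FiCO2, WVP, flow, channel))
  if (any(lens != n)) stop("all per-sample fields must have length(t) = ", n)
  if (n >= 2 && any(diff(t) <= 0)) stop("`t` must be strictly increasing")
  fr <- cbind(FeO2, FeCO2, FiO2, FiCO2)
  if (any(fr <= 0 | fr >= 1)) stop("gas fractions must lie in (0, 1)")
  if (any(flow <= 0)) stop("`flow` must be positive")
  if (is.unsorted(events)) stop("`events` must be sorted")
  if (!all(channel %in% c("baseline", "test")))
    stop("`channel` must be 'baseline' or 'test'")
  structure(list(t = as.numeric(t), FeO2 = FeO2, FeCO2 = FeCO2,
                 FiO2 = FiO2, FiCO2 = FiCO2, WVP = WVP,
                 BP = BP, flow = flow, channel = channel,
                 events = as.numeric(events)),
            class = "resp_trace")
}

#' @export
print.resp_trace <- function(x, ...) {
  cat("<resp_trace> ", length(x$t), " samples over ",
      round(diff(range(x$t)) / 60, 1), " min; ",
      sum(x$channel == "baseline"), " baseline samples; ",
      length(x$events), " alarm event(s)\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.resp_trace <- function(x, ...) {
  data.frame(t_seconds = x$t, FiO2 = x$FiO2, FeO2 = x$FeO2,
             FiCO2 = x$FiCO2, FeCO2 = x$FeCO2, WVP_kPa = x$WVP,
             flow_ml_min = x$flow, channel = x$channel,
             event = as.integer(x$t %in% x$events))
}

#' Write / read a respirometry trace as plain CSV
#'
#' The CSV carries one row per sample with columns `t_seconds, FiO2, FeO2,
#' FiCO2, FeCO2, WVP_kPa, flow_ml_min, channel, event`; alarm onsets are
#' marked with `event = 1`. Barometric pressure is stored in a `# BP_kPa=`
#' comment header.
#'
#' @param trace A `resp_trace`.
#' @param path File path.
#' @return `write_resp_trace` returns `path` invisibly; `read_resp_trace`
#'   returns a `resp_trace`.
#' @export
write_resp_trace <- function(trace, path) {
  stopifnot(inherits(trace, "resp_trace"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# BP_kPa=%.6g", trace$BP), con)
  utils::write.csv(as.data.frame(trace), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_resp_trace
#' @export
read_resp_trace <- function(path) {
  hdr <- readLines(path, n = 1L)
  bp <- 101.325
  if (grepl("^# BP_kPa=", hdr))
    bp <- as.numeric(sub("^# BP_kPa=", "", hdr))
  d <- utils::read.csv(path, comment.char = "#")
  resp_trace(t = d$t_seconds, FeO2 = d$FeO2, FeCO2 = d$FeCO2,
             FiO2 = d$FiO2, FiCO2 = d$FiCO2, WVP = d$WVP_kPa, BP = bp,
             flow = d$flow_ml_min, channel = d$channel,
             events = d$t_seconds[d$event == 1])
}
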