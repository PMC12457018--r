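#' Gompertz growth-curve parameters
#'
#' Parameters of the juvenile Gompertz growth curve used to estimate age
#' (and hence date of birth) from body mass at first capture. The defaults
#' describe early postnatal growth in the bush Karoo rat: an asymptotic
#' mass of 88 g, a growth-rate constant of -0.052 per day and a 15-day
#' inflection offset. Individuals heavier than `eligibility_max_mass` at
#' first capture are considered too old for reliable ageing and are
#' rejected with a distinct, catchable error.
#'
#' @param asymptote_mass Asymptotic body mass (g).
#' @param rate_constant Gompertz rate constant (per day, negative).
#' @param offset_days Additive age offset (days).
#' @param eligibility_max_mass Maximum first-capture mass (g) for which an
#'   age estimate is accepted.
#' @return An object of class `gompertz_params`.
#' @export
#' @examples
#' p <- gompertz_params()
#' estimate_age(65, p)  # ~38 days
gompertz_params <- function(asymptote_mass = 88, rate_constant = -0.052,
                            offset_days = 15, eligibility_max_mass = 65) {
  stopifnot(is.numeric(asymptote_mass), is.numeric(rate_constant),
            is.numeric(offset_days), is.numeric(eligibility_max_mass))
  if (rate_constant >= 0)
    stop("`rate_constant` must be negative (mass approaches the asymptote from below)")
  if (!(asymptote_mass > eligibility_max_mass && eligibility_max_mass > 0))
    stop("need asymptote_mass > eligibility_max_mass > 0")
  structure(list(asymptote_mass = asymptote_mass,
                 rate_constant = rate_constant,
                 offset_days = offset_days,
                 eligibility_max_mass = eligibility_max_mass),
            class = "gompertz_params")
}

#' Estimate age from body mass by inverting the Gompertz growth curve
#'
#' Computes `ln(ln(A / M)) / k + c` where `A` is the asymptotic mass, `k`
#' the (negative) rate constant and `c` the offset in days. The estimate is
#' strictly increasing in mass on its domain `0 < M < A`.
#'
#' @param mass Body mass at first capture (g); may be a vector.
#' @param params A [gompertz_params()] object.
#' @param check_eligibility If `TRUE` (default), masses above the
#'   eligibility threshold raise an error of class
#'   `paceline_eligibility_error`.
#' @return Estimated age in days (unrounded).
#' @export
estimate_age <- function(mass, params = gompertz_params(),
                         check_eligibility = TRUE) {
  stopifnot(inherits(params, "gompertz_params"), is.numeric(mass))
  if (any(!is.finite(mass) | mass <= 0))
    stop("`mass` must be positive and finite")
  if (any(mass >= params$asymptote_mass))
    stop("mass at or above the growth asymptote (", params$asymptote_mass,
         " g): age is undefined")
  if (check_eligibility && any(mass > params$eligibility_max_mass)) {
    stop(structure(class = c("paceline_eligibility_error", "error", "condition"),
                   list(message = paste0(
                     "mass above the ageing eligibility threshold (",
                     params$eligibility_max_mass, " g)"),
                     call = sys.call(-1))))
  }
  log(log(params$asymptote_mass / mass)) / params$rate_constant +
    params$offset_days
}

#' Forward Gompertz growth curve: expected mass at a given age
#'
#' The inverse of [estimate_age()]; used by the synthetic-data generator to
#' produce first-capture masses consistent with a known birth date.
#'
#' @param age Age in days.
#' @param params A [gompertz_params()] object.
#' @return Expected body mass (g).
#' @export
gompertz_mass <- function(age, params = gompertz_params()) {
  stopifnot(inherits(params, "gompertz_params"))
  params$asymptote_mass *
    exp(-exp(params$rate_constant * (age - params$offset_days)))
}

#' Estimate an individual's date of birth from first capture
#'
#' Birth date = date of first capture minus the Gompertz-estimated age at
#' that capture. The calendar date is rounded to the nearest day; the
#' numeric birth date (days since season start) keeps the unrounded age and
#' is the variable used in downstream analyses.
#'
#' @param capture_date First capture date (`Date` or parseable string).
#' @param mass Body mass at first capture (g).
#' @param params A [gompertz_params()] object.
#' @param season_start Origin for the numeric birth date. Defaults to 1 July
#'   of the estimated birth year.
#' @param individual_id Optional identifier carried through to the record.
#' @return A one-row data frame (`birth_record`) with columns
#'   `individual_id`, `first_capture_date`, `mass_at_first_capture`,
#'   `estimated_age`, `birth_date`, `birth_date_numeric`.
#' @export
estimate_birth_date <- function(capture_date, mass, params = gompertz_params(),
                                season_start = NULL, individual_id = NA_character_) {
  capture_date <- as.Date(capture_date)
  age <- estimate_age(mass, params)
  birth <- capture_date - round(age)
  if (is.null(season_start)) {
    yr <- as.integer(format(birth, "%Y"))
    season_start <- as.Date(paste0(yr, "-07-01"))
    ## births estimated before 1 July belong to the previous season
    before <- (capture_date - age) < as.numeric(season_start)
    if (any(before))
      season_start[before] <- as.Date(paste0(yr[before] - 1L, "-07-01"))
  } else season_start <- as.Date(season_start)
  out <- data.frame(
    individual_id = individual_id,
    first_capture_date = capture_date,
    mass_at_first_capture = mass,
    estimated_age = age,
    birth_date = birth,
    birth_date_numeric = as.numeric(capture_date) - age - as.numeric(season_start),
    stringsAsFactors = FALSE)
  class(out) <- c("birth_record", class(out))
  out
}

#' Coarsen numeric birth dates into fixed-width bins
#'
#' Replaces a daily numeric birth date (days since season start) by the
#' midpoint of its bin, supporting robustness checks against
#' pseudo-precision of the growth-curve ageing (two-week and four-week
#' intervals). Bins start at day 0 of the season.
#'
#' @param birth_numeric Numeric birth dates (days since season start).
#' @param interval Bin width in days (typically 14 or 28).
#' @return Binned numeric birth dates (bin midpoints). The coarsened value
#'   is always within `interval / 2` of the daily value.
#' @export
coarsen_birth_date <- function(birth_numeric, interval = 14) {
  stopifnot(is.numeric(birth_numeric), interval > 0)
  (floor(birth_numeric / interval) + 0.5) * interval
}

#' Add estimated birth dates to a cohort/session table
#'
#' Applies [estimate_birth_date()] to the per-individual first-capture
#' records in a session table and attaches `estimated_age`, `birth_date`,
#' `birth_date_numeric` and its 14-/28-day coarsened versions to every
#' session row.
#'
#' @param cohort Session table with columns `id`, `first_capture_date`,
#'   `mass_first_capture` and (optionally) `season_start`.
#' @param params A [gompertz_params()] object.
#' @param season_start Season origin passed to [estimate_birth_date()];
#'   taken from the table's `season_start` column when present.
#' @return The cohort with birth-date columns added.
#' @export
add_birth_dates <- function(cohort, params = gompertz_params(),
                            season_start = NULL) {
  stopifnot(all(c("id", "first_capture_date", "mass_first_capture") %in%
                  names(cohort)))
  first <- !duplicated(cohort$id)
  if (is.null(season_start) && "season_start" %in% names(cohort))
    season_start <- cohort$season_start[first]
  rec <- estimate_birth_date(cohort$first_capture_date[first],
                             cohort$mass_first_capture[first], params,
                             season_start = season_start,
                             individual_id = as.character(cohort$id[first]))
  i <- match(as.character(cohort$id), rec$individual_id)
  cohort$estimated_age <- rec$estimated_age[i]
  cohort$birth_date <- rec$birth_date[i]
  cohort$birth_date_numeric <- rec$birth_date_numeric[i]
  cohort$birth_date_14d <- coarsen_birth_date(cohort$birth_date_numeric, 14)
  cohort$birth_date_28d <- coarsen_birth_date(cohort$birth_date_numeric, 28)
  cohort
}
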