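#' Multiple-infusion dosing regimen
#'
#' A regimen is an ordered table of zero-order intravenous infusion
#' events. Times are hours since the start of the first dose; amounts are
#' mg (or mg/kg when working on a weight-normalized 1-kg subject).
#'
#' @param start Numeric vector of infusion start times, h (>= 0).
#' @param duration Numeric vector of infusion durations, h (> 0),
#'   recycled against \code{start}.
#' @param amount Numeric vector of doses, mg (>= 0), recycled.
#' @return A data frame of class \code{"dosing_regimen"} with columns
#'   \code{start}, \code{duration}, \code{amount}, sorted by start time.
#' @seealso \code{\link{traditional_regimen}}, \code{\link{split_daily_dose}}
#' @export
infusion_regimen <- function(start = numeric(), duration = numeric(),
                             amount = numeric()) {
  n <- length(start)
  duration <- rep_len(duration, n)
  amount <- rep_len(amount, n)
  if (n > 0) {
    if (any(!is.finite(start)) || any(start < 0))
      stop("infusion start times must be finite and non-negative", call. = FALSE)
    if (any(!is.finite(duration)) || any(duration <= 0))
      stop("infusion durations must be strictly positive", call. = FALSE)
    if (any(!is.finite(amount)) || any(amount < 0))
      stop("infusion amounts must be non-negative", call. = FALSE)
  }
  o <- order(start)
  structure(data.frame(start = start[o], duration = duration[o],
                       amount = amount[o]),
            class = c("dosing_regimen", "data.frame"))
}

#' Traditional polymyxin B regimen
#'
#' The standard regimen used as the starting point for feedback control:
#' a 2.5 mg/kg loading dose infused over 2 h at time zero, followed by
#' 1.5 mg/kg maintenance doses infused over 1 h every 12 h, the first at
#' t = 12 h.
#'
#' @param weight Body weight, kg. The default 1 gives per-kg amounts.
#' @param n_days Number of days of dosing to lay out.
#' @param loading_mg_kg,maintenance_mg_kg Doses, mg/kg.
#' @param loading_dur_h,maintenance_dur_h Infusion durations, h.
#' @param interval_h Maintenance dosing interval, h.
#' @return A \code{\link{infusion_regimen}}.
#' @export
traditional_regimen <- function(weight = 1, n_days = 2,
                                loading_mg_kg = 2.5, loading_dur_h = 2,
                                maintenance_mg_kg = 1.5, maintenance_dur_h = 1,
                                interval_h = 12) {
  if (weight <= 0) stop("weight must be positive", call. = FALSE)
  maint_starts <- seq(interval_h, n_days * 24, by = interval_h)
  infusion_regimen(
    start = c(0, maint_starts),
    duration = c(loading_dur_h, rep(maintenance_dur_h, length(maint_starts))),
    amount = weight * c(loading_mg_kg, rep(maintenance_mg_kg, length(maint_starts)))
  )
}

#' Split a daily dose into equal intermittent infusions
#'
#' Turns a total daily dose into a steady-state maintenance schedule of
#' equal zero-order infusions (default every 12 h over 1 h), the pattern
#' used for personalized maintenance dosing.
#'
#' @param daily_dose Total daily dose, mg (>= 0).
#' @param interval_h Dosing interval, h; must divide 24.
#' @param duration_h Infusion duration, h (> 0, <= interval).
#' @param n_days Number of days to lay out.
#' @param start_h Start time of the first infusion, h.
#' @return A \code{\link{infusion_regimen}} whose amounts within any
#'   24-h window sum to \code{daily_dose}.
#' @export
split_daily_dose <- function(daily_dose, interval_h = 12, duration_h = 1,
                             n_days = 10, start_h = 0) {
  if (daily_dose < 0) stop("daily_dose must be non-negative", call. = FALSE)
  if (interval_h <= 0 || 24 %% interval_h != 0)
    stop("interval_h must be a positive divisor of 24", call. = FALSE)
  if (duration_h <= 0 || duration_h > interval_h)
    stop("duration_h must be in (0, interval_h]", call. = FALSE)
  per_dose <- daily_dose / (24 / interval_h)
  starts <- seq(start_h, start_h + n_days * 24 - interval_h, by = interval_h)
  infusion_regimen(start = starts, duration = duration_h, amount = per_dose)
}

#' Sparse PK sampling schedule
#'
#' @param times Strictly increasing, non-negative sampling times, h. May
#'   be empty (the "no feedback" strategy).
#' @return Numeric vector of class \code{"sampling_schedule"}.
#' @export
sampling_schedule <- function(times = numeric()) {
  times <- as.numeric(times)
  if (length(times)) {
    if (any(!is.finite(times)) || any(times < 0))
      stop("sampling times must be finite and non-negative", call. = FALSE)
    if (any(diff(times) <= 0))
      stop("sampling times must be strictly increasing", call. = FALSE)
  }
  structure(times, class = "sampling_schedule")
}
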