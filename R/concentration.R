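# Closed-form plasma concentrations for multiple zero-order infusions
# into a linear two-compartment model, by superposition over events.

# (1 - exp(-lam * t)) / lam, vectorized in t, stable as lam -> 0
# (one-compartment limit with q = 0 yields beta = 0).
.expm1_div <- function(lam, t) {
  if (lam > 1e-12) (1 - exp(-lam * t)) / lam else t * (1 - lam * t / 2)
}

# Unit-rate infusion response of one event at relative times tau
# (tau <= 0 contributes nothing; infusion runs on [0, dur]).
.infusion_response <- function(dc, v1, dur, tau) {
  out <- numeric(length(tau))
  on_ <- tau > 0 & tau <= dur
  off <- tau > dur
  if (dc$repeated) {
    lam <- dc$alpha
    k21 <- dc$k21
    # bolus impulse response h(t) = (1/v1) * (1 + (k21 - lam) t) e^{-lam t};
    # infusion response is its running integral.
    H <- function(t) {
      (1 - exp(-lam * t)) / lam +
        (k21 - lam) * (1 - (1 + lam * t) * exp(-lam * t)) / lam^2
    }
    if (any(on_)) out[on_] <- H(tau[on_]) / v1
    if (any(off)) out[off] <- (H(tau[off]) - H(tau[off] - dur)) / v1
    return(out)
  }
  a <- dc$alpha; b <- dc$beta
  ca <- dc$coef_a; cb <- dc$coef_b
  if (any(on_)) {
    tt <- tau[on_]
    out[on_] <- (ca * .expm1_div(a, tt) + cb * .expm1_div(b, tt)) / v1
  }
  if (any(off)) {
    tt <- tau[off] - dur
    out[off] <- (ca * .expm1_div(a, dur) * exp(-a * tt) +
                 cb * .expm1_div(b, dur) *
                   (if (b > 1e-12) exp(-b * tt) else rep(1, length(tt)))) / v1
  }
  out
}

#' Plasma concentration under a multiple-infusion regimen
#'
#' Evaluates the closed-form central-compartment concentration of the
#' linear two-compartment model at the requested times, superposing the
#' during- and post-infusion biexponential solutions of every event that
#' has started. An infusion contributes nothing at its own start time, so
#' samples scheduled exactly at a dose time are pre-dose troughs.
#'
#' @param params A \code{\link{pk_params}} object (absolute units).
#' @param regimen A \code{\link{infusion_regimen}}.
#' @param times Numeric vector of times, h (>= 0).
#' @return Numeric vector of concentrations, mg/L; non-negative,
#'   continuous in time and linear in all infusion amounts.
#' @examples
#' p <- pk_params(cl = 1.93, v1 = 17.5, q = 4.2, v2 = 17.5)
#' reg <- traditional_regimen(weight = 70)
#' conc_profile(p, reg, times = c(1, 2, 6, 12, 24))
#' @export
conc_profile <- function(params, regimen, times) {
  if (any(!is.finite(times)) || any(times < 0))
    stop("times must be finite and non-negative", call. = FALSE)
  dc <- disposition_constants(params)
  conc <- numeric(length(times))
  for (i in seq_len(nrow(regimen))) {
    amt <- regimen$amount[i]
    if (amt == 0) next
    dur <- regimen$duration[i]
    tau <- times - regimen$start[i]
    conc <- conc + (amt / dur) * .infusion_response(dc, params$v1, dur, tau)
  }
  pmax(conc, 0)
}

#' Numeric AUC of the concentration profile
#'
#' Area under the closed-form concentration curve over \code{[t0, t1]}
#' by adaptive quadrature, with the integration interval split at every
#' infusion start and stop so each piece is smooth.
#'
#' @param params A \code{\link{pk_params}} object.
#' @param regimen A \code{\link{infusion_regimen}}.
#' @param t0,t1 Interval bounds, h, with \code{t1 > t0 >= 0}.
#' @param rel_tol Relative quadrature tolerance per piece.
#' @return AUC in mg·h/L.
#' @export
auc_numeric <- function(params, regimen, t0, t1, rel_tol = 1e-9) {
  if (t0 < 0 || t1 <= t0)
    stop("need t1 > t0 >= 0", call. = FALSE)
  if (nrow(regimen) == 0) return(0)
  knots <- sort(unique(c(t0, t1,
                         regimen$start, regimen$start + regimen$duration)))
  knots <- knots[knots >= t0 & knots <= t1]
  total <- 0
  for (i in seq_len(length(knots) - 1)) {
    piece <- stats::integrate(function(t) conc_profile(params, regimen, t),
                              knots[i], knots[i + 1],
                              rel.tol = rel_tol, abs.tol = 1e-12,
                              subdivisions = 200L)
    total <- total + piece$value
  }
  total
}

#' Steady-state daily AUC from clearance
#'
#' For linear kinetics the steady-state AUC over one 24-h dosing day is
#' the daily dose divided by clearance, independent of V1, Q and V2.
#'
#' @param cl Clearance, L/h (or L/h/kg when the dose is per kg).
#' @param daily_dose Total daily dose, mg (or mg/kg).
#' @return ssAUC(0-24), mg·h/L.
#' @examples
#' auc_ss_daily(cl = 0.0276, daily_dose = 2)  # nominal 2 mg/kg/day
#' @export
auc_ss_daily <- function(cl, daily_dose) {
  if (any(cl <= 0)) stop("cl must be strictly positive", call. = FALSE)
  if (any(daily_dose < 0)) stop("daily_dose must be non-negative", call. = FALSE)
  daily_dose / cl
}
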