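#' Therapeutic AUC target window
#'
#' The steady-state AUC(0-24) window used for polymyxin B dose
#' individualization: 50 mg·h/L (efficacy floor from murine PK/PD
#' targets) to 100 mg·h/L (nephrotoxicity ceiling from the
#' meta-regression), midpoint 75 mg·h/L as the dosing target.
#'
#' @param lower,upper Window bounds, mg·h/L.
#' @param mid Dosing target, mg·h/L; defaults to the midpoint.
#' @return Object of class \code{"target_window"}.
#' @export
target_window <- function(lower = 50, upper = 100, mid = (lower + upper) / 2) {
  if (!(0 < lower && lower < mid && mid < upper))
    stop("need 0 < lower < mid < upper", call. = FALSE)
  structure(list(lower = lower, mid = mid, upper = upper),
            class = "target_window")
}

#' @export
print.target_window <- function(x, ...) {
  cat(sprintf("ssAUC(0-24) target window: %g-%g mg·h/L (dosing target %g)\n",
              x$lower, x$upper, x$mid))
  invisible(x)
}

#' Personalized daily dose for an AUC target
#'
#' The daily dose that brings a subject with estimated clearance
#' \code{cl_est} to the target steady-state AUC:
#' \code{dose = target_auc * cl_est}, so that the predicted
#' ssAUC = dose / cl_est equals the target. Exact inverse of
#' \code{\link{auc_ss_daily}}.
#'
#' @param target_auc Target ssAUC(0-24), mg·h/L.
#' @param cl_est Estimated clearance, L/h (or L/h/kg for a per-kg dose).
#' @return Daily dose, mg (or mg/kg).
#' @examples
#' personalized_daily_dose(75, 0.0276)  # 2.07 mg/kg/day
#' @export
personalized_daily_dose <- function(target_auc, cl_est) {
  if (any(target_auc <= 0) || any(cl_est <= 0))
    stop("target_auc and cl_est must be strictly positive", call. = FALSE)
  target_auc * cl_est
}

#' Clinical presentation rounding
#'
#' Rounds a computed quantity to the nearest clinically usable step
#' (e.g. doses to 0.5 mg/kg/day, so the 2.07 mg/kg/day nominal dose is
#' prescribed as 2; AUC bounds to 10 mg·h/L, so 47.6 becomes 50 and
#' 99.3 becomes 100). Simulations use unrounded values; this utility is
#' for presentation and for the adopted window bounds.
#'
#' @param x Value(s) to round.
#' @param step Rounding step in the units of \code{x}.
#' @return \code{x} rounded to the nearest multiple of \code{step}.
#' @export
clinical_round <- function(x, step = 0.5) {
  if (step <= 0) stop("step must be positive", call. = FALSE)
  round(x / step) * step
}

#' Attainment summary for a set of simulated exposures
#'
#' Classifies steady-state AUCs against the target window (inclusive
#' bounds) and summarizes the exposure and dose distributions the way a
#' sampling-strategy comparison table reports them.
#'
#' @param aucs Numeric vector of ssAUC(0-24) values, mg·h/L.
#' @param window A \code{\link{target_window}}.
#' @param doses Optional vector of the daily doses behind \code{aucs}
#'   (mg/kg/day), for the dose-spread columns.
#' @return Object of class \code{"attainment_summary"}: percentages
#'   within / above / below the window (summing to 100), AUC range and
#'   CV\%, and dose range and CV\% when doses are given.
#' @examples
#' attainment_summary(c(50, 75, 100), target_window())  # all within
#' @export
attainment_summary <- function(aucs, window = target_window(), doses = NULL) {
  if (!length(aucs)) stop("aucs must be nonempty", call. = FALSE)
  within <- aucs >= window$lower & aucs <= window$upper
  above <- aucs > window$upper
  cv <- function(x) 100 * stats::sd(x) / mean(x)
  out <- list(n = length(aucs),
              pct_within = 100 * mean(within),
              pct_above = 100 * mean(above),
              pct_below = 100 * mean(!within & !above),
              auc_min = min(aucs), auc_max = max(aucs), auc_cv = cv(aucs))
  if (!is.null(doses)) {
    out$dose_min <- min(doses); out$dose_max <- max(doses)
    out$dose_cv <- cv(doses)
  }
  structure(out, class = "attainment_summary")
}

#' @export
print.attainment_summary <- function(x, ...) {
  cat(sprintf("n = %d: %.1f%% within, %.1f%% above, %.1f%% below window\n",
              x$n, x$pct_within, x$pct_above, x$pct_below))
  cat(sprintf("  ssAUC range %.3g-%.3g mg·h/L, CV %.1f%%\n",
              x$auc_min, x$auc_max, x$auc_cv))
  if (!is.null(x$dose_cv))
    cat(sprintf("  dose range %.2g-%.2g mg/kg/day, CV %.1f%%\n",
                x$dose_min, x$dose_max, x$dose_cv))
  invisible(x)
}

#' Efficacy-based lower bound of the AUC window
#'
#' Converts a free-drug AUC/MIC efficacy target into a total-drug
#' steady-state AUC: free AUC = target x MIC breakpoint, then total
#' AUC = free AUC / (1 - protein-bound fraction). With the median murine
#' target of 10.0, the 2 mg/L polymyxin breakpoint and 58\% human
#' protein binding this gives 20 and 47.6 mg·h/L; the window adopts the
#' clinically rounded 50.
#'
#' @param fauc_mic_target Free-drug AUC(0-24)/MIC target (unitless).
#' @param mic_breakpoint MIC breakpoint, mg/L.
#' @param protein_bound_fraction Fraction of drug protein-bound, in
#'   \code{[0, 1)}.
#' @return List with \code{free_auc} and \code{total_auc}, mg·h/L.
#' @examples
#' lower_bound_from_pkpd(10, 2, 0.58)
#' @export
lower_bound_from_pkpd <- function(fauc_mic_target = 10, mic_breakpoint = 2,
                                  protein_bound_fraction = 0.58) {
  if (fauc_mic_target <= 0 || mic_breakpoint <= 0)
    stop("fauc_mic_target and mic_breakpoint must be positive", call. = FALSE)
  if (protein_bound_fraction < 0 || protein_bound_fraction >= 1)
    stop("protein_bound_fraction must be in [0, 1)", call. = FALSE)
  free_auc <- fauc_mic_target * mic_breakpoint
  list(free_auc = free_auc,
       total_auc = free_auc / (1 - protein_bound_fraction))
}
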