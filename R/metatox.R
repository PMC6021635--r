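#' Packaged polymyxin B nephrotoxicity study table
#'
#' The study-level table behind the exposure-toxicity meta-regression:
#' 18 study arms (one cohort split into cystic-fibrosis and
#' non-cystic-fibrosis arms) with evaluated subject counts, central
#' daily doses, central body weights where reported, cumulative
#' nephrotoxicity grade percentages on the RIFLE-derived scale
#' (\code{tox_pct_ge25/ge50/ge75}: percent of subjects with >= 25, 50,
#' 75\% decrease in creatinine clearance; \code{NA} where the study's
#' toxicity definition cannot be mapped), and the 25th/50th/75th
#' percentiles of each study's simulated steady-state AUC(0-24)
#' distribution (mg·h/L). Two arms lack a mappable >= 25\% grade and are
#' excluded listwise from the regression.
#'
#' @param path Optional path to an alternative CSV with the same schema.
#' @return Data frame with one row per study arm.
#' @examples
#' studies <- nephrotox_studies()
#' nrow(studies)  # 18
#' @export
nephrotox_studies <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "polymyxin_nephrotox_studies.csv",
                        package = "polybtdm", mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("study", "year", "n_evaluated", "dose_central_mg_day",
            "dose_central_type", "weight_central_kg",
            "tox_pct_ge25", "tox_pct_ge50", "tox_pct_ge75",
            "ssauc_p25", "ssauc_p50", "ssauc_p75")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("study table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(df$n_evaluated < 1)) stop("n_evaluated must be >= 1", call. = FALSE)
  for (i in seq_len(nrow(df))) {
    g <- c(df$tox_pct_ge25[i], df$tox_pct_ge50[i], df$tox_pct_ge75[i])
    g <- g[!is.na(g)]
    if (length(g) && (any(g < 0 | g > 100) || is.unsorted(rev(g))))
      stop("cumulative grade percentages must be in [0,100] and non-increasing (row ",
           i, ")", call. = FALSE)
  }
  df
}

#' Harmonize a study's toxicity report to cumulative RIFLE-derived grades
#'
#' Maps graded acute-kidney-injury counts (RIFLE risk / injury /
#' failure, or equivalent staged definitions) to cumulative percentages
#' of subjects with >= 25, >= 50 and >= 75\% decreases in creatinine
#' clearance. A subject in a higher grade counts in every lower grade.
#' Grades that the study's definition cannot support are returned as
#' \code{NA} (absent), never as zero, so such studies drop out of the
#' corresponding regression rather than biasing it.
#'
#' @param n_evaluated Number of subjects evaluated for nephrotoxicity.
#' @param risk,injury,failure Counts of subjects whose worst grade was
#'   RIFLE risk, injury, failure. \code{NA} = not reported.
#' @param injury_or_failure Combined count when a study pools the two
#'   higher grades (makes the >= 50\% grade unavailable separately
#'   unless \code{failure} is also given).
#' @return Named numeric vector \code{c(ge25=, ge50=, ge75=)} of
#'   cumulative percentages, with \code{NA} for unavailable grades.
#' @examples
#' harmonize_grades(73, risk = 20, injury_or_failure = 24)["ge25"]  # 60.3
#' @export
harmonize_grades <- function(n_evaluated, risk = NA, injury = NA,
                             failure = NA, injury_or_failure = NA) {
  if (n_evaluated < 1) stop("n_evaluated must be >= 1", call. = FALSE)
  counts <- c(risk, injury, failure, injury_or_failure)
  if (all(is.na(counts))) stop("at least one grade must be reported", call. = FALSE)
  if (sum(counts, na.rm = TRUE) > n_evaluated)
    stop("graded counts exceed n_evaluated", call. = FALSE)
  hi <- if (!is.na(injury_or_failure)) injury_or_failure
        else if (!is.na(injury) || !is.na(failure))
          sum(c(injury, failure), na.rm = TRUE)
        else NA_real_
  ge25 <- if (!is.na(risk) && !is.na(hi)) 100 * (risk + hi) / n_evaluated
          else NA_real_
  ge50 <- if (!is.na(injury_or_failure) && is.na(injury) && is.na(failure))
            NA_real_
          else if (!is.na(injury) || !is.na(failure))
            100 * sum(c(injury, failure), na.rm = TRUE) / n_evaluated
          else NA_real_
  ge75 <- if (!is.na(failure)) 100 * failure / n_evaluated else NA_real_
  c(ge25 = ge25, ge50 = ge50, ge75 = ge75)
}

#' Simulate a study's steady-state AUC distribution
#'
#' Draws clearances from the population model and converts the study's
#' central daily dose into a distribution of steady-state AUC(0-24)
#' values (ssAUC = daily dose / CL). When the dose is in mg/day the
#' per-kg population clearance is scaled by the study's central weight
#' (70 kg assumed where unreported). Spread comes from clearance BSV;
#' the central dose is held fixed unless a dose CV is given.
#'
#' @param daily_dose Central daily dose, mg/day (or mg/kg/day with
#'   \code{per_kg = TRUE}).
#' @param model A \code{\link{pop_model}}.
#' @param weight Central body weight, kg; \code{NA} uses
#'   \code{default_weight}.
#' @param per_kg Is \code{daily_dose} already per kg?
#' @param n Number of simulated subjects.
#' @param dose_cv Optional lognormal CV for within-study dose spread
#'   (sensitivity analysis; default 0, fixed dose).
#' @param seed Optional integer seed.
#' @param default_weight Weight assumed when \code{weight} is NA, kg.
#' @return Named vector \code{c(p25=, p50=, p75=)}, mg·h/L.
#' @examples
#' simulate_study_auc(150, pop_model(), weight = 66, n = 2000, seed = 1)
#' @export
simulate_study_auc <- function(daily_dose, model = pop_model(), weight = NA,
                               per_kg = FALSE, n = 5000, dose_cv = 0,
                               seed = NULL, default_weight = 70) {
  if (is.na(daily_dose) || daily_dose <= 0)
    stop("a positive central daily dose is required", call. = FALSE)
  w <- if (per_kg) 1 else if (is.na(weight)) default_weight else weight
  .with_seed(seed, {
    om <- omega_from_cv(model$bsv[["cl"]])
    cl <- stats::rlnorm(n, log(model$typical[["cl"]] * w) - om^2 / 2, om)
    dose <- if (dose_cv > 0) {
      omd <- omega_from_cv(dose_cv)
      daily_dose * stats::rlnorm(n, -omd^2 / 2, omd)
    } else rep(daily_dose, n)
    q <- stats::quantile(dose / cl, c(0.25, 0.5, 0.75), names = FALSE)
    c(p25 = q[1], p50 = q[2], p75 = q[3])
  })
}

#' Weighted exposure-toxicity meta-regression
#'
#' Fits the weighted least-squares line relating study-level
#' nephrotoxicity rates to simulated polymyxin B exposure: by default
#' y = percent of subjects with a >= 25\% creatinine-clearance decrease,
#' x = the study's simulated 75th-percentile ssAUC(0-24), weights = the
#' evaluated subject counts. Studies missing either variable are
#' dropped listwise. The p-value is a two-sided t test on the slope
#' with n - 2 degrees of freedom; the fit is invariant to rescaling all
#' weights by a constant and passes through the weighted means.
#'
#' @param studies Study table, default \code{\link{nephrotox_studies}()}.
#' @param x,y,weights Column names for exposure, toxicity rate and
#'   regression weights.
#' @return Object of class \code{"tox_regression"} wrapping the
#'   \code{\link[stats]{lm}} fit, with \code{slope}, \code{intercept},
#'   \code{slope_se}, \code{t_statistic}, \code{p_value},
#'   \code{n_studies} and the data used. Methods: \code{print},
#'   \code{summary}, \code{coef}, \code{predict}, \code{plot}.
#' @examples
#' fit <- tox_regression()
#' coef(fit)        # intercept, slope
#' fit$p_value
#' @export
tox_regression <- function(studies = nephrotox_studies(),
                           x = "ssauc_p75", y = "tox_pct_ge25",
                           weights = "n_evaluated") {
  d <- data.frame(x = studies[[x]], y = studies[[y]], w = studies[[weights]],
                  study = if ("study" %in% names(studies)) studies$study
                          else seq_len(nrow(studies)))
  d <- d[stats::complete.cases(d[c("x", "y", "w")]), ]
  if (nrow(d) < 3)
    stop("need at least 3 studies with non-missing x, y and weights", call. = FALSE)
  if (sum(d$w) <= 0) stop("total weight must be positive", call. = FALSE)
  fit <- stats::lm(y ~ x, data = d, weights = w)
  # suppress the perfect-fit warning for exactly collinear inputs
  co <- suppressWarnings(summary(fit))$coefficients
  structure(list(lm = fit, data = d,
                 slope = co["x", "Estimate"],
                 intercept = co["(Intercept)", "Estimate"],
                 slope_se = co["x", "Std. Error"],
                 t_statistic = co["x", "t value"],
                 p_value = co["x", "Pr(>|t|)"],
                 n_studies = nrow(d),
                 x_var = x, y_var = y, weight_var = weights),
            class = "tox_regression")
}

#' @export
print.tox_regression <- function(x, ...) {
  cat(sprintf("Weighted exposure-toxicity regression (%d studies)\n", x$n_studies))
  cat(sprintf("  %s = %.4g + %.4g * %s\n", x$y_var, x$intercept, x$slope, x$x_var))
  cat(sprintf("  slope SE %.4g, t = %.3f, P = %.4f (df = %d)\n",
              x$slope_se, x$t_statistic, x$p_value, x$n_studies - 2L))
  invisible(x)
}

#' @export
coef.tox_regression <- function(object, ...) {
  c(intercept = unname(object$intercept), slope = unname(object$slope))
}

#' @export
summary.tox_regression <- function(object, ...) summary(object$lm, ...)

#' @param newx Exposure values (75th-percentile ssAUC, mg·h/L) at which
#'   to predict the toxicity rate.
#' @rdname tox_regression
#' @export
predict.tox_regression <- function(object, newx = NULL, ...) {
  if (is.null(newx)) newx <- object$data$x
  object$intercept + object$slope * newx
}

#' @export
plot.tox_regression <- function(x, ...) {
  d <- x$data
  plot(d$x, d$y, cex = 3 * sqrt(d$w / max(d$w)), pch = 21, bg = "grey80",
       xlab = "75th percentile ssAUC(0-24) (mg·h/L)",
       ylab = "Subjects with ≥25% decrease in CLcr (%)",
       main = "Exposure-toxicity meta-regression", ...)
  graphics::abline(x$intercept, x$slope, lwd = 2)
  invisible(x)
}

#' Toxicity-based upper bound of the AUC window
#'
#' Inverts the fitted exposure-toxicity line at the maximum acceptable
#' mild-nephrotoxicity rate: the exposure at which the predicted rate of
#' >= 25\% creatinine-clearance decreases equals \code{max_rate}. At the
#' published fit and a 40\% ceiling this is 99.3, clinically rounded to
#' 100 mg·h/L.
#'
#' @param fit A \code{\link{tox_regression}}, or a list/vector with
#'   \code{slope} and \code{intercept}.
#' @param max_rate Maximum acceptable rate, \%.
#' @param round_step Clinical rounding step, mg·h/L.
#' @return List with \code{raw} and \code{rounded} bounds, mg·h/L.
#' @examples
#' derive_upper_bound(list(slope = 0.3465, intercept = 5.59))
#' @export
derive_upper_bound <- function(fit, max_rate = 40, round_step = 10) {
  slope <- if (inherits(fit, "tox_regression")) fit$slope else fit[["slope"]]
  intercept <- if (inherits(fit, "tox_regression")) fit$intercept else fit[["intercept"]]
  if (slope <= 0)
    stop("no finite bound: fitted slope must be positive", call. = FALSE)
  raw <- (max_rate - intercept) / slope
  list(raw = raw, rounded = clinical_round(raw, round_step))
}

#' Median and range of a simulated-percentile column
#'
#' Summarizes one percentile column of the study table the way the
#' meta-analysis reports it: sample median (mean of the middle two for
#' even counts), minimum and maximum.
#'
#' @param values Numeric vector (e.g. \code{studies$ssauc_p75}), or the
#'   study table itself with \code{which} naming the column.
#' @param which Column to summarize when \code{values} is a data frame.
#' @return Named vector \code{c(median=, min=, max=)}.
#' @examples
#' summarize_percentile_column(nephrotox_studies(), "ssauc_p75")
#' @export
summarize_percentile_column <- function(values, which = "ssauc_p75") {
  if (is.data.frame(values)) values <- values[[which]]
  values <- values[!is.na(values)]
  if (!length(values)) stop("no non-missing values to summarize", call. = FALSE)
  c(median = stats::median(values), min = min(values), max = max(values))
}
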