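#' Sparse sampling strategy
#'
#' A labelled day-1 sampling schedule for the adaptive feedback control
#' loop. Sampling is constrained to the first day of treatment
#' (times in [0, 24] h); an empty schedule is the "no feedback"
#' comparator.
#'
#' @param times Numeric sampling times, h, all within [0, 24].
#' @param label Optional label for reports.
#' @return Object of class \code{"sampling_strategy"}.
#' @export
sampling_strategy <- function(times = numeric(), label = NULL) {
  sched <- sampling_schedule(times)
  if (length(sched) && any(sched > 24))
    stop("sampling is constrained to the first day (times <= 24 h)", call. = FALSE)
  if (is.null(label))
    label <- if (length(sched)) paste(sched, collapse = ",") else "none"
  structure(list(label = label, times = sched), class = "sampling_strategy")
}

#' The eleven benchmark sampling strategies
#'
#' The 0- to 4-sample day-1 strategies evaluated in the published
#' Monte-Carlo comparison: no sampling; single samples at 12 or 24 h;
#' pairs (2,12), (2,24), (4,24), (12,24); triples (2,4,12), (2,12,24),
#' (4,12,24); and the quadruple (2,4,12,24).
#'
#' @return List of \code{\link{sampling_strategy}} objects, length 11.
#' @export
table3_strategies <- function() {
  times <- list(numeric(), 12, 24, c(2, 12), c(2, 24), c(4, 24), c(12, 24),
                c(2, 4, 12), c(2, 12, 24), c(4, 12, 24), c(2, 4, 12, 24))
  lapply(times, sampling_strategy)
}

#' Evaluate one sampling strategy by Monte-Carlo simulation
#'
#' Runs the full adaptive feedback control loop for \code{n} virtual
#' subjects: draw true parameters from the population model; simulate
#' noisy day-1 concentrations under the traditional regimen at the
#' strategy's times; MAP-estimate the individual clearance; set the new
#' daily dose to \code{window$mid * CL_est}; and score the final
#' steady-state AUC \code{= new dose / true CL} against the window.
#'
#' With an empty schedule there is no feedback: every subject receives
#' the nominal population dose, \code{window$mid} times the typical
#' clearance, clinically rounded (2.07 -> 2 mg/kg/day at defaults).
#' Feedback doses are left unrounded. Non-converged MAP fits (rare) fall
#' back to the best point found and are counted.
#'
#' @param model A \code{\link{pop_model}}.
#' @param strategy A \code{\link{sampling_strategy}} (or numeric times).
#' @param window A \code{\link{target_window}}.
#' @param n Number of simulated subjects.
#' @param seed Integer seed for subject draws and residual noise.
#' @param subjects Optional pre-drawn subject data frame (from
#'   \code{\link{sample_subjects}}); used for common-random-number
#'   comparisons across strategies. Overrides \code{n}.
#' @param regimen Initial regimen; default the traditional per-kg
#'   regimen (2.5 mg/kg/2 h load, 1.5 mg/kg/1 h q12h).
#' @param weight Body weight, kg; default 1 (per-kg normalization: with
#'   per-kg dosing and linear weight scaling, weight cancels out of the
#'   attainment statistics).
#' @param nominal_round_step Rounding step for the no-feedback nominal
#'   dose, mg/kg/day.
#' @param fit_cl_only Passed to \code{\link{map_fit}}.
#' @return Object of class \code{"strategy_result"}: the
#'   \code{\link{attainment_summary}}, a per-subject data frame
#'   (\code{cl_true}, \code{cl_est}, \code{daily_dose}, \code{ssauc},
#'   \code{converged}), the strategy and the count of non-converged
#'   fits.
#' @examples
#' r <- run_strategy(pop_model(), sampling_strategy(24), n = 50, seed = 1)
#' r$attainment
#' @export
run_strategy <- function(model, strategy, window = target_window(),
                         n = 5000, seed = NULL, subjects = NULL,
                         regimen = NULL, weight = 1,
                         nominal_round_step = 0.5, fit_cl_only = FALSE) {
  if (!inherits(strategy, "sampling_strategy"))
    strategy <- sampling_strategy(strategy)
  if (is.null(subjects)) {
    if (n < 1) stop("n must be at least 1", call. = FALSE)
    subjects <- sample_subjects(model, n, weight = weight, seed = seed)
  }
  n <- nrow(subjects)
  times <- as.numeric(strategy$times)

  if (!length(times)) {
    dose <- clinical_round(personalized_daily_dose(window$mid, model$typical[["cl"]]),
                           nominal_round_step)
    per_subject <- data.frame(id = subjects$id,
                              cl_true = subjects$cl / subjects$weight,
                              cl_est = model$typical[["cl"]],
                              daily_dose = dose,
                              converged = TRUE)
  } else {
    obs_seed <- if (is.null(seed)) NULL else (seed + 500009L) %% .Machine$integer.max
    est <- .with_seed(obs_seed, {
      eps_p <- matrix(stats::rnorm(n * length(times), 0, model$residual[["prop_cv"]]),
                      nrow = n)
      eps_a <- matrix(stats::rnorm(n * length(times), 0, model$residual[["add_sd"]]),
                      nrow = n)
      cl_est <- numeric(n)
      conv <- logical(n)
      for (i in seq_len(n)) {
        reg_i <- if (is.null(regimen)) traditional_regimen(weight = subjects$weight[i])
                 else regimen
        p <- pk_params(subjects$cl[i], subjects$v1[i], subjects$q[i], subjects$v2[i])
        f <- conc_profile(p, reg_i, times)
        obs <- data.frame(time = times,
                          conc = pmax(f * (1 + eps_p[i, ]) + eps_a[i, ], 0))
        fit <- map_fit(model, obs, reg_i, weight = subjects$weight[i],
                       fit_cl_only = fit_cl_only)
        cl_est[i] <- fit$per_kg[["cl"]]
        conv[i] <- fit$converged
      }
      list(cl_est = cl_est, conv = conv)
    })
    per_subject <- data.frame(id = subjects$id,
                              cl_true = subjects$cl / subjects$weight,
                              cl_est = est$cl_est,
                              daily_dose = personalized_daily_dose(window$mid, est$cl_est),
                              converged = est$conv)
  }
  per_subject$ssauc <- auc_ss_daily(per_subject$cl_true, per_subject$daily_dose)
  structure(list(strategy = strategy, n = n, window = window,
                 attainment = attainment_summary(per_subject$ssauc, window,
                                                 doses = per_subject$daily_dose),
                 subjects = per_subject,
                 n_nonconverged = sum(!per_subject$converged),
                 seed = seed),
            class = "strategy_result")
}

#' @export
print.strategy_result <- function(x, ...) {
  cat(sprintf("Sampling strategy '%s' (%d sample%s), n = %d subjects\n",
              x$strategy$label, length(x$strategy$times),
              if (length(x$strategy$times) == 1) "" else "s", x$n))
  print(x$attainment)
  if (x$n_nonconverged > 0)
    cat(sprintf("  %d MAP fits did not converge (prior-mode fallback used)\n",
                x$n_nonconverged))
  invisible(x)
}

#' Compare sampling strategies on common subjects
#'
#' Maps \code{\link{run_strategy}} over a list of strategies using one
#' shared set of simulated subjects (common random numbers, so strategy
#' differences are not masked by between-replicate noise) and
#' independent residual-noise streams per strategy.
#'
#' @param model A \code{\link{pop_model}}.
#' @param strategies List of \code{\link{sampling_strategy}} objects;
#'   default the eleven benchmark strategies.
#' @param window A \code{\link{target_window}}.
#' @param n Number of subjects.
#' @param seed Integer master seed; per-strategy noise seeds are derived
#'   by counter offset.
#' @param ... Passed to \code{\link{run_strategy}}.
#' @return Object of class \code{"strategy_table"}: the list of
#'   \code{strategy_result}s plus a summary data frame (one row per
#'   strategy, the comparison-table shape). Methods: \code{print},
#'   \code{summary}, \code{as.data.frame}, \code{plot}.
#' @export
run_strategy_table <- function(model, strategies = table3_strategies(),
                               window = target_window(), n = 5000,
                               seed = NULL, ...) {
  subjects <- sample_subjects(model, n, seed = seed)
  results <- vector("list", length(strategies))
  for (k in seq_along(strategies)) {
    sk <- if (is.null(seed)) NULL else (seed + 1000L * k) %% .Machine$integer.max
    results[[k]] <- run_strategy(model, strategies[[k]], window,
                                 seed = sk, subjects = subjects, ...)
  }
  tab <- do.call(rbind, lapply(seq_along(results), function(k) {
    a <- results[[k]]$attainment
    s <- results[[k]]$strategy
    data.frame(strategy = k, n_samples = length(s$times),
               sampling_times = s$label,
               pct_within = a$pct_within, pct_above = a$pct_above,
               pct_below = a$pct_below,
               auc_min = a$auc_min, auc_max = a$auc_max, auc_cv = a$auc_cv,
               dose_min = a$dose_min, dose_max = a$dose_max,
               dose_cv = a$dose_cv)
  }))
  structure(list(results = results, table = tab, n = n, seed = seed,
                 window = window),
            class = "strategy_table")
}

#' @export
print.strategy_table <- function(x, digits = 3, ...) {
  cat(sprintf("Adaptive feedback control: %d strategies, %d subjects each\n",
              nrow(x$table), x$n))
  tab <- x$table
  num <- vapply(tab, is.numeric, TRUE)
  tab[num] <- lapply(tab[num], signif, digits = digits)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.strategy_table <- function(object, ...) object$table

#' @export
as.data.frame.strategy_table <- function(x, ...) x$table

#' @export
plot.strategy_table <- function(x, ...) {
  tab <- x$table
  bp <- graphics::barplot(tab$pct_within, names.arg = tab$sampling_times,
                          las = 2, ylim = c(0, 100),
                          ylab = "Probability of target attainment (%)",
                          xlab = "", main = "Target window attainment by sampling strategy", ...)
  graphics::abline(h = tab$pct_within[tab$n_samples == 0][1], lty = 2)
  invisible(bp)
}

#' ssAUC histogram data for a strategy result
#'
#' Bin counts of the final steady-state AUC distribution, the data
#' behind the attainment histograms.
#'
#' @param result A \code{\link{run_strategy}} result.
#' @param breaks Passed to \code{\link[graphics]{hist}}.
#' @return Data frame with \code{bin_lower}, \code{bin_upper},
#'   \code{count}.
#' @export
ssauc_histogram <- function(result, breaks = seq(0, 250, by = 10)) {
  h <- graphics::hist(pmin(result$subjects$ssauc, max(breaks) - 1e-9),
                      breaks = breaks, plot = FALSE)
  data.frame(bin_lower = utils::head(h$breaks, -1),
             bin_upper = utils::tail(h$breaks, -1),
             count = h$counts)
}
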