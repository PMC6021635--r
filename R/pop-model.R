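#' Population pharmacokinetic model for polymyxin B
#'
#' Defines per-kg typical disposition parameters, lognormal
#' between-subject variability (BSV), a linear weight-scaling rule
#' (absolute parameter = per-kg value x body weight) and a combined
#' proportional + additive residual error model.
#'
#' The typical clearance 0.0276 L/h/kg with 32.4\% BSV comes from the
#' published critically-ill population model this tool is built around;
#' it is the only disposition parameter with a published typical value.
#' V1, Q and V2 defaults are package choices giving Vss of about
#' 0.5 L/kg and a terminal half-life of roughly 12-13 h, consistent with
#' polymyxin B kinetics; steady-state AUC depends only on CL, so results
#' keyed to ssAUC are insensitive to them.
#'
#' The stated typical values are treated as arithmetic means of the
#' lognormal BSV distributions: \code{ln theta ~ N(ln(mean) - omega^2/2,
#' omega^2)} with \code{omega = sqrt(ln(1 + cv^2))}.
#'
#' @param cl,v1,q,v2 Per-kg typical values: L/h/kg, L/kg, L/h/kg, L/kg.
#' @param bsv Named numeric vector of between-subject CVs (fractions)
#'   for \code{cl}, \code{v1}, \code{q}, \code{v2}.
#' @param prop_cv Proportional residual error CV (fraction).
#' @param add_sd Additive residual error SD, mg/L.
#' @return An object of class \code{"pop_model"}.
#' @examples
#' pop_model()
#' @export
pop_model <- function(cl = 0.0276, v1 = 0.25, q = 0.06, v2 = 0.25,
                      bsv = c(cl = 0.324, v1 = 0.30, q = 0.30, v2 = 0.30),
                      prop_cv = 0.20, add_sd = 0.05) {
  typ <- c(cl = cl, v1 = v1, q = q, v2 = v2)
  if (any(!is.finite(typ)) || any(typ <= 0))
    stop("typical per-kg parameter values must be strictly positive", call. = FALSE)
  bsv <- bsv[c("cl", "v1", "q", "v2")]
  if (any(is.na(bsv)) || any(bsv < 0))
    stop("bsv must supply non-negative CVs named cl, v1, q, v2", call. = FALSE)
  if (prop_cv < 0 || add_sd < 0)
    stop("residual error components must be non-negative", call. = FALSE)
  structure(list(typical = typ, bsv = bsv,
                 residual = c(prop_cv = prop_cv, add_sd = add_sd)),
            class = "pop_model")
}

#' @export
print.pop_model <- function(x, ...) {
  cat("Population PK model (two-compartment, linear weight scaling)\n")
  cat(sprintf("  typical per kg: CL %.4g L/h/kg, V1 %.4g L/kg, Q %.4g L/h/kg, V2 %.4g L/kg\n",
              x$typical["cl"], x$typical["v1"], x$typical["q"], x$typical["v2"]))
  cat(sprintf("  BSV (CV): %s\n",
              paste(sprintf("%s %.1f%%", names(x$bsv), 100 * x$bsv), collapse = ", ")))
  cat(sprintf("  residual error: proportional CV %.0f%%, additive SD %.3g mg/L\n",
              100 * x$residual["prop_cv"], x$residual["add_sd"]))
  invisible(x)
}

#' Lognormal log-scale SD from a coefficient of variation
#'
#' @param cv Coefficient of variation, fraction.
#' @return \code{sqrt(log(1 + cv^2))}.
#' @export
omega_from_cv <- function(cv) sqrt(log(1 + cv^2))

# Run expr with a temporary RNG state seeded by `seed` (NULL = use the
# current stream), restoring the caller's stream afterwards.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Draw virtual subjects from the population model
#'
#' Each disposition parameter is drawn independently from its lognormal
#' BSV distribution (arithmetic mean preserved at the typical value) and
#' scaled linearly by body weight.
#'
#' @param model A \code{\link{pop_model}}.
#' @param n Number of subjects.
#' @param weight Scalar body weight in kg, or a vector of length \code{n}.
#'   The default 1 kg gives per-kg parameters directly (dosing in mg/kg).
#' @param seed Optional integer seed; the caller's RNG stream is left
#'   untouched.
#' @return Data frame with columns \code{id}, \code{weight}, \code{cl},
#'   \code{v1}, \code{q}, \code{v2} (absolute units).
#' @examples
#' s <- sample_subjects(pop_model(), n = 5, weight = 70, seed = 1)
#' @export
sample_subjects <- function(model, n, weight = 1, seed = NULL) {
  if (n < 1) stop("n must be at least 1", call. = FALSE)
  weight <- rep_len(weight, n)
  if (any(weight <= 0)) stop("weight must be positive", call. = FALSE)
  .with_seed(seed, {
    draws <- lapply(stats::setNames(nm = c("cl", "v1", "q", "v2")), function(k) {
      om <- omega_from_cv(model$bsv[[k]])
      if (om == 0) rep(model$typical[[k]], n)
      else stats::rlnorm(n, meanlog = log(model$typical[[k]]) - om^2 / 2, sdlog = om)
    })
    data.frame(id = seq_len(n), weight = weight,
               cl = draws$cl * weight, v1 = draws$v1 * weight,
               q = draws$q * weight, v2 = draws$v2 * weight)
  })
}

#' @rdname sample_subjects
#' @param object A \code{\link{pop_model}} (for the \code{simulate} method).
#' @param nsim Number of subjects to simulate.
#' @param ... Passed on to \code{sample_subjects}.
#' @export
simulate.pop_model <- function(object, nsim = 1, seed = NULL, ...) {
  sample_subjects(object, n = nsim, seed = seed, ...)
}

#' Simulate assayed concentrations for one subject
#'
#' Evaluates the subject's true concentration at the scheduled times and
#' applies the residual error model
#' \code{observed = true * (1 + eps_p) + eps_a}, with
#' \code{eps_p ~ N(0, prop_cv^2)} and \code{eps_a ~ N(0, add_sd^2)}.
#' Negative draws (possible with additive error near the LOQ) are
#' truncated to zero and flagged.
#'
#' @param subject One-row data frame as produced by
#'   \code{\link{sample_subjects}}, or a \code{\link{pk_params}} object.
#' @param regimen A \code{\link{infusion_regimen}}.
#' @param schedule A \code{\link{sampling_schedule}} or numeric times, h.
#' @param residual Named vector \code{c(prop_cv=, add_sd=)}; defaults to
#'   the residual block of \code{model} when given.
#' @param model Optional \code{\link{pop_model}} supplying the residual.
#' @param seed Optional integer seed.
#' @return Data frame with \code{time}, \code{true_conc}, \code{conc}
#'   (mg/L) and a \code{truncated} flag.
#' @export
simulate_observations <- function(subject, regimen, schedule,
                                  residual = NULL, model = NULL, seed = NULL) {
  times <- as.numeric(schedule)
  if (!length(times)) stop("schedule must contain at least one time", call. = FALSE)
  if (is.null(residual)) {
    if (is.null(model)) stop("supply residual= or model=", call. = FALSE)
    residual <- model$residual
  }
  p <- if (inherits(subject, "pk_params")) subject
       else pk_params(subject$cl, subject$v1, subject$q, subject$v2)
  f <- conc_profile(p, regimen, times)
  .with_seed(seed, {
    obs <- f * (1 + stats::rnorm(length(f), 0, residual[["prop_cv"]])) +
      stats::rnorm(length(f), 0, residual[["add_sd"]])
    truncated <- obs < 0
    data.frame(time = times, true_conc = f, conc = pmax(obs, 0),
               truncated = truncated)
  })
}
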