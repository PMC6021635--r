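#' Two-compartment disposition parameters
#'
#' Container for one subject's linear two-compartment disposition
#' parameters, in absolute units: clearance \code{cl} (L/h), central
#' volume \code{v1} (L), intercompartmental clearance \code{q} (L/h) and
#' peripheral volume \code{v2} (L).
#'
#' \code{q = 0} is permitted and collapses the model to one compartment
#' (the peripheral compartment is then unreachable and \code{v2} inert).
#'
#' @param cl Clearance, L/h. Strictly positive.
#' @param v1 Central volume of distribution, L. Strictly positive.
#' @param q Intercompartmental clearance, L/h. Non-negative.
#' @param v2 Peripheral volume of distribution, L. Strictly positive.
#' @return An object of class \code{"pk_params"}.
#' @examples
#' pk_params(cl = 1.93, v1 = 17.5, q = 4.2, v2 = 17.5)
#' @export
pk_params <- function(cl, v1, q, v2) {
  vals <- c(cl = cl, v1 = v1, q = q, v2 = v2)
  if (!all(is.finite(vals)))
    stop("all PK parameters must be finite numbers", call. = FALSE)
  if (cl <= 0 || v1 <= 0 || v2 <= 0)
    stop("cl, v1 and v2 must be strictly positive", call. = FALSE)
  if (q < 0)
    stop("q must be non-negative", call. = FALSE)
  structure(list(cl = cl, v1 = v1, q = q, v2 = v2), class = "pk_params")
}

#' @export
print.pk_params <- function(x, ...) {
  cat("Two-compartment PK parameters:\n")
  cat(sprintf("  CL = %g L/h   V1 = %g L   Q = %g L/h   V2 = %g L\n",
              x$cl, x$v1, x$q, x$v2))
  dc <- disposition_constants(x)
  cat(sprintf("  macro rates: alpha = %g /h, beta = %g /h\n", dc$alpha, dc$beta))
  invisible(x)
}

#' Macro disposition constants of the two-compartment model
#'
#' Converts micro parameters (CL, V1, Q, V2) to the hybrid rate constants
#' of the biexponential disposition function: the exponents
#' \code{alpha > beta >= 0} (eigenvalues of the compartment rate matrix,
#' negated) and the dimensionless bolus coefficients
#' \code{coef_a = (alpha - k21)/(alpha - beta)},
#' \code{coef_b = (k21 - beta)/(alpha - beta)}, which sum to one.
#'
#' The exponents satisfy \code{alpha * beta = (CL * Q)/(V1 * V2)} and
#' \code{alpha + beta = CL/V1 + Q/V1 + Q/V2}. \code{beta} is computed as
#' the product identity divided by \code{alpha} for numerical stability.
#' A repeated eigenvalue (relative gap below 1e-10) is flagged via
#' \code{repeated}; downstream evaluation then uses the confluent
#' \code{t * exp(-lambda * t)} limiting form.
#'
#' @param params A \code{\link{pk_params}} object.
#' @return A list with \code{alpha}, \code{beta}, \code{k10}, \code{k12},
#'   \code{k21}, \code{coef_a}, \code{coef_b}, \code{repeated}.
#' @export
disposition_constants <- function(params) {
  if (!inherits(params, "pk_params")) params <- do.call(pk_params, as.list(params)[c("cl", "v1", "q", "v2")])
  k10 <- params$cl / params$v1
  k12 <- params$q / params$v1
  k21 <- params$q / params$v2
  s <- k10 + k12 + k21
  p <- k10 * k21
  disc <- s * s - 4 * p   # = (k10 + k12 - k21)^2 + 4*k12*k21 >= 0 always
  alpha <- (s + sqrt(max(disc, 0))) / 2
  beta <- if (alpha > 0) p / alpha else 0
  repeated <- (alpha - beta) <= 1e-10 * alpha
  if (repeated) {
    coef_a <- NA_real_
    coef_b <- NA_real_
  } else {
    coef_a <- (alpha - k21) / (alpha - beta)
    coef_b <- (k21 - beta) / (alpha - beta)
  }
  list(alpha = alpha, beta = beta, k10 = k10, k12 = k12, k21 = k21,
       coef_a = coef_a, coef_b = coef_b, repeated = repeated)
}
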