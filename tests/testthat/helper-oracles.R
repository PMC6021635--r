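# Shared fixtures and independent oracles used across test files.

ref_params <- function() pk_params(cl = 1.93, v1 = 17.5, q = 4.2, v2 = 17.5)

# Independent eigenvalue oracle: macro exponents as negated eigenvalues
# of the 2x2 compartment rate matrix.
eigen_exponents <- function(p) {
  k10 <- p$cl / p$v1; k12 <- p$q / p$v1; k21 <- p$q / p$v2
  A <- matrix(c(-(k10 + k12), k21, k12, -k21), 2, 2, byrow = TRUE)
  sort(-Re(eigen(A)$values), decreasing = TRUE)  # alpha, beta
}

# Numeric ODE oracle for the two-compartment infusion system.
ode_conc <- function(p, regimen, times) {
  k10 <- p$cl / p$v1; k12 <- p$q / p$v1; k21 <- p$q / p$v2
  rate_at <- function(t) {
    on_ <- t > regimen$start & t <= regimen$start + regimen$duration
    sum(regimen$amount[on_] / regimen$duration[on_])
  }
  deriv <- function(t, y, parms) {
    list(c(rate_at(t) - (k10 + k12) * y[1] + k21 * y[2],
           k12 * y[1] - k21 * y[2]))
  }
  tt <- sort(unique(c(0, times)))
  sol <- deSolve::lsoda(c(0, 0), tt, deriv, NULL,
                        rtol = 1e-10, atol = 1e-12, hmax = 0.25)
  sol[match(times, tt), 2] / p$v1
}

# Dense-grid trapezoid AUC oracle.
trapz_auc <- function(p, regimen, t0, t1, dt = 1 / 60) {
  tt <- seq(t0, t1, by = dt)
  cc <- conc_profile(p, regimen, tt)
  sum((cc[-1] + cc[-length(cc)]) / 2) * dt
}

# Literal re-implementation of the MAP objective for oracle comparison.
naive_map_objective <- function(log_params, model, obs, regimen, weight = 1) {
  om <- sqrt(log(1 + model$bsv^2))
  theta <- model$typical * exp(-om^2 / 2)
  theta[names(log_params)] <- exp(log_params)
  p <- pk_params(theta[["cl"]] * weight, theta[["v1"]] * weight,
                 theta[["q"]] * weight, theta[["v2"]] * weight)
  val <- 0
  for (j in seq_len(nrow(obs))) {
    f <- conc_profile(p, regimen, obs$time[j])
    s2 <- (model$residual[["prop_cv"]] * f)^2 + model$residual[["add_sd"]]^2
    val <- val + (obs$conc[j] - f)^2 / s2 + log(s2)
  }
  for (k in names(log_params)) {
    mu <- log(model$typical[[k]]) - om[[k]]^2 / 2
    val <- val + (log_params[[k]] - mu)^2 / om[[k]]^2
  }
  val
}
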