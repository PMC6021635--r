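test_that("macro constants satisfy the two-compartment algebraic identities", {
  set.seed(101)
  for (i in 1:25) {
    p <- pk_params(cl = runif(1, 0.5, 10), v1 = runif(1, 5, 60),
                   q = runif(1, 0.5, 12), v2 = runif(1, 5, 80))
    dc <- disposition_constants(p)
    expect_gt(dc$alpha, dc$beta)
    expect_gt(dc$beta, 0)
    expect_equal(dc$alpha * dc$beta, (p$cl * p$q) / (p$v1 * p$v2),
                 tolerance = 1e-12)
    expect_equal(dc$alpha + dc$beta, p$cl / p$v1 + p$q / p$v1 + p$q / p$v2,
                 tolerance = 1e-12)
    expect_equal(dc$coef_a + dc$coef_b, 1, tolerance = 1e-12)
  }
})

test_that("macro exponents match the rate-matrix eigenvalue oracle", {
  p <- ref_params()
  dc <- disposition_constants(p)
  ev <- eigen_exponents(p)
  expect_equal(dc$alpha, ev[1], tolerance = 1e-12)
  expect_equal(dc$beta, ev[2], tolerance = 1e-12)
})

test_that("q = 0 collapses to a one-compartment model", {
  p <- pk_params(cl = 2, v1 = 10, q = 0, v2 = 5)
  dc <- disposition_constants(p)
  expect_equal(dc$alpha, 0.2)
  expect_equal(dc$beta, 0)
  # bolus-like short infusion decays mono-exponentially at 0.2/h
  reg <- infusion_regimen(0, 0.001, 100)
  c1 <- conc_profile(p, reg, 5)
  c2 <- conc_profile(p, reg, 10)
  expect_equal(log(c1 / c2) / 5, 0.2, tolerance = 1e-4)
})

test_that("parameter validation rejects non-positive values", {
  expect_error(pk_params(-1, 10, 2, 10), "positive")
  expect_error(pk_params(1, 0, 2, 10), "positive")
  expect_error(pk_params(1, 10, -2, 10), "non-negative")
  expect_error(pk_params(1, 10, NA, 10), "finite")
})

test_that("concentration is zero before drug, continuous, and linear in dose", {
  p <- ref_params()
  reg <- traditional_regimen(weight = 70)
  expect_equal(conc_profile(p, reg, 0), 0)
  # linearity: doubling all amounts doubles concentration everywhere
  reg2 <- infusion_regimen(reg$start, reg$duration, 2 * reg$amount)
  tt <- c(0.5, 1.99, 2, 2.01, 7, 11.99, 12.5, 13, 23.999, 36)
  expect_equal(conc_profile(p, reg2, tt), 2 * conc_profile(p, reg, tt),
               tolerance = 1e-12)
  # continuity across the infusion-end breakpoint
  eps <- 1e-7
  expect_equal(conc_profile(p, reg, 2 - eps), conc_profile(p, reg, 2 + eps),
               tolerance = 1e-5)
})

test_that("superposition: a two-event regimen is the sum of its single events", {
  p <- ref_params()
  e1 <- infusion_regimen(0, 2, 175)
  e2 <- infusion_regimen(12, 1, 105)
  both <- infusion_regimen(c(0, 12), c(2, 1), c(175, 105))
  tt <- seq(0.5, 30, by = 0.5)
  expect_equal(conc_profile(p, both, tt),
               conc_profile(p, e1, tt) + conc_profile(p, e2, tt),
               tolerance = 1e-12)
})

test_that("closed form agrees with the stiff ODE oracle to 1e-6 relative", {
  set.seed(77)
  for (p in list(ref_params(), pk_params(0.9, 8, 7.5, 40))) {
    reg <- traditional_regimen(weight = 70)
    tt <- sort(runif(50, 0.01, 47))
    cf <- conc_profile(p, reg, tt)
    oc <- ode_conc(p, reg, tt)
    expect_lt(max(abs(cf - oc) / pmax(oc, 1e-9)), 1e-6)
  }
})

test_that("confluent (repeated-eigenvalue) infusion form matches quadrature of its impulse response", {
  # the t*exp(-lambda*t) limiting branch, checked against numeric
  # convolution of the impulse response h(t) = (1+(k21-lambda)t)e^(-lambda t)/v1
  lam <- 0.3; k21 <- 0.1; v1 <- 12; dur <- 1.5
  dc <- list(alpha = lam, beta = lam, k21 = k21, repeated = TRUE)
  h <- function(t) (1 + (k21 - lam) * t) * exp(-lam * t) / v1
  for (t in c(0.4, dur, 2.5, 9)) {
    oracle <- integrate(function(u) h(t - u), 0, min(t, dur), rel.tol = 1e-12)
    got <- polybtdm:::.infusion_response(dc, v1, dur, t)
    expect_equal(got, oracle$value, tolerance = 1e-9)
  }
  # and near-degeneracy in micro space degrades gracefully vs the ODE oracle
  p <- pk_params(cl = 2, v1 = 10, q = 1e-12, v2 = 5e-12)
  reg <- infusion_regimen(0, 1, 100)
  expect_equal(conc_profile(p, reg, c(0.5, 1, 3, 8)),
               ode_conc(p, reg, c(0.5, 1, 3, 8)), tolerance = 1e-5)
})

test_that("steady-state numeric AUC equals daily dose / CL within 0.1%", {
  p <- ref_params()
  reg <- split_daily_dose(210, interval_h = 12, duration_h = 1, n_days = 11)
  auc <- auc_numeric(p, reg, 240, 264)
  expect_equal(auc, 210 / p$cl, tolerance = 1e-3)
})

test_that("numeric AUC matches a 1-minute trapezoid grid within 0.5%", {
  p <- ref_params()
  reg <- traditional_regimen(weight = 70)
  a1 <- auc_numeric(p, reg, 0, 24)
  a2 <- trapz_auc(p, reg, 0, 24)
  expect_equal(a1, a2, tolerance = 5e-3)
})

test_that("AUC edge cases and validation", {
  p <- ref_params()
  expect_equal(auc_numeric(p, infusion_regimen(), 0, 24), 0)
  expect_error(auc_numeric(p, infusion_regimen(0, 1, 10), 24, 24), "t1 > t0")
  expect_error(auc_ss_daily(0, 100), "positive")
  expect_equal(auc_ss_daily(0.5, 75 * 0.5), 75)
  expect_equal(auc_ss_daily(0.0276, 2), 72.46, tolerance = 1e-4)
  expect_equal(auc_ss_daily(3, 0), 0)
})

test_that("regimen constructors validate and order events", {
  expect_error(infusion_regimen(-1, 1, 10), "non-negative")
  expect_error(infusion_regimen(0, 0, 10), "positive")
  r <- infusion_regimen(c(12, 0), c(1, 2), c(105, 175))
  expect_equal(r$start, c(0, 12))
  expect_error(sampling_schedule(c(2, 2)), "increasing")
  expect_error(split_daily_dose(100, interval_h = 7), "divisor")
  s <- split_daily_dose(2, interval_h = 12, duration_h = 1, n_days = 1)
  expect_equal(s$amount, c(1, 1))
})
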