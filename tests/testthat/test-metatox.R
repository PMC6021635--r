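test_that("grade harmonization accumulates counts cumulatively", {
  g <- harmonize_grades(73, risk = 20, injury_or_failure = 24)
  expect_equal(unname(g["ge25"]), 100 * 44 / 73, tolerance = 1e-12)
  expect_equal(round(unname(g["ge25"]), 1), 60.3)
  expect_true(is.na(g["ge50"]))  # pooled injury/failure cannot be split
  g2 <- harmonize_grades(100, risk = 10, injury = 5, failure = 2)
  expect_equal(unname(g2), c(17, 7, 2))
  g0 <- harmonize_grades(50, risk = 0, injury = 0, failure = 0)
  expect_equal(unname(g0), c(0, 0, 0))
})

test_that("unmappable reports yield absent grades, and bad counts error", {
  # a study reporting only 'any nephrotoxicity' has no >=25% mapping
  g <- harmonize_grades(50, injury = 3, failure = 1)
  expect_true(is.na(g["ge25"]))
  expect_false(is.na(g["ge50"]))
  expect_error(harmonize_grades(10, risk = 8, injury = 5), "exceed")
  expect_error(harmonize_grades(10), "at least one grade")
})

test_that("the packaged study table has the documented shape", {
  st <- nephrotox_studies()
  expect_equal(nrow(st), 18)
  expect_equal(sum(is.na(st$tox_pct_ge25)), 2)
  expect_true(all(st$ssauc_p25 <= st$ssauc_p50 & st$ssauc_p50 <= st$ssauc_p75))
  # cumulative grades non-increasing wherever present
  ok <- apply(st[, c("tox_pct_ge25", "tox_pct_ge50", "tox_pct_ge75")], 1,
              function(g) { g <- g[!is.na(g)]; !is.unsorted(rev(g)) })
  expect_true(all(ok))
})

test_that("study AUC simulation matches the closed-form lognormal median", {
  mod <- pop_model()
  sim <- simulate_study_auc(150, mod, weight = 66, n = 40000, seed = 17)
  om <- omega_from_cv(0.324)
  med_oracle <- 150 / (0.0276 * 66 * exp(-om^2 / 2))
  expect_equal(unname(sim["p50"]), med_oracle, tolerance = 0.02)
  expect_true(sim["p25"] <= sim["p50"] && sim["p50"] <= sim["p75"])
})

test_that("zero BSV collapses all study percentiles to dose/CL", {
  mod <- pop_model(bsv = c(cl = 0, v1 = 0, q = 0, v2 = 0))
  sim <- simulate_study_auc(100, mod, weight = 70, n = 100, seed = 1)
  expect_equal(unname(sim), rep(100 / (0.0276 * 70), 3))
  expect_error(simulate_study_auc(NA, mod), "positive central daily dose")
})

test_that("weighted regression reproduces exact and closed-form cases", {
  # perfectly collinear points recover the line exactly, any weights
  d <- data.frame(ssauc_p75 = c(1, 2, 5, 9), tox_pct_ge25 = 2 * c(1, 2, 5, 9) + 1,
                  n_evaluated = c(3, 11, 1, 7))
  f <- tox_regression(d)
  expect_equal(unname(coef(f)), c(1, 2), tolerance = 1e-10)
  # equal weights match the OLS closed form
  set.seed(5)
  d2 <- data.frame(ssauc_p75 = runif(8, 50, 120),
                   tox_pct_ge25 = runif(8, 5, 60), n_evaluated = rep(2, 8))
  f2 <- tox_regression(d2)
  dx <- d2$ssauc_p75 - mean(d2$ssauc_p75)
  dy <- d2$tox_pct_ge25 - mean(d2$tox_pct_ge25)
  expect_equal(unname(f2$slope), sum(dx * dy) / sum(dx^2), tolerance = 1e-12)
})

test_that("weighted regression is weight-scale invariant and passes weighted means", {
  st <- nephrotox_studies()
  f1 <- tox_regression(st)
  st2 <- st; st2$n_evaluated <- st2$n_evaluated * 7.3
  f2 <- tox_regression(st2)
  expect_equal(coef(f1), coef(f2), tolerance = 1e-12)
  expect_equal(f1$p_value, f2$p_value, tolerance = 1e-12)
  d <- f1$data
  xbar <- sum(d$w * d$x) / sum(d$w)
  ybar <- sum(d$w * d$y) / sum(d$w)
  expect_equal(f1$intercept + f1$slope * xbar, ybar, tolerance = 1e-10)
  expect_equal(f1$n_studies, 16)
})

test_that("regression validation catches degenerate inputs", {
  d <- data.frame(ssauc_p75 = c(1, 2), tox_pct_ge25 = c(1, 2),
                  n_evaluated = c(1, 1))
  expect_error(tox_regression(d), "at least 3")
})

test_that("upper-bound derivation inverts the fitted line", {
  ub <- derive_upper_bound(list(slope = 0.3465, intercept = 5.59), max_rate = 40)
  expect_equal(ub$raw, (40 - 5.59) / 0.3465, tolerance = 1e-12)
  expect_equal(round(ub$raw, 1), 99.3)
  expect_equal(ub$rounded, 100)
  # degenerate and round-trip cases
  expect_equal(derive_upper_bound(list(slope = 2, intercept = 40))$raw, 0)
  f <- tox_regression()
  expect_equal(predict(f, derive_upper_bound(f, max_rate = 40)$raw), 40,
               tolerance = 1e-10)
  expect_error(derive_upper_bound(list(slope = -1, intercept = 3)), "positive")
})

test_that("percentile-column summaries match the published medians and ranges", {
  st <- nephrotox_studies()
  s75 <- summarize_percentile_column(st, "ssauc_p75")
  expect_equal(unname(s75), c(80.4, 58.9, 117))
  s50 <- summarize_percentile_column(st, "ssauc_p50")
  expect_equal(unname(s50["median"]), 60.95)  # paper prints 61.0
  expect_lt(abs(s50["median"] - 61.0), 0.051)
  expect_equal(unname(summarize_percentile_column(42)), c(42, 42, 42))
})
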