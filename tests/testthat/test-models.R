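# hand-solvable 6-row dataset (no covariates): oracle by normal equations
tiny_ism_data <- function() {
  tibble::tibble(
    sit_min = c(520, 560, 480, 600, 540, 500),
    stand_min = c(280, 300, 260, 310, 290, 305),
    step_min = c(100, 90, 130, 80, 110, 120),
    wear_min = sit_min + stand_min + step_min,
    total_min = wear_min,
    y = c(2.1, 2.9, 1.4, 3.6, 2.2, 1.8))
}

test_that("ISM coefficients match the normal-equation solution", {
  d <- tiny_ism_data()
  fit <- fit_ism(d, "y", covariates = character())
  X <- cbind(1, d$stand_min / 60, d$step_min / 60, d$wear_min / 60)
  zy <- (d$y - mean(d$y)) / sd(d$y)
  beta <- solve(t(X) %*% X, t(X) %*% zy)
  expect_equal(unname(fit$coefficients), drop(beta), tolerance = 1e-9)
})

test_that("ISM recovers the generating per-hour coefficients within 3 SEs", {
  params <- default_params(n = 1524, seed = 8, truth_mode = "beta")
  co <- generate_cohort(params)
  fit <- fit_ism(co, "bmi")
  truth <- params$beta_truth$bmi
  for (p in c("stand", "step")) {
    nm <- paste0(p, "_h")
    se <- sqrt(fit$covariance[nm, nm])
    expect_lt(abs(fit$coefficients[[nm]] - truth[[p]]), 3 * se)
  }
})

test_that("ISM reallocations scale the published per-hour coefficient", {
  # a fit object holding the published per-hour stepping coefficient
  fit <- structure(list(method = "ISM", outcome = "bmi",
                        coefficients = c(step_h = -0.365, stand_h = -0.1),
                        covariance = diag(c(step_h = 0.0016, stand_h = 0.001)) |>
                          (\(m) { dimnames(m) <- list(c("step_h", "stand_h"),
                                                      c("step_h", "stand_h")); m })(),
                        n = 1524),
                   class = c("ism_fit", "substitution_fit"))
  est30 <- ism_reallocation(fit, "sit", "step", 30)
  expect_equal(est30$estimate, -0.1825, tolerance = 1e-12)
  est60 <- ism_reallocation(fit, "sit", "step", 60)
  expect_identical(est30$estimate, est60$estimate / 2)
  # reversal is exact sign negation
  back <- ism_reallocation(fit, "step", "sit", 30)
  expect_identical(est30$estimate + back$estimate, 0)
  # zero minutes give a degenerate zero interval
  none <- ism_reallocation(fit, "sit", "step", 0)
  expect_identical(none$estimate, 0)
  expect_identical(c(none$ci_low, none$ci_high), c(0, 0))
  expect_error(ism_reallocation(fit, "sit", "lying", 30), "unknown")
  expect_error(ism_reallocation(fit, "stand", "step", 30), "sitting")
})

test_that("CISM recovers the generating ILR coefficients within 3 SEs", {
  params <- default_params(n = 1524, seed = 21)
  co <- generate_cohort(params)
  fit <- fit_cism(co, "bmi")
  truth <- params$gamma_truth$bmi
  for (i in 1:2) {
    se <- sqrt(fit$gamma_covariance[i, i])
    expect_lt(abs(fit$gamma[[i]] - truth[[i]]), 3 * se)
  }
})

test_that("CISM gamma is near zero for an outcome with no composition effect", {
  co <- test_cohort(1524, 1)
  fit <- fit_cism(co, "hba1c")   # generated with zero composition effect
  for (i in 1:2) {
    expect_lt(abs(fit$gamma[[i]]), 3 * sqrt(fit$gamma_covariance[i, i]))
  }
})

test_that("CISM is invariant to the SBP: same fit, same reallocation estimate", {
  co <- test_cohort(400, 6)
  f1 <- fit_cism(co, "bmi", default_ilr_basis())
  f2 <- fit_cism(co, "bmi", build_ilr_basis(alt_sbp()))
  expect_equal(fitted(f1$lm), fitted(f2$lm), tolerance = 1e-9)
  expect_false(isTRUE(all.equal(f1$gamma, f2$gamma, check.attributes = FALSE)))
  r1 <- cism_reallocation(f1, "sit", "step", 45)
  r2 <- cism_reallocation(f2, "sit", "step", 45)
  expect_equal(r1$estimate, r2$estimate, tolerance = 1e-9)
  expect_equal(r1$se, r2$se, tolerance = 1e-9)
})

test_that("CISM reallocation CIs follow the delta method around the estimate", {
  co <- test_cohort(400, 6)
  fit <- fit_cism(co, "bmi")
  r <- cism_reallocation(fit, "sit", "stand", 60)
  dz <- r$delta_z[[1]]
  expect_equal(r$estimate, sum(fit$gamma * dz), tolerance = 1e-12)
  expect_equal(r$se, sqrt(drop(t(dz) %*% fit$gamma_covariance %*% dz)),
               tolerance = 1e-12)
  expect_true(r$ci_low <= r$estimate && r$estimate <= r$ci_high)
  none <- cism_reallocation(fit, "sit", "stand", 0)
  expect_identical(none$estimate, 0)
})

test_that("gamma solved from printed 60-min estimates reproduces them and predicts 30-min effects", {
  gam <- solve_cism_gamma(paper_base, printed_zbmi_60)
  # the solve must reproduce its inputs exactly
  expect_equal(cism_predict(gam, paper_base, "sit", "step", 60), -0.230,
               tolerance = 1e-12)
  expect_equal(cism_predict(gam, paper_base, "step", "sit", 60), 0.315,
               tolerance = 1e-12)
  # frozen oracle values for the 30-min predictions
  p30 <- cism_predict(gam, paper_base, "sit", "step", 30)
  q30 <- cism_predict(gam, paper_base, "step", "sit", 30)
  expect_equal(p30, -0.1196398, tolerance = 1e-6)
  expect_equal(q30, 0.1376889, tolerance = 1e-6)
  # and they agree with the published 30-min estimates within input rounding
  expect_lt(abs(p30 - (-0.122)), 0.01)
  expect_lt(abs(q30 - 0.142), 0.01)
  # gamma itself is basis-dependent but the predictions are not
  gam2 <- solve_cism_gamma(paper_base, printed_zbmi_60, build_ilr_basis(alt_sbp()))
  expect_equal(cism_predict(gam2, paper_base, "sit", "step", 30,
                            build_ilr_basis(alt_sbp())), p30, tolerance = 1e-9)
})

test_that("rank-deficient designs fail loudly, naming the collinear column", {
  co <- test_cohort(400, 6)
  co$age_copy <- co$age
  expect_error(fit_ism(co, "bmi", covariates = c("age", "age_copy")),
               "age_copy")
})

test_that("zero behaviour minutes are refused unless replacement is enabled", {
  co <- test_cohort(400, 6)
  co$step_min[3] <- 0
  expect_error(fit_cism(co, "bmi"), "zero")
  fit <- fit_cism(co, "bmi", zero_policy = "replace")
  expect_equal(fit$n, 400)
  expect_true(all(fit$parts > 0))
})

test_that("behaviour minutes convert to hours elementwise", {
  expect_equal(unname(behaviours_to_hours(paper_base)),
               c(9.1333, 4.7667, 1.7833), tolerance = 1e-4)
  expect_equal(behaviours_to_hours(c(60, 60, 60)), c(1, 1, 1))
  expect_equal(behaviours_to_hours(c(0, 0, 0)), c(0, 0, 0))
})
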