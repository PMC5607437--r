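test_that("the generator is deterministic under a fixed seed", {
  cfg <- generator_config(seed = 101, n_subjects = 12)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(a$records, b$records)
  expect_identical(a$cohort$subjects, b$cohort$subjects)
  expect_identical(a$logs$truth$tokens, b$logs$truth$tokens)
  c2 <- simulate_study(generator_config(seed = 102, n_subjects = 12))
  expect_false(identical(a$records$query, c2$records$query))
})

test_that("covariate draws match configured moments at large n", {
  co <- generate_cohort(generator_config(seed = 7, n_subjects = 5000))
  s <- co$subjects
  expect_lt(abs(mean(s$age) - 81.1), 0.5)
  expect_lt(abs(stats::sd(s$age) - 10.5), 0.6)
  expect_gte(min(s$age), 62)
  expect_lt(abs(mean(s$female) - 35 / 42), 0.02)
  expect_lt(abs(mean(s$education) - 15.5), 0.1)
  # metric targets honour their configured ranges
  expect_true(all(s$unique_terms >= 0.5 & s$unique_terms <= 3.1))
  expect_true(all(s$obscurity >= 0.044 & s$obscurity <= 0.52))
  # obscurity anti-correlates with search volume as configured
  r <- stats::cor(log(s$n_searches), s$obscurity)
  expect_lt(r, -0.15)
  expect_gt(r, -0.31)
})

test_that("cognition is linear in the drawn metric with solved residual SD", {
  co <- generate_cohort(generator_config(seed = 15))
  s <- co$subjects
  # the noiseless linear predictor recovers the coefficients exactly
  fit <- stats::lm(linear_predictor ~ age + female + education + unique_terms,
                   s)
  eff <- co$config$effects$unique_terms
  expect_equal(unname(coef(fit)),
               c(eff$intercept, eff$age, eff$sex, eff$education, eff$metric),
               tolerance = 1e-10)
  expect_equal(summary(fit)$r.squared, 1, tolerance = 1e-12)
  # residuals have the solved SD by construction of the draw
  expect_equal(stats::sd(s$cognitive_z - s$linear_predictor),
               co$residual_sd, tolerance = 0.35)
  # the emitted clinical table reproduces the composite up to the
  # 2-decimal rounding of the raw scores
  comp <- composite_scores(co$clinical, co$norms)
  expect_equal(comp$cognitive_z, s$cognitive_z, tolerance = 0.01)
})

test_that("residual-SD solver hits the expectation identity and its limits", {
  sd1 <- residual_sd_for_r2(0.46, var_explained = 0.1, n = 42, p = 4)
  k <- (42 - 4 - 1) / (42 - 1)
  expect_equal(sd1, sqrt(0.1 * (1 - 0.46) / (k - 1 + 0.46)))
  # larger target R2 means less noise
  expect_gt(sd1, residual_sd_for_r2(0.8, 0.1, 42, 4))
  # an R2 below the small-sample floor is unattainable
  expect_error(residual_sd_for_r2(0.05, 0.1, 42, 4), "unattainable")
})

test_that("bisection calibration converges and validates its bracket", {
  f <- function(x) 2 * x + 1
  mid <- calibrate_subject(target = f(0.5), f, c(0, 1), tol = 1e-9)
  expect_lte(mid$iterations, 2)
  expect_equal(mid$knob, 0.5)
  # monotone response lands within tolerance
  g <- function(x) exp(x) - 3 * x
  res <- calibrate_subject(0.5, g, c(1, 3), tol = 1e-4)
  expect_lte(abs(res$value - 0.5), 1e-4)
  expect_true(res$converged)
  # reversed bracket and unbracketed targets are errors
  expect_error(calibrate_subject(1, f, c(1, 0), tol = 1e-4), "interval")
  expect_error(calibrate_subject(10, f, c(0, 1), tol = 1e-4),
               "not bracketed")
})

test_that("without corruption, cleaning recovers the pristine tokens exactly", {
  cfg <- generator_config(seed = 21, n_subjects = 12,
                          corruption = list(p_typo = 0, p_inflect = 0,
                                            p_accent = 0, p_punct = 0,
                                            p_case = 0))
  st <- simulate_study(cfg)
  tt <- st$logs$truth$tokens
  expect_identical(tt$emitted, tt$pristine)
  cl <- clean_searches(data.frame(subject_id = tt$subject_id,
                                  timestamp = NA, query = tt$emitted),
                       st$corpus)
  expect_identical(cl$tokens$token, tt$pristine)
})

test_that("corrupted tokens are restored at the expected rates", {
  st <- simulate_study(generator_config(seed = 22, n_subjects = 14))
  tt <- st$logs$truth$tokens
  expect_gt(mean(tt$emitted != tt$pristine), 0.15)  # corruption did happen
  cl <- clean_searches(data.frame(subject_id = tt$subject_id,
                                  timestamp = NA, query = tt$emitted),
                       st$corpus)
  expect_equal(nrow(cl$tokens), nrow(tt))  # no token lost or gained
  expect_gte(mean(cl$tokens$token == tt$pristine), 0.95)
})

test_that("per-subject calibration hits its targets within tolerance", {
  st <- simulate_study(generator_config(seed = 23))
  tr <- st$logs$truth$subjects
  cal <- st$config$calibration
  # subjects whose bisection converged (the metric is a step function of
  # the knob, so very small subjects may not admit a solution inside tol)
  ok_u <- tr$converged_rho
  expect_gt(mean(ok_u), 0.6)
  expect_true(all(abs(tr$realized_unique_terms[ok_u] -
                        tr$target_unique_terms[ok_u]) <= cal$tol_unique + 1e-9))
  # obscurity is calibrated against the evolving cohort table; cohort-level
  # agreement is the meaningful check
  expect_lt(abs(mean(tr$realized_obscurity) - mean(tr$target_obscurity)),
            0.05)
})

test_that("recovery summarizes replicate fits against the generating truth", {
  rs <- recovery_study(n_reps = 40, model = "unique_terms", seed = 31)
  expect_equal(rs$true_beta, 0.39)
  expect_equal(nrow(rs$replicates), rs$n_reps)
  expect_lt(abs(rs$mean_beta - 0.39), 5 * rs$mc_se + 1e-12)
  expect_true(all(rs$replicates$r2 > 0 & rs$replicates$r2 < 1))
  expect_output(print(rs), "Parameter recovery")
})
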