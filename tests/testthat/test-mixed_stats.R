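test_that("residualization orthogonalizes covariates against the key design", {
  set.seed(41)
  n <- 400
  tbl <- data.frame(time_of_night = factor(rep(c("early", "late"), n / 2)),
                    participant = rep(c("P1", "P2"), each = n / 2))
  tbl$key_num <- as.integer(tbl$time_of_night) - 1
  # covariate identical to a key predictor: residuals vanish
  tbl$cov_dup <- tbl$key_num
  out <- residualize_covariates(tbl, "cov_dup", "time_of_night")
  expect_lt(max(abs(out$cov_dup)), 1e-10)
  # covariate orthogonal to the design: residuals = centered covariate
  tbl$cov_orth <- rep(c(1, 1, -1, -1), n / 4)
  out2 <- residualize_covariates(tbl, "cov_orth", "time_of_night")
  expect_equal(out2$cov_orth, tbl$cov_orth - mean(tbl$cov_orth),
               tolerance = 1e-10)
  # key + independent noise: residual recovers the noise
  noise <- rnorm(n)
  tbl$cov_mix <- tbl$key_num + noise
  out3 <- residualize_covariates(tbl, "cov_mix", "time_of_night")
  expect_gt(cor(out3$cov_mix, noise), 0.99)
  # residuals orthogonal to the key design
  X <- model.matrix(~time_of_night, tbl)
  expect_lt(max(abs(crossprod(X, out3$cov_mix))), 1e-8)
  # rank-deficient designs are refused with the aliased term named
  tbl$dup2 <- tbl$key_num
  expect_error(residualize_covariates(tbl, "cov_orth", c("key_num", "dup2")),
               "aliased")
})

test_that("stepwise selection keeps signal covariates and drops pure noise", {
  reps <- 20
  kept_noise <- kept_signal <- logical(reps)
  for (i in seq_len(reps)) {
    tbl <- generate_spindle_table(6, 400,
                                  beta = c("(Intercept)" = 1,
                                           time_of_nightlate = 0.4,
                                           duration = 0.6),
                                  sigma_u = 1, sigma_e = 1, seed = 500 + i)
    spec <- model_spec("power", "time_of_night", c("duration", "globality"))
    rtbl <- residualize_covariates(tbl, c("duration", "globality"),
                                   "time_of_night")
    sel <- stepwise_select(rtbl, spec)
    expect_true("time_of_night" %in% sel)   # seed never dropped
    kept_noise[i] <- "globality" %in% sel
    kept_signal[i] <- "duration" %in% sel
  }
  expect_true(all(kept_signal))
  expect_lt(mean(kept_noise), 0.3)
  # no candidates: the seed is returned unchanged
  tbl <- generate_spindle_table(4, 50, seed = 1)
  spec0 <- model_spec("power", "time_of_night")
  expect_equal(unname(stepwise_select(tbl, spec0)), "time_of_night")
})

test_that("stepwise selection is deterministic for a fixed table", {
  tbl <- generate_spindle_table(5, 300,
                                beta = c("(Intercept)" = 1, duration = 0.3),
                                sigma_u = 1, sigma_e = 1, seed = 77)
  spec <- model_spec("power", "time_of_night",
                     c("duration", "globality", "amplitude"))
  rtbl <- residualize_covariates(tbl, spec$candidate_covariates,
                                 "time_of_night")
  expect_identical(stepwise_select(rtbl, spec), stepwise_select(rtbl, spec))
})

test_that("the mixed model reduces to OLS without between-participant variance", {
  tbl <- generate_spindle_table(6, 150,
                                beta = c("(Intercept)" = 2,
                                         time_of_nightlate = 0.5),
                                sigma_u = 0, sigma_e = 1, seed = 3)
  f <- suppressWarnings(fit_lmm(tbl, "power", "time_of_night"))
  ols <- lm(power ~ time_of_night, tbl)
  expect_equal(f$coefficients$estimate, unname(coef(ols)), tolerance = 1e-4)
  expect_equal(f$n_obs, nrow(tbl))
  expect_equal(f$AIC, 2 * f$df - 2 * f$logLik)
})

test_that("inestimable fixed effects and tiny designs are rejected", {
  tbl <- generate_spindle_table(4, 50, seed = 2)
  tbl$zeros <- 0
  expect_error(fit_lmm(tbl, "power", c("time_of_night", "zeros")),
               "rank deficient")
  expect_error(fit_lmm(tbl[tbl$participant == "P01", ], "power",
                       "time_of_night"), "grouping")
})

test_that("likelihood-ratio tests match the chi-square tail", {
  mk <- function(ll, df) structure(list(logLik = ll, df = df, n_obs = 100,
                                        terms = if (df > 3) c("a", "b") else "a"),
                                   class = "spd_lmm_fit")
  r <- lr_test(mk(-100, 5), mk(-103, 3))
  expect_equal(r$chi2, 6)
  expect_equal(r$df, 2)
  expect_equal(r$p, pchisq(6, 2, lower.tail = FALSE))
  expect_equal(r$p, 0.0498, tolerance = 1e-3)
  # identical models: chi2 0, p 1
  same <- lr_test(mk(-50, 4), structure(list(logLik = -50, df = 3, n_obs = 100,
                                             terms = "a"),
                                        class = "spd_lmm_fit"))
  expect_equal(same$chi2, 0)
  expect_equal(same$p, 1)
  expect_error(lr_test(mk(-103, 5), mk(-100, 3)), "negative")
})

test_that("main-effect reduction removes every term containing the factor", {
  terms <- c("time_of_night", "spindle_type", "duration",
             "spindle_type:time_of_night", "duration:time_of_night")
  expect_equal(terms_without(terms, "time_of_night"),
               c("spindle_type", "duration"))
  expect_equal(terms_without(terms, "duration"),
               c("time_of_night", "spindle_type", "spindle_type:time_of_night"))
})

test_that("the full analysis recovers a strong condition effect", {
  tbl <- generate_spindle_table(8, 300,
                                beta = c("(Intercept)" = 1,
                                         time_of_nightlate = 0.5,
                                         duration = 0.4),
                                sigma_u = 1, sigma_e = 1, seed = 9)
  spec <- model_spec("power", "time_of_night", c("duration", "globality"))
  res <- lmm_analysis(tbl, spec)
  expect_lt(res$tests$time_of_night$p, 1e-6)
  expect_true("duration" %in% res$selected)
  co <- res$fit$coefficients
  est <- co$estimate[co$term == "time_of_nightlate"]
  se <- co$se[co$term == "time_of_nightlate"]
  expect_lt(abs(est - 0.5), 3 * se)
})
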