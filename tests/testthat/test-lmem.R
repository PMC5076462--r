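sim_small <- function(seed = 1, n_subj = 12, n_item = 40,
                      beta_cosine = -0.05, sd_subject = c(0.08, 0.02, 0, 0),
                      sd_item = 0.03, sd_resid = 0.12) {
  items <- make_item_set_direct(n_word = n_item, n_nonword = 0, seed = seed)
  plan <- assemble_blocks(items, n_blocks = 1, seed = seed)
  params <- simulation_params(beta_cosine = beta_cosine,
                              sd_subject = sd_subject, sd_item = sd_item,
                              sd_resid = sd_resid, p_error = 0,
                              p_outlier = 0, n_subjects = n_subj)
  tr <- simulate_experiment(plan, params, seed = seed + 1000)
  tr$log_rt <- log(tr$rt)
  tr
}

full_spec <- function() add_fixed_term(baseline_spec(), "cosine")

test_that("with zero random variance the fit collapses to OLS", {
  tr <- sim_small(seed = 2, sd_subject = rep(0, 4), sd_item = 0)
  fit <- fit_lmem(tr, full_spec())
  ols <- lm(log_rt ~ length_target + freq_class_target + length_prime +
              freq_class_prime + cosine, data = tr)
  est <- setNames(fit$estimates$estimate, fit$estimates$term)
  expect_equal(est[names(coef(ols))], coef(ols), tolerance = 1e-4)
  expect_true(fit$singular) # variance components at the boundary
})

test_that("an intercept-only fit on balanced data recovers the grand mean", {
  tr <- sim_small(seed = 3)
  spec <- lmem_spec(fixed = character(), random = list(subject = character()))
  fit <- fit_lmem(tr, spec)
  b0 <- fit$estimates$estimate[fit$estimates$term == "(Intercept)"]
  expect_equal(b0, mean(tr$log_rt), tolerance = 1e-6)
})

test_that("internal covariate standardization is an exact reparameterization", {
  tr <- sim_small(seed = 4)
  f_std <- fit_lmem(tr, full_spec(), scale_covariates = TRUE)
  f_raw <- fit_lmem(tr, full_spec(), scale_covariates = FALSE)
  expect_equal(f_std$logLik, f_raw$logLik, tolerance = 1e-4)
  expect_equal(f_std$k, f_raw$k)
  est_s <- setNames(f_std$estimates$estimate, f_std$estimates$term)
  est_r <- setNames(f_raw$estimates$estimate, f_raw$estimates$term)
  expect_equal(est_s["cosine"], est_r["cosine"], tolerance = 1e-2)
  se_s <- setNames(f_std$estimates$se, f_std$estimates$term)
  se_r <- setNames(f_raw$estimates$se, f_raw$estimates$term)
  expect_equal(se_s["cosine"], se_r["cosine"], tolerance = 1e-2)
})

test_that("AIC, k and logLik are mutually consistent and t = estimate/se", {
  tr <- sim_small(seed = 5)
  fit <- fit_lmem(tr, full_spec())
  expect_equal(fit$AIC, 2 * fit$k - 2 * fit$logLik)
  expect_equal(fit$estimates$t, fit$estimates$estimate / fit$estimates$se)
  # k: 6 fixed + 10 subject covariance + 1 item variance + 1 residual
  expect_equal(fit$k, 18L)
  g <- glance(fit)
  expect_equal(g$AIC, fit$AIC)
  expect_equal(nrow(tidy(fit)), 6L)
})

test_that("the likelihood-ratio test clamps at zero and handles identical fits", {
  tr <- sim_small(seed = 6)
  base <- fit_lmem(tr, baseline_spec())
  full <- fit_lmem(tr, full_spec())
  lrt <- likelihood_ratio_test(base, full)
  expect_gte(lrt$chisq, 0)
  expect_equal(lrt$df, 1L)
  expect_equal(lrt$p_value, pchisq(lrt$chisq, 1, lower.tail = FALSE))
  same <- likelihood_ratio_test(full, full)
  expect_equal(same$chisq, 0)
  expect_equal(same$p_value, 1)
  expect_error(likelihood_ratio_test(full, base), "not nested")
  tr2 <- sim_small(seed = 7)
  other <- fit_lmem(tr2, full_spec())
  expect_error(likelihood_ratio_test(base, other), "identical data")
})

test_that("the LRT statistic is invariant to affine rescaling of the response", {
  tr <- sim_small(seed = 8)
  base <- fit_lmem(tr, baseline_spec())
  full <- fit_lmem(tr, full_spec())
  chisq1 <- likelihood_ratio_test(base, full)$chisq
  tr2 <- tr
  tr2$log_rt <- 3 * tr2$log_rt + 2
  base2 <- fit_lmem(tr2, baseline_spec())
  full2 <- fit_lmem(tr2, full_spec())
  chisq2 <- likelihood_ratio_test(base2, full2)$chisq
  expect_equal(chisq1, chisq2, tolerance = 0.05)
  # induced log-likelihood shift: -n log a
  expect_equal(base2$logLik, base$logLik - nrow(tr) * log(3), tolerance = 0.05)
})

test_that("Wald intervals use the two-sided normal quantile", {
  ci <- wald_ci(0, 1, level = 0.95)
  expect_equal(ci$lower, -1.959964, tolerance = 1e-6)
  expect_equal(ci$upper, 1.959964, tolerance = 1e-6)
  sym <- wald_ci(0, 0.37)
  expect_equal(sym$lower, -sym$upper)
  expect_error(wald_ci(0, 1, level = 1.2), "level")
  expect_error(wald_ci(0, -1), "se")
})

test_that("published-statistic helpers reproduce their defining arithmetic", {
  expect_equal(aic_from_loglik(100, 5), -190)
  lr <- lrt_from_loglik(-50, -48, df = 1)
  expect_equal(lr$chisq, 4)
  expect_equal(lr$p_value, pchisq(4, 1, lower.tail = FALSE))
})

test_that("missing columns and single-level grouping factors are rejected", {
  tr <- sim_small(seed = 9)
  expect_error(fit_lmem(dplyr::select(tr, -cosine), full_spec()),
               "lacks columns")
  tr1 <- tr[tr$subject == "s1", ]
  expect_error(fit_lmem(tr1, full_spec()), ">= 2 levels")
})
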