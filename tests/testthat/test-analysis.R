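make_experiment_trials <- function(seed, n_subj = 14, n_item = 60,
                                   beta_cosine = -0.05) {
  items <- make_item_set_direct(n_word = n_item, n_nonword = n_item / 2,
                                seed = seed)
  plan <- assemble_blocks(items, n_blocks = 2, seed = seed)
  params <- simulation_params(beta_cosine = beta_cosine, n_subjects = n_subj)
  trials <- simulate_experiment(plan, params, seed = seed + 500)
  preprocess_trials(trials)$trials
}

test_that("the experiment analysis returns consistent fits, LRT, CI and curve", {
  tr <- make_experiment_trials(seed = 31)
  an <- run_experiment_analysis(tr)
  expect_s3_class(an, "priming_analysis")
  expect_equal(an$full$k - an$baseline$k, 1L)
  expect_equal(an$lrt$df, 1L)
  expect_equal(
    an$lrt$chisq, max(0, 2 * (an$full$logLik - an$baseline$logLik)),
    tolerance = 1e-8
  )
  beta <- an$full$estimates
  b_cos <- beta$estimate[beta$term == "cosine"]
  expect_equal(an$ci$estimate, b_cos)
  expect_true(an$ci$lower < b_cos & b_cos < an$ci$upper)
  # predicted curve is the exponentiated linear predictor
  expect_equal(an$predicted_curve$predicted_rt,
               exp(an$predicted_curve$predicted_log_rt))
  expect_equal(nrow(an$item_means), length(unique(tr$item)))
  # plot method returns a ggplot without evaluation errors
  p <- ggplot2::autoplot(an)
  expect_s3_class(p, "ggplot")
})

test_that("the pooled model has crossed prime/target intercepts and k = 19", {
  tr1 <- make_experiment_trials(seed = 33)
  tr2 <- make_experiment_trials(seed = 34)
  an <- pooled_analysis(tr1, tr2)
  # 6 fixed + 10 by-subject covariance + 2 crossed intercepts + 1 residual
  expect_equal(an$full$k, 19L)
  expect_equal(an$baseline$k, 18L)
  expect_true(all(c("prime", "target") %in% names(an$full$varcor)))
  expect_gte(an$lrt$chisq, 0)
  comp <- an$model_comparison
  expect_equal(comp$AIC, 2 * comp$k - 2 * comp$logLik)
})

test_that("cosine correlation handles identity, negation, oracle and degeneracy", {
  items <- make_item_set_direct(n_word = 50, seed = 35)
  x <- items$word_pairs$cosine
  expect_equal(cosine_correlation(items, x), 1)
  expect_equal(cosine_correlation(items, 1 - x), -1)
  withr::with_seed(36, {
    y <- x + rnorm(50, 0, 0.1)
    r_direct <- cosine_correlation(items, y)
    # direct formula oracle
    r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(r_direct, r_oracle, tolerance = 1e-12)
  })
  # data-frame interface
  other <- items$word_pairs[, c("prime", "target")]
  other$cosine <- 1 - x
  expect_equal(cosine_correlation(items, other), -1)
  items$word_pairs$cosine <- 0.3
  expect_warning(r <- cosine_correlation(items, x), "zero variance")
  expect_true(is.na(r))
})

test_that("noise-free data give a predicted curve equal to the generative one", {
  items <- make_item_set_direct(n_word = 40, n_nonword = 20, seed = 37)
  plan <- assemble_blocks(items, n_blocks = 2, seed = 37)
  params <- simulation_params(sd_subject = rep(0, 4), sd_item = 0,
                              sd_resid = 0.0001, p_error = 0, p_outlier = 0,
                              n_subjects = 6)
  tr <- preprocess_trials(simulate_experiment(plan, params, seed = 38))$trials
  an <- run_experiment_analysis(tr)
  # at the item covariate means the fitted curve matches the true model
  grid <- an$predicted_curve$cosine
  truth <- params$beta0 + params$beta_cosine * grid +
    params$beta_length_target * mean(tr$length_target) +
    params$beta_freq_target * mean(tr$freq_class_target) +
    params$beta_length_prime * mean(tr$length_prime) +
    params$beta_freq_prime * mean(tr$freq_class_prime)
  expect_equal(an$predicted_curve$predicted_log_rt, truth, tolerance = 1e-3)
})
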