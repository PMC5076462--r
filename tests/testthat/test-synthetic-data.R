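test_that("the synthetic lexicon supplies the stimulus pools", {
  build <- default_build(1)
  lex <- build$lexicon
  expect_gte(nrow(eligible_words(lex, target_constraints())), 300)
  expect_gte(nrow(eligible_words(lex, prime_constraints())), 600)
  expect_false(any(duplicated(lex$word)))
  expect_equal(lex$length, nchar(lex$word))
  expect_equal(lex$frequency_class,
               frequency_class(lex$frequency, max(lex$frequency)))
  # determinism
  lex2 <- generate_lexicon(build$cfg)
  expect_identical(lex, lex2)
})

test_that("a flat frequency law yields all-zero frequency classes", {
  cfg <- generator_config(vocab_size = 50, zipf_exponent = 0, n_docs = 20,
                          sentences_per_doc = 2, tokens_per_sentence = 8,
                          n_function_words = 5, n_categories = 5, seed = 2)
  lex <- generate_lexicon(cfg, check_feasibility = FALSE)
  content <- lex[!lex$is_function, ]
  expect_equal(length(unique(content$frequency)), 1L)
  expect_true(all(frequency_class(content$frequency,
                                  max(content$frequency)) == 0))
})

test_that("corpus token totals track the lexicon frequency targets", {
  build <- default_build(1)
  expect_lt(abs(nrow(build$corpus) - sum(build$lexicon$frequency)) /
              sum(build$lexicon$frequency), 0.10)
  # per-word counts correlate strongly with the targets
  counts <- table(build$corpus$token)
  common <- intersect(names(counts), build$lexicon$word)
  # ring-category mixing reshapes within-category rates, so per-word
  # counts track the Zipf targets strongly but not perfectly
  expect_gt(cor(as.numeric(counts[common]),
                build$lexicon$frequency[match(common, build$lexicon$word)]),
            0.85)
  # determinism
  c2 <- generate_corpus(build$cfg, build$lexicon)
  expect_identical(as.data.frame(build$corpus), as.data.frame(c2))
})

test_that("planted near-synonym pairs are recovered as high-cosine neighbours", {
  build <- default_build(1)
  syn <- attr(build$corpus, "synonym_pairs")
  syn <- syn[syn$word1 %in% build$hal$words & syn$word2 %in% build$hal$words, ]
  cc <- mapply(function(a, b) max(0, cosine(build$hal, a, b)),
               syn$word1, syn$word2)
  expect_gte(mean(cc > 0.8), 0.9)
})

test_that("words from distant ring categories have near-zero cosines", {
  build <- default_build(1)
  catmap <- attr(build$corpus, "category_map")
  C <- build$cfg$n_categories
  withr::with_seed(8, {
    pos <- setNames(catmap$category, catmap$word)
    in_space <- intersect(catmap$word, build$hal$words)
    a <- sample(in_space, 300, replace = TRUE)
    b <- sample(in_space, 300, replace = TRUE)
    d <- abs(pos[a] - pos[b]); d <- pmin(d, C - d)
    far <- d > C / 3
    cc <- mapply(function(x, y) max(0, cosine(build$hal, x, y)),
                 a[far], b[far])
    expect_gte(mean(cc < 0.2), 0.9)
  })
})

test_that("noise-free simulation is an exact function of the covariates", {
  items <- make_item_set_direct(n_word = 60, n_nonword = 20, seed = 3)
  plan <- assemble_blocks(items, n_blocks = 4, seed = 3)
  params <- simulation_params(sd_subject = rep(0, 4), sd_item = 0,
                              sd_resid = 0, p_error = 0, p_outlier = 0,
                              n_subjects = 6)
  trials <- simulate_experiment(plan, params, seed = 5)
  word <- trials[trials$trial_type == "word", ]
  mu <- params$beta0 + params$beta_cosine * word$cosine +
    params$beta_length_target * word$length_target +
    params$beta_freq_target * word$freq_class_target +
    params$beta_length_prime * word$length_prime +
    params$beta_freq_prime * word$freq_class_prime
  expect_equal(log(word$rt), mu, tolerance = 1e-12)
  # OLS recovers all betas to machine precision
  fit <- lm(log(rt) ~ cosine + length_target + freq_class_target +
              length_prime + freq_class_prime, data = word)
  expect_equal(unname(coef(fit)),
               c(params$beta0, params$beta_cosine, params$beta_length_target,
                 params$beta_freq_target, params$beta_length_prime,
                 params$beta_freq_prime),
               tolerance = 1e-9)
})

test_that("the marginal cosine effect and error rate match their targets", {
  items <- make_item_set_direct(n_word = 100, n_nonword = 0, seed = 9)
  # put half the items at cosine 0 and half at 1 for a clean contrast
  items$word_pairs$cosine <- rep(c(0, 1), 50)
  plan <- assemble_blocks(items, n_blocks = 4, seed = 9)
  params <- simulation_params(beta_cosine = -0.05, n_subjects = 400,
                              p_error = 0.017, p_outlier = 0)
  trials <- simulate_experiment(plan, params, seed = 10)
  word <- trials[trials$trial_type == "word", ]
  diff_hat <- mean(log(word$rt[word$cosine == 1])) -
    mean(log(word$rt[word$cosine == 0]))
  # MC standard error of the contrast
  mc_se <- sqrt(var(log(word$rt)) * (2 / (nrow(word) / 2)))
  expect_lt(abs(diff_hat - (-0.05)), 2 * mc_se + 0.01)
  err <- mean(trials$accuracy == "error")
  se_err <- sqrt(0.017 * 0.983 / nrow(trials))
  expect_lt(abs(err - 0.017), 2.5 * se_err)
})

test_that("simulated log-RT variance matches the closed form", {
  items <- make_item_set_direct(n_word = 1, n_nonword = 0, seed = 13)
  items$word_pairs$cosine <- 0.4
  plan <- assemble_blocks(items, n_blocks = 1, seed = 13)
  sds <- c(0.1, 0.05, 0.004, 0.006)
  params <- simulation_params(sd_subject = sds, sd_item = 0.04,
                              sd_resid = 0.15, p_error = 0, p_outlier = 0,
                              n_subjects = 4000)
  trials <- simulate_experiment(plan, params, seed = 14)
  z <- c(1, items$word_pairs$cosine, items$word_pairs$length_target,
         items$word_pairs$freq_class_target)
  v_theory <- drop(t(z) %*% params$Sigma_S %*% z) +
    params$sd_item^2 + params$sd_resid^2
  # single item: item intercept is constant, not a variance source here
  v_theory_item_fixed <- drop(t(z) %*% params$Sigma_S %*% z) + params$sd_resid^2
  v_obs <- var(log(trials$rt))
  expect_lt(abs(v_obs - v_theory_item_fixed) / v_theory_item_fixed, 0.1)
  expect_lt(v_obs, v_theory * 1.1)
})

test_that("non-positive-definite subject covariances are rejected", {
  bad <- matrix(c(1, 2, 2, 2, 1, 2, 2, 2, 1), 3)
  expect_error(simulation_params(corr_subject = rbind(cbind(bad, 0), 0)),
               "positive semi-definite")
})
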