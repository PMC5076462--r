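#' Parameters of the reaction-time generative model
#'
#' Trial-level log reaction times for word trials follow the crossed
#' random-effects linear model the analysis assumes:
#' \deqn{\log RT_{ij} = \beta_0 + \beta_{cos} cos_i + \beta_{lT} lenT_i +
#'   \beta_{fT} fcT_i + \beta_{lP} lenP_i + \beta_{fP} fcP_i +
#'   S_j'(1, cos_i, lenT_i, fcT_i) + I_i + \epsilon_{ij}}
#' with by-subject random vector \eqn{S_j \sim MVN(0, \Sigma_S)} over
#' intercept and cosine/target-length/target-frequency slopes, item
#' intercepts \eqn{I_i \sim N(0, \sigma_I^2)} and residuals
#' \eqn{\epsilon \sim N(0, \sigma_\epsilon^2)}. Covariates enter
#' uncentered and unscaled. Nonword trials share the intercept and noise
#' structure but carry no covariate effects. Each trial is flagged as an
#' error with probability `p_error`; with probability `p_outlier` the RT
#' is replaced by a uniform draw from `outlier_range` (emulating slow
#' timeout-range responses).
#'
#' Defaults give a median RT near 600 ms, a cosine effect of -0.05 log
#' units over the full similarity range, an error rate near 1.7% and an
#' RT-outlier rate near 0.4%, with 44 subjects.
#'
#' @param beta0 Intercept on the log-ms scale.
#' @param beta_cosine,beta_length_target,beta_freq_target,beta_length_prime,beta_freq_prime
#'   Fixed-effect slopes.
#' @param sd_subject Length-4 SDs of the by-subject random effects
#'   (intercept, cosine, target-length, target-frequency slopes).
#' @param corr_subject 4x4 correlation matrix of the by-subject effects.
#' @param sd_item Item random-intercept SD.
#' @param sd_resid Residual SD.
#' @param p_error Error-trial probability.
#' @param p_outlier RT-outlier probability.
#' @param outlier_range Uniform range (ms) replacing outlier RTs.
#' @param n_subjects Number of simulated participants.
#' @return A `simulation_params` list with the assembled `Sigma_S`.
#' @export
simulation_params <- function(beta0 = 6.25, beta_cosine = -0.05,
                              beta_length_target = 0.004,
                              beta_freq_target = 0.01,
                              beta_length_prime = 0.001,
                              beta_freq_prime = 0.001,
                              sd_subject = c(0.10, 0.02, 0.003, 0.003),
                              corr_subject = diag(4),
                              sd_item = 0.04, sd_resid = 0.15,
                              p_error = 0.017, p_outlier = 0.004,
                              outlier_range = c(1501, 3000),
                              n_subjects = 44) {
  stopifnot(length(sd_subject) == 4, all(sd_subject >= 0),
            all(dim(corr_subject) == c(4, 4)),
            sd_item >= 0, sd_resid >= 0,
            length(outlier_range) == 2, outlier_range[1] < outlier_range[2])
  Sigma_S <- diag(sd_subject) %*% corr_subject %*% diag(sd_subject)
  Sigma_S <- (Sigma_S + t(Sigma_S)) / 2
  ev <- eigen(Sigma_S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-10 * max(abs(ev), 1)) {
    rlang::abort("subject random-effect covariance is not positive semi-definite")
  }
  structure(list(
    beta0 = beta0, beta_cosine = beta_cosine,
    beta_length_target = beta_length_target,
    beta_freq_target = beta_freq_target,
    beta_length_prime = beta_length_prime,
    beta_freq_prime = beta_freq_prime,
    Sigma_S = Sigma_S, sd_item = sd_item, sd_resid = sd_resid,
    p_error = assert_probability(p_error, "p_error"),
    p_outlier = assert_probability(p_outlier, "p_outlier"),
    outlier_range = as.numeric(outlier_range),
    n_subjects = assert_scalar_int(n_subjects, "n_subjects", min = 1)
  ), class = "simulation_params")
}

# Draw n samples from MVN(0, Sigma) via the (pivoted, PSD-safe) Cholesky root.
rmvn0 <- function(n, Sigma) {
  p <- nrow(Sigma)
  ch <- suppressWarnings(chol(Sigma, pivot = TRUE))
  piv <- attr(ch, "pivot")
  r <- attr(ch, "rank")
  z <- matrix(rnorm(n * p), n, p)
  out <- z[, seq_len(r), drop = FALSE] %*% ch[seq_len(r), , drop = FALSE]
  out[, order(piv), drop = FALSE]
}

#' Simulate a lexical-decision priming experiment
#'
#' Generates the trial table for `params$n_subjects` participants running
#' through a [assemble_blocks()] plan: block order follows the plan's
#' cyclic Latin-square rows (recycled over participants), within-block
#' trial order is randomized per participant, and log reaction times are
#' drawn from the generative model described in [simulation_params()].
#'
#' @param blocks A `block_plan` from [assemble_blocks()]; its `trials`
#'   table must carry the item covariates (as produced by
#'   [generate_item_set()]).
#' @param params A [simulation_params()] object.
#' @param seed Integer seed.
#' @return A trial tibble with columns `subject`, `item`, `prime`,
#'   `target`, `trial_type`, `block`, `trial_in_block`, `rt`, `accuracy`
#'   (`"correct"`/`"error"`), `cosine`, `length_target`,
#'   `freq_class_target`, `length_prime`, `freq_class_prime`.
#' @export
simulate_experiment <- function(blocks, params = simulation_params(), seed = 1L) {
  stopifnot(inherits(blocks, "block_plan"), inherits(params, "simulation_params"))
  items <- blocks$trials
  n_items <- nrow(items)
  n_subj <- params$n_subjects
  with_seed(seed, {
    S <- rmvn0(n_subj, params$Sigma_S)
    I <- rnorm(n_items, 0, params$sd_item)
    word <- items$trial_type == "word"
    mu_item <- ifelse(word,
      params$beta0 +
        params$beta_cosine * items$cosine +
        params$beta_length_target * items$length_target +
        params$beta_freq_target * items$freq_class_target +
        params$beta_length_prime * items$length_prime +
        params$beta_freq_prime * items$freq_class_prime,
      params$beta0)
    z_cos <- ifelse(word, items$cosine, 0)
    z_lt <- ifelse(word, items$length_target, 0)
    z_ft <- ifelse(word, items$freq_class_target, 0)

    out <- purrr::map(seq_len(n_subj), function(j) {
      order_row <- blocks$participant_orders[((j - 1L) %% nrow(blocks$participant_orders)) + 1L, ]
      idx <- unlist(lapply(order_row, function(b) {
        bi <- which(items$block == b)
        bi[sample.int(length(bi))]
      }), use.names = FALSE)
      log_rt <- mu_item[idx] + I[idx] +
        S[j, 1] + S[j, 2] * z_cos[idx] + S[j, 3] * z_lt[idx] + S[j, 4] * z_ft[idx] +
        rnorm(length(idx), 0, params$sd_resid)
      rt <- exp(log_rt)
      is_out <- runif(length(idx)) < params$p_outlier
      rt[is_out] <- runif(sum(is_out), params$outlier_range[1], params$outlier_range[2])
      tibble(
        subject = paste0("s", j),
        item = items$item[idx],
        prime = items$prime[idx], target = items$target[idx],
        trial_type = items$trial_type[idx],
        block = items$block[idx],
        trial_in_block = unlist(lapply(order_row, function(b) seq_len(sum(items$block == b))), use.names = FALSE),
        rt = rt,
        accuracy = ifelse(runif(length(idx)) < params$p_error, "error", "correct"),
        cosine = items$cosine[idx],
        length_target = items$length_target[idx],
        freq_class_target = items$freq_class_target[idx],
        length_prime = items$length_prime[idx],
        freq_class_prime = items$freq_class_prime[idx]
      )
    })
    dplyr::bind_rows(out)
  })
}
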