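#' Model specifications for the priming analysis
#'
#' `baseline_spec()` is the per-experiment baseline: fixed effects for
#' prime and target lengths and frequency classes, random intercepts for
#' subjects and items, and by-subject random slopes for target length,
#' target frequency *and the similarity predictor itself* (the predictor
#' slope is in the random structure before its fixed effect is tested).
#' `pooled_spec()` replaces the item intercept with crossed random
#' intercepts for primes and for targets (no by-target slopes).
#'
#' @param predictor Similarity predictor column (default `"cosine"`).
#' @return An [lmem_spec()].
#' @export
baseline_spec <- function(predictor = "cosine") {
  lmem_spec(
    response = "log_rt",
    fixed = c("length_target", "freq_class_target",
              "length_prime", "freq_class_prime"),
    random = list(
      subject = c(predictor, "length_target", "freq_class_target"),
      item = character(0)
    )
  )
}

#' @rdname baseline_spec
#' @export
pooled_spec <- function(predictor = "cosine") {
  lmem_spec(
    response = "log_rt",
    fixed = c("length_target", "freq_class_target",
              "length_prime", "freq_class_prime"),
    random = list(
      subject = c(predictor, "length_target", "freq_class_target"),
      prime = character(0),
      target = character(0)
    )
  )
}

#' Run the similarity-predictor analysis on one experiment
#'
#' Fits the baseline model and the baseline plus a fixed effect for the
#' similarity predictor, compares them with a likelihood-ratio test,
#' computes the predictor's Wald confidence interval, and assembles
#' per-item mean RTs with the exponentiated model-predicted RT curve
#' over the predictor range (other covariates held at their means).
#'
#' @param trials Preprocessed trial tibble (see [preprocess_trials()]);
#'   must contain `log_rt`.
#' @param predictor Similarity predictor column (default `"cosine"`).
#' @param level Confidence level for the Wald interval.
#' @param spec Baseline [lmem_spec()]; defaults to [baseline_spec()].
#' @param ... Passed to [fit_lmem()].
#' @return A `priming_analysis`: list with `baseline`, `full` (both
#'   `lmem_fit`), `lrt`, `ci`, `model_comparison`, `item_means`,
#'   `predicted_curve`, and `predictor`.
#' @export
run_experiment_analysis <- function(trials, predictor = "cosine",
                                    level = 0.95,
                                    spec = baseline_spec(predictor), ...) {
  baseline <- fit_lmem(trials, spec, ...)
  full <- fit_lmem(trials, add_fixed_term(spec, predictor), ...)
  lrt <- likelihood_ratio_test(baseline, full)
  est <- full$estimates[full$estimates$term == predictor, ]
  ci <- wald_ci(est$estimate, est$se, level = level)
  comparison <- dplyr::bind_rows(
    dplyr::mutate(glance(baseline), model = "baseline"),
    dplyr::mutate(glance(full), model = paste0("baseline+", predictor))
  ) |>
    dplyr::select("model", "k", "logLik", "AIC", "nobs", "singular")
  item_means <- trials |>
    dplyr::summarise(
      mean_rt = mean(.data$rt),
      predictor_value = .data[[predictor]][1],
      n_trials = dplyr::n(),
      .by = "item"
    )
  grid <- seq(min(trials[[predictor]]), max(trials[[predictor]]), length.out = 101)
  beta <- setNames(full$estimates$estimate, full$estimates$term)
  eta0 <- beta[["(Intercept)"]] +
    sum(vapply(setdiff(names(beta), c("(Intercept)", predictor)),
               function(v) beta[[v]] * mean(trials[[v]]), numeric(1)))
  predicted_curve <- tibble(
    !!predictor := grid,
    predicted_log_rt = eta0 + beta[[predictor]] * grid,
    predicted_rt = exp(eta0 + beta[[predictor]] * grid)
  )
  structure(list(
    baseline = baseline, full = full, lrt = lrt, ci = ci,
    model_comparison = comparison, item_means = item_means,
    predicted_curve = predicted_curve, predictor = predictor
  ), class = "priming_analysis")
}

#' Pooled analysis across two experiments
#'
#' Concatenates the two preprocessed trial tables (subject labels are
#' disambiguated by experiment), replaces the single item random
#' intercept with crossed random intercepts for primes and targets (the
#' same targets recur across experiments with different primes), keeps
#' the by-subject random slopes, and otherwise proceeds as
#' [run_experiment_analysis()]. The model-comparison table reports AIC
#' and log-likelihood for both models.
#'
#' @param trials_exp1,trials_exp2 Preprocessed trial tibbles.
#' @inheritParams run_experiment_analysis
#' @return A `priming_analysis` (see [run_experiment_analysis()]).
#' @export
pooled_analysis <- function(trials_exp1, trials_exp2, predictor = "cosine",
                            level = 0.95, ...) {
  pooled <- dplyr::bind_rows(
    dplyr::mutate(trials_exp1, experiment = "exp1"),
    dplyr::mutate(trials_exp2, experiment = "exp2")
  ) |>
    dplyr::mutate(subject = paste(.data$experiment, .data$subject, sep = ":"),
                  item = paste(.data$experiment, .data$item, sep = ":"))
  run_experiment_analysis(pooled, predictor = predictor, level = level,
                          spec = pooled_spec(predictor), ...)
}

#' @export
print.priming_analysis <- function(x, ...) {
  cat(sprintf("<priming_analysis: predictor '%s'>\n", x$predictor))
  print(x$model_comparison)
  cat(sprintf("LRT: chisq(%d) = %.2f, p = %.3f\n",
              x$lrt$df, x$lrt$chisq, x$lrt$p_value))
  cat(sprintf("%s: beta = %.3f (t = %.2f), %.2f-Wald-CI [%.3f, %.3f]\n",
              x$predictor, x$ci$estimate, x$ci$estimate / x$ci$se,
              x$ci$level, x$ci$lower, x$ci$upper))
  invisible(x)
}

#' Correlate item-set cosines with an alternative similarity measure
#'
#' Pearson correlation, across the word-trial item pairs, between the
#' cosines stored in the item set and a second set of cosines for the
#' same prime-target pairs (e.g. from a space built with the other
#' model).
#'
#' @param items An `item_set` or its `word_pairs` tibble.
#' @param other_cosines Either a function `(prime, target) -> cosine`, a
#'   data frame with columns `prime`, `target`, `cosine`, or a numeric
#'   vector aligned with the word pairs.
#' @return A single Pearson `r`; `NA` with a warning if either cosine set
#'   has zero variance.
#' @export
cosine_correlation <- function(items, other_cosines) {
  pairs <- if (inherits(items, "item_set")) items$word_pairs else as_tibble(items)
  x <- pairs$cosine
  y <- if (is.function(other_cosines)) {
    purrr::map2_dbl(pairs$prime, pairs$target, other_cosines)
  } else if (is.data.frame(other_cosines)) {
    dplyr::left_join(pairs[, c("prime", "target")],
                     other_cosines[, c("prime", "target", "cosine")],
                     by = c("prime", "target"))$cosine
  } else {
    as.numeric(other_cosines)
  }
  if (length(y) != length(x)) rlang::abort("cosine sets have different lengths")
  if (anyNA(y)) rlang::abort("other_cosines is undefined for some word pairs")
  if (sd(x) == 0 || sd(y) == 0) {
    rlang::warn("cosine correlation undefined: zero variance in a cosine set")
    return(NA_real_)
  }
  cor(x, y)
}
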