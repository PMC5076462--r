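#' Specify a linear mixed-effects model
#'
#' A declarative model specification: a response, fixed-effect
#' covariates, and per-grouping-factor random structures (random
#' intercept plus optional slope covariates with a full unstructured
#' covariance). Estimation is by maximum likelihood (not REML) so that
#' likelihood-ratio tests on fixed effects are valid.
#'
#' The per-experiment baseline of the priming analysis is
#' `lmem_spec(fixed = c("length_target", "freq_class_target",
#' "length_prime", "freq_class_prime"), random = list(subject =
#' c("cosine", "length_target", "freq_class_target"), item = character()))`
#' -- note the by-subject cosine random slope is present *before* any
#' cosine fixed effect is tested.
#'
#' @param response Response column (default `"log_rt"`).
#' @param fixed Character vector of fixed-effect covariates (may be empty
#'   for an intercept-only fixed part).
#' @param random Named list: names are grouping factors, values are
#'   character vectors of random-slope covariates (empty vector =
#'   intercept only).
#' @return An `lmem_spec` object.
#' @export
lmem_spec <- function(response = "log_rt", fixed = character(),
                      random = list()) {
  stopifnot(is.character(fixed), is.list(random), length(random) > 0,
            !is.null(names(random)), all(nzchar(names(random))))
  structure(list(response = response, fixed = fixed, random = random),
            class = "lmem_spec")
}

#' @export
format.lmem_spec <- function(x, ...) spec_formula_text(x)

spec_formula_text <- function(spec) {
  fixed <- if (length(spec$fixed) > 0) paste(spec$fixed, collapse = " + ") else "1"
  rand <- vapply(names(spec$random), function(g) {
    slopes <- spec$random[[g]]
    inner <- if (length(slopes) > 0) paste(c("1", slopes), collapse = " + ") else "1"
    sprintf("(%s | %s)", inner, g)
  }, character(1))
  paste(spec$response, "~", paste(c(fixed, rand), collapse = " + "))
}

#' Add a fixed-effect term to a specification
#'
#' @param spec An [lmem_spec()].
#' @param term Covariate to append to the fixed part.
#' @return The augmented `lmem_spec`.
#' @export
add_fixed_term <- function(spec, term) {
  stopifnot(inherits(spec, "lmem_spec"))
  if (term %in% spec$fixed) rlang::abort(sprintf("'%s' is already a fixed term", term))
  spec$fixed <- c(spec$fixed, term)
  spec
}

#' Fit a linear mixed-effects model
#'
#' Maximum-likelihood fit of an [lmem_spec()] via `lme4::lmer`. By
#' default the numeric covariates are standardized internally before
#' fitting and all reported quantities are back-transformed to the
#' original covariate scale; because every random part uses a full
#' unstructured covariance, standardization is an exact affine
#' reparameterization (the maximized likelihood, AIC and parameter count
#' are invariant) that markedly improves the conditioning and speed of
#' the covariance optimization. Reported fixed effects, their
#' covariance, and the random-effect covariance matrices are always on
#' the original scale.
#'
#' Singular (boundary) fits are flagged; with
#' `singular_action = "refit_diagonal"` a singular fit is refitted on the
#' raw covariate scale with independent (diagonal-covariance) random
#' effects, and the result is flagged as the fallback.
#'
#' @param data Trial tibble containing the response, covariates and
#'   grouping factors.
#' @param spec An [lmem_spec()].
#' @param scale_covariates Standardize covariates internally (default
#'   `TRUE`).
#' @param singular_action `"flag"` (default) or `"refit_diagonal"`.
#' @param start Optional random-effect parameter (theta) starting values,
#'   e.g. `theta(previous_fit)`; warm starts speed up replication loops
#'   over a fixed design substantially without changing the optimum.
#' @param opt_tol Optional absolute x/f stopping tolerance handed to the
#'   optimizer (default: lme4's own defaults).
#' @return An `lmem_fit`: list with `estimates` (tibble `term`,
#'   `estimate`, `se`, `t`), `vcov_fixed`, `varcor` (per-group covariance
#'   matrices on the original scale plus `residual_sd`), `logLik`, `k`
#'   (parameter count), `AIC`, `n_obs`, `singular`, `converged`,
#'   `diagonal_fallback`, the fitted `model` and the `spec`.
#' @export
fit_lmem <- function(data, spec, scale_covariates = TRUE,
                     singular_action = c("flag", "refit_diagonal"),
                     start = NULL, opt_tol = NULL) {
  stopifnot(inherits(spec, "lmem_spec"))
  singular_action <- match.arg(singular_action)
  covars <- unique(c(spec$fixed, unlist(spec$random, use.names = FALSE)))
  needed <- unique(c(spec$response, covars, names(spec$random)))
  missing <- setdiff(needed, names(data))
  if (length(missing) > 0) {
    rlang::abort(paste0("data lacks columns: ", paste(missing, collapse = ", ")))
  }
  for (g in names(spec$random)) {
    if (length(unique(data[[g]])) < 2) {
      rlang::abort(sprintf("grouping factor '%s' needs >= 2 levels", g))
    }
  }
  df <- as_tibble(data)[, needed]
  df <- df[complete.cases(df), ]

  scaled <- covars[vapply(covars, function(v) is.numeric(df[[v]]) &&
                            sd(df[[v]]) > 0, logical(1))]
  if (!scale_covariates) scaled <- character(0)
  centers <- vapply(scaled, function(v) mean(df[[v]]), numeric(1))
  scales <- vapply(scaled, function(v) sd(df[[v]]), numeric(1))
  for (v in scaled) df[[v]] <- (df[[v]] - centers[[v]]) / scales[[v]]

  opt_ctrl <- if (is.null(opt_tol)) list() else {
    list(xtol_abs = opt_tol, ftol_abs = opt_tol)
  }
  ctrl <- lme4::lmerControl(calc.derivs = FALSE,
                            check.conv.singular = "ignore",
                            optCtrl = opt_ctrl)
  fml <- stats::as.formula(spec_formula_text(spec))
  lmer_args <- list(formula = fml, data = df, REML = FALSE, control = ctrl)
  if (!is.null(start)) lmer_args$start <- start
  model <- withCallingHandlers(
    do.call(lme4::lmer, lmer_args),
    message = function(m) {
      if (grepl("boundary \\(singular\\)", conditionMessage(m))) {
        invokeRestart("muffleMessage")
      }
    }
  )
  singular <- lme4::isSingular(model)
  diagonal_fallback <- FALSE
  if (singular && singular_action == "refit_diagonal") {
    fml_d <- stats::as.formula(gsub("| ", "|| ", spec_formula_text(spec), fixed = TRUE))
    df_raw <- as_tibble(data)[, needed]
    df_raw <- df_raw[complete.cases(df_raw), ]
    model <- withCallingHandlers(
      lme4::lmer(fml_d, data = df_raw, REML = FALSE, control = ctrl),
      message = function(m) invokeRestart("muffleMessage")
    )
    scaled <- character(0); centers <- numeric(0); scales <- numeric(0)
    diagonal_fallback <- TRUE
    singular <- lme4::isSingular(model)
  }

  beta_std <- lme4::fixef(model)
  V_std <- as.matrix(vcov(model))
  K <- backtransform_matrix(names(beta_std), scaled, centers, scales)
  beta <- drop(K %*% beta_std)
  names(beta) <- names(beta_std)
  V <- K %*% V_std %*% t(K)
  dimnames(V) <- list(names(beta), names(beta))
  se <- sqrt(diag(V))

  vc_std <- lme4::VarCorr(model)
  varcor <- purrr::imap(as.list(vc_std), function(m, g) {
    m <- as.matrix(m)[, , drop = FALSE]
    M <- backtransform_matrix(rownames(m), scaled, centers, scales)
    out <- M %*% m %*% t(M)
    dimnames(out) <- dimnames(m)
    out
  })
  varcor$residual_sd <- attr(vc_std, "sc")

  ll <- logLik(model)
  k <- attr(ll, "df")
  opt <- model@optinfo
  fit <- structure(list(
    estimates = tibble(term = names(beta), estimate = unname(beta),
                       se = unname(se), t = unname(beta / se)),
    vcov_fixed = V, varcor = varcor,
    logLik = as.numeric(ll), k = as.integer(k),
    AIC = 2 * k - 2 * as.numeric(ll),
    n_obs = nrow(model@frame),
    response_checksum = response_checksum(model),
    singular = singular,
    converged = length(opt$conv$lme4$messages %||% character(0)) == 0 &&
      (opt$conv$opt %||% 0) == 0,
    diagonal_fallback = diagonal_fallback,
    model = model, spec = spec,
    scaling = list(centers = centers, scales = scales)
  ), class = "lmem_fit")
  fit
}

# Linear map sending coefficients estimated on standardized covariates
# back to the original scale; `terms` are coefficient names including
# "(Intercept)".
backtransform_matrix <- function(terms, scaled, centers, scales) {
  p <- length(terms)
  K <- diag(p)
  dimnames(K) <- list(terms, terms)
  for (v in intersect(terms, scaled)) {
    K[v, v] <- 1 / scales[[v]]
    if ("(Intercept)" %in% terms) {
      K["(Intercept)", v] <- -centers[[v]] / scales[[v]]
    }
  }
  K
}

response_checksum <- function(model) {
  y <- stats::model.response(stats::model.frame(model))
  c(n = length(y), sum = sum(y), ss = sum(y^2))
}

#' @export
print.lmem_fit <- function(x, ...) {
  cat(sprintf("<lmem_fit: %s>\n", spec_formula_text(x$spec)))
  cat(sprintf("  ML logLik = %.2f, k = %d, AIC = %.2f, n = %d%s%s\n",
              x$logLik, x$k, x$AIC, x$n_obs,
              if (x$singular) " [singular]" else "",
              if (x$diagonal_fallback) " [diagonal fallback]" else ""))
  print(x$estimates)
  invisible(x)
}

#' @rdname fit_lmem
#' @param x An `lmem_fit`.
#' @param ... Unused.
#' @method tidy lmem_fit
#' @export
tidy.lmem_fit <- function(x, ...) x$estimates

#' Random-effect parameter vector of a fit (for warm starts)
#'
#' @param fit An `lmem_fit`.
#' @return The fitted theta vector, suitable as `start` in [fit_lmem()].
#' @export
theta <- function(fit) lme4::getME(fit$model, "theta")

#' @rdname fit_lmem
#' @method glance lmem_fit
#' @export
glance.lmem_fit <- function(x, ...) {
  tibble(logLik = x$logLik, k = x$k, AIC = x$AIC, nobs = x$n_obs,
         sigma = x$varcor$residual_sd, singular = x$singular,
         converged = x$converged)
}

#' Likelihood-ratio test of two nested ML fits
#'
#' \eqn{\chi^2 = 2(\log L_{full} - \log L_{reduced})} (clamped at zero),
#' with degrees of freedom equal to the parameter-count difference and an
#' upper-tail \eqn{\chi^2} p-value. Both fits must be ML fits of nested
#' specifications on identical data.
#'
#' @param reduced,full `lmem_fit` objects, reduced nested in full.
#' @return A tibble with `chisq`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(reduced, full) {
  stopifnot(inherits(reduced, "lmem_fit"), inherits(full, "lmem_fit"))
  if (!all(reduced$spec$fixed %in% full$spec$fixed)) {
    rlang::abort("models are not nested: reduced fixed terms are not a subset")
  }
  same_data <- isTRUE(all.equal(reduced$response_checksum,
                                full$response_checksum, tolerance = 1e-8))
  if (!same_data) rlang::abort("fits are not on identical data")
  df <- full$k - reduced$k
  if (df < 0) rlang::abort("full model has fewer parameters than reduced model")
  chisq <- max(0, 2 * (full$logLik - reduced$logLik))
  p <- if (df == 0) {
    if (chisq <= 1e-10) 1 else NA_real_
  } else {
    pchisq(chisq, df = df, lower.tail = FALSE)
  }
  tibble(chisq = chisq, df = as.integer(df), p_value = p)
}

#' Likelihood-ratio statistics from log-likelihoods
#'
#' Convenience forms of the model-comparison arithmetic for reproducing
#' published statistics from reported quantities:
#' `lrt_from_chisq()` evaluates the upper-tail \eqn{\chi^2} probability
#' of a reported test statistic, `lrt_from_loglik()` first forms
#' \eqn{\chi^2 = 2\,\Delta\log L}, and `aic_from_loglik()` computes
#' \eqn{AIC = 2k - 2\log L}.
#'
#' @param chisq Test statistic.
#' @param logL_reduced,logL_full Maximized log-likelihoods of nested fits.
#' @param df Degrees of freedom (parameter-count difference).
#' @param logL Maximized log-likelihood.
#' @param k Number of free parameters.
#' @return `lrt_*`: a tibble with `chisq`, `df`, `p_value`;
#'   `aic_from_loglik`: a number.
#' @examples
#' lrt_from_chisq(8.15, df = 1) # p = 0.004
#' aic_from_loglik(3425, k = 19) # -6812
#' @export
lrt_from_chisq <- function(chisq, df = 1) {
  stopifnot(chisq >= 0, df >= 1)
  tibble(chisq = chisq, df = as.integer(df),
         p_value = pchisq(chisq, df = df, lower.tail = FALSE))
}

#' @rdname lrt_from_chisq
#' @export
lrt_from_loglik <- function(logL_reduced, logL_full, df = 1) {
  lrt_from_chisq(max(0, 2 * (logL_full - logL_reduced)), df = df)
}

#' @rdname lrt_from_chisq
#' @export
aic_from_loglik <- function(logL, k) 2 * k - 2 * logL

#' Wald confidence interval
#'
#' `estimate +/- z * se` with `z` the standard-normal quantile at
#' `(1 + level) / 2` (1.959964 at the default 0.95 level), two-sided.
#'
#' @param estimate Point estimate.
#' @param se Standard error (> 0).
#' @param level Confidence level in (0, 1).
#' @return A tibble with `estimate`, `se`, `level`, `lower`, `upper`.
#' @examples
#' wald_ci(-0.056, 0.056 / 2.88) # reproduces a printed 0.95 interval
#' @export
wald_ci <- function(estimate, se, level = 0.95) {
  if (!is.numeric(level) || length(level) != 1 || level <= 0 || level >= 1) {
    rlang::abort("level must be in (0, 1)")
  }
  stopifnot(is.numeric(se), se > 0)
  z <- qnorm((1 + level) / 2)
  tibble(estimate = estimate, se = se, level = level,
         lower = estimate - z * se, upper = estimate + z * se)
}
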