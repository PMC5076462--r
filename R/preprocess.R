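#' Trial-exclusion configuration
#'
#' Reference settings: participants and items with error rates above 25%
#' are removed, then error trials, then trials with reaction times under
#' 100 ms or over 1500 ms (bounds exclusive, i.e. RTs in \[100, 1500\]
#' are kept).
#'
#' @param error_rate_threshold Proportion of errors above which a subject
#'   or item is dropped (strictly greater-than).
#' @param rt_min,rt_max RT window in ms.
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(error_rate_threshold = 0.25,
                              rt_min = 100, rt_max = 1500) {
  stopifnot(error_rate_threshold > 0, error_rate_threshold < 1,
            rt_min < rt_max)
  structure(list(error_rate_threshold = error_rate_threshold,
                 rt_min = rt_min, rt_max = rt_max),
            class = "preprocess_config")
}

#' Preprocess a trial table for analysis
#'
#' Pipeline, in order: (1) keep word trials only; (2) drop subjects, then
#' items, whose word-trial error rate exceeds the threshold; (3) drop
#' error trials; (4) drop trials with RT outside \[`rt_min`, `rt_max`\]
#' (the percentage is reported on the post-error-exclusion base); (5) add
#' a natural-log RT column `log_rt`. Counts and percentages at each step
#' are returned alongside the cleaned table.
#'
#' @param trials Trial tibble from [simulate_experiment()] (or the same
#'   layout read with [read_trials()]).
#' @param config A [preprocess_config()].
#' @return A list with `trials` (cleaned tibble with `log_rt`) and
#'   `exclusions` (tibble `step`, `n_before`, `n_removed`, `pct_removed`).
#' @export
preprocess_trials <- function(trials, config = preprocess_config()) {
  stopifnot(is.data.frame(trials))
  steps <- list()
  note <- function(step, before, after) {
    steps[[length(steps) + 1]] <<- tibble(
      step = step, n_before = before, n_removed = before - after,
      pct_removed = if (before > 0) 100 * (before - after) / before else NA_real_
    )
    if (after == 0) {
      rlang::abort(sprintf("no trials remain after preprocessing step '%s'", step))
    }
  }

  n0 <- nrow(trials)
  word <- dplyr::filter(trials, .data$trial_type == "word")
  note("word_trials_only", n0, nrow(word))

  err_rate <- function(df, by) {
    df |>
      dplyr::summarise(rate = mean(.data$accuracy == "error"),
                       .by = dplyr::all_of(by))
  }
  bad_subj <- err_rate(word, "subject") |>
    dplyr::filter(.data$rate > config$error_rate_threshold)
  w1 <- dplyr::anti_join(word, bad_subj, by = "subject")
  bad_item <- err_rate(w1, "item") |>
    dplyr::filter(.data$rate > config$error_rate_threshold)
  w2 <- dplyr::anti_join(w1, bad_item, by = "item")
  note("high_error_subjects_items", nrow(word), nrow(w2))

  w3 <- dplyr::filter(w2, .data$accuracy == "correct")
  note("error_trials", nrow(w2), nrow(w3))

  w4 <- dplyr::filter(w3, .data$rt >= config$rt_min, .data$rt <= config$rt_max)
  note("rt_out_of_range", nrow(w3), nrow(w4))

  list(
    trials = dplyr::mutate(w4, log_rt = log(.data$rt)),
    exclusions = dplyr::bind_rows(steps),
    dropped_subjects = bad_subj$subject,
    dropped_items = bad_item$item
  )
}
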