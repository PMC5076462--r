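#' Generate a synthetic lexicon
#'
#' Builds `vocab_size` pronounceable content words plus
#' `n_function_words` short function words. Content-word frequencies
#' follow a Zipf law with exponent `zipf_exponent`, scaled so the summed
#' frequencies match the corpus's content-token budget; function-word
#' frequencies share the function-token budget. Frequency classes are
#' computed from the frequencies (Leipzig convention,
#' [frequency_class()]); lengths are drawn mostly in the 4-9 letter range
#' and concrete-noun flags with probability `concrete_prob`, so that the
#' stimulus constraint sets (target pool and primes) are satisfiable with
#' a wide margin. Latent ring categories are assigned to content words
#' round-robin over frequency rank, and a fraction of within-category
#' pairs is designated near-synonymous.
#'
#' @param config A [generator_config()].
#' @param check_feasibility Error if the lexicon cannot supply the
#'   reference pool sizes (300 target-pool words, ample primes). Disable
#'   for deliberately degenerate configurations.
#' @return A tibble with columns `word`, `frequency`, `frequency_class`,
#'   `length`, `is_concrete_noun`, `is_function`, `category`,
#'   `synonym_of` (`NA` where unpaired).
#' @export
generate_lexicon <- function(config, check_feasibility = TRUE) {
  stopifnot(inherits(config, "generator_config"))
  V <- config$vocab_size
  total_tokens <- config$n_docs * config$sentences_per_doc * config$tokens_per_sentence
  content_budget <- round(total_tokens * (1 - config$function_word_rate))
  function_budget <- total_tokens - content_budget

  with_seed(stage_seed(config$seed, "lexicon"), {
    lengths <- sample(3:12, V, replace = TRUE,
                      prob = c(.01, .18, .19, .19, .17, .13, .07, .03, .02, .01))
    words <- make_word_forms(lengths)
    fn_words <- make_word_forms(sample(2:3, config$n_function_words, replace = TRUE),
                                forbidden = words)

    w <- seq_len(V)^(-config$zipf_exponent)
    freq <- pmax(1L, as.integer(round(content_budget * w / sum(w))))
    wf <- (seq_len(config$n_function_words))^(-1)
    freq_fn <- pmax(1L, as.integer(round(function_budget * wf / sum(wf))))

    category <- ((seq_len(V) - 1L) %% config$n_categories) + 1L
    synonym_of <- rep(NA_character_, V)
    n_pairs <- floor(config$synonym_fraction * V / 2)
    if (n_pairs > 0) {
      # pair words within a category so partners share a context profile
      by_cat <- split(seq_len(V), category)
      pairable <- purrr::list_c(purrr::map(by_cat, function(ix) {
        ix <- resample(ix)
        ix[seq_len(2 * (length(ix) %/% 2))]
      }))
      take <- pairable[seq_len(2 * n_pairs)]
      first <- take[seq(1, length(take), by = 2)]
      second <- take[seq(2, length(take), by = 2)]
      synonym_of[first] <- words[second]
      synonym_of[second] <- words[first]
    }

    lex <- dplyr::bind_rows(
      tibble(
        word = words, frequency = freq,
        length = as.integer(nchar(words)),
        is_concrete_noun = runif(V) < config$concrete_prob,
        is_function = FALSE, category = category, synonym_of = synonym_of
      ),
      tibble(
        word = fn_words, frequency = freq_fn,
        length = as.integer(nchar(fn_words)),
        is_concrete_noun = FALSE, is_function = TRUE,
        category = NA_integer_, synonym_of = NA_character_
      )
    ) |>
      dplyr::mutate(frequency_class = frequency_class(.data$frequency)) |>
      dplyr::arrange(dplyr::desc(.data$frequency), .data$word) |>
      dplyr::select("word", "frequency", "frequency_class", "length",
                    "is_concrete_noun", "is_function", "category", "synonym_of")
    if (check_feasibility) check_lexicon_feasibility(lex)
    lex
  })
}

# Pronounceable unique word forms: alternating consonant-vowel strings of
# the requested lengths.
make_word_forms <- function(lengths, forbidden = character()) {
  vowels <- strsplit("aeiou", "")[[1]]
  consonants <- setdiff(letters, vowels)
  out <- character(length(lengths))
  seen <- c(forbidden)
  for (i in seq_along(lengths)) {
    for (try in 1:10000) {
      L <- lengths[i]
      chars <- ifelse(seq_len(L) %% 2 == 1,
                      consonants[sample.int(21, L, replace = TRUE)],
                      vowels[sample.int(5, L, replace = TRUE)])
      w <- paste(chars, collapse = "")
      if (!(w %in% seen)) break
      if (try == 10000) rlang::abort("could not generate unique word forms")
    }
    out[i] <- w
    seen <- c(seen, w)
  }
  out
}

check_lexicon_feasibility <- function(lex, n_pool = 300) {
  n_targets_ok <- nrow(eligible_words(lex, target_constraints()))
  n_primes_ok <- nrow(eligible_words(lex, prime_constraints()))
  if (n_targets_ok < n_pool) {
    rlang::abort(sprintf(
      "lexicon infeasible: only %d words satisfy the target-pool constraints (need >= %d)",
      n_targets_ok, n_pool))
  }
  if (n_primes_ok < 2 * n_pool) {
    rlang::abort(sprintf(
      "lexicon infeasible: only %d prime-eligible words (need >= %d)",
      n_primes_ok, 2 * n_pool))
  }
  invisible(lex)
}
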