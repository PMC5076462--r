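#' Build a frequency-ranked vocabulary from a corpus
#'
#' Tallies raw token counts over all tokens (content and function words
#' alike) and keeps the `cap` most frequent surface forms. Frequency ties
#' are broken lexicographically so the ranking is deterministic. Tokens are
#' case-sensitive and not lemmatized.
#'
#' @param corpus A [tok_corpus()] tibble.
#' @param cap Maximum vocabulary size (>= 1).
#' @return A tibble with columns `word`, `freq`, `rank` ordered by
#'   non-increasing frequency; `rank` runs `1..n`.
#' @examples
#' corp <- tok_corpus(doc = c(1, 1, 1), sentence = c(1, 1, 1), pos = 1:3,
#'                    token = c("a", "a", "b"), is_content = TRUE)
#' build_vocabulary(corp, cap = 10)
#' @export
build_vocabulary <- function(corpus, cap) {
  corpus <- validate_corpus(corpus)
  cap <- assert_scalar_int(cap, "cap", min = 1)
  if (nrow(corpus) == 0) rlang::abort("cannot build a vocabulary from an empty corpus")
  corpus |>
    dplyr::count(word = .data$token, name = "freq") |>
    dplyr::arrange(dplyr::desc(.data$freq), .data$word) |>
    head(cap) |>
    dplyr::mutate(freq = as.integer(.data$freq), rank = dplyr::row_number())
}

#' Leipzig-style frequency class
#'
#' `round(log2(f_max / f))`, with `f_max` the frequency of the corpus's most
#' frequent word: class 0 is the top word, and each unit step marks a
#' halving of frequency.
#'
#' @param freq Vector of raw word frequencies (> 0).
#' @param f_max Frequency of the most frequent word; defaults to `max(freq)`.
#' @return Integer frequency classes (>= 0).
#' @examples
#' frequency_class(c(1000, 500, 30), f_max = 1000)
#' @export
frequency_class <- function(freq, f_max = max(freq)) {
  stopifnot(is.numeric(freq), all(freq > 0), f_max >= max(freq))
  as.integer(round(log2(f_max / freq)))
}
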