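#' Generate pronounceable nonword targets
#'
#' A length-matched stand-in for phonotactic nonword generators: each
#' nonword is built by sampling a reference word and replacing every
#' letter with a random letter of the same class (consonants with
#' consonants, vowels with vowels), preserving the consonant/vowel
#' pattern and the exact length. Strings colliding with any lexicon word,
#' with a reference word, or with an already-generated nonword are
#' rejected and redrawn. Because lengths are inherited from the sampled
#' reference words, the nonword length distribution matches the reference
#' distribution by construction.
#'
#' @param n Number of nonwords (>= 0).
#' @param length_range Inclusive length bounds; reference words outside
#'   the range are not used as patterns.
#' @param reference_words Words whose lengths/patterns the nonwords mimic
#'   (typically the target words).
#' @param lexicon Lexicon tibble used for collision checks (optional).
#' @param seed Integer seed; the list is reproducible given the seed.
#' @param max_retries Bounded rejection-sampling budget per nonword.
#' @return Character vector of `n` nonwords.
#' @export
generate_nonwords <- function(n, length_range = c(4, 10), reference_words,
                              lexicon = NULL, seed = 1L, max_retries = 1000) {
  n <- assert_scalar_int(n, "n", min = 0)
  if (n == 0) return(character())
  vowels <- strsplit("aeiou", "")[[1]]
  consonants <- setdiff(letters, vowels)
  refs <- reference_words[nchar(reference_words) >= length_range[1] &
                            nchar(reference_words) <= length_range[2]]
  if (length(refs) == 0) rlang::abort("no reference words within length_range")
  forbidden <- tolower(c(reference_words,
                         if (!is.null(lexicon)) lexicon$word else character()))
  with_seed(seed, {
    out <- character(0)
    tries <- 0
    while (length(out) < n) {
      tries <- tries + 1
      if (tries > max_retries * n) {
        rlang::abort("could not generate collision-free nonwords within the retry budget")
      }
      pattern <- strsplit(tolower(refs[sample.int(length(refs), 1)]), "")[[1]]
      candidate <- paste(vapply(pattern, function(ch) {
        if (ch %in% vowels) vowels[sample.int(5, 1)]
        else consonants[sample.int(21, 1)]
      }, character(1)), collapse = "")
      if (!(candidate %in% forbidden) && !(candidate %in% out)) {
        out <- c(out, candidate)
      }
    }
    out
  })
}
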