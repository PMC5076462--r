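#' Configuration of the synthetic lexicon and corpus generator
#'
#' The generator emulates, at desk scale, the statistical features the
#' space-building and item-generation machinery relies on: a Zipfian
#' vocabulary whose frequency classes span the stimulus constraint ranges,
#' and documents with latent-category co-occurrence structure whose
#' derived spaces yield cosines spanning all ten similarity classes.
#'
#' Content words belong to one of `n_categories` latent categories
#' arranged on a ring. Each document samples one category uniformly and,
#' with probability `mix_prob`, a second category at ring distance `d`
#' drawn with geometrically decaying probability (`mix_decay^d`). Content
#' tokens are drawn from the document's categories with
#' frequency-proportional probability, interleaved with high-frequency
#' function words marked non-content. Ring distance thus translates into
#' a graded co-occurrence signal, which the PPMI+SVD spaces turn into
#' cosines covering the full \[0, 1\] range; a fraction of within-category
#' word pairs is designated near-synonymous and additionally shares
#' immediate contexts.
#'
#' @param vocab_size Number of content words.
#' @param n_categories Number of latent categories (ring length).
#' @param zipf_exponent Zipf exponent `s` of the content-word frequency
#'   law (frequency of rank r proportional to `r^-s`).
#' @param n_docs,sentences_per_doc,tokens_per_sentence Corpus shape.
#' @param n_function_words Number of function (non-content) words.
#' @param function_word_rate Fraction of tokens that are function words.
#' @param synonym_fraction Fraction of content words planted in
#'   near-synonym pairs.
#' @param mix_prob Probability that a document mixes in a second category.
#' @param mix_decay Geometric decay of the second category's ring distance.
#' @param concrete_prob Probability that a content word is flagged as a
#'   concrete noun.
#' @param seed Integer master seed for lexicon and corpus generation.
#' @return A `generator_config` list.
#' @export
generator_config <- function(vocab_size = 1200, n_categories = 400,
                             zipf_exponent = 1, n_docs = 4000,
                             sentences_per_doc = 8, tokens_per_sentence = 12,
                             n_function_words = 25, function_word_rate = 0.5,
                             synonym_fraction = 0.05, mix_prob = 0.8,
                             mix_decay = 0.95, concrete_prob = 0.9,
                             seed = 1L) {
  cfg <- list(
    vocab_size = assert_scalar_int(vocab_size, "vocab_size", min = 2),
    n_categories = assert_scalar_int(n_categories, "n_categories", min = 1),
    zipf_exponent = as.numeric(zipf_exponent),
    n_docs = assert_scalar_int(n_docs, "n_docs", min = 1),
    sentences_per_doc = assert_scalar_int(sentences_per_doc, "sentences_per_doc", min = 1),
    tokens_per_sentence = assert_scalar_int(tokens_per_sentence, "tokens_per_sentence", min = 1),
    n_function_words = assert_scalar_int(n_function_words, "n_function_words", min = 1),
    function_word_rate = assert_probability(function_word_rate, "function_word_rate"),
    synonym_fraction = assert_probability(synonym_fraction, "synonym_fraction"),
    mix_prob = assert_probability(mix_prob, "mix_prob"),
    mix_decay = assert_probability(mix_decay, "mix_decay"),
    concrete_prob = assert_probability(concrete_prob, "concrete_prob"),
    seed = assert_scalar_int(seed, "seed")
  )
  if (cfg$zipf_exponent < 0) rlang::abort("zipf_exponent must be >= 0")
  if (cfg$vocab_size <= cfg$n_categories) {
    rlang::abort("vocab_size must exceed n_categories")
  }
  structure(cfg, class = "generator_config")
}
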