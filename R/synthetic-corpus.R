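#' Generate a synthetic corpus with latent-category structure
#'
#' Emulates the distributional-hypothesis signal that both space models
#' exploit: words with similar meanings occur in similar contexts. Each
#' document samples one ring category uniformly and, with probability
#' `mix_prob`, a second category at a geometrically distributed ring
#' distance; content tokens are drawn frequency-proportionally from the
#' document's categories and interleaved with function words (marked
#' non-content). When a drawn content word has a planted near-synonym
#' partner, the partner is substituted half of the time, so partners share
#' context profiles exactly. Ring distance yields a graded co-occurrence
#' signal whose derived cosines span \[0, 1\].
#'
#' @param config A [generator_config()].
#' @param lexicon Lexicon from [generate_lexicon()] under the same config.
#' @return A [tok_corpus()] tibble; attributes `category_map` (tibble
#'   `word`, `category`), `synonym_pairs` (tibble `word1`, `word2`) and
#'   `doc_categories` record the planted structure for diagnostics.
#' @export
generate_corpus <- function(config, lexicon) {
  stopifnot(inherits(config, "generator_config"))
  content <- lexicon[!lexicon$is_function, ]
  fn <- lexicon[lexicon$is_function, ]
  C <- config$n_categories
  by_cat <- split(seq_len(nrow(content)), content$category)
  syn_partner <- match(content$synonym_of, content$word)

  with_seed(stage_seed(config$seed, "corpus"), {
    n_sent <- config$sentences_per_doc
    n_tok <- config$tokens_per_sentence
    docs <- vector("list", config$n_docs)
    doc_cats <- matrix(NA_integer_, config$n_docs, 2)
    max_d <- max(1L, C %/% 2)
    for (d in seq_len(config$n_docs)) {
      c1 <- sample.int(C, 1)
      c2 <- NA_integer_
      lambda <- 0
      if (runif(1) < config$mix_prob && C > 1) {
        dist <- sample.int(max_d, 1, prob = config$mix_decay^seq_len(max_d))
        dir <- sample(c(-1L, 1L), 1)
        c2 <- ((c1 - 1L + dir * dist) %% C) + 1L
        lambda <- runif(1, 0.2, 0.5)
      }
      doc_cats[d, ] <- c(c1, c2)
      total <- n_sent * n_tok
      is_fn <- runif(total) < config$function_word_rate
      tok <- character(total)
      n_fn_tok <- sum(is_fn)
      if (n_fn_tok > 0) {
        tok[is_fn] <- sample(fn$word, n_fn_tok, replace = TRUE, prob = fn$frequency)
      }
      n_ct <- total - n_fn_tok
      if (n_ct > 0) {
        use_c2 <- !is.na(c2) & runif(n_ct) < lambda
        cat_of <- ifelse(use_c2, c2, c1)
        picks <- integer(n_ct)
        for (cc in unique(cat_of)) {
          sel <- which(cat_of == cc)
          ix <- by_cat[[as.character(cc)]]
          picks[sel] <- ix[sample.int(length(ix), length(sel), replace = TRUE,
                                      prob = content$frequency[ix])]
        }
        # near-synonym substitution: partners trade places half the time
        has_syn <- !is.na(syn_partner[picks])
        swap <- has_syn & runif(n_ct) < 0.5
        picks[swap] <- syn_partner[picks[swap]]
        tok[!is_fn] <- content$word[picks]
      }
      docs[[d]] <- tibble(
        doc = d,
        sentence = rep(seq_len(n_sent), each = n_tok),
        pos = rep(seq_len(n_tok), times = n_sent),
        token = tok, is_content = !is_fn
      )
    }
    corpus <- validate_corpus(dplyr::bind_rows(docs))
    attr(corpus, "category_map") <- tibble(word = content$word,
                                           category = content$category)
    attr(corpus, "synonym_pairs") <- content |>
      dplyr::filter(!is.na(.data$synonym_of), .data$word < .data$synonym_of) |>
      dplyr::select(word1 = "word", word2 = "synonym_of")
    attr(corpus, "doc_categories") <- doc_cats
    corpus
  })
}
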