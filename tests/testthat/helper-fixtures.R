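# Shared fixtures, all built in code.

# Corpus from a list of documents, each a character vector of sentences;
# tokens whitespace-separated, "_"-prefixed tokens are non-content.
make_corpus <- function(docs) {
  rows <- list()
  for (d in seq_along(docs)) {
    for (s in seq_along(docs[[d]])) {
      toks <- strsplit(docs[[d]][s], " ", fixed = TRUE)[[1]]
      noncontent <- startsWith(toks, "_")
      rows[[length(rows) + 1]] <- tibble::tibble(
        doc = d, sentence = s, pos = seq_along(toks),
        token = sub("^_", "", toks), is_content = !noncontent
      )
    }
  }
  semprime::tok_corpus(
    doc = unlist(lapply(rows, `[[`, "doc")),
    sentence = unlist(lapply(rows, `[[`, "sentence")),
    pos = unlist(lapply(rows, `[[`, "pos")),
    token = unlist(lapply(rows, `[[`, "token")),
    is_content = unlist(lapply(rows, `[[`, "is_content"))
  )
}

# A semantic space directly from a vectors matrix (rownames = words).
make_space <- function(vectors, model = "hal") {
  words <- rownames(vectors)
  structure(
    list(words = words, vectors = vectors,
         singular_values = rep(NA_real_, ncol(vectors)),
         k = ncol(vectors),
         vocab = tibble::tibble(word = words, freq = NA_integer_,
                                rank = seq_along(words)),
         meta = list(model = model, k = ncol(vectors), window = NA_integer_,
                     weighting = "none", corpus_id = "toy", seed = 0L)),
    class = "semantic_space"
  )
}

# Unique pronounceable letter strings with the given length range.
rand_words <- function(n, lengths = 4:9) {
  out <- character(0)
  while (length(out) < n) {
    L <- sample(lengths, 1)
    w <- paste(sample(letters, L, TRUE), collapse = "")
    if (!(w %in% out)) out <- c(out, w)
  }
  out
}

# A space of unit vectors at angles theta in [0, pi): for every target,
# clamped cosines to the other words sweep the whole [0, 1] range, so
# every similarity band is richly populated ("engineered abundance").
make_angle_space <- function(n_words = 1200, prefix = "w", seed = 99) {
  withr::with_seed(seed, {
    theta <- sort(runif(n_words, 0, pi))
    v <- cbind(cos(theta), sin(theta))
    rownames(v) <- rand_words(n_words)
    make_space(v)
  })
}

# A lexicon table in which every word of a space is prime- and
# target-eligible (concrete, length 4-9 via renaming is not needed --
# lengths are set explicitly, frequency classes mid-range).
make_abundant_lexicon <- function(words, seed = 7) {
  withr::with_seed(seed, tibble::tibble(
    word = words,
    frequency = sample(20:60, length(words), replace = TRUE),
    frequency_class = sample(10:15, length(words), replace = TRUE),
    length = nchar(words),
    is_concrete_noun = TRUE,
    is_function = FALSE
  ))
}

# Item covariates drawn directly on the stimulus constraint ranges, with
# cosines spanning [0, 1]; used to calibrate the analysis machinery.
make_item_set_direct <- function(n_word = 200, n_nonword = 100, seed = 1) {
  withr::with_seed(seed, {
    all_words <- rand_words(2 * n_word + 2 * n_nonword, lengths = 4:9)
    wp_primes <- all_words[seq_len(n_word)]
    wp_targets <- all_words[n_word + seq_len(n_word)]
    np_primes <- all_words[2 * n_word + seq_len(n_nonword)]
    np_targets <- vapply(
      all_words[2 * n_word + n_nonword + seq_len(n_nonword)],
      function(w) paste(rev(strsplit(w, "")[[1]]), collapse = ""), character(1),
      USE.NAMES = FALSE)
    wp <- tibble::tibble(
      prime = wp_primes, target = wp_targets,
      cosine = runif(n_word),
      class_index = semprime::scheme_class(semprime::similarity_scheme(),
                                           runif(n_word)),
      planned_class = 1L, reassigned = FALSE, trial_type = "word",
      length_target = nchar(wp_targets),
      freq_class_target = sample(10:15, n_word, TRUE),
      length_prime = nchar(wp_primes),
      freq_class_prime = sample(9:16, n_word, TRUE)
    )
    np <- tibble::tibble(
      prime = np_primes, target = np_targets,
      cosine = NA_real_, class_index = NA_integer_,
      planned_class = NA_integer_, reassigned = FALSE,
      trial_type = "nonword",
      length_target = nchar(np_targets),
      freq_class_target = NA_integer_,
      length_prime = nchar(np_primes),
      freq_class_prime = sample(9:16, n_nonword, TRUE)
    )
    structure(list(word_pairs = wp, nonword_pairs = np,
                   scheme = semprime::similarity_scheme(),
                   allocation = NULL, provenance = list(seed = seed)),
              class = "item_set")
  })
}

# One default-configuration synthetic build (lexicon, corpus, both
# spaces), computed lazily and cached for the whole test run.
.build_cache <- new.env(parent = emptyenv())
default_build <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(.build_cache[[key]])) {
    cfg <- semprime::generator_config(seed = seed)
    lex <- semprime::generate_lexicon(cfg)
    corp <- semprime::generate_corpus(cfg, lex)
    .build_cache[[key]] <- list(
      cfg = cfg, lexicon = lex, corpus = corp,
      lsa = semprime::build_space(corp, "lsa", k = 12, vocab_cap = 100000,
                                  seed = seed),
      hal = semprime::build_space(corp, "hal", k = 12, vocab_cap = 100000,
                                  seed = seed)
    )
  }
  .build_cache[[key]]
}
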