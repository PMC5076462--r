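#' Lexical constraint sets for targets and primes
#'
#' The stimulus algorithm restricts words by concreteness, length in
#' letters and Leipzig-style frequency class. The reference settings are
#' concrete nouns of length 4-9 with frequency class 10-15 for the target
#' pool, and concrete nouns of length 4-10 with frequency class 9-16 for
#' primes.
#'
#' @param concrete Require the concrete-noun flag.
#' @param length Inclusive `(min, max)` word length in letters.
#' @param freq_class Inclusive `(min, max)` frequency class.
#' @return A `word_constraints` list.
#' @export
word_constraints <- function(concrete = TRUE, length = c(4, 9),
                             freq_class = c(10, 15)) {
  stopifnot(length(length) == 2, length(freq_class) == 2)
  structure(list(concrete = isTRUE(concrete),
                 length = as.numeric(length),
                 freq_class = as.numeric(freq_class)),
            class = "word_constraints")
}

#' @rdname word_constraints
#' @export
target_constraints <- function() word_constraints(TRUE, c(4, 9), c(10, 15))

#' @rdname word_constraints
#' @export
prime_constraints <- function() word_constraints(TRUE, c(4, 10), c(9, 16))

#' Filter a lexicon by a constraint set
#'
#' @param lexicon Lexicon tibble (`word`, `frequency`, `frequency_class`,
#'   `length`, `is_concrete_noun`).
#' @param constraints A [word_constraints()] object.
#' @return The eligible rows of `lexicon`.
#' @export
eligible_words <- function(lexicon, constraints) {
  stopifnot(inherits(constraints, "word_constraints"))
  out <- lexicon |>
    dplyr::filter(
      .data$length >= constraints$length[1],
      .data$length <= constraints$length[2],
      .data$frequency_class >= constraints$freq_class[1],
      .data$frequency_class <= constraints$freq_class[2]
    )
  if (constraints$concrete) out <- dplyr::filter(out, .data$is_concrete_noun)
  out
}

#' Select the word pool: targets and nonword-trial primes
#'
#' Samples `n_pool` eligible words uniformly at random without
#' replacement, then splits them uniformly at random into `n_targets`
#' target words and `n_pool - n_targets` primes reserved for nonword
#' trials. The reference design draws a pool of 300 medium-frequency
#' concrete nouns and splits it 200 / 100.
#'
#' @param lexicon Lexicon tibble.
#' @param constraints Pool constraints, by default [target_constraints()].
#' @param n_pool Pool size.
#' @param n_targets Number of target words (`<= n_pool`).
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param space Optional `semantic_space`; when given, only words
#'   represented in the space are eligible for the pool (targets must
#'   have vectors for cosine-stratified prime sampling).
#' @return A list with character vectors `targets` and `nonword_primes`.
#' @export
select_word_pool <- function(lexicon, constraints = target_constraints(),
                             n_pool = 300, n_targets = 200, seed = 1L,
                             space = NULL) {
  n_pool <- assert_scalar_int(n_pool, "n_pool", min = 0)
  n_targets <- assert_scalar_int(n_targets, "n_targets", min = 0)
  stopifnot(n_targets <= n_pool)
  if (n_pool == 0) return(list(targets = character(), nonword_primes = character()))
  pool <- eligible_words(lexicon, constraints)
  if (!is.null(space)) pool <- pool[pool$word %in% space$words, ]
  if (nrow(pool) < n_pool) {
    rlang::abort(sprintf(
      paste0("pool exhausted: only %d lexicon words satisfy the pool ",
             "constraints (concrete=%s, length %g-%g, frequency class %g-%g) ",
             "but n_pool = %d"),
      nrow(pool), constraints$concrete, constraints$length[1],
      constraints$length[2], constraints$freq_class[1],
      constraints$freq_class[2], n_pool))
  }
  with_seed(seed, {
    chosen <- resample(pool$word, n_pool)
    targets <- resample(chosen, n_targets)
    list(targets = targets, nonword_primes = setdiff(chosen, targets))
  })
}

#' Assign targets to similarity classes
#'
#' Random allocation that is as equal as possible: class sizes differ by
#' at most one, with exact equality when the class count divides the
#' target count (the reference design assigns 20 of 200 targets to each
#' of 10 classes).
#'
#' @param targets Character vector of target words.
#' @param scheme A [similarity_scheme()] tibble.
#' @param seed Integer seed.
#' @return A tibble with columns `target`, `class_index`.
#' @export
assign_similarity_classes <- function(targets, scheme, seed = 1L) {
  if (nrow(scheme) == 0) rlang::abort("empty similarity scheme")
  n <- length(targets)
  if (n == 0) return(tibble(target = character(), class_index = integer()))
  with_seed(seed, {
    # balanced label pool, trimmed by a random draw of the leftover classes
    base <- rep(scheme$class_index, n %/% nrow(scheme))
    extra <- resample(scheme$class_index, n %% nrow(scheme))
    labels <- resample(c(base, extra))
    tibble(target = targets, class_index = as.integer(labels))
  })
}

#' Sample a prime for one target from its similarity class
#'
#' Draws uniformly at random from the candidate set: words in the space
#' whose clamped cosine to the target falls in the class interval,
#' intersected with the prime-eligible lexicon, minus `excluded` words
#' already used in the item material. Returns `NA` when the candidate set
#' is empty (the caller then re-assigns the target to another class).
#'
#' @param target Target word (must be in the space).
#' @param class_index Similarity class of the target.
#' @param scheme A [similarity_scheme()] tibble.
#' @param space A `semantic_space`.
#' @param lexicon Lexicon tibble.
#' @param excluded Character vector of unavailable words.
#' @param constraints Prime constraints, default [prime_constraints()].
#' @param seed Integer seed.
#' @return A single word, or `NA_character_` if no candidate exists.
#' @export
sample_prime <- function(target, class_index, scheme, space, lexicon,
                         excluded = character(), constraints = prime_constraints(),
                         seed = 1L) {
  cls <- scheme[scheme$class_index == class_index, ]
  if (nrow(cls) != 1) rlang::abort(sprintf("unknown class index %s", class_index))
  eligible <- eligible_words(lexicon, constraints)$word
  candidates <- words_in_similarity_band(
    space, target, cls$lo, cls$hi,
    predicate = setdiff(eligible, c(excluded, target)),
    closed_upper = cls$closed_upper
  )
  if (length(candidates) == 0) return(NA_character_)
  with_seed(seed, resample(candidates, 1))
}

#' Generate the full similarity-stratified item set
#'
#' Implements the pseudo-random item-generation algorithm: each target,
#' pre-assigned to a similarity class, receives a prime sampled uniformly
#' from the words meeting the class's cosine band and the lexical prime
#' constraints. When no candidate exists the target is re-assigned
#' uniformly at random to a different class (with replacement over
#' classes, up to `max_reassignments` attempts per target). Words are
#' never reused across the primes and targets of word trials. Nonword
#' trials pair the reserved nonword primes with generated nonword targets.
#'
#' @param pool Output of [select_word_pool()] (`targets`, `nonword_primes`).
#' @param scheme A [similarity_scheme()] tibble.
#' @param space A `semantic_space`.
#' @param lexicon Lexicon tibble.
#' @param constraints Prime constraints, default [prime_constraints()].
#' @param seed Integer seed governing class assignment, prime sampling,
#'   re-assignment and nonword generation.
#' @param max_reassignments Per-target budget of class re-assignments.
#' @param nonword_length_range Length range for generated nonword targets.
#' @return An `item_set`: list with tibbles `word_pairs` (`prime`,
#'   `target`, `cosine`, `class_index`, `trial_type`, `planned_class`,
#'   `reassigned`) and `nonword_pairs`, the `scheme`, per-class
#'   planned/realized counts (`allocation`), and `provenance`.
#' @export
generate_item_set <- function(pool, scheme, space, lexicon,
                              constraints = prime_constraints(), seed = 1L,
                              max_reassignments = 20,
                              nonword_length_range = c(4, 10)) {
  targets <- pool$targets
  assignment <- assign_similarity_classes(targets, scheme,
                                          seed = stage_seed(seed, "classes"))
  eligible <- eligible_words(lexicon, constraints)$word
  used <- c(targets, pool$nonword_primes)
  rows <- vector("list", length(targets))
  stuck <- character()
  for (i in seq_along(targets)) {
    tgt <- targets[i]
    planned <- assignment$class_index[i]
    cls <- planned
    prime <- NA_character_
    sims <- clamp_cosine(target_cosines(space, tgt))
    cand_pool <- intersect(names(sims)[!is.na(sims)], setdiff(eligible, tgt))
    for (attempt in 0:max_reassignments) {
      if (attempt > 0) {
        cls <- with_seed(stage_seed(seed, paste0("reassign", i, "_", attempt)),
                         resample(setdiff(scheme$class_index, planned), 1))
      }
      b <- scheme[scheme$class_index == cls, ]
      inband <- sims[cand_pool] >= b$lo &
        (if (b$closed_upper) sims[cand_pool] <= b$hi else sims[cand_pool] < b$hi)
      candidates <- setdiff(cand_pool[inband], used)
      if (length(candidates) > 0) {
        prime <- with_seed(stage_seed(seed, paste0("prime", i, "_", attempt)),
                           resample(candidates, 1))
        break
      }
    }
    if (is.na(prime)) {
      stuck <- c(stuck, tgt)
      next
    }
    used <- c(used, prime)
    rows[[i]] <- tibble(
      prime = prime, target = tgt, cosine = unname(sims[prime]),
      class_index = as.integer(cls), planned_class = as.integer(planned),
      reassigned = cls != planned, trial_type = "word"
    )
  }
  if (length(stuck) > 0) {
    rlang::abort(paste0(
      "item generation failed: re-assignment budget exhausted for target(s) ",
      paste(stuck, collapse = ", ")))
  }
  word_pairs <- dplyr::bind_rows(rows)
  nonword_targets <- generate_nonwords(
    length(pool$nonword_primes), length_range = nonword_length_range,
    reference_words = targets, lexicon = lexicon,
    seed = stage_seed(seed, "nonwords")
  )
  nonword_pairs <- tibble(
    prime = pool$nonword_primes, target = nonword_targets,
    cosine = NA_real_, class_index = NA_integer_,
    planned_class = NA_integer_, reassigned = FALSE, trial_type = "nonword"
  )
  # attach the lexical covariates consumed by the RT model and the
  # matching checks (nonword targets have no lexicon frequency)
  lex <- setNames(lexicon$frequency_class, lexicon$word)
  add_covariates <- function(pairs) {
    dplyr::mutate(pairs,
      length_target = nchar(.data$target),
      freq_class_target = as.integer(unname(lex[.data$target])),
      length_prime = nchar(.data$prime),
      freq_class_prime = as.integer(unname(lex[.data$prime]))
    )
  }
  word_pairs <- add_covariates(word_pairs)
  nonword_pairs <- add_covariates(nonword_pairs)
  allocation <- scheme |>
    dplyr::select("class_index") |>
    dplyr::left_join(dplyr::count(assignment, .data$class_index, name = "planned"),
                     by = "class_index") |>
    dplyr::left_join(dplyr::count(word_pairs, .data$class_index, name = "realized"),
                     by = "class_index") |>
    dplyr::mutate(dplyr::across(c("planned", "realized"),
                                ~ tidyr::replace_na(.x, 0L)))
  structure(
    list(word_pairs = word_pairs, nonword_pairs = nonword_pairs,
         scheme = scheme, allocation = allocation,
         provenance = list(space_id = space$meta$corpus_id,
                           model = space$meta$model, seed = as.integer(seed),
                           constraints = constraints,
                           n_reassigned = sum(word_pairs$reassigned))),
    class = "item_set"
  )
}

#' @export
print.item_set <- function(x, ...) {
  cat(sprintf("<item_set: %d word pairs (%d reassigned), %d nonword pairs, %d classes>\n",
              nrow(x$word_pairs), sum(x$word_pairs$reassigned),
              nrow(x$nonword_pairs), nrow(x$scheme)))
  invisible(x)
}
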