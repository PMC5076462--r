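test_that("word-pool selection sizes, disjointness and determinism", {
  lex <- make_abundant_lexicon(make_angle_space(300)$words)
  pool <- select_word_pool(lex, n_pool = 300, n_targets = 200, seed = 3)
  expect_length(pool$targets, 200)
  expect_length(pool$nonword_primes, 100)
  expect_length(intersect(pool$targets, pool$nonword_primes), 0)
  pool2 <- select_word_pool(lex, n_pool = 300, n_targets = 200, seed = 3)
  expect_identical(pool, pool2)
  expect_equal(select_word_pool(lex, n_pool = 0, n_targets = 0, seed = 1),
               list(targets = character(), nonword_primes = character()))
  expect_error(select_word_pool(lex, n_pool = 301, n_targets = 200, seed = 1),
               "pool exhausted")
})

test_that("class assignment is as equal as possible and seeded", {
  s <- similarity_scheme()
  a <- assign_similarity_classes(paste0("t", 1:200), s, seed = 5)
  expect_equal(unname(table(a$class_index)), rep(20L, 10), ignore_attr = TRUE)
  expect_equal(nrow(assign_similarity_classes(character(), s, seed = 1)), 0L)
  b <- assign_similarity_classes(paste0("t", 1:7), similarity_scheme(c(0, 1 / 3, 2 / 3, 1)),
                                 seed = 2)
  expect_equal(sort(as.integer(table(b$class_index))), c(2L, 2L, 3L))
  expect_identical(a, assign_similarity_classes(paste0("t", 1:200), s, seed = 5))
})

test_that("sampled primes always satisfy constraints and the class band", {
  sp <- make_angle_space(400)
  lex <- make_abundant_lexicon(sp$words)
  lex$length[1:50] <- 12L # make some words prime-ineligible
  scheme <- similarity_scheme()
  eligible <- eligible_words(lex, prime_constraints())$word
  withr::with_seed(77, {
    for (i in 1:200) {
      tgt <- sample(sp$words, 1)
      cls <- sample(1:10, 1)
      p <- sample_prime(tgt, cls, scheme, sp, lex, excluded = character(),
                        seed = i)
      if (!is.na(p)) {
        expect_true(p %in% eligible)
        expect_false(p == tgt)
        cc <- max(0, cosine(sp, p, tgt))
        b <- scheme[cls, ]
        expect_true(cc >= b$lo && (cc < b$hi || (b$closed_upper && cc <= b$hi)))
      }
    }
  })
})

test_that("a forced choice and an empty band behave as specified", {
  v <- rbind(t = c(1, 0), near = c(1, 0.05), far = c(0, 1))
  sp <- make_space(v)
  lex <- make_abundant_lexicon(rownames(v))
  scheme <- similarity_scheme()
  # only "near" has clamped cosine in the top class
  expect_equal(sample_prime("t", 10, scheme, sp, lex, seed = 1), "near")
  # class 5 band is empty for this space
  expect_true(is.na(sample_prime("t", 5, scheme, sp, lex, seed = 1)))
  expect_error(sample_prime("absent", 1, scheme, sp, lex, seed = 1), "not in space")
})

test_that("abundant spaces give a complete stratified set with no reuse", {
  sp <- make_angle_space(1200)
  lex <- make_abundant_lexicon(sp$words)
  pool <- select_word_pool(lex, n_pool = 300, n_targets = 200, seed = 11)
  items <- generate_item_set(pool, similarity_scheme(), sp, lex, seed = 11)
  wp <- items$word_pairs
  expect_equal(nrow(wp), 200L)
  expect_equal(sum(wp$reassigned), 0L)
  expect_equal(sort(as.integer(table(wp$class_index))), rep(20L, 10),
               ignore_attr = TRUE)
  # global uniqueness over word-trial primes and targets
  expect_false(any(duplicated(c(wp$prime, wp$target))))
  # every pair in its class band
  b <- items$scheme[wp$class_index, ]
  expect_true(all(wp$cosine >= b$lo &
                    (wp$cosine < b$hi | (b$closed_upper & wp$cosine <= b$hi))))
  expect_equal(nrow(items$nonword_pairs), 100L)
  # determinism of the whole generation
  items2 <- generate_item_set(pool, similarity_scheme(), sp, lex, seed = 11)
  expect_identical(items$word_pairs, items2$word_pairs)
})

test_that("an empty band triggers re-assignment; a single stuck target errors", {
  # space whose candidates all sit in the top band relative to the target
  more <- withr::with_seed(3, {
    th <- runif(60, 0, 0.3) # cosines to the target all > 0.95
    m <- cbind(cos(th), sin(th))
    rownames(m) <- rand_words(60)
    m
  })
  sp <- make_space(rbind(tiger = c(1, 0), more))
  lex <- make_abundant_lexicon(sp$words)
  pool <- list(targets = "tiger", nonword_primes = character())
  scheme <- similarity_scheme()
  # every class except the top one is verified empty for t1
  expect_length(words_in_similarity_band(sp, "tiger", 0, 0.81), 0)
  items <- generate_item_set(pool, scheme, sp, lex, seed = 710)
  expect_equal(nrow(items$word_pairs), 1L)
  expect_equal(items$word_pairs$class_index, 10L)
  planned <- assign_similarity_classes(
    "tiger", scheme, seed = stage_seed(710, "classes"))$class_index
  expect_equal(items$word_pairs$reassigned, planned != 10L)

  # all classes empty (only other word is prime-ineligible) -> failure
  sp2 <- make_space(rbind(tiger = c(1, 0), albatros = c(0, 1)))
  lex2 <- make_abundant_lexicon(c("tiger", "albatros"))
  lex2$length[lex2$word == "albatros"] <- 12L
  expect_error(
    generate_item_set(list(targets = "tiger", nonword_primes = character()),
                      scheme, sp2, lex2, seed = 1),
    "re-assignment budget"
  )
})

test_that("emitted cosines are near-uniform over classes on an abundant space", {
  sp <- make_angle_space(1500, seed = 13)
  lex <- make_abundant_lexicon(sp$words)
  rejections <- 0
  for (sd in 1:10) {
    pool <- select_word_pool(lex, n_pool = 300, n_targets = 200, seed = sd)
    items <- generate_item_set(pool, similarity_scheme(), sp, lex, seed = sd)
    tab <- table(factor(items$word_pairs$class_index, levels = 1:10))
    p <- suppressWarnings(chisq.test(tab)$p.value)
    if (p < 0.01) rejections <- rejections + 1
  }
  expect_lte(rejections, 1) # >= 90% of seeds not rejected at alpha = .01
})
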