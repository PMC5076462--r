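row_cosines <- function(m) {
  m <- as.matrix(m)
  n <- sqrt(rowSums(m^2))
  (m %*% t(m)) / outer(n, n)
}

test_that("svd of a diagonal matrix returns its entries as singular values", {
  w <- Matrix::Matrix(diag(c(3, 2, 1)), sparse = TRUE)
  dimnames(w) <- list(c("a", "b", "c"), c("x", "y", "z"))
  sp <- svd_reduce(w, k = 3)
  expect_equal(sp$singular_values, c(3, 2, 1))
  expect_equal(abs(cosine(sp, "a", "b")), 0)
  expect_true(all(diff(sp$singular_values) <= 0))
})

test_that("full-rank reduction preserves pairwise row cosines", {
  withr::with_seed(41, {
    w <- matrix(abs(rnorm(12 * 9)), 12, 9)
    rownames(w) <- paste0("w", 1:12)
    sp <- svd_reduce(Matrix::Matrix(w, sparse = TRUE), k = 9)
    expect_lt(max(abs(row_cosines(sp$vectors) - row_cosines(w))), 1e-8)
  })
})

test_that("rank-1 truncation collapses cosines to -1, 0 or 1", {
  w <- matrix(c(1, 0.2, 2, 0.3, 0.5, 2), 3, 2, byrow = TRUE)
  rownames(w) <- c("a", "b", "c")
  sp <- svd_reduce(Matrix::Matrix(w, sparse = TRUE), k = 1)
  expect_equal(ncol(sp$vectors), 1L)
  cc <- c(cosine(sp, "a", "b"), cosine(sp, "a", "c"))
  expect_true(all(abs(abs(cc) - 1) < 1e-12 | abs(cc) < 1e-12))
})

test_that("k exceeding both dimensions is rejected; k caps at min dim", {
  w <- Matrix::Matrix(diag(2), sparse = TRUE)
  dimnames(w) <- list(c("a", "b"), c("x", "y"))
  expect_error(svd_reduce(w, k = 3), "exceeds")
})

test_that("cosine is symmetric, bounded, 1 on itself, and errors on unknown words", {
  v <- rbind(a = c(1, 0), b = c(0, 1), c = c(1, 1), z = c(0, 0))
  sp <- make_space(v)
  expect_equal(cosine(sp, "a", "a"), 1)
  expect_equal(cosine(sp, "a", "b"), 0)
  expect_equal(cosine(sp, "a", "c"), sqrt(2) / 2, tolerance = 1e-4)
  expect_equal(cosine(sp, "a", "c"), cosine(sp, "c", "a"))
  expect_error(cosine(sp, "a", "nope"), "not in space")
  expect_error(cosine(sp, "a", "z"), "zero vector")
})

test_that("similarity bands match an exhaustive cosine-scan oracle", {
  withr::with_seed(43, {
    v <- matrix(rnorm(6 * 3), 6, 3)
    rownames(v) <- paste0("w", 1:6)
    sp <- make_space(v)
    for (band in list(c(0, 1), c(0.2, 0.6), c(0.9, 1))) {
      got <- words_in_similarity_band(sp, "w1", band[1], band[2])
      sims <- vapply(paste0("w", 2:6), function(u) {
        max(0, cosine(sp, "w1", u))
      }, numeric(1))
      want <- names(sims)[sims >= band[1] & sims < band[2]]
      expect_equal(got, want)
    }
    # full band with an always-true predicate: every other word below 1
    all_w <- words_in_similarity_band(sp, "w1", 0, 1,
                                      predicate = function(w) TRUE)
    expect_setequal(all_w, paste0("w", 2:6))
  })
})

test_that("space serialization round-trips vectors, metadata and cosines", {
  build <- withr::with_seed(47, {
    w <- matrix(abs(rnorm(50 * 5)), 50, 5)
    rownames(w) <- paste0("w", 1:50)
    svd_reduce(Matrix::Matrix(w, sparse = TRUE), k = 5, seed = 3,
               model = "hal", window = 3L)
  })
  dir <- withr::local_tempdir()
  save_space(build, dir)
  back <- load_space(dir)
  expect_equal(back$vectors, build$vectors, tolerance = 1e-12)
  expect_equal(back$meta$model, "hal")
  expect_equal(back$meta$window, 3L)
  expect_equal(cosine(back, "w1", "w2"), cosine(build, "w1", "w2"),
               tolerance = 1e-12)
  # integrity: missing vectors file
  file.remove(file.path(dir, "vectors.tsv"))
  expect_error(load_space(dir), "incomplete")
})

test_that("tampered space files fail the checksum integrity check", {
  sp <- make_angle_space(20)
  dir <- withr::local_tempdir()
  save_space(sp, dir)
  lines <- readLines(file.path(dir, "vectors.tsv"))
  lines[2] <- paste0("x", substring(lines[2], 2))
  writeLines(lines, file.path(dir, "vectors.tsv"))
  expect_error(load_space(dir), "checksum")
})

test_that("space construction is reproducible bit-for-bit", {
  cfg <- generator_config(vocab_size = 150, n_categories = 15, n_docs = 80,
                          sentences_per_doc = 4, tokens_per_sentence = 10,
                          n_function_words = 8, seed = 6)
  corp <- generate_corpus(cfg, generate_lexicon(cfg, check_feasibility = FALSE))
  s1 <- build_space(corp, "hal", k = 8, vocab_cap = 300, seed = 5)
  s2 <- build_space(corp, "hal", k = 8, vocab_cap = 300, seed = 5)
  expect_identical(s1$vectors, s2$vectors)
})
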