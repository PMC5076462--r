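#' Reduce a weighted co-occurrence matrix to a semantic space
#'
#' Truncated singular value decomposition of the PPMI-weighted matrix.
#' Word vectors are the rows of \eqn{U_k \Sigma_k}, which preserves the
#' pairwise row geometry (hence all row cosines) of the weighted matrix at
#' full rank. The effective dimensionality is `min(k, rank)`. Column signs
#' are fixed deterministically (largest-magnitude loading positive) so the
#' space is bit-for-bit reproducible; the dense LAPACK solver itself is
#' deterministic and `seed` is recorded as provenance metadata.
#'
#' @param weighted Weighted matrix from [ppmi_transform()] (words x contexts).
#' @param k Target dimensionality (>= 1, and no larger than both matrix
#'   dimensions).
#' @param seed Provenance seed recorded in the space metadata.
#' @param vocab Optional vocabulary tibble (`word`, `freq`, `rank`) carried
#'   along for serialization; defaults to a frequency-free stub built from
#'   the row names.
#' @param model Model kind label, `"lsa"` (word-by-document source) or
#'   `"hal"` (word-by-word source).
#' @param window Window size metadata for HAL-type spaces (`NA` for LSA).
#' @param corpus_id Free-form identifier of the source corpus.
#' @return A `semantic_space` object: list with `words`, `vectors`
#'   (words x k matrix), `singular_values`, `k`, `vocab`, `meta`.
#' @examples
#' w <- Matrix::Matrix(diag(c(3, 2, 1)), sparse = TRUE)
#' dimnames(w) <- list(c("a", "b", "c"), c("x", "y", "z"))
#' sp <- svd_reduce(w, k = 3)
#' sp$singular_values
#' @export
svd_reduce <- function(weighted, k, seed = 0L, vocab = NULL,
                       model = c("lsa", "hal"), window = NA_integer_,
                       corpus_id = "unknown") {
  model <- match.arg(model)
  k <- assert_scalar_int(k, "k", min = 1)
  if (k > nrow(weighted) && k > ncol(weighted)) {
    rlang::abort(sprintf("k = %d exceeds both matrix dimensions (%d x %d)",
                         k, nrow(weighted), ncol(weighted)))
  }
  words <- rownames(weighted)
  if (is.null(words)) rlang::abort("weighted matrix must carry word row names")
  k_req <- min(k, nrow(weighted), ncol(weighted))
  dec <- svd(as.matrix(weighted), nu = k_req, nv = 0)
  d <- dec$d[seq_len(k_req)]
  rank <- sum(dec$d > max(dim(weighted)) * .Machine$double.eps * max(dec$d, 0))
  k_eff <- max(1L, min(k_req, rank))
  u <- dec$u[, seq_len(k_eff), drop = FALSE]
  # deterministic sign convention per component
  for (j in seq_len(k_eff)) {
    piv <- which.max(abs(u[, j]))
    if (u[piv, j] < 0) u[, j] <- -u[, j]
  }
  vectors <- sweep(u, 2, d[seq_len(k_eff)], `*`)
  rownames(vectors) <- words
  colnames(vectors) <- paste0("dim", seq_len(k_eff))
  if (is.null(vocab)) {
    vocab <- tibble(word = words, freq = NA_integer_, rank = seq_along(words))
  }
  structure(
    list(
      words = words, vectors = vectors,
      singular_values = d[seq_len(k_eff)], k = k_eff, vocab = vocab,
      meta = list(model = model, k = k_eff, window = window,
                  weighting = "ppmi", corpus_id = corpus_id,
                  seed = as.integer(seed))
    ),
    class = "semantic_space"
  )
}

#' Build an LSA-type or HAL-type semantic space from a corpus
#'
#' Convenience wrapper chaining [build_vocabulary()], the model-appropriate
#' co-occurrence counter, [ppmi_transform()] and [svd_reduce()].
#'
#' @param corpus A [tok_corpus()] tibble.
#' @param model `"lsa"` (word-by-document) or `"hal"` (windowed word-by-word).
#' @param k Reduced dimensionality (the reference setting is 300).
#' @param vocab_cap Vocabulary size cap.
#' @param window Content-word window size for HAL spaces.
#' @param seed Provenance seed stored in the space metadata.
#' @param corpus_id Identifier stored in the space metadata.
#' @return A `semantic_space` object.
#' @export
build_space <- function(corpus, model = c("lsa", "hal"), k = 300,
                        vocab_cap = 100000, window = 3, seed = 0L,
                        corpus_id = "corpus") {
  model <- match.arg(model)
  vocab <- build_vocabulary(corpus, vocab_cap)
  counts <- switch(model,
    lsa = count_word_by_document(corpus, vocab),
    hal = count_word_by_word(corpus, vocab, window = window)
  )
  weighted <- ppmi_transform(counts)
  svd_reduce(weighted, k = k, seed = seed, vocab = vocab, model = model,
             window = if (model == "hal") as.integer(window) else NA_integer_,
             corpus_id = corpus_id)
}

#' @export
print.semantic_space <- function(x, ...) {
  cat(sprintf("<semantic_space: %s, %d words x %d dims, window %s, %s>\n",
              x$meta$model, length(x$words), x$k,
              ifelse(is.na(x$meta$window), "-", x$meta$window),
              x$meta$weighting))
  invisible(x)
}

space_vector <- function(space, word) {
  i <- match(word, space$words)
  if (is.na(i)) rlang::abort(sprintf("word not in space: '%s'", word))
  v <- space$vectors[i, ]
  if (all(v == 0)) rlang::abort(sprintf("word '%s' has a zero vector; cosine undefined", word))
  v
}

#' Cosine similarity between two words in a space
#'
#' The cosine of the angle between the two word vectors,
#' \eqn{\cos(v_1, v_2) = v_1 \cdot v_2 / (\lVert v_1\rVert\,\lVert v_2\rVert)};
#' symmetric in its arguments and bounded in \[-1, 1\].
#'
#' @param space A `semantic_space`.
#' @param w1,w2 Words present in the space with nonzero vectors.
#' @return A single numeric cosine in \[-1, 1\].
#' @examples
#' w <- Matrix::Matrix(diag(c(3, 2, 1)), sparse = TRUE)
#' dimnames(w) <- list(c("a", "b", "c"), c("x", "y", "z"))
#' sp <- svd_reduce(w, k = 3)
#' cosine(sp, "a", "a") # 1
#' @export
cosine <- function(space, w1, w2) {
  v1 <- space_vector(space, w1)
  v2 <- space_vector(space, w2)
  s <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  min(1, max(-1, s))
}

#' Clamp cosines at zero
#'
#' Negative cosines are treated as zero similarity throughout the
#' similarity-class machinery, so clamped cosines live in \[0, 1\].
#'
#' @param x Numeric cosines.
#' @return `pmax(x, 0)`.
#' @export
clamp_cosine <- function(x) pmax(x, 0)

#' All cosines from one target to the rest of the space
#'
#' Unclamped cosines from `target` to every other word, in vocabulary
#' order; words with zero vectors yield `NA`. Clamp with
#' [clamp_cosine()] for similarity-class logic.
#'
#' @param space A `semantic_space`.
#' @param target A word in the space.
#' @return A named numeric vector over all other words.
#' @export
target_cosines <- function(space, target) {
  vt <- space_vector(space, target)
  norms <- sqrt(rowSums(space$vectors^2))
  sims <- drop(space$vectors %*% vt) / (norms * sqrt(sum(vt^2)))
  sims[norms == 0] <- NA_real_
  sims <- setNames(sims, space$words)
  sims[names(sims) != target]
}

#' Words within a cosine-similarity band of a target
#'
#' Returns every in-space word (other than the target) whose clamped
#' cosine to `target` lies in `[lo, hi)` (`[lo, hi]` with
#' `closed_upper = TRUE`, used for the last similarity class) and that
#' passes `predicate`. Order follows the space's vocabulary, so results
#' are deterministic given the space. Words with zero vectors are skipped.
#'
#' @param space A `semantic_space`.
#' @param target Word whose neighbourhood is queried.
#' @param lo,hi Band bounds with `0 <= lo < hi <= 1`.
#' @param predicate Optional filter: a function `word -> logical` or a
#'   character vector of admissible words.
#' @param closed_upper Include the upper bound (default `FALSE`).
#' @return Character vector of words.
#' @export
words_in_similarity_band <- function(space, target, lo, hi, predicate = NULL,
                                     closed_upper = FALSE) {
  stopifnot(lo >= 0, hi <= 1, lo < hi)
  sims <- clamp_cosine(target_cosines(space, target))
  inband <- !is.na(sims) & sims >= lo & (if (closed_upper) sims <= hi else sims < hi)
  out <- names(sims)[inband]
  if (is.character(predicate)) out <- intersect(out, predicate)
  else if (is.function(predicate)) out <- out[vapply(out, predicate, logical(1))]
  else if (!is.null(predicate)) rlang::abort("predicate must be a function or character vector")
  out
}
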