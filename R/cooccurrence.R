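#' Word-by-document co-occurrence counts
#'
#' Cell (w, d) holds the number of tokens of vocabulary word `w` in
#' document `d`; out-of-vocabulary tokens are ignored. This is the raw
#' count matrix behind an LSA-type space.
#'
#' @param corpus A [tok_corpus()] tibble.
#' @param vocab A vocabulary tibble from [build_vocabulary()].
#' @return A sparse `dgCMatrix` (words x documents) with dimnames; rows
#'   follow vocabulary rank order.
#' @export
count_word_by_document <- function(corpus, vocab) {
  corpus <- validate_corpus(corpus)
  docs <- sort(unique(corpus$doc))
  wi <- match(corpus$token, vocab$word)
  di <- match(corpus$doc, docs)
  keep <- !is.na(wi)
  m <- Matrix::sparseMatrix(
    i = wi[keep], j = di[keep], x = 1,
    dims = c(nrow(vocab), length(docs)),
    dimnames = list(vocab$word, paste0("d", docs))
  )
  methods::as(m, "CsparseMatrix")
}

#' Windowed word-by-word co-occurrence counts
#'
#' The count matrix behind a HAL-type space. Only content tokens
#' participate: within each sentence the non-content tokens are dropped,
#' and every ordered pair of remaining tokens at distance `<= window`
#' (distance counted in content tokens) contributes one flat, unweighted
#' count to both (a, b) and (b, a). Pairs never cross sentence boundaries.
#' Out-of-vocabulary content tokens occupy window positions but produce no
#' counts. The result is symmetric with a zero diagonal (a token does not
#' co-occur with itself; repeated forms at distance >= 1 do count).
#'
#' @inheritParams count_word_by_document
#' @param window Window size in content words (>= 1); the window is
#'   symmetric, i.e. `window` content words to each side.
#' @return A sparse symmetric matrix (words x words) in vocabulary order.
#' @export
count_word_by_word <- function(corpus, vocab, window = 3) {
  corpus <- validate_corpus(corpus)
  window <- assert_scalar_int(window, "window", min = 1)
  n <- nrow(vocab)
  content <- corpus |>
    dplyr::filter(.data$is_content) |>
    dplyr::arrange(.data$doc, .data$sentence, .data$pos)
  if (nrow(content) == 0) {
    return(Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                                dims = c(n, n), dimnames = list(vocab$word, vocab$word)))
  }
  idx <- match(content$token, vocab$word)
  sent_key <- cumsum(!duplicated(content[, c("doc", "sentence")]))
  ii <- integer(0); jj <- integer(0)
  for (off in seq_len(window)) {
    k <- seq_len(length(idx) - off)
    if (length(k) == 0) break
    ok <- sent_key[k] == sent_key[k + off] & !is.na(idx[k]) & !is.na(idx[k + off])
    ii <- c(ii, idx[k][ok]); jj <- c(jj, idx[k + off][ok])
  }
  # accumulate both directions; identical forms at distance >= 1 would land
  # on the diagonal, which is held at zero by convention
  same <- ii == jj
  ii2 <- c(ii[!same], jj[!same]); jj2 <- c(jj[!same], ii[!same])
  m <- Matrix::sparseMatrix(i = ii2, j = jj2, x = 1, dims = c(n, n),
                            dimnames = list(vocab$word, vocab$word))
  methods::as(m, "CsparseMatrix")
}
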