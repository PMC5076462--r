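#' Positive pointwise mutual information weighting
#'
#' Replaces each raw co-occurrence count \eqn{n_{wc}} by
#' \deqn{\max\left(0,\ \log\frac{n_{wc}\,N}{n_{w\cdot}\,n_{\cdot c}}\right)}
#' where \eqn{N} is the grand total and the marginals are row and column
#' sums of the count matrix itself (i.e. restricted to the vocabulary, not
#' the raw corpus). The log is natural. Zero-count cells stay exactly zero,
#' so sparsity is preserved; negative PMI values are clamped to zero.
#'
#' @param counts A sparse non-negative count matrix
#'   (from [count_word_by_document()] or [count_word_by_word()]).
#' @return A sparse matrix of the same shape and dimnames with
#'   non-negative real entries.
#' @export
ppmi_transform <- function(counts) {
  if (!methods::is(counts, "sparseMatrix")) {
    counts <- methods::as(Matrix::Matrix(as.matrix(counts), sparse = TRUE),
                          "CsparseMatrix")
  }
  if (any(counts@x < 0)) rlang::abort("co-occurrence counts must be non-negative")
  N <- sum(counts)
  if (N == 0) rlang::abort("degenerate input: all co-occurrence counts are zero")
  rs <- Matrix::rowSums(counts)
  cs <- Matrix::colSums(counts)
  trip <- Matrix::summary(methods::as(counts, "TsparseMatrix"))
  pmi <- log(trip$x * N / (rs[trip$i] * cs[trip$j]))
  out <- Matrix::sparseMatrix(
    i = trip$i, j = trip$j, x = pmax(pmi, 0),
    dims = dim(counts), dimnames = dimnames(counts)
  )
  Matrix::drop0(methods::as(out, "CsparseMatrix"))
}
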