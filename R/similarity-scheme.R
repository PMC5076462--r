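#' Similarity-class scheme
#'
#' An ordered set of contiguous half-open cosine intervals partitioning
#' \[0, 1\]; the last interval is closed at 1 so every clamped cosine
#' belongs to exactly one class. The default reproduces the ten-class
#' stratification used to generate priming material: \[0, 0.09),
#' \[0.09, 0.18), ..., \[0.72, 0.81), \[0.81, 1\].
#'
#' @param breaks Increasing numeric vector of class boundaries starting at
#'   0 and ending at 1.
#' @return A tibble with columns `class_index`, `lo`, `hi`, `closed_upper`.
#' @examples
#' similarity_scheme()
#' similarity_scheme(c(0, 0.5, 1))
#' @export
similarity_scheme <- function(breaks = c(seq(0, 0.81, by = 0.09), 1)) {
  breaks <- as.numeric(breaks)
  if (length(breaks) < 2 || is.unsorted(breaks, strictly = TRUE) ||
      breaks[1] != 0 || breaks[length(breaks)] != 1) {
    rlang::abort("breaks must increase strictly from 0 to 1")
  }
  n <- length(breaks) - 1L
  tibble(
    class_index = seq_len(n),
    lo = breaks[-length(breaks)],
    hi = breaks[-1],
    closed_upper = c(rep(FALSE, n - 1L), TRUE)
  )
}

#' Map clamped cosines to similarity classes
#'
#' @param scheme A [similarity_scheme()] tibble.
#' @param cosine Numeric clamped cosines in \[0, 1\].
#' @return Integer class indices.
#' @examples
#' scheme_class(similarity_scheme(), c(0, 0.09, 0.5, 1))
#' @export
scheme_class <- function(scheme, cosine) {
  stopifnot(all(cosine >= 0 & cosine <= 1))
  idx <- findInterval(cosine, c(scheme$lo, 1), rightmost.closed = TRUE)
  as.integer(pmin(idx, nrow(scheme)))
}

#' Parse a scheme string like "0:0.09:0.18:...:1"
#'
#' @param text Colon-separated break points.
#' @return A [similarity_scheme()] tibble.
#' @export
parse_scheme <- function(text) {
  similarity_scheme(as.numeric(strsplit(text, ":", fixed = TRUE)[[1]]))
}
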