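#' Tokenized corpora as tidy tables
#'
#' A tokenized corpus is represented as a tibble with one row per token and
#' columns `doc` (document index), `sentence` (sentence index within the
#' document), `pos` (token position within the sentence), `token` (surface
#' form) and `is_content` (logical content-word flag). Only content tokens
#' participate in windowed word-by-word co-occurrence counting; all tokens
#' count for vocabulary frequency and word-by-document counts.
#'
#' @param doc,sentence,pos Integer position indices.
#' @param token Character surface forms (non-empty).
#' @param is_content Logical content-word flags.
#' @return A tibble of class `tok_corpus`.
#' @examples
#' tok_corpus(
#'   doc = c(1, 1, 1), sentence = c(1, 1, 1), pos = 1:3,
#'   token = c("the", "striped", "tiger"), is_content = c(FALSE, TRUE, TRUE)
#' )
#' @export
tok_corpus <- function(doc = integer(), sentence = integer(), pos = integer(),
                       token = character(), is_content = logical()) {
  out <- tibble(
    doc = as.integer(doc), sentence = as.integer(sentence),
    pos = as.integer(pos), token = as.character(token),
    is_content = as.logical(is_content)
  )
  validate_corpus(out)
}

validate_corpus <- function(corpus) {
  stopifnot(is.data.frame(corpus))
  needed <- c("doc", "sentence", "pos", "token", "is_content")
  missing <- setdiff(needed, names(corpus))
  if (length(missing) > 0) {
    rlang::abort(paste0("corpus is missing columns: ",
                        paste(missing, collapse = ", ")))
  }
  if (any(!nzchar(corpus$token))) rlang::abort("corpus contains empty tokens")
  class(corpus) <- unique(c("tok_corpus", class(as_tibble(corpus))))
  corpus
}

#' Read a tokenized corpus file
#'
#' The corpus file format is UTF-8 plain text with one sentence per line,
#' whitespace-separated tokens, and a blank line separating documents.
#' Tokens carrying the `noncontent_prefix` (default `"_"`) are parsed as
#' non-content (function) words and the prefix is stripped.
#'
#' @param path Path to the corpus file.
#' @param noncontent_prefix Single-character marker for non-content tokens.
#' @return A [tok_corpus()] tibble.
#' @seealso [write_corpus()]
#' @export
read_corpus <- function(path, noncontent_prefix = "_") {
  if (!file.exists(path)) rlang::abort(paste0("no such corpus file: ", path))
  lines <- readr::read_lines(path)
  # trailing blank lines carry no structure
  while (length(lines) > 0 && !nzchar(trimws(lines[length(lines)]))) {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0) return(tok_corpus())
  blank <- !nzchar(trimws(lines))
  # document index: increments after each blank line
  doc_id <- cumsum(blank) + 1L
  doc_id <- as.integer(factor(doc_id[!blank])) # renumber densely
  keep <- which(!blank)
  sent_in_doc <- stats::ave(seq_along(keep), doc_id, FUN = seq_along)
  rows <- purrr::map(seq_along(keep), function(i) {
    toks <- strsplit(trimws(lines[keep[i]]), "[ \t]+")[[1]]
    if (length(toks) == 0 || any(!nzchar(toks))) {
      rlang::abort(sprintf("malformed corpus line %d: empty token", keep[i]))
    }
    noncontent <- startsWith(toks, noncontent_prefix)
    surface <- ifelse(noncontent, substring(toks, nchar(noncontent_prefix) + 1L), toks)
    if (any(!nzchar(surface))) {
      rlang::abort(sprintf("malformed corpus line %d: bare marker token", keep[i]))
    }
    tibble(
      doc = doc_id[i], sentence = as.integer(sent_in_doc[i]),
      pos = seq_along(toks), token = surface, is_content = !noncontent
    )
  })
  validate_corpus(dplyr::bind_rows(rows))
}

#' Write a tokenized corpus file
#'
#' Inverse of [read_corpus()]: one sentence per line, blank line between
#' documents, non-content tokens prefixed with `noncontent_prefix`.
#'
#' @inheritParams read_corpus
#' @param corpus A [tok_corpus()] tibble.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path, noncontent_prefix = "_") {
  corpus <- validate_corpus(corpus)
  sent_lines <- corpus |>
    dplyr::arrange(.data$doc, .data$sentence, .data$pos) |>
    dplyr::mutate(out = ifelse(.data$is_content, .data$token,
                               paste0(noncontent_prefix, .data$token))) |>
    dplyr::summarise(line = paste(.data$out, collapse = " "),
                     .by = c("doc", "sentence"))
  chunks <- split(sent_lines$line, sent_lines$doc)
  text <- unlist(purrr::imap(chunks, function(ls, i) c(ls, "")), use.names = FALSE)
  text <- text[-length(text)] # no trailing blank
  readr::write_lines(text, path)
  invisible(path)
}
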