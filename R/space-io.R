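#' Save a semantic space to a directory
#'
#' Writes `vocab.tsv` (word, freq, rank), `vectors.tsv` (word plus k
#' tab-separated reals at full precision) and a key-value `meta` file
#' (model kind, k, window, weighting, corpus id, seed, and a checksum of
#' the vectors file used as an integrity check on load).
#'
#' @param space A `semantic_space`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @seealso [load_space()]
#' @export
save_space <- function(space, dir) {
  stopifnot(inherits(space, "semantic_space"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_tsv(space$vocab, file.path(dir, "vocab.tsv"))
  vec_lines <- vapply(seq_along(space$words), function(i) {
    paste(c(space$words[i], sprintf("%.17g", space$vectors[i, ])), collapse = "\t")
  }, character(1))
  readr::write_lines(
    c(paste(c("word", colnames(space$vectors)), collapse = "\t"), vec_lines),
    file.path(dir, "vectors.tsv")
  )
  readr::write_lines(
    paste(c("singular_values", sprintf("%.17g", space$singular_values)), collapse = "\t"),
    file.path(dir, "singular_values.tsv")
  )
  meta <- space$meta
  meta$checksum <- unname(tools::md5sum(file.path(dir, "vectors.tsv")))
  readr::write_lines(
    sprintf("%s: %s", names(meta), vapply(meta, as.character, character(1))),
    file.path(dir, "meta")
  )
  invisible(dir)
}

#' Load a semantic space saved by [save_space()]
#'
#' Restores vectors to full stored precision and verifies the recorded
#' checksum of the vectors file; a mismatch or a missing component raises
#' an integrity error.
#'
#' @param dir Directory written by [save_space()].
#' @return A `semantic_space`.
#' @export
load_space <- function(dir) {
  paths <- file.path(dir, c("vocab.tsv", "vectors.tsv", "meta"))
  if (!all(file.exists(paths))) {
    rlang::abort(paste0("incomplete space directory: ", dir,
                        " (need vocab.tsv, vectors.tsv, meta)"))
  }
  meta_lines <- readr::read_lines(paths[3])
  kv <- strsplit(meta_lines, ": ", fixed = TRUE)
  meta <- setNames(lapply(kv, function(x) paste(x[-1], collapse = ": ")),
                   vapply(kv, `[[`, character(1), 1))
  if (!is.null(meta$checksum)) {
    actual <- unname(tools::md5sum(paths[2]))
    if (!identical(actual, meta$checksum)) {
      rlang::abort("space integrity error: vectors.tsv checksum mismatch")
    }
  }
  vocab <- readr::read_tsv(paths[1], show_col_types = FALSE,
                           col_types = readr::cols(word = "c"))
  vec <- readr::read_tsv(paths[2], show_col_types = FALSE,
                         col_types = readr::cols(word = "c", .default = "d"))
  vectors <- as.matrix(vec[, -1, drop = FALSE])
  rownames(vectors) <- vec$word
  sv_path <- file.path(dir, "singular_values.tsv")
  sv <- if (file.exists(sv_path)) {
    as.numeric(strsplit(readr::read_lines(sv_path), "\t")[[1]][-1])
  } else rep(NA_real_, ncol(vectors))
  k <- as.integer(meta$k)
  if (!identical(k, ncol(vectors))) {
    rlang::abort("space integrity error: meta k does not match vectors.tsv")
  }
  structure(
    list(
      words = vec$word, vectors = vectors, singular_values = sv,
      k = k, vocab = vocab,
      meta = list(model = meta$model, k = k,
                  window = suppressWarnings(as.integer(meta$window)),
                  weighting = meta$weighting, corpus_id = meta$corpus_id,
                  seed = as.integer(meta$seed))
    ),
    class = "semantic_space"
  )
}
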