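# Tab-separated readers/writers for the pipeline's tabular artifacts.

#' Read and write lexicon, item-list and trial tables
#'
#' Plain TSV formats. The item list carries one row per pair with columns
#' `prime`, `target`, `trial_type`, `cosine`, `class_index`,
#' `length_prime`, `freq_class_prime`, `length_target`,
#' `freq_class_target`; [read_items()] reassembles an `item_set` given
#' its scheme. Trial tables round-trip the [simulate_experiment()]
#' layout.
#'
#' @param path File path.
#' @param lexicon,trials Tibbles to write.
#' @param item_set An `item_set` to write.
#' @param scheme Scheme used to rebuild the `item_set` on read.
#' @return Readers return tibbles (or an `item_set`); writers return
#'   `path` invisibly.
#' @name table_io
NULL

#' @rdname table_io
#' @export
write_lexicon <- function(lexicon, path) {
  readr::write_tsv(lexicon, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_lexicon <- function(path) {
  out <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(word = "c",
                                                 .default = readr::col_guess()))
  if ("synonym_of" %in% names(out)) {
    out$synonym_of <- as.character(out$synonym_of)
  }
  out
}

#' @rdname table_io
#' @export
write_items <- function(item_set, path) {
  stopifnot(inherits(item_set, "item_set"))
  dplyr::bind_rows(item_set$word_pairs, item_set$nonword_pairs) |>
    dplyr::select("prime", "target", "trial_type", "cosine", "class_index",
                  "planned_class", "reassigned",
                  "length_prime", "freq_class_prime",
                  "length_target", "freq_class_target") |>
    readr::write_tsv(path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_items <- function(path, scheme = similarity_scheme()) {
  tab <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(prime = "c", target = "c",
                                                 trial_type = "c",
                                                 .default = readr::col_guess()))
  structure(list(
    word_pairs = dplyr::filter(tab, .data$trial_type == "word"),
    nonword_pairs = dplyr::filter(tab, .data$trial_type == "nonword"),
    scheme = scheme,
    allocation = tab |>
      dplyr::filter(.data$trial_type == "word") |>
      dplyr::count(.data$class_index, name = "realized"),
    provenance = list(path = path)
  ), class = "item_set")
}

#' @rdname table_io
#' @export
write_trials <- function(trials, path) {
  readr::write_tsv(trials, path)
  invisible(path)
}

#' @rdname table_io
#' @export
read_trials <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(subject = "c", item = "c",
                                          prime = "c", target = "c",
                                          trial_type = "c", accuracy = "c",
                                          .default = readr::col_guess()))
}
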