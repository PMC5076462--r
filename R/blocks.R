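#' Assemble item blocks with a Latin-square presentation plan
#'
#' Randomly partitions the item material into `n_blocks` blocks with a
#' fixed composition (the reference design: 4 blocks of 50 word + 25
#' nonword trials), and balances block order over participants with a
#' cyclic Latin square: participant `p` sees block order
#' `(p, p+1, ..., p+n-1) mod n`, recycled over participants, so each
#' block occupies each position equally often every `n_blocks`
#' participants. Within-block trial order is randomized per participant
#' at simulation time.
#'
#' @param item_set An `item_set` from [generate_item_set()].
#' @param n_blocks Number of blocks.
#' @param words_per_block,nonwords_per_block Block composition; the
#'   totals must match the item set exactly.
#' @param n_participant_orders Number of participant rows to lay out.
#' @param seed Integer seed for the random partition.
#' @return A `block_plan`: list with `trials` (tibble of all trials with
#'   a `block` column), `participant_orders` (matrix, one row per
#'   participant), and `n_blocks`.
#' @export
assemble_blocks <- function(item_set, n_blocks = 4, words_per_block = NULL,
                            nonwords_per_block = NULL,
                            n_participant_orders = n_blocks, seed = 1L) {
  stopifnot(inherits(item_set, "item_set"))
  n_blocks <- assert_scalar_int(n_blocks, "n_blocks", min = 1)
  nw <- nrow(item_set$word_pairs)
  nn <- nrow(item_set$nonword_pairs)
  words_per_block <- words_per_block %||% (nw / n_blocks)
  nonwords_per_block <- nonwords_per_block %||% (nn / n_blocks)
  if (words_per_block %% 1 != 0 || nonwords_per_block %% 1 != 0 ||
      words_per_block * n_blocks != nw || nonwords_per_block * n_blocks != nn) {
    rlang::abort(sprintf(
      "item counts (%d word, %d nonword) do not divide into %d blocks of %s + %s",
      nw, nn, n_blocks, format(words_per_block), format(nonwords_per_block)))
  }
  trials <- with_seed(seed, {
    dplyr::bind_rows(
      item_set$word_pairs |>
        dplyr::mutate(block = resample(rep(seq_len(n_blocks), words_per_block))),
      item_set$nonword_pairs |>
        dplyr::mutate(block = resample(rep(seq_len(n_blocks), nonwords_per_block)))
    )
  }) |>
    dplyr::arrange(.data$block) |>
    dplyr::mutate(item = paste0("i", dplyr::row_number()))
  orders <- t(vapply(seq_len(n_participant_orders), function(p) {
    ((p - 1L + seq_len(n_blocks) - 1L) %% n_blocks) + 1L
  }, integer(n_blocks)))
  structure(
    list(trials = trials, participant_orders = orders, n_blocks = n_blocks,
         schedule = list(soa_ms = 1000, timeout_ms = 3000, feedback = TRUE)),
    class = "block_plan"
  )
}

#' @export
print.block_plan <- function(x, ...) {
  comp <- dplyr::count(x$trials, .data$block, .data$trial_type)
  cat(sprintf("<block_plan: %d blocks, %d trials, %d participant orders>\n",
              x$n_blocks, nrow(x$trials), nrow(x$participant_orders)))
  print(tidyr::pivot_wider(comp, names_from = "trial_type", values_from = "n"))
  invisible(x)
}
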