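#' Configuration for a full pipeline run
#'
#' Bundles the stage parameters of the whole study emulation. Every
#' stochastic stage derives its seed deterministically from
#' `master_seed` and the stage name via [stage_seed()], so a run is
#' reproducible from the config alone.
#'
#' @param out_dir Output directory for all artifacts.
#' @param master_seed Integer master seed.
#' @param generator A [generator_config()]; its own seed is derived from
#'   `master_seed` if left at the default.
#' @param k Space dimensionality. The default (12) is scaled to the
#'   synthetic corpus; the reference setting for a 100,000-word
#'   vocabulary built from a ~880-million-token corpus is 300.
#' @param window HAL window size in content words.
#' @param vocab_cap Vocabulary cap for space building.
#' @param scheme A [similarity_scheme()].
#' @param n_pool,n_targets Word-pool sizes (reference: 300 / 200).
#' @param n_blocks Blocks per experiment.
#' @param params1,params2 [simulation_params()] for experiments 1 and 2
#'   (reference subject counts 44 and 43).
#' @param preprocess A [preprocess_config()].
#' @param max_reassignments Per-target re-assignment budget.
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir, master_seed = 1L,
                       generator = NULL, k = 12, window = 3,
                       vocab_cap = 100000, scheme = similarity_scheme(),
                       n_pool = 300, n_targets = 200, n_blocks = 4,
                       params1 = simulation_params(n_subjects = 44),
                       params2 = simulation_params(n_subjects = 43),
                       preprocess = preprocess_config(),
                       max_reassignments = 20) {
  master_seed <- assert_scalar_int(master_seed, "master_seed")
  generator <- generator %||% generator_config(seed = stage_seed(master_seed, "generator"))
  stopifnot(inherits(generator, "generator_config"),
            inherits(scheme, "data.frame"),
            inherits(params1, "simulation_params"),
            inherits(params2, "simulation_params"),
            inherits(preprocess, "preprocess_config"))
  structure(list(
    out_dir = out_dir, master_seed = master_seed, generator = generator,
    k = assert_scalar_int(k, "k", min = 1),
    window = assert_scalar_int(window, "window", min = 1),
    vocab_cap = assert_scalar_int(vocab_cap, "vocab_cap", min = 1),
    scheme = scheme, n_pool = n_pool, n_targets = n_targets,
    n_blocks = assert_scalar_int(n_blocks, "n_blocks", min = 1),
    params1 = params1, params2 = params2, preprocess = preprocess,
    max_reassignments = max_reassignments
  ), class = "run_config")
}

#' Run the full study pipeline
#'
#' Executes, in order: synthetic lexicon and corpus generation; LSA- and
#' HAL-space construction; similarity-stratified item generation for two
#' experiments (experiment 1 stratified on LSA cosines, experiment 2 on
#' HAL cosines, sharing the target pool and nonword primes); block
#' assembly; reaction-time simulation; preprocessing; the per-experiment
#' mixed-model analyses with both predictors; and the pooled
#' crossed-random-effects analysis. All intermediate artifacts are
#' written under `config$out_dir` together with a manifest recording
#' stage seeds and file checksums; re-running with the same config
#' reproduces the artifacts.
#'
#' @param config A [run_config()].
#' @param quiet Suppress progress messages.
#' @return Invisibly, a list with the in-memory artifacts: `lexicon`,
#'   `spaces`, `items`, `blocks`, `trials`, `clean`, `analyses`
#'   (per experiment x predictor), `pooled`, `correlations`, `manifest`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(sprintf(...))
  step <- function(name, code) {
    tryCatch(code, error = function(e) {
      rlang::abort(sprintf("pipeline stage '%s' failed: %s", name,
                           conditionMessage(e)))
    })
  }
  ms <- config$master_seed

  say("stage lexicon")
  lexicon <- step("lexicon", generate_lexicon(config$generator))
  write_lexicon(lexicon, file.path(config$out_dir, "lexicon.tsv"))

  say("stage corpus")
  corpus <- step("corpus", generate_corpus(config$generator, lexicon))
  write_corpus(corpus, file.path(config$out_dir, "corpus.txt"))

  say("stage spaces")
  spaces <- step("spaces", list(
    lsa = build_space(corpus, "lsa", k = config$k, vocab_cap = config$vocab_cap,
                      seed = stage_seed(ms, "space_lsa"), corpus_id = "synthetic"),
    hal = build_space(corpus, "hal", k = config$k, vocab_cap = config$vocab_cap,
                      window = config$window, seed = stage_seed(ms, "space_hal"),
                      corpus_id = "synthetic")
  ))
  save_space(spaces$lsa, file.path(config$out_dir, "space_lsa"))
  save_space(spaces$hal, file.path(config$out_dir, "space_hal"))

  say("stage items")
  pool <- step("pool", select_word_pool(
    lexicon, n_pool = config$n_pool, n_targets = config$n_targets,
    seed = stage_seed(ms, "pool"), space = spaces$lsa))
  items <- step("items", list(
    exp1 = generate_item_set(pool, config$scheme, spaces$lsa, lexicon,
                             seed = stage_seed(ms, "items_exp1"),
                             max_reassignments = config$max_reassignments),
    exp2 = generate_item_set(pool, config$scheme, spaces$hal, lexicon,
                             seed = stage_seed(ms, "items_exp2"),
                             max_reassignments = config$max_reassignments)
  ))
  # both predictors for every pair, for the cross-space analyses
  items <- purrr::map(items, add_alternative_cosines, spaces = spaces)
  write_items(items$exp1, file.path(config$out_dir, "items_exp1.tsv"))
  write_items(items$exp2, file.path(config$out_dir, "items_exp2.tsv"))

  say("stage blocks+simulate")
  blocks <- step("blocks", list(
    exp1 = assemble_blocks(items$exp1, n_blocks = config$n_blocks,
                           seed = stage_seed(ms, "blocks_exp1")),
    exp2 = assemble_blocks(items$exp2, n_blocks = config$n_blocks,
                           seed = stage_seed(ms, "blocks_exp2"))
  ))
  trials <- step("simulate", list(
    exp1 = simulate_experiment(blocks$exp1, config$params1,
                               seed = stage_seed(ms, "simulate_exp1")),
    exp2 = simulate_experiment(blocks$exp2, config$params2,
                               seed = stage_seed(ms, "simulate_exp2"))
  ))
  trials <- purrr::map2(trials, blocks, join_item_cosines)
  write_trials(trials$exp1, file.path(config$out_dir, "trials_exp1.tsv"))
  write_trials(trials$exp2, file.path(config$out_dir, "trials_exp2.tsv"))

  say("stage preprocess")
  clean <- step("preprocess", purrr::map(trials, preprocess_trials,
                                         config = config$preprocess))
  purrr::iwalk(clean, function(cl, nm) {
    readr::write_tsv(cl$exclusions,
                     file.path(config$out_dir, paste0("exclusions_", nm, ".tsv")))
  })

  say("stage analysis")
  grid <- tidyr::expand_grid(experiment = c("exp1", "exp2"),
                             predictor = c("cosine_lsa", "cosine_hal"))
  analyses <- step("analysis", purrr::pmap(grid, function(experiment, predictor) {
    run_experiment_analysis(clean[[experiment]]$trials, predictor = predictor)
  }))
  names(analyses) <- paste(grid$experiment, grid$predictor, sep = ".")
  pooled <- step("pooled", purrr::map(
    setNames(c("cosine_lsa", "cosine_hal"), c("lsa", "hal")),
    function(p) pooled_analysis(clean$exp1$trials, clean$exp2$trials,
                                predictor = p)))
  correlations <- list(
    exp1 = cosine_correlation(items$exp1, items$exp1$word_pairs$cosine_hal),
    exp2 = cosine_correlation(items$exp2, items$exp2$word_pairs$cosine_lsa)
  )
  write_analysis_reports(config$out_dir, analyses, pooled)

  manifest <- list(
    master_seed = ms,
    stage_seeds = purrr::map(
      rlang::set_names(c("pool", "items_exp1", "items_exp2", "blocks_exp1",
                         "blocks_exp2", "simulate_exp1", "simulate_exp2",
                         "space_lsa", "space_hal")),
      ~ stage_seed(ms, .x)),
    files = as.list(tools::md5sum(list.files(config$out_dir, "\\.(tsv|txt)$",
                                             full.names = TRUE)))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(lexicon = lexicon, spaces = spaces, items = items,
                 blocks = blocks, trials = trials, clean = clean,
                 analyses = analyses, pooled = pooled,
                 correlations = correlations, manifest = manifest))
}

# Clamped cosines of every word pair in both spaces.
add_alternative_cosines <- function(item_set, spaces) {
  pair_cos <- function(space, primes, targets) {
    vapply(seq_along(primes), function(i) {
      clamp_cosine(cosine(space, primes[i], targets[i]))
    }, numeric(1))
  }
  wp <- item_set$word_pairs
  item_set$word_pairs <- wp |>
    dplyr::mutate(cosine_lsa = pair_cos(spaces$lsa, wp$prime, wp$target),
                  cosine_hal = pair_cos(spaces$hal, wp$prime, wp$target))
  item_set$nonword_pairs <- item_set$nonword_pairs |>
    dplyr::mutate(cosine_lsa = NA_real_, cosine_hal = NA_real_)
  item_set
}

join_item_cosines <- function(trials, blocks) {
  extra <- blocks$trials[, c("item", "cosine_lsa", "cosine_hal")]
  dplyr::left_join(trials, extra, by = "item")
}

write_analysis_reports <- function(out_dir, analyses, pooled) {
  all <- c(analyses, setNames(pooled, paste0("pooled.", names(pooled))))
  fits <- purrr::imap(all, function(a, nm) {
    dplyr::mutate(tidy(a$full), analysis = nm, .before = 1)
  }) |> dplyr::bind_rows()
  comparison <- purrr::imap(all, function(a, nm) {
    dplyr::bind_cols(
      dplyr::mutate(a$model_comparison, analysis = nm, .before = 1),
      dplyr::bind_rows(tibble(chisq = NA_real_, df = NA_integer_,
                              p_value = NA_real_), a$lrt)
    )
  }) |> dplyr::bind_rows()
  item_means <- purrr::imap(all, function(a, nm) {
    dplyr::mutate(a$item_means, analysis = nm, .before = 1)
  }) |> dplyr::bind_rows()
  readr::write_tsv(fits, file.path(out_dir, "fits.tsv"))
  readr::write_tsv(comparison, file.path(out_dir, "model_comparison.tsv"))
  readr::write_tsv(item_means, file.path(out_dir, "item_means.tsv"))
}
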