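#' Fitness of a chromosome: train the assigned models, score word accuracy
#'
#' Decodes the chromosome into per-phoneme topology specs and a global
#' mixture count, builds and trains the model bank on the training split
#' (flat start, embedded re-estimation, incremental mixture growth), decodes
#' the fitness split through the grammar network and returns the pooled word
#' accuracy. Any training or decoding failure yields the floor fitness -100
#' (all reference words deleted) with a warning.
#'
#' @param chromosome Integer chromosome.
#' @param codec A [make_codec()] result.
#' @param train,fit [speech_corpus()] training and fitness-evaluation splits
#'   (disjoint; every phoneme must occur in `train`).
#' @param lexicon An [asr_lexicon()].
#' @param grammar An [asr_grammar()].
#' @param config A [ga_config()] (supplies EM iteration budgets).
#' @param cache Optional environment used as a fitness cache keyed on the
#'   gene vector; identical chromosomes are not retrained.
#' @param network Optional pre-compiled [compile_network()] result.
#' @return Word accuracy percentage on the fitness split.
#' @export
evaluate_fitness <- function(chromosome, codec, train, fit, lexicon, grammar,
                             config = ga_config(), cache = NULL,
                             network = NULL) {
  key <- paste(chromosome, collapse = ",")
  if (!is.null(cache) && !is.null(cache[[key]])) return(cache[[key]])
  dec <- decode_chromosome(codec, chromosome)
  if (is.null(network)) network <- compile_network(lexicon, grammar)
  val <- tryCatch({
    d <- ncol(train$features[[1]])
    ms <- model_set(dec$specs, feature_dim = d)
    trained <- train_models(ms, train, target_M = dec$n_mix,
                            n_iter = config$train_iter,
                            split_iter = config$split_iter,
                            lexicon = lexicon)
    corpus_accuracy(trained$model_set, fit, network)
  }, error = function(e) {
    warning(sprintf("fitness evaluation failed (%s); assigning floor -100",
                    conditionMessage(e)), call. = FALSE)
    -100
  })
  if (!is.null(cache)) cache[[key]] <- val
  val
}

#' Run the micro-genetic algorithm over HMM topology assignments
#'
#' Executes the full loop for `T_iter` iterations: seeded initialization,
#' fitness evaluation (training + decoding per chromosome, cached), roulette
#' selection, linear crossover with weight `alpha = 1 - beta`, scheduled
#' mutation (`beta` stepped up with run progress), and elitist replacement.
#' The best-so-far fitness is therefore monotone non-decreasing, and the
#' whole run is reproducible from the config seed.
#'
#' @param config A [ga_config()].
#' @param train,fit [speech_corpus()] training and fitness splits.
#' @param lexicon An [asr_lexicon()].
#' @param grammar An [asr_grammar()].
#' @param inventory Phoneme inventory defining the codec; defaults to the
#'   phones appearing in the training transcriptions.
#' @param verbose Print per-iteration progress.
#' @return An object of class `ga_result`: a list with `best` (individual),
#'   `assignment` (tibble: phoneme, topology, states; attribute-free), `n_mix`
#'   (optimized global mixture count), `trajectory` (tibble: iteration, best,
#'   mean, beta), `population` (final), `codec`, `config` and `n_evaluations`
#'   (unique chromosomes trained).
#' @export
run_micro_ga <- function(config, train, fit, lexicon, grammar,
                         inventory = NULL, verbose = FALSE) {
  if (is.null(inventory)) inventory <- sort(unique(unlist(train$phones)))
  codec <- make_codec(inventory)
  network <- compile_network(lexicon, grammar)
  cache <- new.env(parent = emptyenv())
  set.seed(config$seed)

  eval_ind <- function(ind) {
    if (is.na(ind$fitness)) {
      ind$fitness <- evaluate_fitness(ind$chromosome, codec, train, fit,
                                      lexicon, grammar, config,
                                      cache = cache, network = network)
    }
    ind
  }

  pop <- init_population(codec, config, seed = NULL)
  pop <- lapply(pop, eval_ind)
  fitness_of <- function(p) vapply(p, function(i) i$fitness, numeric(1))

  traj <- tibble::tibble(iteration = 0L, best = max(fitness_of(pop)),
                         mean = mean(fitness_of(pop)), beta = 0)
  for (it in seq_len(config$T_iter)) {
    w <- 100 * (it - 1) / config$T_iter
    beta <- beta_schedule(w)
    alpha <- 1 - beta
    dist <- selection_distribution(fitness_of(pop))
    sel <- roulette_select(dist, config$X)
    children <- list()
    for (cp in seq_len(nrow(sel$couples))) {
      pair <- sel$couples[cp, ]
      off <- linear_crossover(pop[[pair[1]]]$chromosome,
                              pop[[pair[2]]]$chromosome, alpha, codec)
      children <- c(children, list(off$c, off$d))
    }
    children <- c(children, mutate_parents(pop, beta, codec))
    offspring <- lapply(children, function(ch) {
      eval_ind(list(chromosome = ch, fitness = NA_real_))
    })
    pop <- replace_population(pop, offspring)
    f <- fitness_of(pop)
    traj <- dplyr::bind_rows(traj, tibble::tibble(iteration = it,
                                                  best = max(f),
                                                  mean = mean(f),
                                                  beta = beta))
    if (verbose) {
      message(sprintf("iter %d/%d: beta=%.2f best=%.2f mean=%.2f",
                      it, config$T_iter, beta, max(f), mean(f)))
    }
  }
  best <- pop[[which.max(fitness_of(pop))]]
  dec <- decode_chromosome(codec, best$chromosome)
  assignment <- tibble::tibble(
    phoneme = codec$phonemes,
    topology = vapply(dec$specs, function(s) {
      c("Bakis-1", "Bakis-2", "Ergodic")[s$topo_type + 1L]
    }, character(1)),
    states = vapply(dec$specs, function(s) s$n_states, integer(1))
  )
  structure(list(best = best, assignment = assignment, n_mix = dec$n_mix,
                 trajectory = traj, population = pop, codec = codec,
                 config = config,
                 n_evaluations = length(ls(cache))),
            class = "ga_result")
}

#' @export
print.ga_result <- function(x, ...) {
  cat(sprintf(
    "<ga_result: best fitness %.2f%% WAcc, %d mixtures, %d evaluations>\n",
    x$best$fitness, x$n_mix, x$n_evaluations))
  invisible(x)
}

#' Per-phoneme assignment table of a micro-GA run
#'
#' @param x A `ga_result`.
#' @param ... Unused.
#' @return A tibble with `phoneme`, `topology`, `states` and the global
#'   `mixtures` repeated per row (the layout of the published assignment
#'   tables).
#' @export
tidy.ga_result <- function(x, ...) {
  dplyr::mutate(x$assignment, mixtures = x$n_mix)
}

#' One-row summary of a micro-GA run
#'
#' @param x A `ga_result`.
#' @param ... Unused.
#' @return A tibble with best/initial fitness, mixture count, topology
#'   composition counts and evaluation count.
#' @export
glance.ga_result <- function(x, ...) {
  tibble::tibble(
    best_fitness = x$best$fitness,
    initial_best = x$trajectory$best[1],
    n_mix = x$n_mix,
    n_bakis1 = sum(x$assignment$topology == "Bakis-1"),
    n_bakis2 = sum(x$assignment$topology == "Bakis-2"),
    n_ergodic = sum(x$assignment$topology == "Ergodic"),
    mean_states = mean(x$assignment$states),
    iterations = max(x$trajectory$iteration),
    n_evaluations = x$n_evaluations
  )
}

#' Convergence plot of a micro-GA run
#'
#' @param object A `ga_result`.
#' @param ... Unused.
#' @return A ggplot of best and mean fitness per iteration.
#' @export
autoplot.ga_result <- function(object, ...) {
  tr <- tidyr_longer(object$trajectory)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$iteration, y = .data$wacc,
                                   linetype = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "micro-GA iteration", y = "fitness (% word accuracy)",
                  linetype = NULL) +
    ggplot2::theme_minimal()
}

# small reshape helper (avoids a tidyr dependency for one pivot)
tidyr_longer <- function(traj) {
  dplyr::bind_rows(
    tibble::tibble(iteration = traj$iteration, wacc = traj$best,
                   series = "best"),
    tibble::tibble(iteration = traj$iteration, wacc = traj$mean,
                   series = "mean")
  )
}
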