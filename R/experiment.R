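#' Matched-pairs significance test on per-sentence error counts
#'
#' Compares two recognizers scored on the same test sentences by a sign-flip
#' (randomization) test on the per-sentence error-count differences: under
#' the null of no difference, each sentence's difference is symmetric around
#' zero, so the observed sum of differences is compared against its
#' distribution over random sign assignments. Two-sided. Exact enumeration of
#' all 2^n sign assignments is used for small n (always, with a warning, for
#' fewer than 6 pairs); otherwise a seeded Monte-Carlo permutation.
#'
#' @param baseline_errors,gaop_errors Numeric vectors of per-sentence error
#'   counts (D + S + I) from the two systems, same sentences, same order.
#' @param method `"auto"` (exact up to 12 pairs), `"exact"`, or
#'   `"permutation"`.
#' @param n_resamples Monte-Carlo resamples (default 10000).
#' @param seed Seed for the Monte-Carlo draw.
#' @return A list with `p_value`, `statistic` (observed sum of differences),
#'   `n` (pairs) and `method` used.
#' @export
matched_pairs_test <- function(baseline_errors, gaop_errors,
                               method = c("auto", "exact", "permutation"),
                               n_resamples = 10000L, seed = 1L) {
  method <- match.arg(method)
  if (length(baseline_errors) != length(gaop_errors)) {
    stopf("paired score vectors must have equal length")
  }
  d <- as.numeric(baseline_errors) - as.numeric(gaop_errors)
  n <- length(d)
  if (n < 6L && method != "exact") {
    warning("fewer than 6 pairs; using exact enumeration", call. = FALSE)
    method <- "exact"
  }
  if (method == "auto") method <- if (n <= 12L) "exact" else "permutation"
  t_obs <- sum(d)
  if (method == "exact") {
    signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
    t_null <- as.numeric(signs %*% d)
    p <- mean(abs(t_null) >= abs(t_obs) - 1e-12)
  } else {
    p <- with_seed(seed, {
      hits <- 0L
      for (b in seq_len(n_resamples)) {
        t_b <- sum(d * sample(c(-1, 1), n, replace = TRUE))
        if (abs(t_b) >= abs(t_obs) - 1e-12) hits <- hits + 1L
      }
      (hits + 1) / (n_resamples + 1)
    })
  }
  list(p_value = p, statistic = t_obs, n = n, method = method)
}

#' Run the full baseline-versus-optimized comparison on a synthetic cohort
#'
#' For every speaker in the cohort: pools training data according to the
#' chosen scheme, trains each single-topology baseline recognizer (Bakis-1
#' with 3 states, Bakis-2 with 4, Ergodic with 3; all at the baseline mixture
#' order) and scores it on the speaker's fitness and test splits; then runs
#' the micro-GA (whose seeded individuals include those baselines, so its
#' fitness-set result can never fall below the best baseline), retrains the
#' winning assignment and scores it on the held-out test split. A
#' matched-pairs test compares per-sentence test errors of the best baseline
#' and the optimized system.
#'
#' @param cohort A [make_cohort()] result.
#' @param scheme Training-data scheme: `"dysarthria_specific"` pools training
#'   data within each severity level, `"scheme1_all_speakers"` pools all
#'   speakers, `"scheme2_target_only"` uses only the target speaker.
#' @param baselines Character subset of
#'   `c("bakis1", "bakis2", "ergodic")`.
#' @param config A [ga_config()]; its seed drives the GA for every speaker
#'   (offset per speaker) and `baseline_mixtures` sets the baseline mixture
#'   order.
#' @param run_ga Set `FALSE` to score baselines only.
#' @param verbose Print progress.
#' @return An object of class `asr_experiment`: `report` (tibble: speaker,
#'   level, system, states, mixtures, fitness_wacc, test_wacc),
#'   `trajectories` (per-speaker GA convergence tibbles), `assignments`
#'   (per-speaker optimized assignment tables), `matched_pairs` (tibble:
#'   speaker, p_value, statistic), `scheme`, `config`.
#' @export
run_experiment <- function(cohort,
                           scheme = c("dysarthria_specific",
                                      "scheme1_all_speakers",
                                      "scheme2_target_only"),
                           baselines = c("bakis1", "bakis2", "ergodic"),
                           config = ga_config(), run_ga = TRUE,
                           verbose = FALSE) {
  scheme <- match.arg(scheme)
  baselines <- match.arg(baselines, several.ok = TRUE)
  codec <- make_codec(cohort$inventory)
  network <- compile_network(cohort$lexicon, cohort$grammar)
  P <- codec$P
  mix <- config$baseline_mixtures
  baseline_chroms <- list(
    bakis1 = c(rep(0L, P), rep(3L, P), mix),
    bakis2 = c(rep(1L, P), rep(4L, P), mix),
    ergodic = c(rep(2L, P), rep(3L, P), mix)
  )
  baseline_names <- c(bakis1 = sprintf("SD Bakis-1 (3, %d)", mix),
                      bakis2 = sprintf("SD Bakis-2 (4, %d)", mix),
                      ergodic = sprintf("SD Ergodic (3, %d)", mix))
  levels_of <- vapply(cohort$speakers, function(s) s$level, character(1))

  pool_for <- function(s_idx) {
    keep <- switch(scheme,
                   scheme1_all_speakers = seq_along(cohort$speakers),
                   scheme2_target_only = s_idx,
                   dysarthria_specific =
                     which(levels_of == levels_of[s_idx]))
    parts <- lapply(keep, function(k) {
      cs <- corpus_split(cohort$speakers[[k]]$corpus, "train")
      cs$id <- paste0(cohort$speakers[[k]]$id, "_", cs$id)
      cs
    })
    out <- dplyr::bind_rows(parts)
    class(out) <- c("speech_corpus", class(out))
    out
  }

  # train a chromosome's models on a pool, score on fitness and test splits
  score_system <- function(chrom, pool, fitc, testc) {
    dec <- decode_chromosome(codec, chrom)
    ms <- model_set(dec$specs, feature_dim = ncol(pool$features[[1]]))
    trained <- train_models(ms, pool, target_M = dec$n_mix,
                            n_iter = config$train_iter,
                            split_iter = config$split_iter,
                            lexicon = cohort$lexicon)$model_set
    ft <- corpus_accuracy(trained, fitc, network, per_sentence = TRUE)
    te <- corpus_accuracy(trained, testc, network, per_sentence = TRUE)
    list(fitness = ft$wacc, test = te$wacc, test_sentences = te$sentences)
  }

  report <- list()
  trajectories <- list()
  assignments <- list()
  mp <- list()
  for (s in seq_along(cohort$speakers)) {
    spk <- cohort$speakers[[s]]
    pool <- pool_for(s)
    fitc <- corpus_split(spk$corpus, "fitness")
    testc <- corpus_split(spk$corpus, "test")
    if (verbose) message("speaker ", spk$id, " (", spk$level, ")")
    base_scores <- lapply(baselines, function(b) {
      sc <- tryCatch(score_system(baseline_chroms[[b]], pool, fitc, testc),
                     error = function(e) {
                       warning(sprintf("speaker %s baseline %s failed: %s",
                                       spk$id, b, conditionMessage(e)),
                               call. = FALSE)
                       NULL
                     })
      if (!is.null(sc)) {
        report[[length(report) + 1L]] <<- tibble::tibble(
          speaker = spk$id, level = spk$level, system = baseline_names[[b]],
          fitness_wacc = sc$fitness, test_wacc = sc$test)
      }
      sc
    })
    names(base_scores) <- baselines
    if (!run_ga) next
    ok <- !vapply(base_scores, is.null, logical(1))
    ga_fit <- tryCatch({
      cfg <- config
      cfg$seed <- config$seed + 17L * s
      ga <- run_micro_ga(cfg, pool, fitc, cohort$lexicon, cohort$grammar,
                         inventory = cohort$inventory, verbose = verbose)
      trajectories[[spk$id]] <- ga$trajectory
      assignments[[spk$id]] <- tidy(ga)
      sc <- score_system(ga$best$chromosome, pool, fitc, testc)
      report[[length(report) + 1L]] <- tibble::tibble(
        speaker = spk$id, level = spk$level, system = "GA-op",
        fitness_wacc = ga$best$fitness, test_wacc = sc$test)
      if (any(ok)) {
        best_b <- names(which.max(vapply(base_scores[ok],
                                         function(x) x$fitness, numeric(1))))
        mtest <- matched_pairs_test(base_scores[[best_b]]$test_sentences$errors,
                                    sc$test_sentences$errors,
                                    seed = config$seed + s)
        mp[[length(mp) + 1L]] <- tibble::tibble(
          speaker = spk$id, baseline = baseline_names[[best_b]],
          p_value = mtest$p_value, statistic = mtest$statistic)
      }
      ga
    }, error = function(e) {
      warning(sprintf("speaker %s GA stage failed: %s", spk$id,
                      conditionMessage(e)), call. = FALSE)
      NULL
    })
  }
  structure(list(report = dplyr::bind_rows(report),
                 trajectories = trajectories,
                 assignments = assignments,
                 matched_pairs = dplyr::bind_rows(mp),
                 scheme = scheme, config = config),
            class = "asr_experiment")
}

#' @export
print.asr_experiment <- function(x, ...) {
  cat(sprintf("<asr_experiment (%s): %d speakers, %d systems scored>\n",
              x$scheme, length(unique(x$report$speaker)), nrow(x$report)))
  print(x$report)
  invisible(x)
}

#' Comparison table of an experiment
#'
#' @param x An `asr_experiment`.
#' @param ... Unused.
#' @return The report tibble (speaker, level, system, fitness and test word
#'   accuracies).
#' @export
tidy.asr_experiment <- function(x, ...) x$report

#' One-row experiment summary
#'
#' @param x An `asr_experiment`.
#' @param ... Unused.
#' @return A tibble with the mean test accuracy of the best baseline and of
#'   the optimized system, their mean gain, and the share of speakers
#'   improved.
#' @export
glance.asr_experiment <- function(x, ...) {
  base <- x$report |>
    dplyr::filter(.data$system != "GA-op") |>
    dplyr::group_by(.data$speaker) |>
    dplyr::slice_max(.data$fitness_wacc, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  gaop <- dplyr::filter(x$report, .data$system == "GA-op")
  j <- dplyr::inner_join(base, gaop, by = "speaker",
                         suffix = c("_base", "_gaop"))
  tibble::tibble(
    n_speakers = nrow(j),
    mean_baseline_test = mean(j$test_wacc_base),
    mean_gaop_test = mean(j$test_wacc_gaop),
    mean_gain = mean(j$test_wacc_gaop - j$test_wacc_base),
    prop_improved = mean(j$test_wacc_gaop > j$test_wacc_base)
  )
}

#' Bar chart of baseline versus optimized test accuracy per speaker
#'
#' @param object An `asr_experiment`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.asr_experiment <- function(object, ...) {
  ggplot2::ggplot(object$report,
                  ggplot2::aes(x = .data$speaker, y = .data$test_wacc,
                               fill = .data$system)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "test word accuracy (%)", fill = NULL) +
    ggplot2::theme_minimal()
}
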