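#' Ground-truth generator specification
#'
#' Describes the synthetic speaker used to manufacture feature corpora:
#' inventory size, feature dimension (default 39, matching a 12-MFCC +
#' energy + delta + acceleration front end), the distribution of true
#' per-phoneme topologies and state counts, the true mixture order, and a
#' `separation` knob fixing the minimum distance between phone means in
#' units of the (unit) emission standard deviation.
#'
#' @param P Number of phonemes including silence (default 40).
#' @param feature_dim Feature vector dimension (default 39).
#' @param topo_probs Probabilities of a phoneme's true topology being
#'   Bakis-1 / Bakis-2 / Ergodic.
#' @param state_probs Named probabilities over state counts 3..11; the
#'   default concentrates on 3-6 states, the range typical of monophones.
#' @param n_mix True mixture components per state (default 1).
#' @param separation Minimum inter-phone mean distance in emission standard
#'   deviations (default 4).
#' @param state_spread Standard deviation of per-state mean offsets around
#'   the phone center (default 1): the magnitude of the within-phone spectral
#'   trajectory relative to the unit emission noise. Values above the
#'   separation make temporal modelling, not just the phone mean, carry the
#'   discrimination.
#' @param confusable_fraction Fraction of non-silence phones placed as
#'   "twins" of another phone: same spectral center, so the pair is
#'   distinguished only by its temporal dynamics (trajectory shape, topology
#'   and duration). Emulates the spectrally confusable phone pairs of
#'   disordered speech, where temporal modelling carries the contrast.
#'   Default 0.
#' @return An object of class `truth_spec`.
#' @export
truth_spec <- function(P = 40L, feature_dim = 39L,
                       topo_probs = c(bakis1 = 0.5, bakis2 = 0.25,
                                      ergodic = 0.25),
                       state_probs = c("3" = 0.3, "4" = 0.3, "5" = 0.2,
                                       "6" = 0.2),
                       n_mix = 1L, separation = 4, state_spread = 1,
                       confusable_fraction = 0) {
  if (P < 3L) stopf("P must be >= 3 (function word plus noun/verb classes)")
  if (separation <= 0) stopf("separation must be positive")
  stopifnot(all(names(state_probs) %in% as.character(3:11)))
  if (confusable_fraction < 0 || confusable_fraction > 1) {
    stopf("confusable_fraction must be in [0, 1]")
  }
  structure(list(P = as.integer(P), feature_dim = as.integer(feature_dim),
                 topo_probs = topo_probs / sum(topo_probs),
                 state_probs = state_probs / sum(state_probs),
                 n_mix = as.integer(n_mix), separation = separation,
                 state_spread = state_spread,
                 confusable_fraction = confusable_fraction),
            class = "truth_spec")
}

#' Severity profile for synthetic dysarthric speech
#'
#' Three knobs emulate hallmark acoustic consequences of dysarthria:
#' `duration_dilation` multiplies self-loop odds (phoneme prolongation from
#' slowed speaking rate), `variance_inflation` scales emission variances
#' (articulatory imprecision), and `substitution_rate` is the probability
#' that a phone is realized as its nearest confusable while the transcription
#' keeps the intended words (the errors are acoustic). A neutral profile is
#' `(1, 1, 0)`. No claim of clinical realism is made.
#'
#' @param duration_dilation Multiplicative self-loop boost, `>= 1`.
#' @param variance_inflation Multiplicative variance scale, `>= 1`.
#' @param substitution_rate Phone substitution probability in `[0, 1]`.
#' @return An object of class `severity_profile`.
#' @export
severity_profile <- function(duration_dilation = 1, variance_inflation = 1,
                             substitution_rate = 0) {
  if (duration_dilation < 1 || variance_inflation < 1) {
    stopf("dilation and inflation multipliers must be >= 1")
  }
  if (substitution_rate < 0 || substitution_rate > 1) {
    stopf("substitution_rate must be in [0, 1]")
  }
  structure(list(duration_dilation = duration_dilation,
                 variance_inflation = variance_inflation,
                 substitution_rate = substitution_rate),
            class = "severity_profile")
}

#' Preset severity profiles by dysarthria level
#'
#' @param level `"none"`, `"mild"`, `"moderate"` or `"severe"`.
#' @return A [severity_profile()].
#' @export
severity_preset <- function(level = c("none", "mild", "moderate", "severe")) {
  switch(match.arg(level),
         none = severity_profile(1, 1, 0),
         mild = severity_profile(1.1, 1.2, 0.02),
         moderate = severity_profile(1.4, 1.6, 0.06),
         severe = severity_profile(1.8, 2.2, 0.12))
}

#' Apply a severity profile to a model bank
#'
#' Boosts self-loop probabilities by the dilation factor (rows renormalized),
#' scales emission variances by the inflation factor. Substitution is applied
#' at synthesis time, not here.
#'
#' @param model_set A [model_set()].
#' @param severity A [severity_profile()].
#' @return The transformed `model_set`.
#' @export
apply_severity <- function(model_set, severity) {
  model_set$hmms <- lapply(model_set$hmms, function(h) {
    n <- h$spec$n_states
    for (i in seq_len(n)) {
      row <- c(h$trans[i, ], h$exit[i])
      row[i] <- row[i] * severity$duration_dilation
      row <- row / sum(row)
      h$trans[i, ] <- row[seq_len(n)]
      h$exit[i] <- row[n + 1L]
    }
    h$states <- lapply(h$states, function(st) {
      st$var <- st$var * severity$variance_inflation
      st
    })
    h
  })
  model_set
}

#' Generate ground-truth phone models
#'
#' Draws each phoneme's true topology and state count from the spec's
#' distributions (silence is fixed at Bakis-1 with 3 states, as assignment
#' tables for real speakers consistently show), places phone mean vectors so
#' the minimum pairwise distance equals `separation`, and adds unit-variance
#' emission noise with mild per-state mean offsets.
#'
#' @param spec A [truth_spec()].
#' @param seed Integer seed (deterministic output).
#' @param inventory Optional phoneme labels; defaults to
#'   [default_phone_inventory()] when `P = 40`, else `p01..pNN` plus `"sil"`.
#' @return A list with `model_set` (the truth bank) and `assignment`
#'   (tibble: phoneme, topology, states).
#' @export
make_truth_models <- function(spec = truth_spec(), seed = 1L,
                              inventory = NULL) {
  if (is.null(inventory)) {
    inventory <- if (spec$P == 40L) default_phone_inventory() else {
      c(sprintf("p%02d", seq_len(spec$P - 1L)), "sil")
    }
  }
  stopifnot(length(inventory) == spec$P, "sil" %in% inventory)
  with_seed(seed, {
    topo <- sample(0:2, spec$P, replace = TRUE, prob = spec$topo_probs)
    state_vals <- as.integer(names(spec$state_probs))
    nst <- state_vals[sample.int(length(state_vals), spec$P, replace = TRUE,
                                 prob = spec$state_probs)]
    topo[inventory == "sil"] <- 0L
    nst[inventory == "sil"] <- 3L
    d <- spec$feature_dim
    centers <- matrix(rnorm(spec$P * d), spec$P, d)
    dmin <- min(stats::dist(centers))
    centers <- centers * (spec$separation / dmin)
    # spectrally confusable twins: same center, dynamics carry the contrast
    cf <- spec$confusable_fraction %||% 0
    if (cf > 0) {
      nonsil <- which(inventory != "sil")
      n_twin <- floor(cf * length(nonsil) / 2) * 2L
      if (n_twin >= 2L) {
        twins <- matrix(sample(nonsil, n_twin), ncol = 2L)
        centers[twins[, 2L], ] <- centers[twins[, 1L], ]
      }
    }
    specs <- lapply(seq_len(spec$P), function(j) topology_spec(topo[j], nst[j]))
    names(specs) <- inventory
    ms <- model_set(specs, feature_dim = d, n_mix = spec$n_mix)
    ms$hmms <- lapply(seq_len(spec$P), function(j) {
      h <- ms$hmms[[j]]
      n <- h$spec$n_states
      # truth transitions: moderate self-loops so durations average ~2 frames
      tr <- truth_transitions(h$mask)
      h$entry <- tr$entry; h$trans <- tr$trans; h$exit <- tr$exit
      h$states <- lapply(seq_len(n), function(s) {
        off <- rnorm(d, sd = spec$state_spread)
        M <- spec$n_mix
        mu <- matrix(rep(centers[j, ] + off, M), M, d, byrow = TRUE) +
          matrix(rnorm(M * d, sd = 0.3), M, d)
        list(w = rep(1 / M, M), mu = mu, var = matrix(1, M, d))
      })
      h
    })
    names(ms$hmms) <- inventory
    list(model_set = ms,
         assignment = tibble::tibble(
           phoneme = inventory,
           topology = c("Bakis-1", "Bakis-2", "Ergodic")[topo + 1L],
           states = as.integer(nst)))
  })
}

truth_transitions <- function(mask) {
  n <- length(mask$entry)
  trans <- matrix(0, n, n)
  exit <- numeric(n)
  if (mask$spec$topo_type == 2L) {
    entry <- rep(1 / n, n)
    for (i in seq_len(n)) {
      row <- rep(0.4 / n, n)   # spread over all states
      row[i] <- row[i] + 0.35  # plus a dwell component
      exit[i] <- 1 - sum(row)
      trans[i, ] <- row
    }
  } else {
    entry <- c(1, rep(0, n - 1L))
    for (i in seq_len(n)) {
      targets <- which(mask$trans[i, ] & seq_len(n) != i)
      adv <- 0.5
      trans[i, i] <- 0.5
      if (length(targets) > 0L) {
        w <- rev(seq_along(targets))  # favour the nearest forward state
        trans[i, targets] <- adv * w / sum(w)
        if (mask$exit[i]) {
          # last reachable rows share advance mass with the exit arc
          trans[i, targets] <- trans[i, targets] * 0.5
          exit[i] <- adv * 0.5
        }
      } else {
        exit[i] <- adv
      }
    }
  }
  list(entry = entry, trans = trans, exit = exit)
}

#' Build a toy lexicon and nonsense-sentence grammar
#'
#' Emulates the structure of the small-vocabulary nonsense-sentence corpus:
#' monosyllabic nouns (2-4 phones), bisyllabic verbs (4-6 phones) and the
#' function words "the" and "is", arranged in the six-slot template
#' "the X is Y the Z". Pronunciations are drawn at random from the
#' non-silence inventory and are guaranteed distinct.
#'
#' @param n_nouns Number of nouns (default 74; at least 2).
#' @param n_verbs Number of verbs (default 37; at least 1).
#' @param inventory Phoneme inventory (silence excluded from pronunciations).
#' @param seed Integer seed.
#' @return A list with `lexicon` ([asr_lexicon()]) and `grammar`
#'   ([asr_grammar()], kind `sentence_template`).
#' @export
build_toy_lexicon <- function(n_nouns = 74L, n_verbs = 37L,
                              inventory = default_phone_inventory(),
                              seed = 1L) {
  if (n_nouns < 2L || n_verbs < 1L) {
    stopf("need n_nouns >= 2 and n_verbs >= 1")
  }
  phones <- setdiff(inventory, "sil")
  if (length(phones) < 2L) stopf("phone inventory too small to build words")
  with_seed(seed, {
    draw_pron <- function(len_range) {
      len <- sample(len_range, 1L)
      sample(phones, len, replace = length(phones) < len)
    }
    draw_distinct <- function(k, len_range, taken) {
      out <- list()
      attempts <- 0L
      while (length(out) < k) {
        attempts <- attempts + 1L
        if (attempts > 200L * k) {
          stopf("phone inventory too small to build %d distinct words", k)
        }
        p <- draw_pron(len_range)
        key <- paste(p, collapse = " ")
        if (!key %in% taken) {
          taken <- c(taken, key)
          out[[length(out) + 1L]] <- p
        }
      }
      list(prons = out, taken = taken)
    }
    fw <- draw_distinct(2L, 2:2, character(0))        # the, is
    nn <- draw_distinct(n_nouns, 2:4, fw$taken)
    vb <- draw_distinct(n_verbs, 4:6, nn$taken)
    nouns <- sprintf("noun%02d", seq_len(n_nouns))
    verbs <- sprintf("verb%02d", seq_len(n_verbs))
    lex <- asr_lexicon(c("the", "is", nouns, verbs),
                       c(fw$prons, nn$prons, vb$prons),
                       inventory = inventory)
    grammar <- asr_grammar("sentence_template",
                           list("the", nouns, "is", verbs, "the", nouns))
    list(lexicon = lex, grammar = grammar)
  })
}

#' Synthesize sentences from ground-truth models
#'
#' Word sequences follow the nonsense-corpus generation scheme: nouns are
#' paired without replacement as X and Z (X != Z) and verbs drawn without
#' replacement to form the base sentences, then each base sentence is
#' duplicated with X and Z swapped, so every noun and verb occurs in two
#' sentences. When `n` exceeds that capacity the scheme restarts with a fresh
#' random pairing (with a message). Features are sampled from the
#' severity-transformed truth models; at `substitution_rate`, individual
#' phones are realized as their nearest confusable while the word and phone
#' transcriptions keep the intended sentence.
#'
#' @param truth A truth `model_set` (from [make_truth_models()]).
#' @param lexicon An [asr_lexicon()].
#' @param grammar A six-slot template [asr_grammar()].
#' @param n Number of sentences (default 74).
#' @param severity A [severity_profile()].
#' @param seed Integer seed.
#' @return A [speech_corpus()] with `split = NA`.
#' @export
synthesize_sentences <- function(truth, lexicon, grammar, n = 74L,
                                 severity = severity_profile(), seed = 1L) {
  stopifnot(inherits(truth, "model_set"), n >= 1L)
  nouns <- grammar$slots[[2L]]
  verbs <- grammar$slots[[4L]]
  gen_models <- apply_severity(truth, severity)
  confusable <- confusable_map(truth)
  with_seed(seed, {
    seqs <- list()
    while (length(seqs) < n) {
      base_n <- min(floor(length(nouns) / 2), length(verbs))
      if (base_n < 1L) stopf("grammar has too few nouns/verbs")
      ns <- sample(nouns)
      vs <- sample(verbs)
      base <- lapply(seq_len(base_n), function(b) {
        c("the", ns[2L * b - 1L], "is", vs[b], "the", ns[2L * b])
      })
      swapped <- lapply(base, function(s) s[c(1L, 6L, 3L, 4L, 5L, 2L)])
      if (length(seqs) + 2L * base_n > n && length(seqs) > 0L) {
        message("sentence request exceeds non-replacement capacity; ",
                "restarting the pairing scheme with replacement")
      }
      seqs <- c(seqs, base, swapped)
    }
    seqs <- seqs[seq_len(n)]
    feats <- vector("list", n)
    phones <- vector("list", n)
    for (i in seq_len(n)) {
      ph <- expand_phones(seqs[[i]], lexicon)
      realized <- ph
      if (severity$substitution_rate > 0) {
        for (k in which(realized != "sil")) {
          if (runif(1) < severity$substitution_rate) {
            realized[k] <- confusable[[realized[k]]]
          }
        }
      }
      chain <- gen_models$hmms[realized]
      feats[[i]] <- sample_from_models(chain, seed = NULL)$features
      phones[[i]] <- ph
    }
    speech_corpus(id = sprintf("s%04d", seq_len(n)), features = feats,
                  words = seqs, phones = phones)
  })
}

# nearest phone by overall mean distance (acoustic confusability proxy)
confusable_map <- function(truth) {
  labs <- names(truth$hmms)
  means <- t(vapply(truth$hmms, function(h) {
    colMeans(do.call(rbind, lapply(h$states, function(st) {
      colSums(st$mu * st$w)
    })))
  }, numeric(truth$feature_dim)))
  dm <- as.matrix(stats::dist(means))
  diag(dm) <- Inf
  dm[, labs == "sil"] <- Inf  # never substitute toward silence
  out <- lapply(seq_along(labs), function(i) labs[which.min(dm[i, ])])
  names(out) <- labs
  out
}

#' Tag a corpus with train / fitness / test splits
#'
#' Sentence-level random split into the three tasks; the draw is repeated
#' (up to 100 attempts) until the training split covers every phoneme, so
#' every model can be flat-started and re-estimated.
#'
#' @param corpus A [speech_corpus()].
#' @param fractions Numeric of length 3 summing to 1 (train, fitness, test).
#' @param seed Integer seed.
#' @param inventory Phoneme inventory the train split must cover; defaults to
#'   all phones occurring in the corpus.
#' @return The corpus with `split` filled in.
#' @export
make_splits <- function(corpus, fractions = c(train = 0.5, fitness = 0.25,
                                              test = 0.25),
                        seed = 1L, inventory = NULL) {
  if (abs(sum(fractions) - 1) > 1e-8) stopf("fractions must sum to 1")
  n <- nrow(corpus)
  if (is.null(inventory)) inventory <- unique(unlist(corpus$phones))
  sizes <- floor(fractions * n)
  rem <- n - sum(sizes)
  if (rem > 0) {
    extra <- order(fractions * n - sizes, decreasing = TRUE)[seq_len(rem)]
    sizes[extra] <- sizes[extra] + 1L
  }
  tags <- rep(c("train", "fitness", "test"), times = sizes)
  with_seed(seed, {
    for (attempt in seq_len(100L)) {
      perm <- sample.int(n)
      split <- character(n)
      split[perm] <- tags
      covered <- unique(unlist(corpus$phones[split == "train"]))
      if (all(inventory %in% covered)) {
        corpus$split <- split
        return(corpus)
      }
    }
    stopf("could not cover all phonemes in the training split after 100 draws; use a larger corpus")
  })
}

#' Generate a cohort of synthetic dysarthric speakers
#'
#' All speakers share one lexicon and grammar; each speaker gets its own
#' truth models (fresh topology/state draws plus per-speaker mean jitter)
#' transformed by the severity preset of its level, and a split corpus. The
#' default level mix (4 mild, 3 moderate, 3 severe) mirrors the grouping of
#' small dysarthric-speech study panels.
#'
#' @param n_speakers Number of speakers (default 10).
#' @param levels Character vector of severity levels per speaker.
#' @param spec A [truth_spec()].
#' @param n_sentences Sentences per speaker (default 74).
#' @param n_nouns,n_verbs Lexicon size (defaults 74 / 37).
#' @param fractions Split fractions (train, fitness, test).
#' @param seed Integer seed.
#' @return A list with `speakers` (list of per-speaker lists: `id`, `level`,
#'   `truth`, `assignment`, `corpus`), `lexicon`, `grammar`, `inventory`.
#' @export
make_cohort <- function(n_speakers = 10L,
                        levels = c(rep("mild", 4), rep("moderate", 3),
                                   rep("severe", 3)),
                        spec = truth_spec(), n_sentences = 74L,
                        n_nouns = 74L, n_verbs = 37L,
                        fractions = c(train = 0.5, fitness = 0.25,
                                      test = 0.25),
                        seed = 1L) {
  stopifnot(length(levels) == n_speakers)
  base_seed <- as.integer(seed)
  inventory <- if (spec$P == 40L) default_phone_inventory() else {
    c(sprintf("p%02d", seq_len(spec$P - 1L)), "sil")
  }
  lex <- build_toy_lexicon(n_nouns, n_verbs, inventory = inventory,
                           seed = base_seed)
  speakers <- lapply(seq_len(n_speakers), function(s) {
    sseed <- base_seed + 1000L * s
    tm <- make_truth_models(spec, seed = sseed, inventory = inventory)
    corpus <- synthesize_sentences(tm$model_set, lex$lexicon, lex$grammar,
                                   n = n_sentences,
                                   severity = severity_preset(levels[s]),
                                   seed = sseed + 1L)
    corpus <- make_splits(corpus, fractions, seed = sseed + 2L,
                          inventory = inventory)
    list(id = sprintf("spk%02d", s), level = levels[s],
         truth = tm$model_set, assignment = tm$assignment, corpus = corpus)
  })
  list(speakers = speakers, lexicon = lex$lexicon, grammar = lex$grammar,
       inventory = inventory)
}
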