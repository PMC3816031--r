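#' Compile a lexicon and grammar into a decoding network
#'
#' Builds the word-level structure of the recognition network: each word
#' instance is the concatenation of its pronunciation's phone models, slots of
#' a sentence template are wired in order (uniform word-transition
#' probabilities; no language model), and silence models bracket the
#' utterance. A `word_loop` grammar wires all vocabulary words in parallel
#' with return arcs; word models are duplicated into two alternating banks so
#' immediate word repetitions remain recoverable from the state path.
#'
#' The network stores structure only; acoustic parameters are bound at decode
#' time from the model set passed to [viterbi_decode()].
#'
#' @param lexicon An [asr_lexicon()].
#' @param grammar An [asr_grammar()].
#' @param sil Label of the silence phone bracketing the utterance (set to
#'   `NULL` to omit).
#' @param max_loop_words For `word_loop` grammars, maximum number of words in
#'   a hypothesis (loop is unrolled implicitly; this only bounds decoding
#'   through the exit arc and is not a hard limit on path length).
#' @return An object of class `decode_network`.
#' @export
compile_network <- function(lexicon, grammar, sil = "sil",
                            max_loop_words = NULL) {
  all_words <- unique(unlist(grammar$slots))
  missing <- setdiff(all_words, lexicon$word)
  if (length(missing) > 0L) {
    stopf("grammar word(s) missing from lexicon: %s",
          paste(missing, collapse = ", "))
  }
  # order words within a slot by lexicon order for deterministic tie behaviour
  slots <- lapply(grammar$slots, function(ws) {
    ws[order(match(ws, lexicon$word))]
  })

  labels <- character(0)
  word_of <- integer(0)      # word-instance id per phone instance
  word_labels <- character(0)
  arcs <- list()
  first_inst <- list()       # per word instance: first/last phone instance
  last_inst <- list()

  add_word <- function(w) {
    pron <- lexicon_lookup(lexicon, w)[[1]]
    wid <- length(word_labels) + 1L
    word_labels[[wid]] <<- w
    start <- length(labels) + 1L
    labels <<- c(labels, pron)
    word_of <<- c(word_of, rep(wid, length(pron)))
    if (length(pron) > 1L) {
      arcs[[length(arcs) + 1L]] <<-
        data.frame(from = start + seq_len(length(pron) - 1L) - 1L,
                   to = start + seq_len(length(pron) - 1L), logp = 0)
    }
    first_inst[[wid]] <<- start
    last_inst[[wid]] <<- start + length(pron) - 1L
    wid
  }
  add_sil <- function() {
    start <- length(labels) + 1L
    labels <<- c(labels, sil)
    word_of <<- c(word_of, 0L)
    start
  }
  connect <- function(from_insts, to_insts, logp) {
    arcs[[length(arcs) + 1L]] <<-
      expand.grid(from = from_insts, to = to_insts, KEEP.OUT.ATTRS = FALSE) |>
      transform(logp = logp)
  }

  use_sil <- !is.null(sil)
  if (grammar$kind == "sentence_template") {
    slot_ids <- lapply(slots, function(ws) vapply(ws, add_word, integer(1)))
    sil_in <- if (use_sil) add_sil() else NULL
    sil_out <- if (use_sil) add_sil() else NULL
    for (s in seq_along(slot_ids)[-1]) {
      prev_last <- unlist(last_inst[slot_ids[[s - 1L]]])
      cur_first <- unlist(first_inst[slot_ids[[s]]])
      connect(prev_last, cur_first, -log(length(cur_first)))
    }
    heads <- unlist(first_inst[slot_ids[[1L]]])
    tails <- unlist(last_inst[slot_ids[[length(slot_ids)]]])
    if (use_sil) {
      connect(sil_in, heads, -log(length(heads)))
      connect(tails, sil_out, 0)
      entry <- data.frame(inst = sil_in, logp = 0)
      exit <- data.frame(inst = sil_out, logp = 0)
    } else {
      entry <- data.frame(inst = heads, logp = -log(length(heads)))
      exit <- data.frame(inst = tails, logp = 0)
    }
  } else {
    words <- slots[[1L]]
    # two alternating banks so consecutive repeats of a word change instance
    bank_a <- vapply(words, add_word, integer(1))
    bank_b <- vapply(words, add_word, integer(1))
    sil_in <- if (use_sil) add_sil() else NULL
    sil_out <- if (use_sil) add_sil() else NULL
    n_next <- length(words) + 1L  # continue to any word, or stop
    for (wid in bank_a) {
      connect(last_inst[[wid]], unlist(first_inst[bank_b]), -log(n_next))
    }
    for (wid in bank_b) {
      connect(last_inst[[wid]], unlist(first_inst[bank_a]), -log(n_next))
    }
    heads <- unlist(first_inst[bank_a])
    tails <- c(unlist(last_inst[bank_a]), unlist(last_inst[bank_b]))
    if (use_sil) {
      connect(sil_in, heads, -log(length(words)))
      connect(tails, sil_out, -log(n_next))
      entry <- data.frame(inst = sil_in, logp = 0)
      exit <- data.frame(inst = sil_out, logp = 0)
    } else {
      entry <- data.frame(inst = heads, logp = -log(length(words)))
      exit <- data.frame(inst = tails, logp = -log(n_next))
    }
  }

  arcs <- if (length(arcs)) do.call(rbind, arcs) else {
    data.frame(from = integer(0), to = integer(0), logp = numeric(0))
  }
  structure(list(struct = composite_structure(labels, arcs, entry, exit,
                                              word_of),
                 word_labels = word_labels, grammar_kind = grammar$kind,
                 sil = if (use_sil) sil else NA_character_),
            class = "decode_network")
}

#' @export
print.decode_network <- function(x, ...) {
  cat(sprintf("<decode_network (%s): %d phone instances, %d word instances>\n",
              x$grammar_kind, length(x$struct$labels),
              length(x$word_labels)))
  invisible(x)
}

# Bind acoustic parameters to a network structure.
instantiate_network <- function(network, model_set) {
  bad <- setdiff(unique(network$struct$labels), names(model_set$hmms))
  if (length(bad) > 0L) {
    stopf("network uses phone(s) missing from the model set: %s",
          paste(bad, collapse = ", "))
  }
  instantiate_composite(network$struct,
                        function(k) model_set$hmms[[network$struct$labels[k]]],
                        tie = "label")
}

#' Viterbi word recognition
#'
#' Finds the maximum-log-probability admissible path through the decoding
#' network for a feature sequence and reads the word sequence off the state
#' path (silence is dropped from the hypothesis). Ties are resolved
#' deterministically toward the lowest-numbered state, i.e. earliest word in
#' lexicon order.
#'
#' @param model_set A trained [model_set()].
#' @param network A [compile_network()] result.
#' @param features A numeric frames-by-dimensions matrix.
#' @param comp Optional pre-instantiated network (internal; lets
#'   [corpus_accuracy()] bind parameters once for many sentences).
#' @return A list with `words` (character hypothesis; empty if no admissible
#'   path), `score` (path log-probability; `-Inf` if none) and `failed`
#'   (logical).
#' @export
viterbi_decode <- function(model_set, network, features, comp = NULL) {
  if (is.null(comp)) comp <- instantiate_network(network, model_set)
  if (!is.matrix(features) || nrow(features) == 0L) {
    stopf("features must be a non-empty matrix of frames")
  }
  res <- .cpp_viterbi(comp$logpi, comp$logA, comp$logeta,
                      composite_logB(comp, features))
  if (!length(res$path)) {
    return(list(words = character(0), score = -Inf, failed = TRUE))
  }
  wid <- comp$smap$word[res$path]
  runs <- rle(wid)$values
  runs <- runs[runs != 0L]
  list(words = network$word_labels[runs], score = res$score, failed = FALSE)
}

#' Pooled word accuracy of a model set over a corpus
#'
#' Decodes every sentence in the corpus with [viterbi_decode()], aligns each
#' hypothesis against its reference with [align_transcripts()], pools the
#' counts N, D, S, I across sentences and applies the word-accuracy formula.
#' Failed decodes count as deletions of all reference words.
#'
#' @param model_set A trained [model_set()].
#' @param corpus A [speech_corpus()].
#' @param network A [compile_network()] result.
#' @param per_sentence If `TRUE`, also return the per-sentence alignment
#'   count table.
#' @return The pooled word accuracy (percentage, may be negative). With
#'   `per_sentence = TRUE`, a list with `wacc` and a tibble `sentences`
#'   (`id`, `N`, `D`, `S`, `I`, `errors`).
#' @export
corpus_accuracy <- function(model_set, corpus, network,
                            per_sentence = FALSE) {
  if (nrow(corpus) == 0L) stopf("corpus is empty")
  comp <- instantiate_network(network, model_set)
  rows <- lapply(seq_len(nrow(corpus)), function(i) {
    ref <- corpus$words[[i]]
    hyp <- viterbi_decode(model_set, network, corpus$features[[i]],
                          comp = comp)
    a <- if (hyp$failed) {
      list(N = length(ref), D = length(ref), S = 0L, I = 0L)
    } else {
      align_transcripts(ref, hyp$words)
    }
    tibble::tibble(id = corpus$id[i], N = a$N, D = a$D, S = a$S, I = a$I,
                   errors = a$D + a$S + a$I)
  })
  tab <- dplyr::bind_rows(rows)
  wacc <- 100 * (sum(tab$N) - sum(tab$D) - sum(tab$S) - sum(tab$I)) /
    sum(tab$N)
  if (per_sentence) list(wacc = wacc, sentences = tab) else wacc
}
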