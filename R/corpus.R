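#' Speech corpus container
#'
#' A speech corpus is a tibble with one row per sentence and columns:
#' `id` (character sentence identifier), `features` (list of `T` by `d`
#' numeric matrices, one acoustic frame per row), `words` (list of character
#' word transcriptions), `phones` (list of character phone transcriptions,
#' including boundary silences), and `split` (one of `"train"`, `"fitness"`,
#' `"test"`, or `NA` before [make_splits()] is applied).
#'
#' @param id Character vector of sentence identifiers (unique).
#' @param features List of numeric matrices (frames by dimensions).
#' @param words List of character vectors (word transcriptions).
#' @param phones List of character vectors (phone transcriptions).
#' @param split Optional character vector of split tags.
#' @return A tibble of class `speech_corpus`.
#' @export
speech_corpus <- function(id, features, words, phones,
                          split = rep(NA_character_, length(id))) {
  if (anyDuplicated(id)) stopf("sentence ids must be unique")
  out <- tibble::tibble(id = as.character(id), features = features,
                        words = words, phones = phones,
                        split = as.character(split))
  class(out) <- c("speech_corpus", class(out))
  out
}

corpus_split <- function(corpus, which) {
  out <- corpus[!is.na(corpus$split) & corpus$split == which, ]
  class(out) <- unique(c("speech_corpus", class(out)))
  out
}

#' Build a pronunciation lexicon
#'
#' @param words Character vector of words (unique).
#' @param prons List of character vectors, the phone sequence of each word.
#' @param inventory Optional phoneme inventory to validate pronunciations
#'   against.
#' @return A tibble of class `asr_lexicon` with columns `word` and `phones`.
#' @examples
#' asr_lexicon(c("the", "bat"), list(c("dh", "ah"), c("b", "ae", "t")))
#' @export
asr_lexicon <- function(words, prons, inventory = NULL) {
  if (anyDuplicated(words)) stopf("lexicon words must be unique")
  if (length(words) != length(prons)) {
    stopf("words and prons must have equal length")
  }
  if (!is.null(inventory)) {
    bad <- setdiff(unique(unlist(prons)), inventory)
    if (length(bad) > 0L) {
      stopf("pronunciation phone(s) outside the inventory: %s",
            paste(bad, collapse = ", "))
    }
  }
  out <- tibble::tibble(word = as.character(words), phones = prons)
  class(out) <- c("asr_lexicon", class(out))
  out
}

lexicon_lookup <- function(lexicon, word) {
  i <- match(word, lexicon$word)
  if (anyNA(i)) {
    stopf("word(s) missing from lexicon: %s",
          paste(word[is.na(i)], collapse = ", "))
  }
  lexicon$phones[i]
}

#' Sentence grammar
#'
#' Two grammar kinds are supported: a `sentence_template` (an ordered list of
#' slots, each slot a set of allowed words, e.g. the six-slot nonsense frame
#' "the X is Y the Z") and a `word_loop` (any sequence of vocabulary words).
#'
#' @param kind `"sentence_template"` or `"word_loop"`.
#' @param slots For templates, a list of character vectors (allowed words per
#'   slot, in order). For word loops, a single character vector of words.
#' @return An object of class `asr_grammar`.
#' @export
asr_grammar <- function(kind = c("sentence_template", "word_loop"), slots) {
  kind <- match.arg(kind)
  if (kind == "word_loop" && is.character(slots)) slots <- list(slots)
  if (!length(slots) || any(!lengths(slots))) {
    stopf("grammar slots must be non-empty")
  }
  structure(list(kind = kind, slots = lapply(slots, as.character)),
            class = "asr_grammar")
}

#' @export
print.asr_grammar <- function(x, ...) {
  cat(sprintf("<asr_grammar %s, %d slot(s)>\n", x$kind, length(x$slots)))
  invisible(x)
}

#' Count or enumerate the word sequences a grammar admits
#'
#' For a sentence template, admissible sequences are the Cartesian product of
#' the slots; for a word loop, all sequences of the given length.
#'
#' @param grammar An [asr_grammar()].
#' @param length_ Sequence length; required for `word_loop`, ignored for
#'   templates (which fix the length at the number of slots).
#' @return Number of admissible word sequences (a double, as counts grow
#'   combinatorially).
#' @export
count_admissible_sequences <- function(grammar, length_ = NULL) {
  if (grammar$kind == "sentence_template") {
    prod(vapply(grammar$slots, length, integer(1)))
  } else {
    if (is.null(length_)) stopf("length_ is required for word_loop grammars")
    length(grammar$slots[[1]])^length_
  }
}

# Expand a word sequence to its phone sequence, with silence at the sentence
# boundaries and optionally between words.
expand_phones <- function(words, lexicon, sil = "sil", interword_sil = FALSE) {
  prons <- lexicon_lookup(lexicon, words)
  sep <- if (interword_sil) list(sil) else list(character(0))
  body <- unlist(mapply(function(p, last) c(p, if (!last) sep[[1]]),
                        prons, seq_along(prons) == length(prons),
                        SIMPLIFY = FALSE))
  c(sil, body, sil)
}
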