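#' Minimal-edit alignment of a hypothesis against a reference
#'
#' Dynamic-programming string alignment with unit costs for deletions,
#' substitutions and insertions (the raw operation counts entering the
#' word-accuracy formula). Backtrace prefers matches, then substitutions,
#' then deletions, then insertions, which makes the D/S/I decomposition
#' deterministic; the total `D + S + I` is the Levenshtein distance.
#'
#' @param ref Character vector, the correct transcription (may be empty).
#' @param hyp Character vector, the recognizer output (may be empty).
#' @return An object of class `alignment_result`: a list with counts `N`
#'   (reference length), `D`, `S`, `I`, and `pairs`, a tibble with columns
#'   `ref`, `hyp`, `op` (`"match"`, `"sub"`, `"del"`, `"ins"`).
#' @examples
#' align_transcripts(c("a", "b", "c", "d"), c("a", "c", "d"))
#' @export
align_transcripts <- function(ref, hyp) {
  n <- length(ref)
  m <- length(hyp)
  D <- matrix(0L, n + 1L, m + 1L)
  D[, 1L] <- 0:n
  D[1L, ] <- 0:m
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      sub <- D[i, j] + (ref[i] != hyp[j])
      D[i + 1L, j + 1L] <- min(sub, D[i, j + 1L] + 1L, D[i + 1L, j] + 1L)
    }
  }
  # backtrace
  i <- n; j <- m
  ops <- character(0); rr <- character(0); hh <- character(0)
  while (i > 0L || j > 0L) {
    if (i > 0L && j > 0L && D[i + 1L, j + 1L] == D[i, j] + (ref[i] != hyp[j])) {
      ops <- c(if (ref[i] == hyp[j]) "match" else "sub", ops)
      rr <- c(ref[i], rr); hh <- c(hyp[j], hh)
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && D[i + 1L, j + 1L] == D[i, j + 1L] + 1L) {
      ops <- c("del", ops); rr <- c(ref[i], rr); hh <- c(NA_character_, hh)
      i <- i - 1L
    } else {
      ops <- c("ins", ops); rr <- c(NA_character_, rr); hh <- c(hyp[j], hh)
      j <- j - 1L
    }
  }
  structure(list(N = n,
                 D = sum(ops == "del"),
                 S = sum(ops == "sub"),
                 I = sum(ops == "ins"),
                 pairs = tibble::tibble(ref = rr, hyp = hh, op = ops)),
            class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("<alignment: N=%d D=%d S=%d I=%d>\n", x$N, x$D, x$S, x$I))
  invisible(x)
}

#' Word recognition accuracy
#'
#' The percentage accuracy `100 * (N - D - S - I) / N` over an edit alignment
#' of reference and hypothesis. Insertions are penalized, so the accuracy can
#' be negative; it equals 100 exactly when the hypothesis matches the
#' reference.
#'
#' @param a An [align_transcripts()] result, or a list with fields `N`, `D`,
#'   `S`, `I`.
#' @return The accuracy percentage (scalar).
#' @examples
#' word_accuracy(align_transcripts(c("a", "b", "c", "d"), c("a", "c", "d")))
#' @export
word_accuracy <- function(a) {
  if (a$N < 1) stopf("word_accuracy requires a non-empty reference (N >= 1)")
  100 * (a$N - a$D - a$S - a$I) / a$N
}
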