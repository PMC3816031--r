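#' Phone HMM topology specification
#'
#' A topology specification pairs a transition-structure type with a number of
#' emitting states. Three structures are supported, following common practice
#' in acoustic modelling of phonemes:
#'
#' * **Bakis-1** (`0`): strict left-to-right; each state has a self-loop and an
#'   advance-by-one arc.
#' * **Bakis-2** (`1`): Bakis-1 plus skip-by-two arcs (state *i* to *i + 2*),
#'   i.e. a left-to-right structure with additional forward transitions.
#' * **Ergodic** (`2`): every emitting state can reach every other emitting
#'   state (including itself) in one step.
#'
#' The number of emitting states ranges over 3 to 11, the span reported for
#' phoneme and small-vocabulary word models in the disordered-speech ASR
#' literature.
#'
#' @param topo_type Topology code: integer `0` (Bakis-1), `1` (Bakis-2) or `2`
#'   (Ergodic), or one of the strings `"bakis1"`, `"bakis2"`, `"ergodic"`.
#' @param n_states Integer number of emitting states, between 3 and 11.
#'
#' @return An object of class `topology_spec` with fields `topo_type` and
#'   `n_states`.
#' @examples
#' topology_spec("bakis1", 3)
#' topology_spec(2, 5)
#' @export
topology_spec <- function(topo_type, n_states) {
  if (is.character(topo_type)) {
    topo_type <- match(match.arg(topo_type, topology_names()),
                       topology_names()) - 1L
  }
  topo_type <- as.integer(topo_type)
  n_states <- as.integer(n_states)
  if (length(topo_type) != 1L || is.na(topo_type) || !topo_type %in% 0:2) {
    stopf("topo_type must be 0 (Bakis-1), 1 (Bakis-2) or 2 (Ergodic)")
  }
  if (length(n_states) != 1L || is.na(n_states) ||
      n_states < 3L || n_states > 11L) {
    stopf("n_states must be an integer in [3, 11], got %s", n_states)
  }
  structure(list(topo_type = topo_type, n_states = n_states),
            class = "topology_spec")
}

topology_names <- function() c("bakis1", "bakis2", "ergodic")

#' @export
format.topology_spec <- function(x, ...) {
  sprintf("<topology_spec %s, %d states>",
          c("Bakis-1", "Bakis-2", "Ergodic")[x$topo_type + 1L], x$n_states)
}

#' @export
print.topology_spec <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Build the transition mask for a topology specification
#'
#' The mask marks which arcs of a phone HMM are permitted. Non-emitting entry
#' and exit states (HTK convention) bracket the emitting states so phone
#' models concatenate into sentence models:
#'
#' * Bakis structures enter at state 1 and exit from the last state; emitting
#'   arcs are self-loops plus advance-by-one (Bakis-1), with skip-by-two arcs
#'   added for Bakis-2.
#' * The Ergodic structure enters at any state, exits from any state, and
#'   permits all emitting-to-emitting arcs.
#'
#' @param spec A [topology_spec()].
#' @return An object of class `transition_mask` with logical fields `entry`
#'   (length `n`), `trans` (`n` by `n`) and `exit` (length `n`), where `n` is
#'   the number of emitting states.
#' @examples
#' m <- build_transition_mask(topology_spec("bakis2", 4))
#' sum(m$trans) # 9 emitting-to-emitting arcs: 4 self + 3 advance + 2 skip
#' @export
build_transition_mask <- function(spec) {
  if (!inherits(spec, "topology_spec")) spec <- do.call(topology_spec, spec)
  n <- spec$n_states
  trans <- matrix(FALSE, n, n)
  if (spec$topo_type == 2L) {
    trans[] <- TRUE
    entry <- rep(TRUE, n)
    exit <- rep(TRUE, n)
  } else {
    diag(trans) <- TRUE
    trans[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)] <- TRUE
    if (spec$topo_type == 1L && n >= 3L) {
      trans[cbind(seq_len(n - 2L), seq_len(n - 2L) + 2L)] <- TRUE
    }
    entry <- c(TRUE, rep(FALSE, n - 1L))
    exit <- c(rep(FALSE, n - 1L), TRUE)
  }
  structure(list(entry = entry, trans = trans, exit = exit, spec = spec),
            class = "transition_mask")
}

#' @export
print.transition_mask <- function(x, ...) {
  cat(format(x$spec), "-", sum(x$trans), "emitting arcs\n")
  invisible(x)
}

#' @rdname build_transition_mask
#' @param x A `transition_mask`.
#' @param ... Unused.
#' @return `as.matrix()` returns the full logical matrix over
#'   entry + emitting + exit states.
#' @export
as.matrix.transition_mask <- function(x, ...) {
  n <- length(x$entry)
  full <- matrix(FALSE, n + 2L, n + 2L)
  rn <- c("entry", paste0("s", seq_len(n)), "exit")
  dimnames(full) <- list(rn, rn)
  full[1L, 1L + seq_len(n)] <- x$entry
  full[1L + seq_len(n), 1L + seq_len(n)] <- x$trans
  full[1L + seq_len(n), n + 2L] <- x$exit
  full
}
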