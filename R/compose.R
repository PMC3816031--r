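# Composite HMMs: phone models concatenated into sentence models (for
# embedded training) or wired into decoding networks. A composite is described
# by a set of phone *instances* plus instance-level arcs; instantiation turns
# it into the dense log-probability arrays consumed by the C++ core.
#
# Instance-level description:
#   labels  : character, phone label per instance
#   arcs    : data.frame(from, to, logp) between instances
#   entry   : data.frame(inst, logp) composite entry points
#   exit    : data.frame(inst, logp) composite exit points
#   word    : integer word-instance id per phone instance (0 = none/silence)

composite_structure <- function(labels, arcs, entry, exit,
                                word = rep(0L, length(labels))) {
  list(labels = labels, arcs = arcs, entry = entry, exit = exit,
       word = as.integer(word))
}

chain_structure <- function(labels) {
  K <- length(labels)
  arcs <- if (K > 1L) {
    data.frame(from = seq_len(K - 1L), to = seq_len(K - 1L) + 1L, logp = 0)
  } else {
    data.frame(from = integer(0), to = integer(0), logp = numeric(0))
  }
  composite_structure(labels, arcs,
                      entry = data.frame(inst = 1L, logp = 0),
                      exit = data.frame(inst = K, logp = 0))
}

# Structural (parameter-independent) part of a composite: state offsets,
# tied-state table and index maps. Computed once per sentence or network and
# reused across EM iterations; composite_fill() binds the numbers.
composite_skeleton <- function(struct, hmms, tie = c("label", "instance")) {
  tie <- match.arg(tie)
  K <- length(struct$labels)
  ns <- vapply(hmms, function(h) h$spec$n_states, integer(1))
  off <- cumsum(c(0L, ns))
  S <- off[K + 1L]
  key_of <- if (tie == "label") {
    paste(struct$labels, "")
  } else {
    paste(seq_len(K), "")
  }
  keys <- paste0(rep(key_of, ns), unlist(lapply(ns, seq_len)))
  tied_keys <- unique(keys)
  state2tied <- match(keys, tied_keys) - 1L
  first_idx <- match(tied_keys, keys)
  inst_of_state <- rep(seq_len(K), ns)
  state_in_phone <- unlist(lapply(ns, seq_len))
  list(struct = struct, K = K, ns = ns, offsets = off, S = S,
       state2tied = state2tied,
       tied = data.frame(key = tied_keys,
                         inst = inst_of_state[first_idx],
                         label = struct$labels[inst_of_state[first_idx]],
                         state = state_in_phone[first_idx]),
       smap = data.frame(state = seq_len(S), inst = inst_of_state,
                         label = struct$labels[inst_of_state],
                         state_in_phone = state_in_phone,
                         word = struct$word[inst_of_state]))
}

# Bind current model parameters to a skeleton: dense log arrays plus
# tied-state emission parameter lists.
composite_fill <- function(skel, hmms) {
  struct <- skel$struct
  K <- skel$K
  ns <- skel$ns
  off <- skel$offsets
  S <- skel$S

  logpi <- rep(-Inf, S)
  logeta <- rep(-Inf, S)
  logA <- matrix(-Inf, S, S)
  for (k in seq_len(K)) {
    idx <- off[k] + seq_len(ns[k])
    logA[idx, idx] <- safe_log(hmms[[k]]$trans)
  }
  for (r in seq_len(nrow(struct$entry))) {
    k <- struct$entry$inst[r]
    idx <- off[k] + seq_len(ns[k])
    logpi[idx] <- pmax(logpi[idx],
                       struct$entry$logp[r] + safe_log(hmms[[k]]$entry))
  }
  for (r in seq_len(nrow(struct$exit))) {
    k <- struct$exit$inst[r]
    idx <- off[k] + seq_len(ns[k])
    logeta[idx] <- pmax(logeta[idx],
                        struct$exit$logp[r] + safe_log(hmms[[k]]$exit))
  }
  if (nrow(struct$arcs) > 0L) {
    for (r in seq_len(nrow(struct$arcs))) {
      a <- struct$arcs$from[r]
      b <- struct$arcs$to[r]
      ia <- off[a] + seq_len(ns[a])
      ib <- off[b] + seq_len(ns[b])
      block <- outer(safe_log(hmms[[a]]$exit), safe_log(hmms[[b]]$entry),
                     `+`) + struct$arcs$logp[r]
      logA[ia, ib] <- log_add_mat(logA[ia, ib], block)
    }
  }

  n_tied <- nrow(skel$tied)
  logw <- vector("list", n_tied)
  mu <- vector("list", n_tied)
  va <- vector("list", n_tied)
  for (s in seq_len(n_tied)) {
    st <- hmms[[skel$tied$inst[s]]]$states[[skel$tied$state[s]]]
    logw[[s]] <- safe_log(st$w)
    mu[[s]] <- st$mu
    va[[s]] <- st$var
  }
  c(skel, list(logpi = logpi, logA = logA, logeta = logeta,
               params = list(logw = logw, mu = mu, var = va)))
}

# One-shot convenience: skeleton + fill.
instantiate_composite <- function(struct, hmm_for,
                                  tie = c("label", "instance")) {
  hmms <- lapply(seq_along(struct$labels), hmm_for)
  skel <- composite_skeleton(struct, hmms, tie)
  composite_fill(skel, hmms)
}

log_add_mat <- function(a, b) {
  m <- pmax(a, b)
  out <- m + log(exp(a - m) + exp(b - m))
  out[!is.finite(m)] <- -Inf
  out
}

composite_logB <- function(comp, features) {
  tied_logB <- .cpp_tied_logB(features, comp$params$logw, comp$params$mu,
                              comp$params$var)
  tied_logB[comp$state2tied + 1L, , drop = FALSE]
}

#' Exact forward log-likelihood of a feature sequence under a phone chain
#'
#' Concatenates the given phone HMMs into a sentence model (exit of each phone
#' feeding the entry of the next) and evaluates the exact forward sum over all
#' state paths, in log space.
#'
#' @param hmm_chain A list of [phone_hmm()] objects, in utterance order, or a
#'   single `phone_hmm`.
#' @param features A numeric matrix of acoustic frames (frames by dimensions).
#' @return The log-likelihood (a scalar; `-Inf` if no path explains the
#'   sequence).
#' @export
sequence_loglik <- function(hmm_chain, features) {
  if (inherits(hmm_chain, "phone_hmm")) hmm_chain <- list(hmm_chain)
  if (!is.matrix(features) || nrow(features) == 0L) {
    stopf("features must be a non-empty matrix of frames")
  }
  d <- unique(vapply(hmm_chain, function(h) h$feature_dim, integer(1)))
  if (length(d) != 1L || d != ncol(features)) {
    stopf("feature dimension mismatch between models and features")
  }
  struct <- chain_structure(vapply(hmm_chain, function(h) h$label,
                                   character(1)))
  comp <- instantiate_composite(struct, function(k) hmm_chain[[k]],
                                tie = "instance")
  .cpp_forward(comp$logpi, comp$logA, comp$logeta,
               composite_logB(comp, features))
}

#' Sample a feature sequence from a phone chain
#'
#' Draws a state path through the concatenated phone models (entry to exit,
#' phone by phone) and one acoustic frame per visited state from that state's
#' Gaussian mixture. Used by the synthetic corpus generator.
#'
#' @param hmm_chain A list of [phone_hmm()] objects in utterance order.
#' @param seed Optional integer seed; the same seed yields the identical
#'   sequence.
#' @return A list with `features` (frames by dimensions matrix) and
#'   `alignment` (tibble with `frame`, `phone`, `instance`, `state`).
#' @export
sample_from_models <- function(hmm_chain, seed = NULL) {
  if (inherits(hmm_chain, "phone_hmm")) hmm_chain <- list(hmm_chain)
  with_seed(seed, {
    frames <- list()
    al_phone <- character(0)
    al_inst <- integer(0)
    al_state <- integer(0)
    for (k in seq_along(hmm_chain)) {
      h <- hmm_chain[[k]]
      n <- h$spec$n_states
      j <- sample.int(n, 1L, prob = h$entry)
      repeat {
        st <- h$states[[j]]
        m <- if (length(st$w) == 1L) 1L else sample.int(length(st$w), 1L,
                                                        prob = st$w)
        x <- rnorm(h$feature_dim, st$mu[m, ], sqrt(st$var[m, ]))
        frames[[length(frames) + 1L]] <- x
        al_phone <- c(al_phone, h$label)
        al_inst <- c(al_inst, k)
        al_state <- c(al_state, j)
        nxt <- sample.int(n + 1L, 1L, prob = c(h$trans[j, ], h$exit[j]))
        if (nxt == n + 1L) break
        j <- nxt
      }
    }
    features <- do.call(rbind, frames)
    list(features = features,
         alignment = tibble::tibble(frame = seq_len(nrow(features)),
                                    phone = al_phone, instance = al_inst,
                                    state = al_state))
  })
}
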