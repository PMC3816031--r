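#' Construct a phone HMM
#'
#' A phone HMM carries a masked transition structure (see
#' [build_transition_mask()]) and one diagonal-covariance Gaussian-mixture
#' emission per emitting state. Transitions are stored as probabilities:
#' `entry` (distribution over first emitting states), `trans` (emitting-state
#' matrix) and `exit` (per-state probability of leaving the phone), with
#' `trans[i, ] + exit[i]` summing to one. Freshly constructed models have
#' uniform transitions over the allowed arcs and standard-normal single
#' Gaussians; use [flat_start()] to initialize emissions from data.
#'
#' @param label Phoneme symbol.
#' @param spec A [topology_spec()].
#' @param feature_dim Dimension of the acoustic feature vectors.
#' @param n_mix Number of mixture components per state (default 1).
#' @return An object of class `phone_hmm`.
#' @examples
#' phone_hmm("aa", topology_spec("bakis1", 3), feature_dim = 4)
#' @export
phone_hmm <- function(label, spec, feature_dim, n_mix = 1L) {
  mask <- build_transition_mask(spec)
  n <- spec$n_states
  trans <- uniform_transitions(mask)
  states <- replicate(n, list(
    w = rep(1 / n_mix, n_mix),
    mu = matrix(0, n_mix, feature_dim),
    var = matrix(1, n_mix, feature_dim)
  ), simplify = FALSE)
  structure(list(label = label, spec = spec, mask = mask,
                 entry = trans$entry, trans = trans$trans, exit = trans$exit,
                 states = states, feature_dim = as.integer(feature_dim)),
            class = "phone_hmm")
}

# Uniform probabilities over the allowed arcs of a mask; each emitting row is
# uniform over its allowed outgoing arcs including the exit arc.
uniform_transitions <- function(mask) {
  n <- length(mask$entry)
  entry <- mask$entry / sum(mask$entry)
  trans <- matrix(0, n, n)
  exit <- numeric(n)
  for (i in seq_len(n)) {
    k <- sum(mask$trans[i, ]) + mask$exit[i]
    trans[i, mask$trans[i, ]] <- 1 / k
    if (mask$exit[i]) exit[i] <- 1 / k
  }
  list(entry = entry, trans = trans, exit = exit)
}

#' @export
print.phone_hmm <- function(x, ...) {
  cat(sprintf("<phone_hmm '%s' %s, dim %d, %d mixture(s)>\n", x$label,
              sub("^<topology_spec (.*)>$", "\\1", format(x$spec)),
              x$feature_dim, length(x$states[[1]]$w)))
  invisible(x)
}

#' Construct a bank of phone HMMs
#'
#' @param specs Named list of [topology_spec()] objects, one per phoneme
#'   symbol; names are the phoneme labels.
#' @param feature_dim Dimension of the acoustic feature vectors.
#' @param n_mix Number of mixture components per state (default 1).
#' @param variance_floor Lower bound applied to every emission variance;
#'   either a scalar or a per-dimension vector. [flat_start()] resets it to
#'   1e-2 times the global per-dimension data variance.
#' @return An object of class `model_set`: a named list of `phone_hmm` objects
#'   plus `feature_dim` and `variance_floor`.
#' @examples
#' specs <- list(aa = topology_spec("bakis1", 3), sil = topology_spec("bakis1", 3))
#' model_set(specs, feature_dim = 4)
#' @export
model_set <- function(specs, feature_dim, n_mix = 1L, variance_floor = 1e-6) {
  if (is.null(names(specs)) || anyDuplicated(names(specs))) {
    stopf("specs must be a named list with unique phoneme labels")
  }
  hmms <- lapply(names(specs), function(p) {
    phone_hmm(p, specs[[p]], feature_dim, n_mix)
  })
  names(hmms) <- names(specs)
  structure(list(hmms = hmms, feature_dim = as.integer(feature_dim),
                 variance_floor = variance_floor),
            class = "model_set")
}

#' @export
print.model_set <- function(x, ...) {
  cat(sprintf("<model_set: %d phone HMMs, feature dim %d>\n",
              length(x$hmms), x$feature_dim))
  invisible(x)
}

#' Summarize a model bank as a tibble
#'
#' @param x A `model_set`.
#' @param ... Unused.
#' @return A tibble with one row per phoneme: `phoneme`, `topology`, `states`,
#'   `mixtures`.
#' @export
tidy.model_set <- function(x, ...) {
  tibble::tibble(
    phoneme = names(x$hmms),
    topology = vapply(x$hmms, function(h) {
      c("Bakis-1", "Bakis-2", "Ergodic")[h$spec$topo_type + 1L]
    }, character(1)),
    states = vapply(x$hmms, function(h) h$spec$n_states, integer(1)),
    mixtures = vapply(x$hmms, function(h) length(h$states[[1]]$w), integer(1))
  )
}

floor_variances <- function(hmm, floor) {
  hmm$states <- lapply(hmm$states, function(st) {
    st$var <- pmax(st$var, matrix(floor, nrow(st$var), ncol(st$var),
                                  byrow = TRUE))
    st
  })
  hmm
}

#' Flat-start initialization from a training corpus
#'
#' Sets every emission of every phone HMM to the global Gaussian of the pooled
#' training frames (identical mean and variance everywhere) and leaves
#' transition probabilities uniform over the allowed arcs. The variance floor
#' is set to 1e-2 times the global per-dimension variance.
#'
#' @param model_set A [model_set()].
#' @param train A [speech_corpus()] whose phone transcriptions cover every
#'   phoneme of the bank.
#' @return The initialized `model_set`.
#' @export
flat_start <- function(model_set, train) {
  stopifnot(inherits(model_set, "model_set"))
  if (nrow(train) == 0L) stopf("training corpus is empty")
  seen <- unique(unlist(train$phones))
  missing <- setdiff(names(model_set$hmms), seen)
  if (length(missing) > 0L) {
    stopf("phoneme(s) absent from training transcriptions: %s",
          paste(missing, collapse = ", "))
  }
  frames <- do.call(rbind, train$features)
  if (ncol(frames) != model_set$feature_dim) {
    stopf("corpus feature dimension %d does not match model feature_dim %d",
          ncol(frames), model_set$feature_dim)
  }
  gmean <- colMeans(frames)
  gvar <- apply(frames, 2, function(v) mean((v - mean(v))^2))
  floor <- pmax(1e-2 * gvar, 1e-8)
  gvar <- pmax(gvar, floor)
  model_set$variance_floor <- floor
  model_set$hmms <- lapply(model_set$hmms, function(h) {
    M <- length(h$states[[1]]$w)
    h$states <- lapply(h$states, function(st) {
      list(w = rep(1 / M, M),
           mu = matrix(gmean, M, length(gmean), byrow = TRUE),
           var = matrix(gvar, M, length(gvar), byrow = TRUE))
    })
    tr <- uniform_transitions(h$mask)
    h$entry <- tr$entry
    h$trans <- tr$trans
    h$exit <- tr$exit
    h
  })
  model_set
}

#' Grow the mixture order of every state by binary splitting
#'
#' Repeatedly duplicates the heaviest-weight components of each state until
#' every state has `target_M` components (the HTK-style "mixing up"
#' convention): the duplicated component's weight is halved and the two copies
#' get means perturbed by plus/minus 0.2 standard deviations. No re-estimation
#' is performed here; see [embedded_reestimate()] for the interleaved
#' split-then-retrain schedule used during fitness evaluation.
#'
#' @param model_set A [model_set()].
#' @param target_M Target number of components per state, in `[1, 16]` and at
#'   least the current mixture order.
#' @return The `model_set` with `target_M` components per state.
#' @export
split_mixtures <- function(model_set, target_M) {
  target_M <- as.integer(target_M)
  if (target_M < 1L || target_M > 16L) {
    stopf("target_M must be in [1, 16], got %d", target_M)
  }
  cur <- length(model_set$hmms[[1]]$states[[1]]$w)
  if (target_M < cur) {
    stopf("target_M (%d) is below the current mixture order (%d)",
          target_M, cur)
  }
  if (target_M == cur) return(model_set)
  model_set$hmms <- lapply(model_set$hmms, function(h) {
    h$states <- lapply(h$states, split_state_mixture, target_M = target_M)
    h
  })
  model_set
}

split_state_mixture <- function(st, target_M) {
  while (length(st$w) < target_M) {
    j <- which.max(st$w)
    sd_j <- sqrt(st$var[j, , drop = TRUE])
    mu_a <- st$mu[j, ] + 0.2 * sd_j
    mu_b <- st$mu[j, ] - 0.2 * sd_j
    w_half <- st$w[j] / 2
    st$w <- c(st$w[-j], w_half, w_half)
    st$mu <- rbind(st$mu[-j, , drop = FALSE], mu_a, mu_b)
    st$var <- rbind(st$var[-j, , drop = FALSE],
                    st$var[j, , drop = FALSE], st$var[j, , drop = FALSE])
    rownames(st$mu) <- rownames(st$var) <- NULL
  }
  st$w <- st$w / sum(st$w)
  st
}
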