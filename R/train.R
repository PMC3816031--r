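#' Embedded Baum-Welch re-estimation over sentence models
#'
#' For each training sentence, the phone models named by its phone
#' transcription are concatenated into a composite sentence HMM; the
#' forward-backward algorithm accumulates state, transition and mixture
#' occupancies (in log space throughout), which are pooled across sentences
#' per phone and re-estimated. Disallowed arcs stay at zero and every
#' emission variance is floored at the model set's variance floor.
#'
#' The total log-likelihood reported for each iteration is evaluated under
#' the parameters at the start of that iteration, so the sequence is
#' non-decreasing (EM monotonicity) up to floor effects. Sentences with a
#' zero-probability path are skipped and counted.
#'
#' @param model_set A [model_set()], typically after [flat_start()].
#' @param train A [speech_corpus()] of training sentences.
#' @param n_iter Maximum number of EM iterations (default 20).
#' @param tol_per_frame Early-stop threshold: stop when the per-frame
#'   log-likelihood gain drops below this (default 1e-4).
#' @param lexicon Optional [asr_lexicon()] used to expand word transcriptions
#'   when a sentence carries no phone transcription.
#' @return A list with `model_set` (re-estimated), `loglik` (numeric vector,
#'   one total log-likelihood per completed iteration) and `n_skipped`
#'   (sentences skipped in the final iteration).
#' @export
embedded_reestimate <- function(model_set, train, n_iter = 20L,
                                tol_per_frame = 1e-4, lexicon = NULL) {
  stopifnot(inherits(model_set, "model_set"))
  if (nrow(train) == 0L) stopf("training corpus is empty")
  phones_list <- lapply(seq_len(nrow(train)), function(i) {
    ph <- train$phones[[i]]
    if (is.null(ph) || !length(ph)) {
      if (is.null(lexicon)) {
        stopf("sentence '%s' has no phone transcription and no lexicon given",
              train$id[i])
      }
      ph <- expand_phones(train$words[[i]], lexicon)
    }
    bad <- setdiff(ph, names(model_set$hmms))
    if (length(bad) > 0L) {
      stopf("sentence '%s' uses phone(s) missing from the model set: %s",
            train$id[i], paste(bad, collapse = ", "))
    }
    ph
  })
  skels <- lapply(phones_list, function(ph) {
    composite_skeleton(chain_structure(ph), model_set$hmms[ph], tie = "label")
  })
  total_frames <- sum(vapply(train$features, nrow, integer(1)))
  logliks <- numeric(0)
  n_skipped <- 0L
  for (iter in seq_len(n_iter)) {
    res <- em_pass(model_set, train$features, phones_list, skels)
    model_set <- res$model_set
    logliks <- c(logliks, res$loglik)
    n_skipped <- res$n_skipped
    if (iter > 1L) {
      gain <- logliks[iter] - logliks[iter - 1L]
      if (is.finite(gain) && gain < tol_per_frame * total_frames) break
    }
  }
  if (n_skipped > 0L) {
    warning(sprintf("%d sentence(s) had zero-probability paths and were skipped",
                    n_skipped), call. = FALSE)
  }
  list(model_set = model_set, loglik = logliks, n_skipped = n_skipped)
}

# One accumulate-and-update EM pass; returns the pre-update total loglik.
em_pass <- function(model_set, features_list, phones_list, skels = NULL) {
  labels <- names(model_set$hmms)
  acc <- lapply(model_set$hmms, function(h) {
    n <- h$spec$n_states
    M <- length(h$states[[1]]$w)
    d <- h$feature_dim
    list(ent = numeric(n), trans = matrix(0, n, n), exit = numeric(n),
         occ = matrix(0, n, M),
         sumx = replicate(n, matrix(0, M, d), simplify = FALSE),
         sumx2 = replicate(n, matrix(0, M, d), simplify = FALSE))
  })
  total_ll <- 0
  n_skipped <- 0L
  for (i in seq_along(features_list)) {
    hmms_i <- model_set$hmms[phones_list[[i]]]
    comp <- if (is.null(skels)) {
      instantiate_composite(chain_structure(phones_list[[i]]),
                            function(k) hmms_i[[k]], tie = "label")
    } else {
      composite_fill(skels[[i]], hmms_i)
    }
    est <- .cpp_estep(comp$logpi, comp$logA, comp$logeta, comp$state2tied,
                      comp$params$logw, comp$params$mu, comp$params$var,
                      features_list[[i]])
    if (!is.finite(est$loglik)) {
      n_skipped <- n_skipped + 1L
      next
    }
    total_ll <- total_ll + est$loglik
    acc <- pool_sentence(acc, est, comp)
  }
  if (n_skipped == length(features_list)) {
    stopf("all sentences had zero-probability paths; training cannot proceed")
  }
  model_set <- mstep_update(model_set, acc)
  list(model_set = model_set, loglik = total_ll, n_skipped = n_skipped)
}

# Pool one sentence's composite occupancies into per-phone accumulators.
# Training composites are chains, so cross-phone transitions only occur
# between consecutive instances.
pool_sentence <- function(acc, est, comp) {
  K <- length(comp$ns)
  off <- comp$offsets
  labs <- comp$struct$labels
  for (k in seq_len(K)) {
    lab <- labs[k]
    idx <- off[k] + seq_len(comp$ns[k])
    within <- est$trans[idx, idx, drop = FALSE]
    incoming <- if (k > 1L) {
      prev <- off[k - 1L] + seq_len(comp$ns[k - 1L])
      colSums(est$trans[prev, idx, drop = FALSE])
    } else 0
    outgoing <- if (k < K) {
      nxt <- off[k + 1L] + seq_len(comp$ns[k + 1L])
      rowSums(est$trans[idx, nxt, drop = FALSE])
    } else 0
    acc[[lab]]$ent <- acc[[lab]]$ent + est$ent[idx] + incoming
    acc[[lab]]$exit <- acc[[lab]]$exit + est$exit[idx] + outgoing
    acc[[lab]]$trans <- acc[[lab]]$trans + within
  }
  for (s in seq_len(nrow(comp$tied))) {
    lab <- comp$tied$label[s]
    j <- comp$tied$state[s]
    acc[[lab]]$occ[j, ] <- acc[[lab]]$occ[j, ] + est$occ[[s]]
    acc[[lab]]$sumx[[j]] <- acc[[lab]]$sumx[[j]] + est$sumx[[s]]
    acc[[lab]]$sumx2[[j]] <- acc[[lab]]$sumx2[[j]] + est$sumx2[[s]]
  }
  acc
}

mstep_update <- function(model_set, acc) {
  floor <- model_set$variance_floor
  model_set$hmms <- lapply(names(model_set$hmms), function(lab) {
    h <- model_set$hmms[[lab]]
    a <- acc[[lab]]
    n <- h$spec$n_states
    if (sum(a$ent) > 0) {
      e <- a$ent * h$mask$entry
      if (sum(e) > 0) h$entry <- e / sum(e)
    }
    for (i in seq_len(n)) {
      row <- a$trans[i, ] * h$mask$trans[i, ]
      ex <- if (h$mask$exit[i]) a$exit[i] else 0
      denom <- sum(row) + ex
      if (denom > 0) {
        h$trans[i, ] <- row / denom
        h$exit[i] <- ex / denom
      }
    }
    d <- h$feature_dim
    for (j in seq_len(n)) {
      occ <- a$occ[j, ]
      tot <- sum(occ)
      if (tot <= 1e-10) next
      st <- h$states[[j]]
      keep <- occ > 1e-10
      w <- occ / tot
      mu <- st$mu
      va <- st$var
      for (m in which(keep)) {
        mu[m, ] <- a$sumx[[j]][m, ] / occ[m]
        va[m, ] <- a$sumx2[[j]][m, ] / occ[m] - mu[m, ]^2
      }
      va <- pmax(va, matrix(floor, nrow(va), d, byrow = TRUE))
      h$states[[j]] <- list(w = w, mu = mu, var = va)
    }
    h
  })
  names(model_set$hmms) <- vapply(model_set$hmms, function(h) h$label,
                                  character(1))
  model_set
}

#' Full training pipeline: flat start, re-estimation, mixture growth
#'
#' Flat-starts the bank on the training corpus, runs embedded re-estimation,
#' then grows the mixture order by incremental binary splitting (doubling up
#' to `target_M`, trimming overshoot by splitting only the heaviest
#' components) with a few re-estimation passes after each split.
#'
#' @inheritParams embedded_reestimate
#' @param target_M Global Gaussian-mixture component count, in `[1, 16]`.
#' @param split_iter EM iterations after each mixture split (default 5).
#' @return A list with `model_set` and `loglik` (concatenated trajectory of
#'   the initial re-estimation; splits restart the likelihood scale).
#' @export
train_models <- function(model_set, train, target_M = 1L, n_iter = 20L,
                         split_iter = 5L, tol_per_frame = 1e-4,
                         lexicon = NULL) {
  model_set <- flat_start(model_set, train)
  fit <- embedded_reestimate(model_set, train, n_iter = n_iter,
                             tol_per_frame = tol_per_frame, lexicon = lexicon)
  model_set <- fit$model_set
  M <- length(model_set$hmms[[1]]$states[[1]]$w)
  while (M < target_M) {
    M <- min(2L * M, as.integer(target_M))
    model_set <- split_mixtures(model_set, M)
    model_set <- embedded_reestimate(model_set, train, n_iter = split_iter,
                                     tol_per_frame = tol_per_frame,
                                     lexicon = lexicon)$model_set
  }
  list(model_set = model_set, loglik = fit$loglik)
}
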