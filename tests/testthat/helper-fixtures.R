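# Shared fixtures and independent oracles for the test suite.

# A hand-built phone HMM with fully specified numbers (no training), so tests
# control every parameter. means: n_states x d matrix; self: self-loop prob.
fixed_phone <- function(label, topo = "bakis1", n_states = 3, means = NULL,
                        vars = 1, self = 0.5, d = 2) {
  h <- phone_hmm(label, topology_spec(topo, n_states), feature_dim = d)
  if (is.null(means)) means <- matrix(0, n_states, d)
  for (j in seq_len(n_states)) {
    h$states[[j]] <- list(w = 1,
                          mu = matrix(means[j, ], 1, d),
                          var = matrix(vars, 1, d))
  }
  # left-to-right: self + advance (+ exit from last); ergodic left uniform
  if (topo != "ergodic") {
    n <- n_states
    h$trans[] <- 0
    for (j in seq_len(n - 1)) {
      h$trans[j, j] <- self
      h$trans[j, j + 1] <- 1 - self
    }
    h$trans[n, n] <- self
    h$exit <- c(rep(0, n - 1), 1 - self)
    h$entry <- c(1, rep(0, n - 1))
  }
  h
}

# Independent forward-probability oracle: enumerate every state path of the
# composite (single-phone) HMM and sum path probabilities directly.
brute_force_loglik <- function(hmm, features) {
  n <- hmm$spec$n_states
  T_ <- nrow(features)
  paths <- as.matrix(expand.grid(rep(list(seq_len(n)), T_)))
  dens <- function(j, x) {
    st <- hmm$states[[j]]
    sum(vapply(seq_along(st$w), function(m) {
      st$w[m] * prod(stats::dnorm(x, st$mu[m, ], sqrt(st$var[m, ])))
    }, numeric(1)))
  }
  total <- 0
  for (p in seq_len(nrow(paths))) {
    path <- paths[p, ]
    pr <- hmm$entry[path[1]] * dens(path[1], features[1, ])
    if (T_ > 1) {
      for (t in 2:T_) {
        pr <- pr * hmm$trans[path[t - 1], path[t]] * dens(path[t], features[t, ])
      }
    }
    pr <- pr * hmm$exit[path[T_]]
    total <- total + pr
  }
  log(total)
}

# Minimal tractable world: P phones (incl. sil), small lexicon and template
# grammar, corpus sampled from its own truth models.
tiny_world <- function(seed = 1, P = 6, d = 3, n_sent = 30, separation = 4,
                       level = "none", n_nouns = 4, n_verbs = 2) {
  ts <- truth_spec(P = P, feature_dim = d, separation = separation,
                   state_probs = c("3" = 0.5, "4" = 0.5))
  tm <- make_truth_models(ts, seed = seed)
  lx <- build_toy_lexicon(n_nouns, n_verbs, inventory = names(tm$model_set$hmms),
                          seed = seed)
  co <- suppressMessages(
    synthesize_sentences(tm$model_set, lx$lexicon, lx$grammar, n = n_sent,
                         severity = severity_preset(level), seed = seed + 1))
  co <- make_splits(co, seed = seed + 2)
  list(truth = tm, lexicon = lx$lexicon, grammar = lx$grammar, corpus = co,
       inventory = names(tm$model_set$hmms))
}

train_split <- function(world) phonotop:::corpus_split(world$corpus, "train")
fitness_split <- function(world) phonotop:::corpus_split(world$corpus, "fitness")
test_split <- function(world) phonotop:::corpus_split(world$corpus, "test")
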