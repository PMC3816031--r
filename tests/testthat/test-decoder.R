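test_that("network compilation validates and counts admissible sequences", {
  lex <- asr_lexicon(c("the", "cat", "dog", "runs"),
                     list(c("dh", "ah"), c("k", "ae", "t"),
                          c("d", "ao", "g"), c("r", "ah", "n")))
  g1 <- asr_grammar("sentence_template", list("the", "cat"))
  expect_equal(count_admissible_sequences(g1), 1)

  # the full-scale nonsense-sentence template: 74 * 37 * 74 ordered sequences
  nouns <- sprintf("n%02d", 1:74)
  verbs <- sprintf("v%02d", 1:37)
  g <- asr_grammar("sentence_template",
                   list("the", nouns, "is", verbs, "the", nouns))
  expect_equal(count_admissible_sequences(g), 74 * 37 * 74)

  gl <- asr_grammar("word_loop", c("cat", "dog"))
  expect_equal(count_admissible_sequences(gl, length_ = 3), 8)

  g_bad <- asr_grammar("sentence_template", list("the", "unicorn"))
  expect_error(compile_network(lex, g_bad), "unicorn")
})

test_that("decoding returns the single admissible sequence regardless of fit", {
  w <- tiny_world(seed = 9, n_sent = 10)
  one_noun <- w$grammar$slots[[2]][1]
  one_verb <- w$grammar$slots[[4]][1]
  g1 <- asr_grammar("sentence_template",
                    list("the", one_noun, "is", one_verb, "the", one_noun))
  net <- compile_network(w$lexicon, g1)
  x <- w$corpus$features[[1]]
  out <- viterbi_decode(w$truth$model_set, net, x)
  expect_equal(out$words, c("the", one_noun, "is", one_verb, "the", one_noun))
  expect_false(out$failed)
})

test_that("viterbi path score is a max over paths and below the forward sum", {
  means <- matrix(c(-3, 0, 3, 1, -1, 2), 3, 2)
  h <- fixed_phone("p", "bakis1", 3, means = means, self = 0.4)
  x <- matrix(rnorm(8, sd = 2), 4, 2)
  lex <- asr_lexicon("w", list("p"))
  g <- asr_grammar("sentence_template", list("w"))
  ms <- structure(list(hmms = list(p = h), feature_dim = 2L,
                       variance_floor = 1e-8), class = "model_set")
  net <- compile_network(lex, g, sil = NULL)
  out <- viterbi_decode(ms, net, x)
  fwd <- sequence_loglik(list(h), x)
  expect_lte(out$score, fwd + 1e-10)

  # brute-force max-path oracle
  paths <- as.matrix(expand.grid(rep(list(1:3), 4)))
  best <- -Inf
  for (p in seq_len(nrow(paths))) {
    path <- paths[p, ]
    lp <- log(h$entry[path[1]]) +
      sum(dnorm(x[1, ], h$states[[path[1]]]$mu[1, ], 1, log = TRUE))
    for (t in 2:4) {
      tp <- h$trans[path[t - 1], path[t]]
      if (tp == 0) { lp <- -Inf; break }
      lp <- lp + log(tp) +
        sum(dnorm(x[t, ], h$states[[path[t]]]$mu[1, ], 1, log = TRUE))
    }
    if (is.finite(lp)) lp <- lp + log(max(h$exit[path[4]], 0))
    best <- max(best, lp)
  }
  expect_equal(out$score, best, tolerance = 1e-8)
})

test_that("well-separated word models are recovered almost surely", {
  # two one-phone words with means 5 sd apart; features sampled from W
  d <- 2
  hw <- fixed_phone("pw", "bakis1", 3,
                    means = matrix(0, 3, d), self = 0.5, d = d)
  hv <- fixed_phone("pv", "bakis1", 3,
                    means = matrix(5, 3, d), self = 0.5, d = d)
  sil <- fixed_phone("sil", "bakis1", 3,
                     means = matrix(-5, 3, d), self = 0.3, d = d)
  ms <- structure(list(hmms = list(pw = hw, pv = hv, sil = sil),
                       feature_dim = 2L, variance_floor = 1e-8),
                  class = "model_set")
  lex <- asr_lexicon(c("W", "V"), list("pw", "pv"))
  g <- asr_grammar("sentence_template", list(c("W", "V")))
  net <- compile_network(lex, g, sil = "sil")
  set.seed(13)
  hits <- 0
  for (i in 1:50) {
    x <- sample_from_models(list(sil, hw, sil))$features
    out <- viterbi_decode(ms, net, x)
    hits <- hits + identical(out$words, "W")
  }
  expect_gte(hits, 49)
})

test_that("word-loop decoding recovers immediate word repetitions", {
  # self-loop 0 pins word length at 3 frames, so the segmentation is forced
  d <- 2
  ha <- fixed_phone("pa", "bakis1", 3, means = matrix(0, 3, d), self = 0)
  hb <- fixed_phone("pb", "bakis1", 3, means = matrix(6, 3, d), self = 0)
  ms <- structure(list(hmms = list(pa = ha, pb = hb), feature_dim = 2L,
                       variance_floor = 1e-8), class = "model_set")
  lex <- asr_lexicon(c("A", "B"), list("pa", "pb"))
  net <- compile_network(lex, asr_grammar("word_loop", c("A", "B")),
                         sil = NULL)
  set.seed(14)
  x <- sample_from_models(list(ha, ha, hb))$features
  out <- viterbi_decode(ms, net, x)
  expect_equal(out$words, c("A", "A", "B"))
})

test_that("corpus accuracy pools counts and ignores sentence order", {
  w <- tiny_world(seed = 10, n_sent = 24)
  tr <- train_split(w)
  net <- compile_network(w$lexicon, w$grammar)
  # decoding with the generating models on clean data is near-perfect
  acc <- corpus_accuracy(w$truth$model_set, w$corpus, net,
                         per_sentence = TRUE)
  expect_gte(acc$wacc, 95)
  shuffled <- w$corpus[rev(seq_len(nrow(w$corpus))), ]
  class(shuffled) <- class(w$corpus)
  expect_equal(corpus_accuracy(w$truth$model_set, shuffled, net), acc$wacc)
  # pooled formula consistency
  expect_equal(acc$wacc,
               100 * (sum(acc$sentences$N) - sum(acc$sentences$errors)) /
                 sum(acc$sentences$N))
})
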