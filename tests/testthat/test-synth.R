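test_that("truth generation is deterministic and reports its assignment", {
  ts <- truth_spec(P = 6, feature_dim = 3, topo_probs = c(1, 0, 0),
                   state_probs = c("3" = 1))
  tm1 <- make_truth_models(ts, seed = 2)
  tm2 <- make_truth_models(ts, seed = 2)
  expect_identical(tm1$model_set, tm2$model_set)
  expect_true(all(tm1$assignment$topology == "Bakis-1"))
  expect_true(all(tm1$assignment$states == 3))
  # silence is pinned to the standard 3-state left-to-right model
  tm3 <- make_truth_models(truth_spec(P = 8, feature_dim = 3,
                                      topo_probs = c(0, 0, 1),
                                      state_probs = c("6" = 1)), seed = 3)
  sil_row <- tm3$assignment[tm3$assignment$phoneme == "sil", ]
  expect_equal(sil_row$topology, "Bakis-1")
  expect_equal(sil_row$states, 3L)
})

test_that("well-separated truth phones are identifiable from samples", {
  ts <- truth_spec(P = 6, feature_dim = 3, separation = 5)
  tm <- make_truth_models(ts, seed = 7)
  labs <- names(tm$model_set$hmms)
  set.seed(8)
  hits <- 0
  n_seg <- 1000
  draws <- sample(labs, n_seg, replace = TRUE)
  for (i in seq_len(n_seg)) {
    x <- sample_from_models(tm$model_set$hmms[draws[i]])$features
    scores <- vapply(labs, function(p) {
      sequence_loglik(tm$model_set$hmms[p], x)
    }, numeric(1))
    hits <- hits + (labs[which.max(scores)] == draws[i])
  }
  expect_gte(hits / n_seg, 0.99)
})

test_that("toy lexicon matches the nonsense-corpus structure", {
  lx <- build_toy_lexicon(74, 37, seed = 5)
  expect_equal(nrow(lx$lexicon), 113)  # 74 nouns + 37 verbs + the + is
  expect_equal(length(lx$grammar$slots), 6)
  expect_identical(build_toy_lexicon(74, 37, seed = 5)$lexicon, lx$lexicon)
  # pronunciations distinct and sized by word class
  prons <- vapply(lx$lexicon$phones, paste, character(1), collapse = " ")
  expect_false(anyDuplicated(prons) > 0)
  nouns <- lx$lexicon[grepl("^noun", lx$lexicon$word), ]
  verbs <- lx$lexicon[grepl("^verb", lx$lexicon$word), ]
  expect_true(all(lengths(nouns$phones) %in% 2:4))
  expect_true(all(lengths(verbs$phones) %in% 4:6))
  expect_false("sil" %in% unlist(lx$lexicon$phones))
})

test_that("sentence synthesis follows the swap-pairing scheme", {
  w_env <- tiny_world(seed = 20, n_sent = 10)
  ts <- truth_spec(P = 8, feature_dim = 3)
  tm <- make_truth_models(ts, seed = 20)
  lx <- build_toy_lexicon(74, 37, inventory = names(tm$model_set$hmms),
                          seed = 20)
  co <- synthesize_sentences(tm$model_set, lx$lexicon, lx$grammar, n = 74,
                             seed = 21)
  expect_equal(nrow(co), 74)
  expect_true(all(lengths(co$words) == 6))
  # sentences 38..74 swap X and Z of sentences 1..37, same verb
  for (b in 1:37) {
    base <- co$words[[b]]
    swp <- co$words[[37 + b]]
    expect_equal(swp, base[c(1, 6, 3, 4, 5, 2)])
  }
  # every noun/verb appears exactly twice across the 74 sentences
  xs <- vapply(co$words, `[`, character(1), 2)
  zs <- vapply(co$words, `[`, character(1), 6)
  ys <- vapply(co$words, `[`, character(1), 4)
  expect_true(all(table(c(xs, zs)) == 2))
  expect_true(all(table(ys) == 2))
  # deterministic under the seed
  co2 <- synthesize_sentences(tm$model_set, lx$lexicon, lx$grammar, n = 74,
                              seed = 21)
  expect_identical(co$features, co2$features)
  # wrap-around beyond capacity is flagged
  expect_message(
    synthesize_sentences(tm$model_set, lx$lexicon, lx$grammar, n = 80,
                         seed = 21), "capacity")
})

test_that("phoneme prolongation lengthens sentences at matched seeds", {
  ts <- truth_spec(P = 6, feature_dim = 3)
  tm <- make_truth_models(ts, seed = 30)
  lx <- build_toy_lexicon(6, 3, inventory = names(tm$model_set$hmms),
                          seed = 30)
  frames_under <- function(sev) {
    co <- suppressMessages(
      synthesize_sentences(tm$model_set, lx$lexicon, lx$grammar, n = 40,
                           severity = sev, seed = 31))
    mean(vapply(co$features, nrow, integer(1)))
  }
  neutral <- frames_under(severity_profile(1, 1, 0))
  dilated <- frames_under(severity_profile(2, 1, 0))
  expect_gt(dilated, neutral)
})

test_that("severity knobs validate and presets grade upward", {
  expect_error(severity_profile(0.5, 1, 0), ">= 1")
  expect_error(severity_profile(1, 1, 1.5), "substitution_rate")
  lv <- lapply(c("none", "mild", "moderate", "severe"), severity_preset)
  dil <- vapply(lv, `[[`, numeric(1), "duration_dilation")
  expect_true(all(diff(dil) > 0))
})

test_that("splits hit requested sizes, cover all phonemes, and reproduce", {
  ts <- truth_spec(P = 8, feature_dim = 3)
  tm <- make_truth_models(ts, seed = 33)
  lx <- build_toy_lexicon(8, 4, inventory = names(tm$model_set$hmms),
                          seed = 33)
  co <- suppressMessages(
    synthesize_sentences(tm$model_set, lx$lexicon, lx$grammar, n = 80,
                         seed = 34))
  sp <- make_splits(co, c(train = 0.5, fitness = 0.25, test = 0.25),
                    seed = 35)
  expect_equal(as.numeric(table(sp$split)[c("train", "fitness", "test")]),
               c(40, 20, 20))
  covered <- unique(unlist(sp$phones[sp$split == "train"]))
  expect_true(all(names(tm$model_set$hmms) %in% covered))
  sp2 <- make_splits(co, c(train = 0.5, fitness = 0.25, test = 0.25),
                     seed = 35)
  expect_identical(sp$split, sp2$split)
  expect_error(make_splits(co, c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("cohorts share the lexicon and mirror the severity grouping", {
  ts <- truth_spec(P = 6, feature_dim = 3)
  ch <- make_cohort(n_speakers = 10,
                    levels = c(rep("mild", 4), rep("moderate", 3),
                               rep("severe", 3)),
                    spec = ts, n_sentences = 12, n_nouns = 4, n_verbs = 2,
                    seed = 44)
  expect_length(ch$speakers, 10)
  expect_equal(table(vapply(ch$speakers, `[[`, character(1), "level")),
               table(c(rep("mild", 4), rep("moderate", 3), rep("severe", 3))))
  ch2 <- make_cohort(n_speakers = 10,
                     levels = c(rep("mild", 4), rep("moderate", 3),
                                rep("severe", 3)),
                     spec = ts, n_sentences = 12, n_nouns = 4, n_verbs = 2,
                     seed = 44)
  expect_identical(ch$speakers[[1]]$corpus$features,
                   ch2$speakers[[1]]$corpus$features)
})

test_that("rising variance inflation weakly degrades recognition", {
  ts <- truth_spec(P = 6, feature_dim = 3, separation = 2.5)
  tm <- make_truth_models(ts, seed = 50)
  lx <- build_toy_lexicon(6, 3, inventory = names(tm$model_set$hmms),
                          seed = 50)
  net <- compile_network(lx$lexicon, lx$grammar)
  wacc_at <- function(vi) {
    co <- suppressMessages(
      synthesize_sentences(tm$model_set, lx$lexicon, lx$grammar, n = 16,
                           severity = severity_profile(1, vi, 0), seed = 51))
    corpus_accuracy(tm$model_set, co, net)
  }
  accs <- vapply(c(1, 4, 16), wacc_at, numeric(1))
  expect_true(all(diff(accs) <= 0))
  expect_lt(accs[3], accs[1])
})

test_that("confusable twins share spectral centers", {
  ts <- truth_spec(P = 10, feature_dim = 4, confusable_fraction = 0.5)
  tm <- make_truth_models(ts, seed = 60)
  centers <- t(vapply(tm$model_set$hmms, function(h) {
    colMeans(t(vapply(h$states, function(st) colSums(st$mu * st$w),
                      numeric(4))))
  }, numeric(4)))
  dists <- as.matrix(dist(centers))
  diag(dists) <- Inf
  # twin pairs sit far closer than the nominal separation
  expect_lt(sort(apply(dists, 1, min))[1], ts$separation / 2)
})
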