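test_that("forward log-likelihood matches exhaustive path enumeration", {
  set.seed(42)
  for (topo in c("bakis1", "ergodic")) {
    for (rep in 1:3) {
      means <- matrix(rnorm(6, sd = 2), 3, 2)
      h <- fixed_phone("p", topo, 3, means = means, self = 0.4)
      if (topo == "ergodic") {
        # randomize ergodic transitions away from uniform
        tr <- matrix(runif(9), 3, 3)
        ex <- runif(3)
        sc <- rowSums(tr) + ex
        h$trans <- tr / sc
        h$exit <- ex / sc
        h$entry <- c(0.5, 0.3, 0.2)
      }
      for (T_ in c(1, 3, 5)) {
        x <- matrix(rnorm(T_ * 2), T_, 2)
        expect_equal(sequence_loglik(list(h), x), brute_force_loglik(h, x),
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("single-state-path closed form and order sensitivity hold", {
  # deterministic path: self-loop 0 forces one frame per state
  means <- matrix(c(0, 0, 5, 5, -5, -5), 3, 2, byrow = TRUE)
  h <- fixed_phone("p", "bakis1", 3, means = means, self = 0)
  x <- means  # 3 frames, each exactly at its state mean
  expected <- sum(dnorm(0, 0, 1, log = TRUE) * 6)  # 3 frames x 2 dims at mean
  expect_equal(sequence_loglik(list(h), x), expected, tolerance = 1e-10)

  # a left-to-right model must score a reversed non-stationary sequence lower
  h2 <- fixed_phone("p", "bakis1", 3, means = means, self = 0.3)
  fwd <- sequence_loglik(list(h2), x)
  rev_ <- sequence_loglik(list(h2), x[3:1, ])
  expect_equal(fwd, brute_force_loglik(h2, x), tolerance = 1e-8)
  expect_equal(rev_, brute_force_loglik(h2, x[3:1, ]), tolerance = 1e-8)
  expect_gt(fwd, rev_)
})

test_that("sequence_loglik validates its inputs", {
  h <- fixed_phone("p")
  expect_error(sequence_loglik(list(h), matrix(0, 0, 2)), "non-empty")
  expect_error(sequence_loglik(list(h), matrix(0, 3, 5)), "dimension")
})

with_seed_dwells <- function(h, n) {
  set.seed(99)
  unlist(lapply(seq_len(n), function(i) {
    al <- sample_from_models(list(h), seed = NULL)$alignment
    rle(al$state)$lengths
  }))
}

test_that("model sampling is deterministic and respects path structure", {
  h <- fixed_phone("p", "bakis1", 3, self = 0.5)
  s1 <- sample_from_models(list(h), seed = 7)
  s2 <- sample_from_models(list(h), seed = 7)
  expect_identical(s1, s2)

  # self-loop 0 forces exactly one frame per state
  h0 <- fixed_phone("p", "bakis1", 3, self = 0)
  s <- sample_from_models(list(h0), seed = 1)
  expect_equal(nrow(s$features), 3)
  expect_equal(s$alignment$state, 1:3)

  # geometric dwell: self-loop 0.5 gives mean dwell 2 frames per state
  h5 <- fixed_phone("p", "bakis1", 3, self = 0.5)
  dwells <- with_seed_dwells(h5, n = 3500)
  expect_equal(mean(dwells), 2, tolerance = 0.05)
})

test_that("flat start pools global statistics and floors variances", {
  w <- tiny_world(seed = 3)
  tr <- train_split(w)
  specs <- setNames(lapply(w$inventory, function(p) topology_spec("bakis1", 3)),
                    w$inventory)
  ms <- flat_start(model_set(specs, feature_dim = 3), tr)

  frames <- do.call(rbind, tr$features)
  gmean <- colMeans(frames)       # direct-summation oracle
  gvar <- colMeans(sweep(frames, 2, gmean)^2)
  for (h in ms$hmms) {
    for (st in h$states) {
      expect_equal(as.numeric(st$mu), gmean, tolerance = 1e-10)
      expect_equal(as.numeric(st$var), gvar, tolerance = 1e-10)
    }
  }
  expect_equal(ms$variance_floor, pmax(1e-2 * gvar, 1e-8), tolerance = 1e-12)

  # constant corpus: zero variance must hit the floor
  const <- tr
  const$features <- lapply(const$features, function(f) {
    matrix(2, nrow(f), ncol(f))
  })
  msc <- flat_start(model_set(specs, feature_dim = 3), const)
  st <- msc$hmms[[1]]$states[[1]]
  expect_equal(as.numeric(st$mu), rep(2, 3))
  expect_equal(as.numeric(st$var), msc$variance_floor)
})

test_that("flat start reports uncovered phonemes by name", {
  w <- tiny_world(seed = 4)
  tr <- train_split(w)
  specs <- setNames(
    lapply(c(w$inventory, "zz"), function(p) topology_spec("bakis1", 3)),
    c(w$inventory, "zz"))
  expect_error(flat_start(model_set(specs, feature_dim = 3), tr), "zz")
})

test_that("embedded re-estimation increases likelihood monotonically", {
  w <- tiny_world(seed = 5)
  tr <- train_split(w)
  specs <- setNames(lapply(w$inventory, function(p) topology_spec("bakis1", 4)),
                    w$inventory)
  ms <- flat_start(model_set(specs, feature_dim = 3), tr)
  fit <- embedded_reestimate(ms, tr, n_iter = 12, tol_per_frame = 0)
  expect_true(all(diff(fit$loglik) > -1e-6))
  for (h in fit$model_set$hmms) {
    expect_equal(rowSums(h$trans) + h$exit, rep(1, h$spec$n_states),
                 tolerance = 1e-10)
    expect_true(all(h$trans[!h$mask$trans] == 0))
    for (st in h$states) {
      expect_true(all(st$var >= matrix(fit$model_set$variance_floor,
                                       nrow(st$var), ncol(st$var),
                                       byrow = TRUE) - 1e-12))
    }
  }
})

test_that("forced-alignment training recovers per-position state means", {
  # truth with self-loop 0 emits exactly one frame per state, so the sample
  # mean of frames at position j is an exact oracle for state j's mean
  set.seed(11)
  means <- matrix(c(-4, 0, 0, 4, 4, -4), 3, 2, byrow = TRUE)
  truth <- fixed_phone("p", "bakis1", 3, means = means, self = 0)
  sents <- lapply(1:60, function(i) sample_from_models(list(truth))$features)
  co <- speech_corpus(sprintf("s%02d", 1:60), sents,
                      words = replicate(60, "w", simplify = FALSE),
                      phones = replicate(60, "p", simplify = FALSE))
  ms <- flat_start(model_set(list(p = topology_spec("bakis1", 3)),
                             feature_dim = 2), co)
  fit <- embedded_reestimate(ms, co, n_iter = 25)
  pos_means <- t(sapply(1:3, function(j) {
    colMeans(do.call(rbind, lapply(sents, function(f) f[j, ])))
  }))
  got <- t(sapply(fit$model_set$hmms$p$states, function(st) st$mu[1, ]))
  expect_equal(got, pos_means, tolerance = 0.05, ignore_attr = TRUE)
})

test_that("state-mean recovery error decreases with corpus size", {
  ts <- truth_spec(P = 4, feature_dim = 3, separation = 4,
                   topo_probs = c(1, 0, 0), state_probs = c("3" = 1))
  tm <- make_truth_models(ts, seed = 21)
  err_at <- function(n) {
    set.seed(100 + n)
    labs <- names(tm$model_set$hmms)
    phs <- lapply(seq_len(n), function(i) sample(labs, 3, replace = TRUE))
    feats <- lapply(phs, function(ph) {
      sample_from_models(tm$model_set$hmms[ph])$features
    })
    co <- speech_corpus(sprintf("s%04d", seq_len(n)), feats,
                        words = phs, phones = phs)
    specs <- setNames(lapply(labs, function(p) topology_spec("bakis1", 3)), labs)
    ms <- flat_start(model_set(specs, feature_dim = 3), co)
    fit <- embedded_reestimate(ms, co, n_iter = 15)
    mean(vapply(labs, function(p) {
      tru <- t(sapply(tm$model_set$hmms[[p]]$states, function(s) s$mu[1, ]))
      est <- t(sapply(fit$model_set$hmms[[p]]$states, function(s) s$mu[1, ]))
      mean(abs(est - tru))
    }, numeric(1)))
  }
  errs <- vapply(c(50, 200, 800), err_at, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("mixture splitting follows the binary-split convention", {
  w <- tiny_world(seed = 6)
  tr <- train_split(w)
  specs <- setNames(lapply(w$inventory, function(p) topology_spec("bakis1", 3)),
                    w$inventory)
  ms <- flat_start(model_set(specs, feature_dim = 3), tr)

  # M = 1 -> 2: equal halves at mu +/- 0.2 sd
  m2 <- split_mixtures(ms, 2)
  st0 <- ms$hmms[[1]]$states[[1]]
  st2 <- m2$hmms[[1]]$states[[1]]
  expect_equal(st2$w, c(0.5, 0.5))
  expect_equal(st2$mu[1, ], st0$mu[1, ] + 0.2 * sqrt(st0$var[1, ]),
               ignore_attr = TRUE)
  expect_equal(st2$mu[2, ], st0$mu[1, ] - 0.2 * sqrt(st0$var[1, ]),
               ignore_attr = TRUE)

  # identity when target equals current order
  expect_identical(split_mixtures(m2, 2), m2)
  expect_error(split_mixtures(m2, 1), "below")

  # growth to 16 keeps weights a distribution in every state
  m16 <- split_mixtures(ms, 16)
  for (h in m16$hmms) {
    for (st in h$states) {
      expect_length(st$w, 16)
      expect_equal(sum(st$w), 1, tolerance = 1e-10)
    }
  }
})
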