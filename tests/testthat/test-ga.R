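test_that("codec length follows m = 2P + 1", {
  expect_equal(make_codec(default_phone_inventory())$m, 81)
  expect_equal(make_codec("sil")$m, 3)
  expect_equal(make_codec(c(sprintf("p%d", 1:9), "sil"))$m, 21)
  expect_error(make_codec(c("a", "a")), "duplicate")
  expect_error(make_codec(character(0)), "non-empty")
})

test_that("chromosome decode/encode round-trips and validates domains", {
  codec <- make_codec(c("aa", "bb", "sil"))
  set.seed(2)
  doms <- phonotop:::gene_domains(codec)
  for (i in 1:100) {
    ch <- vapply(doms, function(d) sample(d, 1L), integer(1))
    dec <- decode_chromosome(codec, ch)
    expect_identical(encode_chromosome(codec, dec$specs, dec$n_mix), ch)
  }
  # value 12 is legal only where the gene domain admits it (the mixture
  # gene); it is rejected in topology and state slots
  ok <- c(0L, 1L, 2L, 5L, 3L, 11L, 12L)
  expect_silent(validate_chromosome(codec, ok))
  bad <- ok
  bad[1] <- 12L
  expect_error(validate_chromosome(codec, bad), "gene 1")
  bad2 <- ok
  bad2[4] <- 12L
  expect_error(validate_chromosome(codec, bad2), "gene 4")
})

test_that("initial population carries the three seeded recognizers", {
  codec <- make_codec(c(sprintf("p%d", 1:5), "sil"))
  cfg <- ga_config(seed = 5)
  pop <- init_population(codec, cfg)
  expect_length(pop, 10)
  P <- codec$P
  expect_equal(pop[[1]]$chromosome, c(rep(0L, P), rep(3L, P), 6L))
  expect_equal(pop[[2]]$chromosome, c(rep(1L, P), rep(4L, P), 6L))
  expect_equal(pop[[3]]$chromosome, c(rep(2L, P), rep(3L, P), 6L))
  for (ind in pop) expect_silent(validate_chromosome(codec, ind$chromosome))
  expect_identical(init_population(codec, cfg), pop)  # seeded determinism
})

test_that("selection distribution implements the negative-fitness shift", {
  d <- selection_distribution(c(-2, 0, 4))
  expect_equal(d$probs, c(0, 0.25, 0.75), tolerance = 1e-12)
  expect_equal(d$cumprobs, c(0, 0.25, 1), tolerance = 1e-12)
  expect_equal(d$shift, 2)

  expect_equal(selection_distribution(c(2, 2))$probs, c(0.5, 0.5))
  # all-equal negatives shift to zero total: uniform fallback
  expect_equal(selection_distribution(c(-5, -5))$probs, c(0.5, 0.5))
  expect_equal(sum(selection_distribution(rnorm(7)^2)$probs), 1,
               tolerance = 1e-12)
})

test_that("roulette picks follow the cumulative-interval rule", {
  d <- list(probs = c(0.25, 0.25, 0.5), cumprobs = c(0.25, 0.5, 1), shift = 0)
  sel <- roulette_select(d, 4, r = c(0.1, 0.6, 0.9, 0.2))
  expect_equal(sel$indices, c(1, 3, 3, 1))
  expect_equal(dim(sel$couples), c(2, 2))

  # zero-probability individuals are never selected
  dz <- selection_distribution(c(-3, 1))
  set.seed(3)
  sel <- roulette_select(dz, 10)
  expect_true(all(sel$indices == 2))
})

test_that("empirical roulette frequencies match the distribution", {
  d <- selection_distribution(c(10, 30, 60))
  set.seed(17)
  idx <- roulette_select(d, 10000)$indices
  freq <- tabulate(idx, 3) / 10000
  expect_equal(freq, d$probs, tolerance = 0.02)
})

test_that("linear crossover blends, rounds half away, and clamps", {
  codec <- make_codec(c("a", "b", "sil"))
  a <- c(0L, 0L, 0L, 3L, 3L, 3L, 1L)
  b <- c(2L, 2L, 2L, 7L, 7L, 7L, 16L)
  # alpha = 1 reproduces the parents exactly
  off <- linear_crossover(a, b, 1, codec)
  expect_identical(off$c, a)
  expect_identical(off$d, b)
  # state genes 3 and 7 at alpha 0.7: 4.2 -> 4 and 5.8 -> 6
  off <- linear_crossover(a, b, 0.7, codec)
  expect_equal(off$c[4], 4L)
  expect_equal(off$d[4], 6L)
  # topology genes 0 and 2 at alpha 0.5 meet in the middle
  off <- linear_crossover(a, b, 0.5, codec)
  expect_equal(off$c[1], 1L)
  expect_equal(off$d[1], 1L)
  # offspring always stay in-domain
  set.seed(23)
  doms <- phonotop:::gene_domains(codec)
  for (i in 1:50) {
    p1 <- vapply(doms, function(d) sample(d, 1L), integer(1))
    p2 <- vapply(doms, function(d) sample(d, 1L), integer(1))
    off <- linear_crossover(p1, p2, runif(1), codec)
    expect_silent(validate_chromosome(codec, off$c))
    expect_silent(validate_chromosome(codec, off$d))
  }
})

test_that("mutation counts follow Y = round(beta X) and h = round(beta m)", {
  inv40 <- default_phone_inventory()
  codec <- make_codec(inv40)  # m = 81
  cfg <- ga_config(seed = 31)
  pop <- init_population(codec, cfg)
  set.seed(31)
  expect_length(mutate_parents(pop, 0.10, codec), 1)  # Y = round(1.0)
  expect_length(mutate_parents(pop, 0.30, codec), 3)  # Y = round(3.0)
  expect_length(mutate_parents(pop, 0, codec), 0)
  # h = round(0.1 * 81) = 8 positions, all actually changed
  set.seed(32)
  mut <- mutate_parents(pop[1], 1, codec)  # Y = 1 parent, h = round(81) = 81
  set.seed(33)
  muts <- mutate_parents(pop, 0.10, codec)
  parent_matches <- vapply(pop, function(ind) {
    sum(ind$chromosome != muts[[1]])
  }, integer(1))
  expect_equal(min(parent_matches), 8)  # differs from its parent in h spots
  expect_silent(validate_chromosome(codec, muts[[1]]))
})

test_that("mutation probability schedule steps at the printed levels", {
  expect_equal(beta_schedule(0), 0)
  expect_equal(beta_schedule(9.9), 0)
  expect_equal(beta_schedule(10), 0.10)
  expect_equal(beta_schedule(29), 0.10)
  expect_equal(beta_schedule(30), 0.30)
  expect_equal(beta_schedule(50), 0.40)
  expect_equal(beta_schedule(70), 0.50)
  expect_equal(beta_schedule(100), 0.50)
  expect_error(beta_schedule(-1), "w must be")
  expect_error(beta_schedule(101), "w must be")
})

test_that("replacement is elitist with incumbents winning ties", {
  mk <- function(f, tag) list(chromosome = tag, fitness = f)
  pop <- list(mk(50, 1L), mk(40, 2L), mk(30, 3L), mk(20, 4L))
  # all offspring worse: population unchanged
  off <- list(mk(10, 5L), mk(5, 6L))
  expect_identical(replace_population(pop, off), pop)
  # one offspring beats the worst incumbent: exactly that swap
  off <- list(mk(25, 7L))
  new <- replace_population(pop, off)
  expect_equal(vapply(new, `[[`, numeric(1), "fitness"), c(50, 40, 30, 25))
  expect_equal(new[[4]]$chromosome, 7L)
  # tie: incumbent stays
  off <- list(mk(20, 8L))
  new <- replace_population(pop, off)
  expect_equal(new[[4]]$chromosome, 4L)
})

test_that("a full micro-GA run is reproducible and monotone", {
  w <- tiny_world(seed = 40, P = 5, d = 3, n_sent = 24, n_nouns = 3,
                  n_verbs = 2)
  cfg <- ga_config(X = 4, T_iter = 3, seed = 40, train_iter = 3,
                   split_iter = 1)
  ga1 <- suppressWarnings(run_micro_ga(cfg, train_split(w), fitness_split(w),
                                       w$lexicon, w$grammar,
                                       inventory = w$inventory))
  ga2 <- suppressWarnings(run_micro_ga(cfg, train_split(w), fitness_split(w),
                                       w$lexicon, w$grammar,
                                       inventory = w$inventory))
  expect_identical(ga1$best$chromosome, ga2$best$chromosome)
  expect_identical(ga1$trajectory, ga2$trajectory)
  expect_true(all(diff(ga1$trajectory$best) >= 0))
  expect_equal(nrow(ga1$trajectory), cfg$T_iter + 1)
  # assignment table covers the inventory; tidy() adds the mixture column
  expect_equal(ga1$assignment$phoneme, w$inventory)
  expect_true(all(tidy(ga1)$mixtures == ga1$n_mix))
  expect_equal(nrow(glance(ga1)), 1)
})

test_that("fitness evaluation caches by gene vector", {
  w <- tiny_world(seed = 41, P = 4, d = 3, n_sent = 20, n_nouns = 3,
                  n_verbs = 2)
  codec <- make_codec(w$inventory)
  cfg <- ga_config(seed = 41, train_iter = 2, split_iter = 1)
  cache <- new.env(parent = emptyenv())
  ch <- c(rep(0L, codec$P), rep(3L, codec$P), 2L)
  net <- compile_network(w$lexicon, w$grammar)
  t1 <- system.time(
    f1 <- evaluate_fitness(ch, codec, train_split(w), fitness_split(w),
                           w$lexicon, w$grammar, cfg, cache = cache,
                           network = net))[3]
  t2 <- system.time(
    f2 <- evaluate_fitness(ch, codec, train_split(w), fitness_split(w),
                           w$lexicon, w$grammar, cfg, cache = cache,
                           network = net))[3]
  expect_identical(f1, f2)
  expect_lt(t2, t1 / 2)
})
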