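#' Chromosome codec for the topology search space
#'
#' A candidate solution assigns each of the `P` phonemes a topology code and a
#' state count, plus one global Gaussian-mixture component count, encoded as
#' an integer vector of `m = 2P + 1` genes: genes `1..P` are topology codes
#' (`0` Bakis-1, `1` Bakis-2, `2` Ergodic), genes `P+1..2P` are state counts
#' (3 to 11), and gene `2P + 1` is the mixture count (1 to 16). For the
#' 40-phoneme inventory this gives an 81-gene chromosome.
#'
#' @param inventory Character vector of phoneme symbols (unique, non-empty);
#'   fixes the gene ordering.
#' @return An object of class `chromosome_codec` with fields `phonemes`, `P`
#'   and `m`.
#' @examples
#' make_codec(default_phone_inventory())$m # 81
#' @export
make_codec <- function(inventory) {
  inventory <- as.character(inventory)
  if (!length(inventory)) stopf("phoneme inventory must be non-empty")
  if (anyDuplicated(inventory)) {
    stopf("phoneme inventory contains duplicates: %s",
          paste(unique(inventory[duplicated(inventory)]), collapse = ", "))
  }
  P <- length(inventory)
  structure(list(phonemes = inventory, P = P, m = 2L * P + 1L),
            class = "chromosome_codec")
}

#' @export
print.chromosome_codec <- function(x, ...) {
  cat(sprintf("<chromosome_codec: P=%d phonemes, m=%d genes>\n", x$P, x$m))
  invisible(x)
}

#' Standard 40-phoneme inventory
#'
#' The ARPAbet-style monophone set (15 vowels, 24 consonants) plus a silence
#' phone, matching the inventory size of small-vocabulary American-English
#' dysarthric-speech corpora.
#'
#' @return Character vector of 40 phoneme symbols, `"sil"` last.
#' @export
default_phone_inventory <- function() {
  c("aa", "ae", "ah", "ao", "aw", "ay", "eh", "er", "ey", "ih", "iy", "ow",
    "oy", "uh", "uw",
    "b", "ch", "d", "dh", "f", "g", "hh", "jh", "k", "l", "m", "n", "ng",
    "p", "r", "s", "sh", "t", "th", "v", "w", "y", "z", "zh", "sil")
}

# Per-gene domains as a list of integer vectors, in gene order.
gene_domains <- function(codec) {
  c(replicate(codec$P, 0:2, simplify = FALSE),
    replicate(codec$P, 3:11, simplify = FALSE),
    list(1:16))
}

#' Validate a chromosome against a codec
#'
#' @param codec A [make_codec()] result.
#' @param chromosome Integer vector of length `m`.
#' @return Invisibly `TRUE`; otherwise an error naming the offending gene.
#' @export
validate_chromosome <- function(codec, chromosome) {
  if (length(chromosome) != codec$m) {
    stopf("chromosome length %d does not match codec m = %d",
          length(chromosome), codec$m)
  }
  doms <- gene_domains(codec)
  for (i in seq_len(codec$m)) {
    if (!chromosome[i] %in% doms[[i]]) {
      stopf("gene %d value %s outside its domain [%d, %d]", i,
            chromosome[i], min(doms[[i]]), max(doms[[i]]))
    }
  }
  invisible(TRUE)
}

#' Decode a chromosome into topology specs and a mixture count
#'
#' @inheritParams validate_chromosome
#' @return A list with `specs` (named list of [topology_spec()], one per
#'   phoneme) and `n_mix` (global mixture count).
#' @export
decode_chromosome <- function(codec, chromosome) {
  validate_chromosome(codec, chromosome)
  P <- codec$P
  specs <- lapply(seq_len(P), function(j) {
    topology_spec(chromosome[j], chromosome[P + j])
  })
  names(specs) <- codec$phonemes
  list(specs = specs, n_mix = as.integer(chromosome[codec$m]))
}

#' Encode topology specs and a mixture count into a chromosome
#'
#' Inverse of [decode_chromosome()]; the round trip is the identity.
#'
#' @inheritParams validate_chromosome
#' @param specs Named list of [topology_spec()] in codec phoneme order.
#' @param n_mix Global mixture count.
#' @return Integer chromosome of length `m`.
#' @export
encode_chromosome <- function(codec, specs, n_mix) {
  stopifnot(identical(names(specs), codec$phonemes))
  as.integer(c(vapply(specs, function(s) s$topo_type, integer(1)),
               vapply(specs, function(s) s$n_states, integer(1)),
               n_mix))
}

#' Micro-GA run configuration
#'
#' @param X Population size (even, default 10).
#' @param T_iter Iteration budget (default 30; convergence changes are
#'   typically minimal after 20).
#' @param seed Integer seed for the whole run.
#' @param baseline_mixtures Mixture gene assigned to the three seeded
#'   individuals (default 6, the baseline recognizer's mixture order).
#' @param train_iter EM iterations for each fitness evaluation's initial
#'   re-estimation (default 20).
#' @param split_iter EM iterations after each mixture split (default 5).
#' @return An object of class `ga_config`.
#' @export
ga_config <- function(X = 10L, T_iter = 30L, seed = 1L,
                      baseline_mixtures = 6L, train_iter = 20L,
                      split_iter = 5L) {
  X <- as.integer(X)
  T_iter <- as.integer(T_iter)
  if (X < 4L || X %% 2L != 0L) stopf("X must be an even integer >= 4")
  if (T_iter < 1L) stopf("T_iter must be >= 1")
  if (!baseline_mixtures %in% 1:16) {
    stopf("baseline_mixtures must be in [1, 16]")
  }
  structure(list(X = X, T_iter = T_iter, seed = as.integer(seed),
                 baseline_mixtures = as.integer(baseline_mixtures),
                 train_iter = as.integer(train_iter),
                 split_iter = as.integer(split_iter)),
            class = "ga_config")
}

#' Seeded initial population
#'
#' The first three individuals are the standard single-topology recognizers:
#' Bakis-1 with 3 states for all phonemes, Bakis-2 with 4 states for all
#' phonemes, and Ergodic with 3 states for all phonemes (each with the
#' baseline mixture gene). The remaining individuals are uniform-random
#' within the gene domains.
#'
#' @param codec A [make_codec()] result.
#' @param config A [ga_config()].
#' @param seed Optional seed; defaults to the config's. Pass `NULL` to use
#'   the current RNG state.
#' @return A list of `X` individuals, each a list with `chromosome` and
#'   `fitness` (`NA` until evaluated).
#' @export
init_population <- function(codec, config = ga_config(),
                            seed = config$seed) {
  P <- codec$P
  seeded <- list(
    c(rep(0L, P), rep(3L, P), config$baseline_mixtures),
    c(rep(1L, P), rep(4L, P), config$baseline_mixtures),
    c(rep(2L, P), rep(3L, P), config$baseline_mixtures)
  )
  doms <- gene_domains(codec)
  with_seed(seed, {
    pop <- c(seeded, lapply(seq_len(config$X - 3L), function(i) {
      vapply(doms, function(d) sample(d, 1L), integer(1))
    }))
    lapply(pop, function(ch) list(chromosome = as.integer(ch),
                                  fitness = NA_real_))
  })
}

#' Roulette-wheel selection distribution
#'
#' Converts a vector of fitness values into selection probabilities
#' proportional to fitness. When any fitness is negative, the absolute value
#' of the most negative fitness is first added to all of them, so the most
#' negative individual gets selection probability exactly zero. If every
#' shifted fitness is zero the distribution degenerates to uniform.
#'
#' @param fitnesses Numeric vector (length at least 2).
#' @return An object of class `selection_distribution` with `probs`,
#'   `cumprobs` and `shift`.
#' @examples
#' selection_distribution(c(-2, 0, 4))$probs # 0, 0.25, 0.75
#' @export
selection_distribution <- function(fitnesses) {
  if (length(fitnesses) < 2L) stopf("need at least 2 fitness values")
  if (anyNA(fitnesses)) stopf("fitnesses contain NA")
  shift <- if (any(fitnesses < 0)) abs(min(fitnesses)) else 0
  f <- fitnesses + shift
  tot <- sum(f)
  probs <- if (tot > 0) f / tot else rep(1 / length(f), length(f))
  structure(list(probs = probs, cumprobs = cumsum(probs), shift = shift),
            class = "selection_distribution")
}

#' Roulette-wheel parent selection
#'
#' Draws `X` parents by the cumulative-probability interval rule: a uniform
#' draw below `C(1)` selects the first individual, otherwise the `x` whose
#' cumulative interval `(C(x-1), C(x)]` contains the draw. Consecutive picks
#' form `X/2` couples.
#'
#' @param dist A [selection_distribution()].
#' @param X Number of parents to draw (even).
#' @param r Optional numeric vector of `X` uniform draws (for reproducing a
#'   hand-worked selection); defaults to `runif(X)`.
#' @return A list with `indices` (length `X`) and `couples` (`X/2` by 2
#'   matrix).
#' @export
roulette_select <- function(dist, X, r = NULL) {
  if (is.null(r)) r <- runif(X)
  if (length(r) != X) stopf("r must have length X")
  cum <- dist$cumprobs
  idx <- vapply(r, function(ri) which(ri <= cum + 1e-15)[1L], integer(1))
  idx[is.na(idx)] <- length(cum)
  list(indices = idx, couples = matrix(idx, ncol = 2L, byrow = TRUE))
}

#' Linear (arithmetic) crossover of two chromosomes
#'
#' Offspring genes are the weighted blends `c_i = alpha*a_i + (1-alpha)*b_i`
#' and `d_i = alpha*b_i + (1-alpha)*a_i`, rounded half away from zero and
#' clamped to each gene's domain, so offspring are always valid chromosomes.
#' With `alpha = 1` the offspring equal the parents.
#'
#' @param a,b Integer chromosomes under the same codec.
#' @param alpha Blend weight in `[0, 1]` (tied to the mutation probability by
#'   `alpha = 1 - beta`).
#' @param codec A [make_codec()] result.
#' @return A list of two offspring chromosomes `c` and `d`.
#' @export
linear_crossover <- function(a, b, alpha, codec) {
  if (length(a) != codec$m || length(b) != codec$m) {
    stopf("parent chromosomes do not match the codec")
  }
  if (alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1]")
  doms <- gene_domains(codec)
  lo <- vapply(doms, min, integer(1))
  hi <- vapply(doms, max, integer(1))
  cc <- pmin(pmax(round_half_away(alpha * a + (1 - alpha) * b), lo), hi)
  dd <- pmin(pmax(round_half_away(alpha * b + (1 - alpha) * a), lo), hi)
  list(c = as.integer(cc), d = as.integer(dd))
}

#' Scheduled mutation of randomly chosen parents
#'
#' Selects `Y = round(beta * X)` parents without replacement and, in each,
#' resamples `h = round(beta * m)` distinct gene positions to a *different*
#' value within the gene's domain.
#'
#' @param population List of individuals (as from [init_population()]).
#' @param beta Mutation probability in `[0, 1]`.
#' @param codec A [make_codec()] result.
#' @return A list of mutated chromosomes (length `Y`; empty when
#'   `round(beta * X) == 0`).
#' @export
mutate_parents <- function(population, beta, codec) {
  if (beta < 0 || beta > 1) stopf("beta must be in [0, 1]")
  X <- length(population)
  Y <- round_half_away(beta * X)
  if (Y == 0) return(list())
  h <- round_half_away(beta * codec$m)
  doms <- gene_domains(codec)
  chosen <- sample.int(X, Y)
  lapply(chosen, function(p) {
    ch <- population[[p]]$chromosome
    pos <- sample.int(codec$m, h)
    for (g in pos) {
      alt <- setdiff(doms[[g]], ch[g])
      ch[g] <- if (length(alt) == 1L) alt else sample(alt, 1L)
    }
    as.integer(ch)
  })
}

#' Mutation-probability schedule
#'
#' The mutation probability is stepped up over the run: `beta = 0` before 10%
#' progress, then 0.10, 0.30, 0.40 and 0.50 from 10%, 30%, 50% and 70% of the
#' iteration budget onward (a discretization of the logarithmic ramp
#' `beta = 0.2*ln(w) - 0.36`). The crossover weight is always
#' `alpha = 1 - beta`, so the search shifts from explorative crossover toward
#' exploitative mutation as the run progresses.
#'
#' @param w Progress percentage in `[0, 100]` (100 * iteration index / T).
#' @return The mutation probability `beta`.
#' @examples
#' beta_schedule(0)  # 0
#' beta_schedule(10) # 0.10
#' beta_schedule(70) # 0.50
#' @export
beta_schedule <- function(w) {
  if (!is.finite(w) || w < 0 || w > 100) {
    stopf("progress w must be in [0, 100], got %s", w)
  }
  if (w < 10) 0 else if (w < 30) 0.10 else if (w < 50) 0.30 else
    if (w < 70) 0.40 else 0.50
}

#' Elitist replacement
#'
#' Pools incumbents and offspring and keeps the best `X` by fitness;
#' incumbents win ties. Consequently the best fitness in the population never
#' decreases.
#'
#' @param population List of evaluated individuals.
#' @param offspring List of evaluated individuals.
#' @return The new population (same size as `population`).
#' @export
replace_population <- function(population, offspring) {
  pool <- c(population, offspring)
  fit <- vapply(pool, function(ind) ind$fitness, numeric(1))
  if (anyNA(fit)) stopf("all individuals must be evaluated before replacement")
  pool[order(-fit)[seq_along(population)]]  # stable: incumbents first on ties
}
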