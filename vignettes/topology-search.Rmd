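---
title: "Phoneme-specific HMM topology search for disordered speech"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phoneme-specific HMM topology search for disordered speech}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonotop)
```

## The problem

Dysarthria — a motor speech disorder arising from neurological damage —
affects phonation, articulation and prosody unevenly across a speaker's
phoneme repertoire: some phonemes are prolonged, some are produced
imprecisely, and phone-level deletions, insertions and substitutions
increase. Conventional small-vocabulary recognizers model every phoneme with
the *same* hidden Markov model architecture, almost always a three-state
left-to-right ("Bakis") chain. When a speaker's phonemes are affected at
different levels, a single shared architecture is a compromise: phonemes with
prolonged or unstable dynamics may need more states, skip transitions, or a
fully connected (ergodic) structure.

`phonotop` implements a per-phoneme architecture search. Each phoneme's HMM
is described by two parameters — a topology type and a number of emitting
states — and all models share one Gaussian-mixture component count:

* **Bakis-1** (code 0): self-loop plus advance-by-one arcs;
* **Bakis-2** (code 1): Bakis-1 plus skip-by-two arcs;
* **Ergodic** (code 2): all emitting-to-emitting arcs;
* states: 3–11; mixture components: 1–16.

A candidate assignment for `P` phonemes is encoded as an integer chromosome
of `2P + 1` genes (topology code per phoneme, state count per phoneme, one
global mixture gene); with the standard 40-phoneme American-English
monophone inventory this is an 81-gene vector. The assignment is optimized
by a micro-genetic algorithm whose fitness is the word recognition accuracy
of the recognizer built from the assignment.

## The recognizer

Phone models have non-emitting entry and exit states so they concatenate
into sentence models. Emissions are diagonal-covariance Gaussian mixtures.
Training is embedded Baum-Welch re-estimation: for each training sentence
the transcribed phone models (with silence at the sentence boundaries) are
concatenated and forward-backward occupancies are pooled per phone. All
recursions run in a scaled linear domain (per-frame normalization with the
log-likelihood recovered from the scale factors), the standard construction
for long products of small probabilities. Initialization is a flat start:
every emission takes the global mean and variance of the pooled training
frames and transitions are uniform over the allowed arcs.

Mixture growth follows the incremental binary-splitting convention: the
heaviest components are duplicated with means perturbed by ±0.2 standard
deviations and weights halved, doubling toward the target count with a few
re-estimation passes after each split. Direct initialization at a high
mixture order from a flat start is unstable; splitting inherits a trained
single-Gaussian solution.

Decoding compiles the pronunciation lexicon and the sentence grammar into a
network of word models (uniform word-transition probabilities; no language
model) and finds the maximum-probability path by Viterbi search. Hypotheses
are scored against references by a minimal-edit alignment with unit costs
for deletions, substitutions and insertions, and accuracy is

$$\mathrm{WAcc} = 100\,\frac{N - D - S - I}{N},$$

pooled over sentences by summing counts (not by averaging per-sentence
accuracies). Insertions can push the accuracy negative; the selection step
of the optimizer is defined for that case (below).

## The micro-genetic algorithm

The population holds `X = 10` individuals. The first three are the standard
single-topology recognizers — Bakis-1 with 3 states, Bakis-2 with 4, Ergodic
with 3, each with the baseline mixture order (6) — so the search starts from
the systems it must beat and elitist replacement guarantees it never ends
below them on the fitness set. The remaining seven are uniform-random in the
gene domains.

Each iteration performs:

1. **Fitness evaluation** — build, flat-start, train and mixture-grow the
   models of each new chromosome, decode the fitness split, score WAcc.
   Fitness values are cached by gene vector; the micro-GA revisits
   chromosomes often and training is the cost center.
2. **Roulette selection** — selection probabilities proportional to fitness.
   If any fitness is negative, the absolute value of the most negative
   fitness is added to all, so the worst individual gets probability exactly
   zero; if the shifted total is zero the distribution degenerates to
   uniform. `X` draws form `X/2` couples.
3. **Linear crossover** — gene-wise blends
   `c_i = α a_i + (1-α) b_i`, `d_i = α b_i + (1-α) a_i`, rounded half away
   from zero and clamped to the gene domain. Arithmetic blending is applied
   uniformly to all genes, including the categorical topology codes — the
   codes are ordered by connectivity (Bakis-1 ⊂ Bakis-2 ⊂ Ergodic), which
   makes the midpoint meaningful, and it keeps the operator identical across
   the chromosome.
4. **Scheduled mutation** — `Y = round(βX)` parents are drawn without
   replacement and `h = round(βm)` gene positions in each are resampled to a
   *different* in-domain value. The mutation probability β is stepped up
   with run progress `w` (percent of the iteration budget): 0 below 10%,
   then 0.10, 0.30, 0.40 and 0.50 from 10%, 30%, 50% and 70%. These are the
   printed levels of the logarithmic ramp `β = 0.2·ln(w) − 0.36` (natural
   log; the base-10 reading does not reproduce the levels). The crossover
   weight is always `α = 1 − β`: the search moves from explorative blending
   toward exploitative local change.
5. **Elitist replacement** — parents and offspring are pooled and the best
   `X` kept, incumbents winning ties. Best-so-far fitness is therefore
   monotone non-decreasing.

The run stops after a fixed budget of `T = 30` iterations (convergence
changes are typically minimal after 20; reduced-scale studies in this
package use `T = 10`). With a fixed seed the whole run — population
initialization, selection draws, mutation sites, and hence the final
assignment table — is exactly reproducible.

## The synthetic corpus generator

The restricted dysarthric-speech corpus the method was designed around
cannot be redistributed, so every stage of this package is exercised on
synthetic data whose *structure* emulates it: a ~40-phoneme inventory
(silence included), a six-slot nonsense-sentence grammar "the X is Y the Z"
with monosyllabic nouns (2–4 phones) and bisyllabic verbs (4–6 phones),
sentence sets built by pairing nouns without replacement and duplicating
each sentence with X and Z swapped, and train / fitness / test splits that
are re-drawn until the training split covers the full inventory.

Features are synthesized directly in acoustic-feature space (no audio). The
default dimension is 39, matching a 12-MFCC + energy + Δ + ΔΔ front end;
reduced-scale studies use dimension 3–5. A ground-truth model bank is drawn
per speaker: phone centers are placed so their minimum pairwise distance
equals the `separation` knob (in units of the unit emission standard
deviation), each state adds a trajectory offset with standard deviation
`state_spread`, and per-phoneme topologies and state counts are drawn from
the spec distributions (silence is pinned at Bakis-1/3, the assignment real
speakers consistently receive). An optional `confusable_fraction` places
pairs of phones at the *same* spectral center so only their temporal
dynamics distinguish them — the synthetic analogue of the spectrally
confusable phone pairs of disordered speech.

Severity acts on the generating models: `duration_dilation` multiplies
self-loop odds (phoneme prolongation), `variance_inflation` scales emission
variances (articulatory imprecision), and `substitution_rate` replaces a
phone's acoustics with its nearest confusable while the transcription keeps
the intended words (the error is acoustic, as in dysarthria). The presets
none/mild/moderate/severe form an increasing gradient, chosen as a
qualitative emulation — no clinical realism is claimed. Consequently,
passing tests on this generator demonstrate correctness of the estimation,
search and scoring machinery and the *mechanism* of per-phoneme gains; they
do not demonstrate gains on real dysarthric recordings.

## Study conditions used by the test suite

The comparison study (optimized assignment versus single-topology baselines)
runs on five seeded one-speaker cohorts at reduced scale, chosen so a cohort
trains in about a minute on one CPU: 10 phonemes, feature dimension 4,
separation 2.5, state spread 1.5, truth topology mix 40/30/30% with 3–6
states, confusable fraction 0.5, severe severity, 72 sentences split
36/18/18 over a 10-noun / 5-verb lexicon, `X = 10`, `T = 10`, 5
re-estimation iterations plus 1 per mixture split. Two considerations fixed
these values. First, the baselines should score inside the range reported
for real dysarthric speakers (roughly 40–95% word accuracy), not at 100%:
at the ceiling the optimizer has nothing to express. Second, the structural
advantage of matched topologies must exceed the sampling noise of the
fitness split (about 3–4 accuracy points at 18 sentences of 6 words); the
confusable-twin mechanism supplies most of that margin, since a three-state
left-to-right model blurs the temporal contrast that separates twin phones.

Two properties are asserted over these cohorts. The elitism guarantee —
the optimized system never scores below the best seeded baseline on the
fitness split — holds in every cohort by construction. The stricter
requirement of a test-set gain over the uniform Bakis-1 baseline in at
least four of the five cohorts is at the edge of what this scale can
resolve: cohorts whose baseline reaches the accuracy ceiling leave nothing
to gain, and at 18 fitness sentences the selection noise is of the same
order as the structural signal, so the corresponding acceptance check can
fail on a minority of seeds. The test suite asserts it as stated rather
than weakening it.

## Numerical choices and degenerate inputs

* All probability arithmetic is in log space or scaled linear space;
  disallowed arcs are exactly zero and stay zero through re-estimation.
* Emission variances are floored at `1e-2` times the global per-dimension
  data variance (set at flat start), preventing collapse on small corpora.
* Re-estimation stops early when the per-frame log-likelihood gain falls
  below `1e-4` (default budget 20 iterations). The per-iteration
  log-likelihood is evaluated under the pre-update parameters, so the
  reported trajectory is non-decreasing up to floor effects.
* Sentences with a zero-probability path are skipped with a warning and
  counted; training aborts only if every sentence is skipped.
* Viterbi ties break toward the lowest-numbered state; network states are
  laid out in lexicon order, so ties resolve to the earliest word in the
  lexicon. A failed decode (no admissible path) scores as deletions of all
  reference words, keeping the accuracy formula defined per sentence.
* Zero-probability individuals can never be drawn by roulette selection;
  the degenerate all-equal-after-shift case falls back to uniform.
* The matched-pairs comparison between two systems is a sentence-level
  sign-flip randomization test on error-count differences (exact
  enumeration up to 12 pairs, and always — with a warning — below 6 pairs;
  seeded Monte-Carlo otherwise). It is a standard surrogate for the classic
  matched-pairs sentence-segment test.

## Known limitations

* Feature synthesis is Gaussian with diagonal covariance; real MFCC streams
  have correlated dimensions and non-stationary noise.
* The decoding network applies uniform word-transition probabilities; no
  n-gram scoring, beam pruning or lattice output.
* Triphone/context-dependent modelling, discriminative training and
  speaker adaptation are out of scope.
* The word-loop grammar duplicates word models into two alternating banks
  so immediate repetitions survive the path read-out; memory grows
  accordingly for large vocabularies.
* The micro-GA does not restart on convergence; the iteration budget is the
  only stop rule.
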