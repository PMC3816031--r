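Package: phonotop
Title: Phoneme-Specific HMM Topology Optimization for Disordered-Speech Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Small-vocabulary hidden Markov model (HMM) speech recognition with
    per-phoneme topology search for dysarthric speakers. Each phoneme HMM may
    take a Bakis-1 (left-to-right), Bakis-2 (left-to-right with skip arcs) or
    Ergodic transition structure with 3 to 11 emitting states, and all models
    share a global Gaussian-mixture component count; the assignment is
    optimized by a micro-genetic algorithm (roulette selection, linear
    crossover, scheduled mutation) whose fitness is word recognition accuracy
    obtained by embedded Baum-Welch training and Viterbi grammar decoding.
    Includes a synthetic dysarthric-speech feature corpus generator with
    severity knobs (phoneme prolongation, variance inflation, phone
    substitution), HTK-style parameter and master label file input/output,
    word-accuracy scoring by minimal edit alignment, a matched-pairs
    significance test, and an experiment harness comparing single-topology
    baseline recognizers against the optimized assignment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    rlang,
    generics,
    ggplot2,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
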