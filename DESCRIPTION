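Package: nolhho
Title: Harris Hawks Optimization with Nonlinear Energy Decay and Random
    Opposition-Based Learning for DNA Storage Code Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Implements the Harris hawks optimization (HHO) metaheuristic and
    its NOL-HHO variant, which augments HHO with a nonlinear escape-energy
    schedule and random opposition-based learning (ROL) with elitist survivor
    selection. Ships the classical 23-function benchmark suite (sphere through
    Shekel) for optimizer evaluation, and applies the optimizer to construct
    sets of fixed-length quaternary DNA words for data storage that satisfy
    the no-runlength constraint, a fixed GC weight, and a minimum pairwise
    Hamming distance. Includes exact branch-and-bound and randomized greedy
    baselines for verifying constructed code sizes, Wilcoxon rank-sum
    comparison of optimizers over repeated runs, and FASTA input/output for
    codeword sets.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
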