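# nolhho

Designing codeword sets for DNA data storage is a constrained packing
problem: find as many length-n words over {A, C, G, T} as possible such
that no word contains a homopolymer (no two adjacent bases equal), every
word carries exactly w G/C bases, and every pair of words differs in at
least d positions. Each constraint guards a failure mode of real DNA
storage — homopolymers inflate synthesis and sequencing errors, uneven GC
content destabilizes duplexes, and similar sequences cross-hybridize. The
size of the largest such set, A^GC,NL(n, d, w), bounds the storage
capacity and the code rate R = log4(M)/n; every concrete valid set of size
M is a certificate that A^GC,NL(n, d, w) >= M.

This package implements the machinery to construct such certificates with
a metaheuristic, and the metaheuristic itself:

* **HHO** — Harris hawks optimization, a population optimizer whose
  exploration/exploitation balance is driven by a per-hawk escape energy
  E = (2r − 1)·E1(t), with four "besiege" attack moves and Lévy-flight
  rapid dives.
* **NOL-HHO** — HHO with two modifications: a nonlinear decay of the
  energy envelope E1 (slow early, fast late, so exploration stays possible
  until ~91% of the run instead of dying at 50%), and per-iteration random
  opposition-based learning, x̂_j = a_j + b_j − r_j·x_j, with elitist
  union top-N survivor selection.
* The classical **23-function benchmark suite** (sphere … Shekel) with
  known optima, a repeated-run evaluation protocol, and Wilcoxon rank-sum
  comparison of optimizers.
* A **code builder** that grows DNA code sets word by word, where each
  word is found by NOL-HHO over a continuous relaxation of the word space,
  plus two independent oracles: an exact branch-and-bound maximum-clique
  search for small n and a randomized greedy baseline.

## A worked example

Construct a code for n = 5, d = 3, w = 2 and audit it:

```r
library(nolhho)

cs <- grow_code_set(5, 3, w = 2, restarts = 1000, stop_size = 20, seed = 101)
cs
#> DNA code set: 20 words, n = 5, d >= 3, GC weight 2 (rate 0.432)
#>    AGCAT TGTAC TGACA ATCTG AGTGA ACAGT ...

validate_code_set(cs)
#> Code set report (n=5, d=3, w=2): PASS
#>   20 words, min pairwise distance 3

exhaustive_best(4, 3, 2)$size   # exact maximum for the smaller (4,3,2) cell
#> [1] 12
```

Twenty words of length 5 at pairwise distance >= 3 certifies
A^GC,NL(5, 3, 2) >= 20. On the optimizer side, the standard protocol (30
hawks, 500 iterations, 30 independent runs) reproduces the exact floors on
the multimodal benchmarks:

```r
exp <- run_benchmark_table(functions = c(9, 10, 11),
                           algorithms = "NOL-HHO", runs = 30, seed = 1)
exp$summary
#>    id dim algorithm          avg std
#> 1  F9  30   NOL-HHO 0.000000e+00   0
#> 2 F10  30   NOL-HHO 4.440892e-16   0
#> 3 F11  30   NOL-HHO 0.000000e+00   0
```

The zero means are exact: once every coordinate is small enough, the
Rastrigin and Griewank forms round to 0.0 in double precision, and
4.44e-16 is the double-precision floor of the Ackley form at the origin.

A command-line interface for building and verifying code sets is installed
with the package:

```sh
Rscript $(Rscript -e 'cat(system.file("cli", "dnacode.R", package="nolhho"))') \
    build --n 5 --d 3 --w 2 --restarts 1000 --stop-size 20 --seed 101 --out codes.fasta
```

## Package layout

| Area | Functions |
| --- | --- |
| Benchmarks | `benchmark_suite()`, `benchmark_function()`, `evaluate_objective()`, `suite_manifest()` |
| Optimizer | `hho_run()`, `nolhho_run()`, `hho_config()`, `escape_energy()`, `levy_step()`, `exploration_move()`, `exploitation_move()` |
| NOL strategies | `nonlinear_energy_factor()`, `linear_energy_factor()`, `opposite_point()`, `rol_transform()`, `select_survivors()` |
| DNA codes | `dna_code_set()`, `validate_code_set()`, `hamming_distance()`, `gc_content()`, `has_no_runlength()`, `code_rate()`, FASTA/text IO |
| Builder | `grow_code_set()`, `exhaustive_best()`, `greedy_baseline()`, `candidate_fitness()`, `enumerate_feasible_words()` |
| Experiments | `run_benchmark_table()`, `run_dimension_sweep()`, `wilcoxon_compare()`, `run_bound_grid()`, `reference_benchmarks()`, `reference_bounds()` |

The methods vignette (`vignettes/nolhho-methods.Rmd`) documents the model,
the design decisions and their rationale, and known limitations.
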