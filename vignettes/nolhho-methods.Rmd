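---
title: "NOL-HHO: methods, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NOL-HHO: methods, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nolhho)
```

## The optimizer

Harris hawks optimization (HHO) is a population metaheuristic modeled on
cooperative hawk hunting. A population of N "hawks" (candidate solutions in
a box domain) tracks the best solution found so far, the "rabbit". Each
iteration every hawk draws an escape energy

$$E = (2r - 1)\,E_1(t), \qquad r \sim U(0,1),$$

where $E_1(t)$ is a deterministic envelope decaying from 2 to 0 over the
run. When $|E| \ge 1$ the hawk explores (perching relative to a random
flock member, or relative to the rabbit and the flock mean); when $|E| < 1$
it exploits with one of four "besiege" moves selected by a second uniform
draw crossed with $|E| \lessgtr 0.5$: soft besiege, hard besiege, and their
progressive-rapid-dive variants in which a dive candidate and, failing
that, a Lévy-flight candidate replace the hawk only when strictly better.
The Lévy steps use the Mantegna construction,
$0.01\, u\sigma/|v|^{1/\beta}$ with $u, v$ standard normal and
$\beta = 1.5$ by default.

Baseline HHO decays the envelope linearly, $E_1 = 2(1 - t/T)$. The direct
consequence is that $E_1 < 1$ for all $t > T/2$: in the entire second half
of the run $|E| < 1$ always, so no hawk can explore, and a population
trapped near a local optimum stays trapped. NOL-HHO replaces the envelope
with a nonlinear decay,

$$E_1(t) = b_{fin} - (b_{fin} - b_{ini})\,
  \frac{1 - e^{(t/T)^5}}{1 - e}, \qquad b_{ini} = 0,\; b_{fin} = 2,$$

which satisfies $E_1(0) = 2$, $E_1(T) = 0$, decreases strictly, dominates
the linear envelope pointwise, and crosses 1 only at $t \approx 0.91\,T$:
exploration stays possible almost to the end, followed by a short,
aggressive exploitation phase. Algebraically equivalent rearrangements of
this schedule exist (e.g. via $(1-e^s)/(1-e) = (e^s-1)/(e-1)$); the form
above, characterized by the $(b_{fin} - b_{ini})$ prefactor, the $1/(1-e)$
factor, the $(t/T)^5$ exponent, the 2-to-0 endpoints and the
slow-early/fast-late shape, is the single normative schedule in this
package.

The second ingredient is random opposition-based learning (ROL). Classical
opposition-based learning mirrors a point through the box center,
$\hat{x}_j = a_j + b_j - x_j$ (an involution). ROL randomizes the mirror,

$$\hat{x}_j = a_j + b_j - r_j x_j, \qquad r_j \sim U(0,1)
  \text{ independently per dimension},$$

spreading the mirrored candidates over a region. Once per iteration, after
all position updates, the whole population is mirrored and the N best of
the 2N originals-plus-mirrors survive (union top-N selection, per the
"select N better individuals" rule; not pairwise better-of-two). The
selection is elitist: the best individual always survives, and the
population mean fitness cannot degrade across the ROL step.

Implementation notes, where the published description leaves room:

* $E_0 = 2r - 1$ is redrawn per hawk per iteration, matching the reference
  HHO implementation, not once per iteration.
* Branch probabilities are all "equal probability": exploration strategy at
  $q \lessgtr 0.5$, exploitation at $r \lessgtr 0.5$ crossed with
  $|E| \lessgtr 0.5$.
* Out-of-box coordinates are clamped to the nearest bound after every move
  (including mirrored points), the simplest contract.
* Minimization throughout; maximization problems must be negated.
* One iteration's moves are computed as a batch against the population
  state at the start of the iteration. The per-row uniform draws are
  vectorized; a seeded run is exactly reproducible.
* ROL is applied to the full population every iteration. The initial
  population is uniform in the box and is not opposition-initialized; the
  flow places ROL strictly inside the iteration loop, and extending it to
  initialization is a variant, not the default.
* The `rand()` in the ROL mirror is per-dimension (the subscript on
  $\hat{x}_j$); a per-individual scalar variant is available via
  `rol_per_dimension = FALSE` but is not the default.

## The benchmark suite

`benchmark_suite()` provides the 23 classical test functions used across
the HHO/GWO literature: unimodal F1–F7 (sphere, Schwefel 2.22/1.2/2.21,
Rosenbrock, step, noisy quartic), scalable multimodal F8–F13 (Schwefel
sine, Rastrigin, Ackley, Griewank, two penalized functions) and
fixed-dimension multimodal F14–F23 (Shekel's foxholes, Kowalik, six-hump
camel, Branin, Goldstein–Price, Hartmann 3/6, Shekel 5/7/10), with their
conventional boxes and known optima. F7's additive uniform noise is drawn
from the seeded stream so runs stay reproducible. F8's optimum is stored as
$-418.9829 \times \text{dim}$ (the 4-decimal convention); tests allow for
that rounding. Two floating-point facts matter for reading results:

* Rastrigin and Griewank evaluate to exactly 0.0 once every coordinate is
  below roughly $10^{-9}$ in magnitude (the cosine terms round to 1 and
  the quadratic contributions are absorbed), so a fully converged
  optimizer prints an exact zero mean.
* Ackley at (numerically) the origin does not evaluate to 0 but to its
  double-precision floor; in this implementation the floor is
  4.44e-16. Printed floors of 8.88e-16 elsewhere reflect a different
  (equally rounding-determined) summation order in other languages.

## DNA storage codes

A storage code here is a set of length-n words over {A, C, G, T} under
three constraints: no-runlength (no two adjacent bases equal — forbids
homopolymers, which inflate synthesis/sequencing error and promote
secondary structure), fixed GC weight w (G+C count per word, stabilizing
melting behavior; w = n/2 for even n), and minimum pairwise Hamming
distance d (suppresses nonspecific hybridization and allows substitution
errors to be corrected). $A^{GC,NL}(n, d, w)$ denotes the maximum such set
size; every concrete valid set of size M certifies the lower bound
$A^{GC,NL}(n,d,w) \ge M$, and the code rate is $\log_4(M)/n$. Words map to
base-4 digits by A-0, G-1, C-2, T-3. For odd n the GC weight defaults to
$\lfloor n/2 \rfloor$; swapping A with C and T with G is a distance- and
runlength-preserving bijection between weight-w and weight-(n−w) codes, so
floor versus ceiling makes no difference to the attainable sizes.

### The builder

`grow_code_set()` grows a code one word at a time. Each candidate word is
found by NOL-HHO over the continuous box $[0,4]^n$; a position decodes by
flooring each coordinate to a digit. The search minimizes a penalty
objective

$$f(x) = P \cdot \#\{\text{adjacent equal pairs}\}
       + P \cdot |GC - w| + \max(0,\, d - \text{minDist}(x, S)),
  \qquad P = n + 1,$$

with minDist against an empty set defined as n, so $f = 0$ exactly when
the decoded word is admissible — a clean stopping rule (`target_fitness =
0`). Among admissible words evaluated in one search, the lexicographically
smallest is accepted, which makes a seeded build fully deterministic.
After `max_failures` consecutive failed searches the current set is
treated as maximal for this trajectory.

Two design choices depart from a naive incremental loop, and both were
forced by measurement:

* **Perturbative restarts.** Restarting from scratch makes the achieved
  size distribution that of a random maximal set, which sits well below
  the best known packings (for example, random maximal sets for n = 4,
  d = 3, w = 2 are almost always size 6–10; the true maximum is 12, hit in
  under 0.5% of random growths). Each restart round therefore perturbs the
  incumbent: with probability 1/2 it force-inserts a random feasible word
  and evicts the kept words conflicting with it (the classic plateau-escape
  move of clique/packing search), otherwise it drops a random fraction
  (about 12%) of the set; growth then resumes and the best set ever seen
  is retained. Worse-off trajectories usually reset to the incumbent best.
* **Wide, shallow inner searches seeded on the feasible stratum.**
  Population fitness evaluation is batched (one-hot digit encoding and a
  single crossproduct against the current set), so a 150–600-hawk,
  10-iteration search costs little more than a 15-hawk, 40-iteration one
  while screening an order of magnitude more candidate words per search.
  Initial hawks are placed on random feasible words (uniformly jittered
  inside their decode cell) rather than uniformly in the box, so a search
  opens with a wide screen of the feasible stratum before the optimizer
  recombines toward distant words. The default population width scales
  with $\sqrt{|\text{feasible words}|}\cdot d/2$ because admissible words
  thin out sharply as d grows.

Budgets are expressed in restart rounds; more rounds only ever improve the
result. The documented per-cell budgets used by the reproduction script
(3000–10000 rounds depending on the cell, with early exit once the target
size is certified) were sized so that the published bounds are reached with
margin on a desk machine; the dense n = 7, d = 3 cell is the slowest at
roughly 5–10 CPU minutes.

### The oracles

Two independent constructions audit the builder. `exhaustive_best()`
enumerates all feasible words, builds the compatibility graph (edge iff
Hamming distance ≥ d) and finds a maximum clique by Tomita-style
branch-and-bound with a greedy-coloring bound — exact values for small n
(dense instances beyond n = 5 get slow). `greedy_baseline()` is randomized
first-fit over shuffled feasible orderings. The builder must never exceed
the exact maximum, and should match or beat the greedy baseline.

## Evaluation protocol

`run_benchmark_table()` follows the standard comparison protocol: 30
search agents, 500 iterations, 30 independent runs per (algorithm,
function), reporting per-cell mean and standard deviation. Per-run seeds
derive from one master seed by a counter scheme (`derive_seed()`), so a
whole experiment reruns bit-identically. `wilcoxon_compare()` applies the
two-sided Mann–Whitney/Wilcoxon rank-sum test to per-run best values
(significance at 5%); fully tied samples — which do occur when both
optimizers hit an exact floor in every run — report p = 1 with a warning
rather than a spurious test statistic. Published results for nine other
optimizers (GA, PSO, BBO, FPA, GWO, BAT, FA, MFO, DE) and prior
altruistic-search lower bounds ship as frozen reference tables
(`reference_benchmarks()`, `reference_bounds()`) for side-by-side display;
they are quoted constants and are never recomputed.

## What the tests do and do not show

The test suite verifies the optimizer's contracts (elitism, box
invariance, schedule shape, ROL containment and selection), checks the
evaluators against independent straight-line oracles, and reproduces the
headline results end to end: exact maxima at n = 4 (32/12/4 for
d = 2/3/4), published lower-bound sizes on five (n, d) cells, and the
floor means on Rastrigin/Ackley/Griewank under the standard protocol. All
of this concerns synthetic mathematical objectives and idealized code
constraints. It says nothing about wet-lab behavior of the constructed
sequences: no melting-temperature, secondary-structure or
reverse-complement screening is performed, and Hamming distance is a proxy
that ignores insertions and deletions. Constructed sets are certificates
for the combinatorial bounds, not validated oligo libraries.

## Known limitations

* Large cells of the bound grid (e.g. n = 10, d = 2, where the best known
  size exceeds 13,000) are out of desk-scale reach of this builder and are
  not part of the reproduction targets; the d = 2 column generally favors
  specialized constructions over stochastic search.
* `exhaustive_best()` is exponential; dense instances beyond n = 5 can take
  minutes to hours.
* The optimizer assumes box constraints only; equality/inequality
  constraint handling beyond clamping is out of scope, as are maximization
  mode, island/parallel populations, and other opposition-learning
  variants (quasi-opposition, center-based).
* Wilcoxon p-values for floor functions where both algorithms are tied in
  every run carry no information (reported as p = 1 with a tie warning).
* The two NOL ingredients pull in different directions on shifted optima.
  For a symmetric box the ROL mirror reduces to $-r_j x_j$, a randomized
  contraction toward the origin. Combined with elitist survivor selection
  this is a powerful accelerant on the origin-centered benchmarks (the
  F1–F4 and F9–F11 floors in the test suite are reached through exactly
  this mechanism) but measurably slows final refinement on the penalized
  functions F12/F13, whose optima sit at $-1$ and $+1$: in this
  implementation NOL-HHO trails plain HHO there, even though the nonlinear
  schedule alone improves on HHO. The comparison test records this
  directional property as measured; users targeting objectives with
  optima far from the box center may prefer `rol = FALSE` with
  `schedule = "nonlinear"`.
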