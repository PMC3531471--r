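---
title: "Beam-search heuristics for the shortest common supersequence problem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beam-search heuristics for the shortest common supersequence problem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scsbeam)
```

## The problem

A string $t$ *embeds* a string $s$ (equivalently, $t$ is a supersequence of
$s$) when all symbols of $s$ occur in $t$ in the same order, not
necessarily contiguously. Given an alphabet $\Sigma$ of size $q$ and $m$
strings $s_1,\dots,s_m$, the shortest common supersequence problem (SCSP)
asks for a minimum-length $t$ that embeds every $s_i$. The problem is
NP-hard even for $q = 2$ or when all strings have length two, so exact
methods only reach small instances and practical solvers are heuristic.
The problem matters in bioinformatics: a common supersequence of a set of
oligonucleotide probes is exactly a schedule of synthesis cycles that can
deposit all of them on a microarray, so shorter supersequences mean fewer,
cheaper and less error-prone fabrication cycles.

Throughout, progress of a partial solution $y$ on string $s_i$ is measured
by $\lambda_i(y)$, the length of the longest prefix of $s_i$ embedded by
$y$ (`lambda_prefix()`); the *remaining* part of $s_i$ has length
$r_i = |s_i| - \lambda_i$. A candidate is complete when every $r_i = 0$.

## The embedding-probability heuristic

To rank partial solutions at equal constructed length the package uses the
probability that a single random string would finish the job. For a fixed
string of length $i$ and a uniform random string of length $j$ over $q$
symbols,

$$P(i,j) = \tfrac{1}{q}\,P(i-1,j-1) + \bigl(1-\tfrac{1}{q}\bigr)\,P(i,j-1),
\qquad P(0,j)=1,\quad P(i,j)=0 \text{ for } i>j,$$

which `build_probability_table()` tabulates exactly (the $i=1$ row has the
closed form $1-(1-1/q)^j$). The heuristic value of a candidate is the
product $\prod_i P(r_i, j)$ over the remaining lengths
(`heuristic_value()`), treating the strings as independent.

Two numerical choices matter here:

* **Reference length $j$.** The product needs one common random-string
  length. The default (`length_mode = "max_remaining"`) sets
  $j = \max_i r_i$ per candidate, which needs no global horizon estimate; a
  `fixed` mode is available. With $j$ fixed, embedding one more symbol of
  any string never decreases the value ($P$ is nonincreasing in $i$). With
  `max_remaining` this monotonicity holds whenever the advanced string is
  not the unique longest remainder; advancing the unique maximum shrinks
  $j$ as well, and the value can then decrease slightly (e.g. $q=2$,
  $r = (4,3) \to (3,3)$ gives $0.0195 \to 0.0156$). This is a property of
  the per-candidate horizon, not a defect of the table; the ranking it
  induces still rewards balanced progress, which is what beam selection
  needs.
* **Log space.** Products over many strings underflow double precision
  (100 strings with $P \approx 10^{-4}$ each are far below
  `.Machine$double.xmin`), so ranking uses $\sum_i \log P(r_i, j)$.
  `-Inf` values (some $r_i > j$ in fixed mode) are valid and simply rank
  last, with ties broken by total progress $\sum_i \lambda_i$ and then by
  insertion order, keeping runs reproducible.

## Probabilistic beam search

`pbs_solve()` performs level-synchronous construction. At each level every
beam member is extended with every symbol that *contributes* (embeds a new
symbol of at least one string); the first complete child terminates the
search. Otherwise selection builds the next beam from the child set:

1. children are ranked by log heuristic value;
2. the best $k_b$ become *dominators* and enter the beam unconditionally;
3. until the beam holds $k_w$ members, the next member is the pool's best,
   or — with probability $\mu$ — a draw by Baker's linear ranking
   (rank $r$ of $N$ has weight $N-r+1$); a selected candidate whose
   $\lambda$ vector is componentwise $\le$ that of some dominator is
   *dominance-pruned*: it consumes the draw but not a beam slot.

$\mu$ is the probability of the *ranking* branch: at $\mu = 0$ selection is
purely greedy, and larger $\mu$ gives weaker candidates more chances. This
orientation is forced by the perturbation schedule below, which "increases
randomness" from 0 to 0.65 precisely to diversify the repair search.
With $\mu = 0$ and $k_b = k_w$ the algorithm is plain deterministic beam
search and its output is seed-independent.

Defaults are $k_w = 100$ and $k_b = 11$, the settings that a sensitivity
analysis of this algorithm family singles out as robust: solution quality
improves consistently with beam width until run time dominates, and a
moderate dominator count beats both none and one. Linear ranking uses the
fixed weights $N-r+1$ (no selective-pressure parameter), the simplest
standard form.

## Local search with beam search inside

Two operators shorten an existing supersequence $z$; both only ever accept
strict improvements, so they are non-worsening by construction.

**Reduction** (`pbs_reduction()`): for each split $z = w_p\,y_p$ the suffix
$y_p$ is fixed; each string contributes the prefix not covered by its
longest suffix embeddable in $y_p$ (`longest_embedded_suffix_split()`,
found by a right-to-left greedy scan); beam search re-solves this
sub-instance, and if the replacement prefix is strictly shorter than $p$
the solution is rewritten and the scan restarts from the first split.
Design choices: the scan runs ascending ($p = 1, 2, \dots$), restarts from
the beginning after any improvement, and *includes the trivial split with
the empty suffix* ($p = |z|$), i.e. a full re-solve counts as one more
split. The last choice is deliberate: without it the operator stalls one
symbol above the optimum on a noticeable fraction of small padded
instances, because no proper split can see the global rearrangement; with
it, reduction recovers optima from padded solutions essentially always at
desk scale, at the cost of one extra sub-solve per scan. Splits where some
uncovered prefix is already $\ge p$ long are skipped without consuming
randomness — no replacement could be shorter. The inner beam search runs
deterministically ($\mu = 0$) by default because the sub-instances number
in the hundreds per scan.

**Perturbation** (`pbs_perturbation()`): each round replaces one uniformly
chosen position of the incumbent by a different uniformly chosen symbol,
keeps the mutated prefix, and repairs feasibility by beam-search solving
the sub-instance of string remainders not embedded by that prefix; the
concatenation is accepted only if strictly shorter. The repair randomness
$\mu$ ramps linearly from 0 to 0.65 over the rounds
(`perturbation_schedule()`, default 100 rounds): early rounds stay close
to the incumbent, later rounds explore. Position and symbol are drawn
uniformly from the *current* incumbent, the minimal-assumption reading of
an "arbitrary" mutation.

## The multilevel anytime driver

`mpbs_solve()` runs several (default 5) seeded constructions, keeps the
shortest, then alternates reduction and perturbation until a wall-clock
budget runs out, recording every improvement in a trace
(`elapsed_sec, best_length, phase`). The incumbent never worsens, so the
driver can be interrupted at any time. The deadline is checked between
sub-instance solves — a running sub-solve finishes first — so overshoot is
bounded by one sub-instance.

Seeding is structured: phase $p$ of round $k$ uses a seed derived from the
base seed and $(k, p)$ alone. A round therefore behaves identically no
matter how many rounds fit in the budget, which makes runs reproducible in
everything except where the deadline truncates the loop; the optional
`max_rounds` cap makes a run fully deterministic end to end when the
budget does not bind. Two early exits are built in: a user-supplied
`target_length` (e.g. a known optimum or bound), and the universal lower
bound $\max_i |s_i|$, reaching which certifies optimality.

## Baselines and oracles

* `majority_merge()` appends the symbol at the most string fronts;
  `weighted_majority_merge()` scores each front by the remaining length of
  its string (the linear weight), shortening long strings first. Ties
  default to alphabet order; a seeded random tie-break is available. Note
  the two heuristics only coincide while all remaining lengths are equal —
  after the first step they legitimately diverge even on equal-length
  inputs.
* `alphabet_leftmost()` cycles a fixed alphabet permutation, skipping
  unproductive symbols.
* `exact_scs()` is a breadth-first shortest-path search over the product
  state space of embedded-prefix vectors (edges are alphabet symbols
  advancing at least one coordinate, tried in alphabet order for
  determinism). States are capped (`state_limit`, default $2\times 10^6$)
  because memory is the product of $(|s_i|+1)$. `lcs_length()` supports
  the two-string identity $|SCS(x,y)| = |x|+|y|-|LCS(x,y)|$ used to
  cross-check it.

## Synthetic instances and what they do (not) show

`generate_random_instance()` draws every string i.i.d. uniformly over the
alphabet. The default layout — eight strings, four of length 40 and four
of length 80, alphabet sizes 2–24 — mirrors the classical random benchmark
for this problem family. Uniform random strings are the hardest case for
front-counting greedy heuristics but lack the skewed symbol composition,
repeats and mutual similarity of real DNA/protein sets; results on them
demonstrate correctness and the qualitative algorithm ordering, not
performance on biological sequence collections, which can be loaded via
`read_fasta()` / `read_instance_text()` instead.

Degenerate inputs are handled explicitly: empty strings are dropped at
instance load with a warning; a one-symbol alphabet admits no perturbation
(the incumbent is returned unchanged, with a warning); an instance whose
strings are all embedded mid-extension terminates construction at that
child.

## Problem sizes used in the shipped experiments

The test-suite and the acceptance script work at desk scale, chosen so a
complete run stays comfortable on one CPU: 200 oracle-checked instances
with $m \le 4$, $|s_i| \le 8$, $q \le 4$; exhaustive-enumeration
cross-checks on the subset with total length $\le 10$; Monte-Carlo
validation of the probability table at 20\,000 trials per entry; and 20
benchmark-style instances ($q = 8$, $4\times40 + 4\times80$) for the
beam-width trend and the algorithm ordering, the latter with a 30 s budget
per multilevel run. The acceptance script repeats the comparison across
alphabet sizes 2–24 with a 20 s budget per instance.

## Known limitations

* The exact solver is memory-bound by the product state space; beyond
  `state_limit` it refuses rather than degrades.
* Reduction and perturbation solve many sub-instances; on very large
  inputs (hundreds of long strings) each improvement round is expensive
  and the anytime curve flattens slowly.
* The embedding-probability model assumes independent uniform strings; on
  highly similar inputs the heuristic underestimates sharing, and the beam
  relies more on dominance pruning.
* `dominates()` compares only at equal constructed length, which is all
  level-synchronous search needs; no cross-level pruning is attempted.
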