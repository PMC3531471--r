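# scsbeam

Beam-search heuristics for the **shortest common supersequence problem
(SCSP)**: given strings `s_1, ..., s_m` over an alphabet of size `q`, find
a minimum-length string `t` that embeds every `s_i` as a subsequence. The
problem is NP-hard even for binary alphabets. It shows up wherever ordered
tasks must share one schedule — most prominently in oligonucleotide
microarray manufacturing, where a common supersequence of the probes *is*
the sequence of synthesis cycles, and every saved cycle saves time, cost
and fabrication errors.

## What is inside

The package's core is a **probabilistic beam search (PBS)** used at three
levels, plus the classical machinery around it:

* Partial solutions are ranked by the probability that one random string
  of length `j` would embed all remaining string parts,
  `h(c) = prod_i P(r_i, j)`, where `P` solves the recurrence
  `P(i,j) = (1/q) P(i-1,j-1) + (1-1/q) P(i,j-1)` with `P(0,j) = 1`,
  `P(i,j) = 0` for `i > j`, and `r_i` is the unembedded remainder of
  string `i`. Ranking is done in log space.
* Beam selection mixes greedy choice with Baker linear-ranking sampling
  (randomness parameter `mu`), keeps the top `kb` children as
  *dominators*, and discards candidates whose per-string progress vector
  is componentwise dominated by a dominator.
* `pbs_reduction()` shortens an existing solution by re-solving, for every
  prefix/suffix split, the sub-instance of string prefixes not covered by
  the suffix; `pbs_perturbation()` mutates one symbol, repairs by PBS and
  accepts strict improvements, ramping `mu` from 0 to 0.65.
* `mpbs_solve()` is the anytime driver: several seeded constructions, then
  alternating reduction/perturbation under a wall-clock budget, with a
  trace of every improvement.
* Baselines and oracles: `majority_merge()`, `weighted_majority_merge()`,
  `alphabet_leftmost()`, exact `exact_scs()` (BFS over the product state
  space) and `lcs_length()`.
* Instance tooling: seeded uniform-random benchmark instances
  (`generate_random_instance()`), plain-text and FASTA input, trace CSV /
  solution / JSON result export, and a CLI
  (`system.file("cli", "scs.R", package = "scsbeam")`).

## Worked example

```r
library(scsbeam)

inst <- generate_random_instance(4, seed = 11)   # 8 strings, 4x40 + 4x80, q = 4
nchar(majority_merge(inst))                      # 170
nchar(pbs_solve(inst, pbs_config(kw = 100, kb = 100, mu = 0)))  # 173

res <- mpbs_solve(inst, mpbs_config(time_budget = 10, seed = 1))
res$length                                       # 150
res$trace
#>   elapsed_sec best_length        phase
#> 1       0.028         159 construction
#> 2       0.059         156 construction
#> 3       7.921         152    reduction
#> 4       9.251         150 perturbation
```

Majority Merge needs 170 symbols and plain deterministic beam search 173;
the multilevel driver starts from a 159-symbol construction and works down
to 150 within its 10 s budget — the trace shows which phase found each
improvement, and the incumbent never worsens (the anytime contract). Any
solution can be validated with `is_supersequence_of_all(res$solution, inst)`.

The same run from a shell:

```sh
Rscript $(Rscript -e 'cat(system.file("cli","scs.R",package="scsbeam"))') \
    solve --algo mpbs --input instance.txt --time 10 --seed 1 --trace trace.csv
```

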