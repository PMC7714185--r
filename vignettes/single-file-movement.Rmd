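---
title: "Recovering clustered social structure from single-file movement orders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering clustered social structure from single-file movement orders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(singlefile)
```

## The question and the model

Many animal groups — primates especially — are believed to be organized
into clusters: a few core individuals, each trailed by followers. When a
group crosses a road or a river it often strings out into single file,
and the passing order is one of the few social observables that can be
collected cheaply and without instrumenting the animals. This package
simulates that situation end to end to ask a concrete methodological
question: does the *order* alone, observed a realistic number of times,
suffice to recover the number of clusters?

The generative model is deliberately minimal.

**Spatial layer.** A group has `n_I` subgroups. Subgroup `i` has one
*independenter* placed as `x_i ~ N(0, σ_I² I₂)` and `n_D` *dependers*
placed as `N(x_i, σ_D² I₂)`. Both covariances are isotropic diagonal; no
correlation between axes is modelled, and all subgroups share one `n_D`
and one `σ_D`. Agent IDs are fixed: independenters are `1..n_I`, and
depender `j` of subgroup `i` is `n_I + (i−1)·n_D + j`, so dependers are
listed after the independenters, grouped by subgroup. `σ_D = 1` by
default: it is the distance unit, and only the ratio `σ_I/σ_D` matters
for how well the clusters separate.

**Movement layer.** A single-file movement is a permutation of the
agents built by the nearest-neighbour chain rule: the initiator is drawn
uniformly at random; afterwards the next mover is always the
Euclidean-nearest not-yet-moved agent to the *last* mover (not to any
earlier mover — the rule chains strictly on the previous agent). No
speeds, trajectories or waiting times are modelled; movement is reduced
to order.

**Network layer.** Each movement contributes a binary adjacency matrix
over consecutive pairs — the adjacency of a Hamiltonian path, so exactly
`N − 1` unit edges. Summing over `n_exp` movements gives the weighted
graph `G`, whose half-weight is always `M = (N−1) n_exp` (a conservation
law the tests assert on every simulated run). Importantly, every
movement redraws the agent coordinates: the latent memberships persist
while the realized spatial configuration is fresh each observation, as
it would be on different days in the field.

**Inference layer.** `G` is clustered by Louvain modularity
optimization at resolution 1, and recovery is scored as
`r = n_eval / n_I`. The score deliberately compares only the *count* of
communities, not the assignment: it is the coarsest — and most robust —
summary of structural recovery, and it is the quantity swept over the
parameter grid.

## Parameters that matter

| parameter | meaning | default / typical | units |
|---|---|---|---|
| `n_I` | subgroups (true cluster count) | 1–20 | count |
| `n_D` | dependers per subgroup | 1–20 | count |
| `σ_I` | independenter spread | 1–100 | distance (σ_D units) |
| `σ_D` | depender spread | 1 (fixed scale) | distance |
| `n_exp` | observed movements per run | 10 or 30 | count |
| `n_reps` | Monte-Carlo replicates | 1000 | count |

`n_exp` is chosen to be experimentally feasible — tens, not thousands,
of observed crossings. `n_reps = 1000` makes the Monte-Carlo error on a
mean score of order 0.01 or less, small against the 0.05 band within
which we call recovery "perfect".

## Why greedy modularity stops at the true clustering

Louvain merges clusters only while modularity rises. For a partition
with communities `p ≠ q`, merging them changes modularity by exactly

$$Q' - Q = \frac{m}{M} - \frac{K_p K_q}{2M^2},$$

with `m` the weight between the two communities and `K_p`, `K_q` their
total strengths (`merge_modularity_delta()`; the identity is verified
against direct differencing of the modularity definition to 1e−12 on
random graphs). The true clustering therefore resists every pairwise
merge whenever `m < K_p K_q / (2M)`.

In the separated regime `σ_I ≫ σ_D` subgroups appear as contiguous
blocks in every movement, so a movement assigns `n_D` within-block edges
to its first and last blocks and `n_D + 1` to interior ones, giving
`K_p, K_q ≤ n_D·n_exp` for terminal blocks — note the stated bound is
exact only for terminal blocks; interior blocks can exceed it by the
boundary edges, which is why `empirical_between_weight()` is checked
against the relaxed form. A sufficient merge-resistance condition is
then `m < (n_D n_exp)² / (2M)` (`sufficient_condition_bound()`).

For the expected between weight `m`, two normalizations are reported by
`expected_between_weight()` and never silently reconciled. Dividing the
total between-subgroup weight `(n_I − 1) n_exp` by the `n_I (n_I − 1)`
*ordered* subgroup pairs gives `n_exp / n_I` ("as-printed").
Exhaustive enumeration of all `n_I!` block orderings, counting how often
a given unordered pair is adjacent, gives `2 n_exp / n_I` — twice as
much, because an unordered pair is adjacent with probability `2/n_I`
(at `n_I = 2` the pair is adjacent in *every* movement, so the
expectation is `n_exp`, not `n_exp/2`). The qualitative conclusion is
unaffected: either value falls below the sufficient bound once `n_exp`
is moderately large, with the bound roughly `n_D/2` times the expected
`m`. Enumeration is exhaustive up to `n_I = 7` (5040 orderings); beyond
that the adjacency probability `2/n_I`, to which the enumeration
provably sums, is substituted directly.

## Numerical and design choices

- **Tie-breaking.** The nearest-neighbour argmin breaks ties by lowest
  agent ID. Ties have probability zero under the continuous spatial
  model, but replayed or hand-built coordinates can produce them, and
  file-replay tests require byte-determinism.
- **Degenerate inputs.** `N = 1` gives an edgeless graph on which
  modularity is undefined; `run_single_simulation()` refuses it rather
  than inventing a score (the evaluation grid starts at `n_D = 1`).
  `modularity_q()` and `louvain_communities()` raise the same error on
  any edgeless graph. Isolated nodes — possible only in re-ingested
  external data — become singleton communities.
- **Louvain implementation.** Delegated to `igraph::cluster_louvain()`
  at resolution 1; the package pins down the contract (weighted
  modularity, seeded determinism via R's RNG, canonical labels
  `1..n_eval` by first appearance) and verifies it against
  `best_partition_bruteforce()`, an exhaustive set-partition search
  used as an independent oracle on graphs of up to 10 nodes.
- **Seeding.** One seed governs a whole run (population draws,
  initiators, Louvain visit order). Replicate and sweep-cell seeds are
  pre-drawn from the master seed (`sample.int` under `set.seed`), so
  results are independent of execution order and would survive a
  parallel backend unchanged.
- **Integer weights.** Aggregate weights are counts on simple edges; no
  multigraph, no association indices other than adjacency-in-order.
  All on-disk IDs and positions are 1-based.

## What the generator does and does not emulate

The generator reproduces the study conditions: hierarchical Gaussian
placement, uniform initiators, strict nearest-neighbour chaining, fresh
coordinates per observation. Real single-file data differ in ways that
are out of scope here: per-subgroup variation in size and spread,
misidentified or unrecorded animals mid-file, initiators biased by
dominance, and movement dynamics beyond pure order. Passing tests
therefore show that the *inference chain* works under the stated
generative assumptions — not that field data satisfy those assumptions.
The score also only counts communities; a run could in principle score
`r = 1` with permuted memberships, though in the separated regime the
recovered partition is checked to equal the planted one.

## Problem sizes used in the checks

The packaged checks run the full study design where it is cheap (1000
replicates for the headline regime `n_I = 5, n_D = 10, σ_I = 10,
n_exp = 30`; 500 replicates per cell for the monotonicity contrasts)
and a reduced 4×4×2×2 grid (`n_I, n_D ∈ {2,5,10,20}×{1,5,10,20}`,
`σ_I ∈ {1,100}`, `n_exp ∈ {10,30}`, 100 replicates per cell) for the
score surface, whose full-resolution contours are stochastic and are
replaced by ordering properties: mean score increasing in `σ_I` and
`n_D`, decreasing in `n_I` away from the `n_I ∈ {1, 2}` edge, accuracy
`|r̄ − 1|` improving with `n_exp` (raw mean `r` is not monotone in
`n_exp`: the over-split cells at `σ_I = 1, n_exp = 10` collapse toward
1 with more observations), and near-perfect scores in the
`σ_I = 100, n_exp = 30` corner. The full 4000-cell
reference grid (`default_sweep_grid()`) remains available through
`sweep_scores()` and the `sfm sweep` subcommand.

## Known limitations

- `expected_between_weight()` treats block orderings as uniform; weak
  spatial correlations between consecutive movements are absent by
  construction (coordinates are redrawn), but within a movement the
  chain rule does not make all block orderings exactly equiprobable at
  moderate `σ_I`.
- The sufficient merge-resistance bound is one-sided: failing it says nothing
  about merging being favourable.
- At `n_I = 1` the "smaller `n_I` is better" ordering reverses (a
  single subgroup can only be over-split); the behaviour is reported
  but not asserted against.

```{r example, eval = FALSE}
p <- sfm_params(n_I = 5, n_D = 5, sigma_I = 10, n_exp = 10)
run <- run_single_simulation(p, seed = 1)
run$score

sw <- sweep_scores(n_I = c(2, 5, 10, 20), n_D = c(1, 5, 10, 20),
                   sigma_I = 100, n_exp = 10, n_reps = 100, seed = 1)
plot(sw)
```
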