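# singlefile

Field workers often cannot record the dyadic interactions (grooming,
aggression) or continuous GPS proximities that animal social network
analysis usually feeds on. What they *can* often record — at a road
crossing, a river ford, a camera trap — is the order in which a group
passes in single file. `singlefile` is an agent-based simulation toolkit
for asking whether that serial order alone carries enough information to
reconstruct the latent clustered structure of the group, and under which
conditions.

## The model

A group of `N = n_I (n_D + 1)` agents consists of `n_I` subgroups, each
with one **independenter** (core animal) and `n_D` **dependers**
(followers). Locations are drawn hierarchically in the plane:

- independenter *i*: `x_i ~ N(0, σ_I² I₂)`,
- depender *j* of subgroup *i*: `x_k ~ N(x_i, σ_D² I₂)` with
  `k = n_I + (i−1)·n_D + j` (σ_D = 1 by default).

A **single-file movement** is generated by a bottom-up rule: a uniformly
random initiator moves first, then repeatedly the Euclidean-nearest
not-yet-moved agent to the *last* mover moves next, yielding a
permutation `y_1 … y_N`. Each of `n_exp` observed movements (with fresh
coordinates each time) contributes a binary adjacency matrix marking
consecutive pairs; their entrywise sum is the weighted social graph `G`
with half-weight `M = (N−1) n_exp`. The graph is clustered with the
Louvain algorithm, which greedily maximizes the weighted Newman
modularity

```
Q = (1/2M) Σ_ij (a_ij − k_i k_j / 2M) δ(C(i), C(j)),
```

and recovery is scored as `r = n_eval / n_I`, the ratio of the number of
communities found to the true subgroup count (`r = 1` is perfect,
`r > 1` over-, `r < 1` under-estimation). Monte-Carlo sweeps average `r`
over replicates across a parameter grid. A companion set of analytic
checks quantifies why greedy modularity merging stops at the true
clustering: merging true subgroups `p, q` changes modularity by exactly
`Q′ − Q = m/M − K_p K_q / (2M²)`, and in the separated regime
(`σ_I ≫ σ_D`) the expected between-subgroup weight `m` sits well below
the sufficient bound `(n_D n_exp)² / (2M)`.

## Worked example

```r
library(singlefile)

p <- sfm_params(n_I = 5, n_D = 5, sigma_I = 10, sigma_D = 1, n_exp = 10)
run <- run_single_simulation(p, seed = 1)
run
#> Simulation run: n_I = 5, n_D = 5, sigma_I = 10, n_exp = 10 (seed 1)
#>   communities found: n_eval = 5; score r = 1

graph_half_weight(run$graph)
#> [1] 290                # M = (30 - 1) * 10

res <- average_score(sfm_params(5, 10, sigma_I = 10, n_exp = 30),
                     n_reps = 100, seed = 1)
res$mean_r
#> [1] 1                  # cluster count recovered in every replicate
```

Here the 30-agent group (5 subgroups of 6) was observed 10 times; the
aggregated movement graph carries total edge weight `2M = 580`, and
Louvain finds exactly the 5 planted subgroups, so `r = 1`. Averaged over
100 replicates at the stronger observation regime (`n_exp = 30`), the
mean score stays at 1: with that many observed crossings the subgroup
count is recovered essentially always.

The same pipeline is scriptable from a shell:

```sh
Rscript exec/sfm simulate --n-i 5 --n-d 5 --sigma-i 10 --n-exp 10 --seed 42 --out run1/
Rscript exec/sfm sweep --n-i 2,5,10 --n-d 1,5 --sigma-i 1,100 --n-exp 10 --reps 100 --seed 1 --out sweep.csv
Rscript exec/sfm theory-check --n-i 10 --n-d 5 --sigma-i 1000 --n-exp 30 --seed 1
```

`simulate` dumps the movements CSV, edge-list TSV, GraphML, partition
CSV, score CSV and a JSON manifest that reproduces the run bit-for-bit.

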