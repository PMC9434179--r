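# reversim

Forward-in-time Wright–Fisher simulation of what happens to a microbial
population *after* a costly adaptive mutation — think an antibiotic-resistance
mutation — has fixed and the selecting environment is removed.

Two escape routes then compete. The population can **revert**: a single
mutation at the original site restores the wild-type allele and removes the
whole cost *c*. Or it can **compensate**: any of *n* second-site mutations
removes a proportion *p* of the cost while keeping the resistance. Reversion
targets one site, compensation targets many, so compensation is much better
supplied with mutations — but every partially compensated genotype is less
fit than the true wild type. Which route wins is governed by the mutation
supply *Nμ* (expected new mutations per target per generation) and by the
quality of compensation: whether any of the compensatory targets are *fully*
compensating (*m* of the *n*, at wild-type fitness). The package is aimed at
evolutionary microbiologists and population geneticists who want to interpret
reversion/compensation outcomes from evolution experiments — e.g. why
mutator strains revert while non-mutators compensate — or to plan how many
populations and sequenced clones an experiment needs.

## The model in brief

A haploid population of fixed size *N* evolves in discrete generations from
an all-resistant start. Genotypes fall into *n* + 3 classes — `RES`,
`COM1..COMn`, `WT`, `CR` (compensated **and** reverted) — with relative
fitnesses

| class | fitness |
|---|---|
| `RES` | 1 − *c* |
| `COMi` (ordinary) | 1 − *c*(1 − *p*) |
| `COMi` (fully compensating, *i* ≤ *m*) | 1 |
| `WT`, `CR` | 1 |

Each generation, every mutational target fires at rate *μ* per cell (one
multinomial draw over the fates of the `RES` class; optional
`Com → CR` binomials; at most one mutational step per cell per generation),
and the next generation is a fitness-weighted multinomial resample of size
*N*. A class is called *present* at the end of a run if it holds at least 10
cells (0.1% of the default *N* = 10,000), the point at which an advantaged
lineage is established and expected to fix.

On top of the stochastic engine the package provides

* an analytic approximation for the race between reversion and compensatory
  fixation (`p_reversal_before_fixation()`), including the Kimura fixation
  probability and deterministic selection trajectories;
* an exact finite-state Markov-chain oracle for tiny instances
  (`exact_small_oracle()`), used to validate the engine;
* experiment-scale tooling: clone sampling without replacement
  (`sample_clones()`), replicate grids with derived per-replicate seeds
  (`experiment_grid()`, `run_grid()`), and drivers for the four canonical
  computational experiments (`run_reversion_race()`,
  `run_two_background_reversal()`, `run_clone_panels()`,
  `run_full_compensation()`);
* a thin command-line front end (`exec/reversim`) writing tidy CSV/JSON.

## Worked example

Simulate one population at intermediate-to-high mutation supply
(*Nμ* = 1) for 100 generations, classify the outcome, and "sequence" ten
clones:

```r
library(reversim)

p <- sim_params(N = 10000, G = 100, mu = 1e-4, c = 0.15, p = 0.5,
                n = 100, seed = 2026)
traj <- run_replicate(p)
traj
#> Wright-Fisher trajectory: 100 generations, N = 10000, 103 genotype classes
#> final state: COM1=1, COM2=32, COM5=12, ... COM99=37, WT=9457, CR=181

classify_outcome(traj, p)
#> outcome: soft_reversal (present: WT, CR, Com)

sample_clones(traj, p, replicate_id = 1)
#> clone sample (replicate 1): WT WT WT COM77 WT WT WT WT WT WT
```

The reversal mutation has arisen on two genetic backgrounds (directly from
`RES`, and on a compensated background as `CR`) — the soft-sweep signature of
high mutation supply. A sequenced sample is dominated by reverted clones with
some compensated clones still segregating.

Sweep the number *m* of fully compensating mutations at high supply
(*Nμ* = 10, 200 replicates per cell):

```r
fc <- run_full_compensation(m = c(0, 1, 3), Nmu = 10, replicates = 200,
                            master_seed = 1)
fc$summary[, c("Nmu", "m", "mean_reverted", "reverted_q025",
               "reverted_q975", "share_wt", "expected_share")]
#>   Nmu m mean_reverted reverted_q025 reverted_q975 share_wt expected_share
#> 1  10 0          9.48             7         10.00    0.939           1.00
#> 2  10 1          4.75             1          8.00    0.482           0.50
#> 3  10 3          2.56             0          5.03    0.244           0.25
```

`mean_reverted` is the average number of reverted clones in samples of 10,
with the 2.5–97.5 percentile interval across replicates; `share_wt` is the
mean final wild-type share. Even a single fully compensating mutation halves
reversion: the reversal lineage and the *m* equally fit, equally mutable
compensating lineages each expect the share 1/(*m* + 1), so with *m* = 3 a
10-clone sample is expected to hold 2.5 reverted clones.

From the shell, the same experiments:

```sh
exec/reversim race --mu 1e-7,1e-6,1e-5,1e-4,1e-3 --replicates 200 --out-dir out/
exec/reversim full-compensation --m 0,1,3,5,10 --Nmu 10 --out-dir out/
```

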