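---
title: "The reversion-compensation model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The reversion-compensation model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(reversim)
```

## The question

A haploid microbial population fixes a resistance (or other adaptive)
mutation, and then the selecting pressure is removed: the adaptation now
carries a fitness cost $c$. Two evolutionary escape routes compete. The
population can *revert* — a single mutation restores the wild-type allele and
removes the whole cost — or it can *compensate* — any of $n$ second-site
mutations removes a proportion $p$ of the cost while retaining resistance.
Reversion targets a single site, compensation targets many; compensation is
therefore far better supplied with mutations, but each compensated genotype
is less fit than the reverted wild type (unless the compensatory mutation is
one of $m$ *fully compensating* targets with wild-type fitness). Which route
wins, and when, is controlled almost entirely by the mutation supply
$N\mu$ — the expected number of new mutations per target per generation —
and by the quality of compensation.

`reversim` simulates this race forward in time and provides the matching
analytic approximation, outcome classification, experiment-scale clone
sampling, and replicate-grid drivers.

## The model

**Genotype classes.** The population is partitioned into $n + 3$ classes:
`RES` (resistant, uncompensated — the whole population at generation 0),
`COM1..COMn` (resistant plus one compensatory mutation; by convention
targets $1..m$ are the fully compensating ones — targets are exchangeable,
so any other assignment is isomorphic), `WT` (reverted wild type), and `CR`
(compensated reversal: a compensatory mutation followed by a reversal).
Genealogy beyond these labels is not tracked.

**Fitness.** Relative to the wild type: $w_{WT} = w_{CR} = 1$,
$w_{RES} = 1 - c$, $w_{COM_i} = 1 - c(1-p)$ for ordinary targets and $1$ for
fully compensating ones. The defaults $c = 0.15$, $p = 0.5$ give the triple
$0.85 / 0.925 / 1$. Entries are computed from the closed forms, never by
accumulation.

**Mutation.** Every mutational target (the reversal site and each of the $n$
compensatory sites) mutates at the same per-cell per-generation rate $\mu$.
A cell takes at most one mutational step per generation: the fates of all
`RES` cells are one multinomial draw over $n + 2$ destinations (stay, `WT`,
each `COMi`), and — when the second-mutation channel is enabled — each `COMi`
class loses a binomial number of its *start-of-generation* cells to `CR`.
`WT` and `CR` never mutate; compensated cells never change compensatory
target; nothing mutates back to `RES` (the environment no longer selects for
resistance, and regaining it is not modelled). Validation enforces
$(n+1)\mu \le 1$ so the per-cell probabilities are a distribution. Drawing
one multinomial per source class is mathematically identical to per-cell
Bernoulli draws (cells within a class are exchangeable) and exponentially
cheaper.

**Reproduction.** Non-overlapping Wright-Fisher generations: the next
generation is one multinomial draw of $N$ offspring with class probabilities
proportional to `counts * fitness`. Counts stay integers throughout; there is
no frequency-space shortcut, so drift variance is exact even for classes
hovering near the 10-cell presence threshold.

**Order of events.** Mutation first, then reproduction. The alternative
order differs by $O(\mu s)$ per generation at these parameter values and
does not move regime boundaries; the choice is fixed rather than exposed
because the exact oracle and every test would otherwise need a matching
switch for no scientific gain.

**Outcome classification.** A class (or the pooled compensated group) is
*present* when its final count is at least `presence_threshold` cells
(default 10, i.e. 0.1% of the default $N = 10{,}000$) — at that size an
advantaged lineage has escaped drift and is expected to fix. Five derived
labels cover the scenario space (`persistence`, `compensation`, `reversion`,
`soft_reversal`, `mixed`); the flags are the primitive truth and the label is
convenience. Simultaneous presence of `WT` and `CR` is the two-background
(soft) reversal signature.

**Clone sampling.** `sample_clones()` draws `sample_size` cells *without*
replacement (multivariate hypergeometric), emulating colony picking; with
$k = 10$ of $N = 10^4$ the difference from with-replacement sampling is
$O(k/N) = 10^{-3}$ and no alternative is offered.

## The analytic race approximation

For the race setting (second mutations off, $m = 0$),
`p_reversal_before_fixation()` approximates the probability that a reversal
establishes before compensation fixes:

1. The pooled compensatory class is treated deterministically as the
   infinite-population limit of the simulator's own dynamics: starting from
   frequency 0 it receives inflow $n \mu x_{RES}(t)$ per generation and is
   advanced by the selection recursion with fitnesses $1 - c(1-p)$ vs
   $1 - c$. The inflow term matters: compensatory mutations keep arising
   every generation, and a one-off seed at generation 0 makes the
   compensatory sweep far too slow (we measured the resulting race
   probability 0.27 too high at $N\mu = 0.1$).
2. Compensation counts as fixed at the first generation $t_{fix}$ where the
   resistant frequency falls below `presence_threshold / N` — the same rule
   the simulator applies, since deterministic dynamics never literally reach
   absorption.
3. While $t < t_{fix}$, the hazard of a successful reversal is
   $h_t = N x_{RES}(t) \mu \, P_{fix}(s_t, N)$ with $s_t = 1/\bar w_t - 1$,
   the advantage of the wild type over the mean fitness in the generation
   the mutation arises. $P_{fix}$ is Kimura's diffusion form
   $(1 - e^{-2s})/(1 - e^{-2Ns})$, continuous at $s = 0$ with value $1/N$;
   at these parameters it differs from the $2s$ branching rule by under 10%
   and is better behaved at small $s$ and small $N$.
4. $p = 1 - \exp(-\sum_t h_t)$.

The approximation assumes the reversal is the only mutation whose fate is in
doubt and that its fate is set in its generation of origin. Both assumptions
fail upward at high supply, where many lineages sweep at once and mean
fitness rises faster than the deterministic compensatory trajectory implies —
so the curve is expected to sit *above* the simulated points at
$N\mu \ge 1$ and within a few percentage points of them below. On the
default grid (200 replicates per cell) we measure analytic
$\{0.03, 0.20, 0.76, 1.0, 1.0\}$ against simulated
$\{0.04, 0.23, 0.68, 1.0, 1.0\}$ for $N\mu \in \{0.001, \dots, 10\}$.
Time-inhomogeneous interference corrections would close the remaining gap
but are deliberately out of scope: the approximation's value is its
transparency.

The illustrative pre-fixation rise of the resistant allele (the phase before
generation 0 of the simulations) is available through
`deterministic_sweep()`; the selective benefit during that phase is
presentation-only and defaults to mirroring the cost ($s = 0.15$ against the
susceptible resident, from frequency $1/N$).

## Fully compensating mutations and the 1/(m+1) partition

With $m$ fully compensating targets and high supply, the reversal and the
$m$ fully compensating lineages are exchangeable: same fitness 1, same rate
$\mu$, so each expects the long-run share $1/(m+1)$
(`expected_reversal_share()`). With $m = 3$, a 10-clone sample is expected
to contain 2.5 reverted clones.

This clean partition holds only while compensated genotypes cannot
themselves revert. We measured the alternative directly (200 replicates,
$N\mu = 10$, $G = 100$): with the `Com -> CR` channel enabled, `CR` lineages
— also at wild-type fitness — establish from the first generations' large
pool of partially compensated cells and take roughly 30–55% of the final
population, pushing the wild-type-only share to about 0.20 at $m = 3$
(mean 1.9 reverted clones of 10) and the combined reversal-allele share to
about 0.48; the fully compensated class at $m = 1$ reaches only about 0.28.
None of these reproduce the $1/(m+1)$ expectations. `run_full_compensation()`
therefore disables the channel by default and exposes
`allow_second_mutation` (and `count_cr_as_reverted`, for deciding whether a
sampled `CR` clone counts as "reverted") for the enabled variant.

## The exact oracle

`exact_small_oracle()` computes the exact distribution over population
states at generation $G$ by composing the mutation kernel and the
multinomial reproduction kernel as dense matrices over all compositions of
$N$ into $n + 3$ parts, then powering from the all-`RES` start. It is the
independent correctness reference for the stochastic engine: on a
$N = 10$, $n = 1$, $\mu = 0.01$, $G = 20$ instance (286 states) the engine's
Monte-Carlo $P(\text{WT count} \ge 1)$ over 50,000 replicates must sit
within three standard errors of the exact value. The default cap of 5,000
states keeps the dense matrices small; the oracle refuses anything larger.

## Randomness and reproducibility

Each replicate runs under its own seed. Grid drivers derive all per-replicate
seeds up front from the master seed (one seeded `sample.int()` call), so a
grid is reproducible as a whole, independent of execution order, and
insensitive to how many cells precede a given replicate. `run_replicate()`
restores the caller's RNG state. Reproducibility is bit-level for a fixed
package and R version; across R versions only distributional equivalence is
promised.

## Default study conditions and problem sizes

The canonical conditions are $N = 10{,}000$; $G = 500$ for the race
experiment and $G = 100$ elsewhere; $\mu \in [10^{-7}, 10^{-3}]$ giving
$N\mu \in [0.001, 10]$; $c = 0.15$ (0.05 and 0.3 are supported variants
that rescale the time axis without changing outcomes); $p = 0.5$; $n = 100$;
$m \in \{0, 1, 3, 5, 10\}$; presence threshold 10 cells; 10-clone samples;
10 populations per experiment-scale panel. Requested supplies whose implied
$\mu$ would exceed $10^{-3}$ (e.g. $N\mu = 100$ at $n = 100$, which would
violate $(n+1)\mu \le 1$) are realized by enlarging $N$ at fixed supply
(`params_for_supply()`), treating the supply — not the rate — as the
controlling composite.

Grid drivers default to 200 replicates per cell, which resolves outcome
probabilities to a standard error of at most ~0.035 and keeps a full
five-supply race grid under ten seconds on one core; the original
experiments' 1,000 replicates per cell are one flag away
(`replicates = 1000`).

```{r example}
race <- run_reversion_race(mu = 10^seq(-7, -3), replicates = 50,
                           master_seed = 1)
race$summary[, c("Nmu", "p_wt", "se_wt", "p_wt_analytic")]
```

## What the simulations do and do not emulate

The generator reproduces the population-genetic skeleton of a serial-passage
or long-term culture experiment: drift at census size, a single environment
switch, point mutations at a uniform rate, and a three-tier fitness
landscape. It deliberately omits horizontal gene transfer and plasmid
conjugation, sign epistasis and rugged landscapes, multi-step resistance,
demographic structure or bottlenecks, and mutation-rate evolution (a mutator
strain is represented only through a larger $\mu$). Consequently, passing
tests show the engine is a correct Wright-Fisher implementation of this
model — not that real populations, with their more complex demography and
epistasis, will match the simulated regime boundaries quantitatively.

## Numerical and degenerate-input choices

* $\mu = 0$ is legal and yields exact stasis; monomorphic states are exact
  fixed points of reproduction.
* `fixation_probability()` switches to the neutral limit $1/N$ only within
  $|s| < 10^{-12}$; for strongly deleterious $s$ the expression underflows
  cleanly to 0.
* The deterministic sweep saturates at 1 in double precision after roughly
  $\ln(10^{16} N)/\ln(w_i/w_r)$ generations; tests that assert strict
  monotonicity stay short of that horizon.
* Ties in outcome labelling cannot occur: the label decision tree is
  evaluated on boolean flags in a fixed order (`soft_reversal` before
  `reversion` before `compensation`).
* Percentile intervals use the default type-7 sample quantile; a constant
  statistic collapses to a point interval.

## Known limitations

The analytic module covers only the $m = 0$ race; there is no closed-form
treatment of the $m \ge 1$ partition beyond the exchangeability argument.
The oracle is exponential in $N$ and $n$ and is a test instrument, not a
user-facing solver. Outcome labels summarize a single final state; a
replicate that would resolve differently a few generations later (e.g. `WT`
at 9 cells) is classified by the letter of the threshold rule.
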