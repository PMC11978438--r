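---
title: "Cumulative cultural evolution with algorithmic mediation: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cumulative cultural evolution with algorithmic mediation: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ccesim)
```

## The model

`ccesim` simulates how a population accumulates increasingly complex
culture when individuals can innovate on their own, copy successful
peers over a social network, and receive recommendations from a global
algorithm that knows every trait ever innovated.

### Cultural space

Cultural traits live on a grid of `X` parallel *branches* by an
unbounded ladder of *complexity levels*. Traits are functionally
dependent: an agent can only acquire a level-`l` trait if it already
holds some trait at level `l - 1` (on any branch — the dependency is on
depth of know-how, not on staying within one branch, so mixed-branch
repertoires are legal). Each `(branch, level)` pair carries an integer
payoff `z`, fixed for the whole world: it is drawn once, on first touch,
and every agent that ever acquires that trait receives the same payoff.
Payoffs are produced by drawing an exponential variate, squaring,
doubling, and rounding half-up:

  z = round(2 d^2),   d ~ Exp(rate)

Squaring a thin-tailed draw makes high-quality innovations rare among a
mass of worthless attempts. The exponential rate is a tunable parameter;
the default `2 log 2 ≈ 1.386` is calibrated so that `P(z = 0) = 1/2`
exactly — half of all conceivable traits are *unviable* and can never be
acquired — while payoffs of 50 or more remain roughly a one-in-a-thousand
event (`P(z >= 50) = exp(-rate * sqrt(24.75)) ≈ 1.0e-3`). These two
closed forms are asserted in the test suite by Monte-Carlo. Rounding is
half-up (`floor(x + 0.5)`) rather than R's banker's rounding; the choice
is immaterial in probability but fixed for reproducibility.

The level axis is represented lazily (a memoized map keyed by
`(branch, level)`), so no level cap is ever imposed. Because payoffs are
world-level constants, an unviable pair stays unviable forever, and the
count of distinct traits is well defined.

### Agents and the per-step cycle

`N` agents occupy fixed positions on a static undirected network. Each
agent holds a finite effort budget `B` (default 1000), a contiguous
repertoire with exactly one trait per level up to its `max_level`, and a
cumulative payoff `Z_i` — the sum of its repertoire's payoffs. Initially
all agents are naive (empty repertoire).

Every time step, each agent executes one cycle:

1. **Death–birth.** With probability `q = 1/N` the agent is replaced by
   a naive newborn in the same network position with a fresh budget `B`
   (on average one replacement per step). The newborn proceeds with the
   rest of the cycle in its birth step.
2. **Learning.** With probability `r` (the *mediation ratio*) the step
   is dispatched to algorithmic mediation, otherwise to social learning.
   - *Social learning*: the agent selects the neighbour with the highest
     cumulative payoff (ties uniform at random; two alternative
     strategies, highest-level and random-neighbour, are available). If
     the teacher owns a trait at the learner's next level
     (`max_level + 1`) and the budget covers `Cs` (default 5), that
     exact trait is copied and `Cs` is charged. Failed attempts are
     free.
   - *Algorithmic mediation*: a "perfect" recommender with full
     knowledge of every trait innovated so far (the *archive*) proposes
     the highest-payoff archived trait at exactly the learner's next
     level; the agent acquires it for `Cr` (default 1). If the archive
     has nothing at that level, or the budget is short, no cost is
     charged.
3. **Innovation.** Only if learning did not succeed: the agent draws a
   uniformly random branch and attempts level `max_level + 1`. The cost
   `Ci` (default 10) is charged on *every* funded attempt; the trait is
   acquired only if viable (`z > 0`), in which case it also enters the
   archive. Unviable draws end the step empty-handed. An agent whose
   budget is below every applicable cost simply idles until replaced.

The cost ordering `Cr < Cs < Ci` (recommendations cheaper than copying,
copying cheaper than inventing) is enforced by `sim_config()`.

Within a step, agents act in a fresh uniformly random order with
*sequential* state updates: an agent acting late in the step sees
changes made earlier in the same step. The alternative — synchronous
updates against the start-of-step state — would introduce simultaneous-
copy artefacts; the sequential schedule also keeps the death–birth
bookkeeping exact. One observable consequence, exercised in the tests:
on the very first step a late-acting agent may already copy a trait that
an earlier-acting neighbour just innovated.

### Measures

After every step the package records the population's

* **performance** `Z(t)`: mean cumulative payoff,
* **complexity** `L(t)`: mean highest level,
* **diversity** `T(t)`: number of distinct traits innovated so far
  (the archive size; monotone by construction).

Because budgets are finite and replacement is slow, all three settle
into a quasi-stationary regime (the tests verify that per-realization
slopes of `Z(t)` over the final window are statistically
indistinguishable from zero). Summaries (`stationary_summary()`,
`run_sweep()`) therefore average each series over the final `window`
steps of each realization (default 200 steps of a `20 N`-step horizon)
and then across realizations, reporting between-realization standard
errors. `T` is summarized by the same window mean as the other measures;
it is nearly flat in the stationary regime, so this coincides with its
maximum.

## Networks

`build_network()` wraps igraph generators behind a small contract
(simple, undirected, stable node identities):

* `complete` — every pair connected,
* `erdos_renyi` — G(n, p) with `p = k/(n-1)` so the expected mean
  degree is exactly the target `k`; isolated nodes are *kept* (no
  reconnection), because reconnecting would bias the sparse limit
  `k -> 0` where the innovation-heavy regime lives,
* `small_world` — Watts–Strogatz with `k/2` lattice neighbours per side
  and rewiring probability 0.1 by default (both configurable; the graph
  is simplified, which can shave a few edges off the target),
* `scale_free` — Barabási–Albert with `m = round(k/2)`,
* `user_supplied` — plain-text edge lists, two 0-based integer columns.

Node ids are 1-based in the R API; the file format stays 0-based.

## Randomness and reproducibility

A single master seed drives everything. It spawns one derived seed for
network generation and one for the dynamics (derivation is a small
Lehmer-step mixer, exact in double arithmetic and always below 2^31),
so the same topology can be re-paired with different dynamic
realizations. Inside a run, payoff first-touch draws share the dynamics
stream; a standalone `payoff_table()` additionally carries its own
private stream so that interactive exploration never perturbs a
caller's RNG state. In `run_sweep()` per-realization seeds are derived
from `(master seed, grid row, realization index)`, making sweep tables
identical regardless of execution order. Identical seeds give
bit-identical trajectories.

All tie-breaks (teacher selection, recommendation) are uniform at
random and drawn from the seeded streams.

## Two engines

The per-agent cycle is implemented twice, deliberately:

* a **pure-R reference engine** composed of the exported operation
  functions (`death_birth()`, `select_neighbour()`, `social_learn()`,
  `algorithmic_learn()`, `innovate()`, `agent_step()`, `time_step()`),
  convenient to audit step by step, and
* a **compiled engine** (Rcpp) that runs the whole horizon in one call
  and is the default: at the reference problem size (N = 100, horizon
  2000, hundreds of realizations per sweep) the interpreted loop is
  orders of magnitude too slow for interactive use.

Both use R's RNG. They are cross-checked statistically in the test
suite (30 realizations per engine on a common grid point; means within
four pooled standard errors), and the compiled engine returns per-agent
action counters so that the exact budget ledger

  B - budget_i = Cs * (social successes) + Cr * (recommendations) + Ci * (innovation attempts)

is asserted at every step of audited runs, alongside repertoire
contiguity, exact recomputation of `Z_i`, world-consistency of
repertoire payoffs against the payoff map, and archive monotonicity.

## Reference parameter set and problem sizes

Defaults are frozen to the reference conditions: `N = 100`, `B = 1000`,
`Ci = 10`, `Cs = 5`, `Cr = 1`, `X = 100`, `q = 1/N`, horizon `20 N`,
stationary window 200, 200 realizations for production sweeps. The test
suite and the acceptance script run the same conditions with 20–40
realizations per grid point, which keeps Monte-Carlo standard errors
small relative to the effects they check (the reported standard errors
make this auditable) while keeping the default check runs in the
minutes range.

Behavioural checks the suite performs at these conditions:

* the mean payoff of complete-graph populations grows ~ logarithmically
  with N (correlation with `log N` above 0.95 across N = 50–400);
* trait diversity falls monotonically as random networks densify
  (k = 2, 8, 32);
* mean complexity rises monotonically with the mediation ratio `r`,
  while mean payoff peaks at an *interior* `r` — neither pure social
  learning (`r = 0`) nor pure mediation (`r = 1`) is ever optimal;
* on very sparse networks (k = 1) the optimal mediation ratio lands
  near `r ≈ 0.7`;
* a lone immortal innovator (`N = 1`, `q = 0`, huge X) reaches a mean
  final level of `(B/Ci) * P(z > 0) = 50`, the closed-form sanity
  anchor.

## What the generator does and does not emulate

The simulation is a stylized world: static simple networks, a uniform
branch choice at innovation, costs independent of level and payoff, a
perfect, static, unbiased recommender, and no trait loss, recombination
or algorithmic innovation. Passing tests demonstrate the internal
consistency of this mechanism and its qualitative regimes
(exploration–exploitation trade-offs in both `k` and `r`); they say
nothing about fitted real-world platforms, co-evolving recommender
behaviour, or populations whose networks rewire.

## Numerical and degenerate-input choices

* Rounding of payoffs is half-up; the boundary has probability zero.
* `horizon = 0` is rejected (there is no series to summarize);
  summaries error on series shorter than the window rather than
  silently shrinking it.
* Agents with empty neighbourhoods skip teacher selection (consuming no
  randomness) and fall through to innovation.
* In `algorithmic_learn()` the archive-empty check precedes the budget
  check, and both precede any tie-break draw, so failed attempts
  consume no randomness.
* Budgets are stored as doubles; with integer costs all ledger
  identities are exact, and the tests assert exact equality.

## A worked example

```{r example, eval = FALSE}
library(ccesim)

base <- sim_config(n = 100, k = 1)
tab <- run_sweep(data.frame(r = seq(0, 1, by = 0.1)), base,
                 realizations = 40, seed = 1)
tab[, c("r", "Z_max", "se_Z", "L_max", "T_max")]
tab$r[which.max(tab$Z_max)]   # ~0.7: mixing beats either pure regime
```

The same sweep is what `scripts/acceptance.R` re-runs end to end.
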