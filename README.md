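# ccesim

Agent-based simulation of **cumulative cultural evolution** on social
networks, with **algorithmic mediation** of information.

## The problem

Human culture accumulates: tools, methods and theories are built on top
of earlier ones, faster than any individual could manage alone, because
people copy each other as well as invent. Increasingly, a third channel
sits between people: recommender systems, search engines and language
models that aggregate what everyone knows and redistribute it globally.
`ccesim` is for researchers in cultural evolution and computational
social science who want to study, in a controlled mechanistic model, how
this algorithmic channel interacts with network-based social learning —
when it helps a population accumulate valuable culture, and when it
hurts.

## The model in brief

`N` budget-limited agents live on a static undirected network. Cultural
traits occupy `X` branches × unbounded complexity levels; a level-`l`
trait requires owning some level-`l−1` trait, and each `(branch, level)`
pair carries a world-level integer payoff

    z = round(2 d²),  d ~ Exp(λ),  λ = 2 ln 2,

so half of all traits are unviable (`z = 0`) and payoffs near 50 are
roughly one-in-a-thousand events. Each time step every agent, in random
order:

1. dies and is replaced by a naive newborn with probability `q = 1/N`;
2. learns — with probability `r` from a perfect global archive of all
   innovated traits (the algorithm recommends the highest-payoff trait
   at the agent's next level, cost `Cr`), otherwise from its
   highest-payoff neighbour (cost `Cs`);
3. innovates on a random branch if learning failed (cost `Ci` on every
   attempt, success only if the trait is viable).

Costs satisfy `Cr < Cs < Ci` and drain a finite budget `B`, so the
population settles into a quasi-stationary state summarized by the mean
payoff `Z̄`, mean complexity `L̄` and trait diversity `T̄` over the last
200 steps, averaged across realizations.

## Worked example

Sweep the mediation ratio `r` on a very sparse random network (mean
degree `k = 1`):

```r
library(ccesim)

base <- sim_config(n = 100, k = 1)
tab <- run_sweep(data.frame(r = seq(0, 1, by = 0.1)), base,
                 realizations = 40, seed = 1)
tab[, c("r", "Z_max", "se_Z", "L_max", "T_max")]
#>      r     Z_max      se_Z    L_max     T_max
#> 1  0.0  229.7455  3.501917 52.04839 6356.7130
#> 2  0.1  805.2818 15.974962 55.11700 6588.0463
#> 3  0.2 1112.6736 16.898449 60.22740 7021.6647
#> 4  0.3 1342.2157 16.656844 64.10678 7412.0921
#> 5  0.4 1592.0035 22.597058 70.44282 7882.3522
#> 6  0.5 1761.5506 20.944272 75.55224 8231.4591
#> 7  0.6 1968.0252 23.208747 80.32562 8586.2061
#> 8  0.7 2117.8844 25.350727 86.86428 8521.3074
#> 9  0.8 2081.7183 25.106516 90.64688 7526.3900
#> 10 0.9 1896.9792 21.379771 97.01846 4988.3930
#> 11 1.0  386.3989  7.193220 97.72883  568.5071

tab$r[which.max(tab$Z_max)]
#> [1] 0.7
```

Reading the numbers: complexity `L_max` rises monotonically with `r`
(recommendations always push agents up the trait ladder), but
performance `Z_max` peaks at an *interior* mediation ratio — here
`r = 0.7` — because pure social learning (`r = 0`, `Z_max ≈ 230`)
leaves sparse populations starved of information, while pure mediation
(`r = 1`, `Z_max ≈ 386`) collapses diversity (`T_max` drops from
thousands to hundreds as everyone copies the same recommended traits)
and with it the supply of high-payoff innovations. Standard errors are
between-realization.

Single runs return per-step series:

```r
sim <- run_simulation(sim_config(n = 100, k = 1, r = 0.7, seed = 7))
stationary_summary(sim)
#>      Z_max    L_max   T_max se_Z se_L se_T realizations window
#> 1 2277.055 86.02365 8712.71   NA   NA   NA            1    200
```

A thin command-line wrapper is installed as `exec/ccesim`
(subcommands `run`, `sweep`, `show-config`; YAML configs mirroring
`sim_config()` arguments).

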