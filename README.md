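# collrep — collective reputations and indirect reciprocity in public goods games

`collrep` is an agent-based simulator for studying how cooperation evolves
when reputations are judged at the *group* level.  In a public goods game,
a donor faces not one recipient but a whole group with mixed reputations.
The package models observers who compress that group into a single binary
**collective reputation**: observer *i* deems group *G′* good iff the
fraction of members *i* privately considers good reaches an assessment
criterion λ,

    r_i(G') = 1  iff  Σ_{j∈G'} M_ij ≥ λ·|G'| ,

where *M* is the private image matrix.  On top of this sit the
**leading-eight social norms** (L1–L8, including Simple Standing, Stern
Judging, Staying and Judging) plus unconditional cooperation (ALLC) and
defection (ALLD), a public goods game with payoffs
π_C = R·c·n_C/k − c and π_D = R·c·n_C/k (synergy R = αk), private noisy
observation (observation probability q, perception error ε), and an
evolutionary layer: Fermi imitation P = 1/(1+exp(−s(π_j−π_i))), closed-form
fixation probabilities of the imitation birth–death chain, and the
rare-mutation embedded Markov chain whose stationary distribution gives the
selection–mutation equilibrium and its cooperation rate.  The critical
payoff parameter α_c = (N−1)/(N−k) separates the unconditional phases.

Who it is for: researchers in evolutionary game theory and social evolution
who want a fast, tested, reproducible engine for collective-reputation
indirect reciprocity — phase diagrams over (α, λ), fixation tables, and
criterion-evolution experiments — without writing a simulator from scratch.

## A worked example

Reputation dynamics in a population split equally among Simple Standing
(L3), ALLC and ALLD at a strict criterion (λ = 0.9):

```r
library(collrep)
players <- make_players(c(rep("L3", 20), rep("ALLC", 20), rep("ALLD", 20)),
                        lambda = 0.9)
params <- sim_params(N = 60, k = 10, alpha = 1, q = 0.9, eps = 0.05,
                     steps = 22000, burn_in = 0.1, seed = 1)
simulate_reputation_dynamics(players, params)
#> <rep_stats> 19800 accumulated rounds
#>     label size coop_freq  mean_nc mean_payoff
#>    L3|0.9   20 0.2554499 4.043751    3.788301
#>  ALLC|0.9   20 1.0000000 4.773283    3.773283
#>  ALLD|0.9   20 0.0000000 3.764508    3.764508
#> good-opinion proportions (observer rows):
#>           target
#> observer   L3|0.9 ALLC|0.9 ALLD|0.9
#>   L3|0.9    0.826    0.987    0.747
#>   ALLC|0.9  1.000    1.000    1.000
#>   ALLD|0.9  0.000    0.000    0.000
```

Read the last column of the first row block: L3 players assign good
reputations to **74.7%** of the unconditional defectors.  In a strict
society almost every recipient group looks bad, defection against a
bad-looking group is justified under Simple Standing, so free riders are
whitewashed — the norm can no longer tell them apart from justified
defectors.  The cooperation frequencies show the consequence: L3 players
cooperate in only 26% of their games while ALLD free-rides at equal payoff.

The evolutionary layer turns such sweeps into equilibria:

```r
cfg <- scenario_config("phase_grid", strategy = "L1", seed = 5)
grid <- run_phase_grid(cfg)          # (alpha, lambda) -> equilibrium
find_lambda_c(grid)$lambda_c         # criterion most conducive to cooperation
#> [1] 0.7
```

`critical_alpha(60, 10)` returns `1.18`: above it unconditional cooperation
is favoured; below it, only the leading-eight norms can carry cooperation,
and only at moderate strictness.

A thin CLI wraps the same functions
(`Rscript inst/cli/collrep.R phase-grid --strategy L1 --seed 5 --out out/`),
with subcommands `reputation`, `phase-grid`, `criterion-evolution`,
`fixation` and `fixture`.

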