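---
title: "Collective reputations in public goods games: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Collective reputations in public goods games: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(collrep)
```

## The question

Indirect reciprocity explains cooperation through reputations: people help
those with good standing and norms decide how standing changes.  The classic
setting is dyadic — one donor, one recipient — where the eight "leading"
third-order norms (L1–L8) are known to stabilize cooperation.  Real
interactions, however, are often collective: a player faces a *group* of
recipients with mixed reputations and must still make one binary choice.
`collrep` models this situation.  Donors and observers compress a recipient
group into a single binary *collective reputation*: observer $i$ deems group
$G'$ good iff the fraction of members $i$ privately considers good reaches an
assessment criterion $\lambda$,

$$ r^i_{G'} = \mathbf{1}\!\left[\textstyle\sum_{j \in G'} M_{ij}(t) \ge \lambda\,|G'|\right], $$

where $M(t)$ is the private image matrix ($M_{ij} = 1$ iff $i$ currently
considers $j$ good).  $\lambda$ is a strictness dial: a society with small
$\lambda$ is forgiving about bad apples inside a group, a society with
$\lambda$ near 1 demands near-unanimous goodness.  The package asks how this
dial interacts with the economics of the public goods game and with the
leading-eight norms' known abilities to sustain cooperation.

## The game and the reputation dynamics

Each round, $k$ of the $N$ players are drawn uniformly without replacement.
Every member decides whether to contribute a cost $c$ to a common pool that
is multiplied by a synergy factor $R$ and split equally, so with $n_C$
contributors

$$ \pi_C = \frac{R\,c\,n_C}{k} - c, \qquad \pi_D = \frac{R\,c\,n_C}{k}, $$

and defectors always earn exactly $c$ more than cooperators in the same
group.  We usually scale the synergy with group size, $R(k) = \alpha k$; the
payoff parameter $\alpha$ is then the natural axis of the social dilemma.

Although the game is symmetric, reputations are updated as if each member
in turn were the donor facing the other $k-1$ members as a recipient group.
A donor acts on its *own* information: its self-image $M_{ii}$ and the
collective reputation (at its own $\lambda$) of the other members.  Every
observer $h$ then re-assesses every donor through its norm's assessment rule
$d(r_a, r_p, b)$, where $r_a = M_{hi}(t)$ is $h$'s prior opinion of the
donor, $r_p$ is the collective reputation of the recipients *in $h$'s eyes*,
and $b$ is the action $h$ perceived.  Because assessments are private and
noisy, two observers can legitimately disagree about the same act — the
worked example in `make_fixture("worked-example")` shows a donor who
sees 3 of its 4 recipients as good (a good group at $\lambda = 0.7$) while
an outside observer counts only 2 (a bad group), so the observer may punish
a cooperation the donor considered obviously right.

The information model: group members always learn each other's actions;
outsiders observe a round with probability $q$ (one draw per observer per
round — the round is seen whole or not at all); each observed action other
than one's own is misperceived independently with probability $\epsilon$.
Updating is synchronous — all assessments of a round read the pre-round
matrix.  ALLC players always consider everyone good and always cooperate;
ALLD players are their mirror image; their opinion rows are therefore pinned
constants rather than simulated.

Design points that the model statement leaves open, and how we resolved
them:

* **Initial matrix** — all-good (benign start), configurable.  All reported
  statistics discard a burn-in prefix, so the initialization only matters
  through equilibration speed.
* **Perception error scope** — the default applies $\epsilon$ uniformly to
  *every* observer, including a donor interpreting its own action
  (`eps_scope = "all"`); `"no-self"` and `"out-group"` restrict it.  The
  uniform reading is the most literal one (each player's action "might be
  mistakenly interpreted by an observer", with no self-exemption), and it is
  the only scope with a qualitative consequence: under the stricter scopes a
  leading-eight donor's self-image, once good, can never turn bad (helping a
  good-looking group and justified defection both preserve it), so the
  channel by which norms that reward cooperation between bad parties
  (L1, L2) re-seed cooperation in strict societies is structurally closed.
  All three scopes reproduce the framework's quantitative benchmarks (the
  whitewashing levels of strict societies, the criterion-fixation bounds);
  we verified the choice against those benchmarks rather than deciding it
  on taste.
* **Self-image** — a donor uses $M_{ii}$ as its $r_a$ when acting and
  re-assesses itself each round it plays (subject to `eps_scope`); private
  assessment requires a self-view and nothing in the model exempts the
  donor.
* **Threshold arithmetic** — the comparison $\sum M_{ij} \ge \lambda |G'|$
  is evaluated exactly, no rounding of $\lambda |G'|$; the boundary is
  inclusive, and for $|G'| = 1$ the collective reputation reduces to the
  single opinion entry for every $\lambda \in (0,1]$, recovering the dyadic
  game.

## The evolutionary layer

Strategies evolve on a slower timescale by imitation: a random player either
mutates (rate $\mu$) or copies a random role model $j$ with the Fermi
probability $P = \{1 + e^{-s(\pi_j - \pi_i)}\}^{-1}$ ($s$ = selection
strength).  In the rare-mutation limit the population is almost always
homogeneous and the dynamics reduce to an embedded Markov chain over
homogeneous states whose transitions are single-mutant fixation
probabilities.  For the imitation birth–death chain these have the standard
closed form

$$ \rho = \left[ 1 + \sum_{m=1}^{N-1} \prod_{l=1}^{m}
   e^{-s\,(\pi_{\mathrm{mut}}(l) - \pi_{\mathrm{res}}(l))} \right]^{-1}, $$

evaluated in log space so strong selection cannot overflow.  The
composition-dependent expected payoffs $\pi(\cdot)$ come from simulating the
reputation dynamics at every mixed composition $m = 1..N-1$.  A neutral
mutant fixes with probability exactly $1/N$; `fixation_probability()` is
validated against that identity, against the $N = 2$ and constant-difference
closed forms, and against direct stochastic simulation of the imitation
chain (`agent_based_evolution()`).

Two structural shortcuts keep this honest but fast:

* **Payoffs are per-game and $\alpha$-free sweeps.**  Expected payoffs are
  conditional on participation; the participation probability $k/N$ is the
  same for everyone, so conditioning only rescales the effective selection
  strength.  More importantly, while strategies are frozen the *behaviour*
  of a composition (each class's cooperation frequency and the mean number
  of cooperators in its games) does not depend on $\alpha$ at all — payoffs
  are recovered afterwards as $\pi = \alpha c \bar n_C - c \bar a$.  One
  behaviour sweep therefore serves an entire $\alpha$ grid
  (`composition_behaviour()` + `composition_payoffs()`), and the on-disk
  cache key accordingly omits $\alpha$.
* **Embedded chain.**  Mutations are uniform over the other states;
  transition $i \to j$ is $\rho_{j \to i}/(n-1)$ and the selection–mutation
  equilibrium is the left fixed vector of this row-stochastic matrix,
  computed by a direct linear solve with an explicit irreducibility check
  (all Fermi fixation probabilities are strictly positive, so the check only
  trips on malformed inputs).

The critical payoff parameter separating the unconditional phases follows
from the payoff formulas under hypergeometric group sampling: a focal
cooperator's and defector's expected per-game payoffs differ by
$\alpha c (N-k)/(N-1) - c$ at *every* ALLC/ALLD mixture, which vanishes at

$$ \alpha_c = \frac{N-1}{N-k} $$

(`critical_alpha()`; $= 1.18$ at $N = 60$, $k = 10$).  The package also
carries `payoff_difference_bruteforce()`, an independent summation over the
full hypergeometric distribution of co-players, used by the tests to verify
the closed form rather than trust the algebra.

The cooperation-optimal criterion $\lambda_c$ is operationalized in
`find_lambda_c()`: on an $(\alpha, \lambda)$ phase grid, $\lambda_c$ is the
criterion minimizing the smallest $\alpha$ whose equilibrium cooperation
rate reaches a threshold (default 0.5 — "cooperation maintained" has no
canonical numeric definition, so the threshold is explicit and
configurable), ties broken toward the more relaxed criterion.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| $N$ | population size | 60 | baseline of the group-interaction setting |
| $k$ | group size | 10 | ditto; $k=2$ recovers the dyadic game |
| $c$ | contribution cost | 1 | payoff unit |
| $\alpha$ | payoff parameter, $R = \alpha k$ | scanned | the social-dilemma axis; $\alpha_c = 1.18$ |
| $\lambda$ | assessment criterion | scanned | the strictness axis |
| $q$ | observation probability | 0.9 | gossip is good but not perfect |
| $\epsilon$ | perception error | 0.05 | private noise that seeds disagreement |
| $s$ | selection strength | 1 | moderate selection |
| $\mu$ | mutation rate | $\to 0$ | embedded-chain (rare-mutation) regime |

## What the simulations emulate — and what they do not

The generator reproduces the study conditions of the framework: well-mixed
finite populations, binary private reputations, round-robin donor framing
inside randomly re-drawn groups, private noisy observation.  Passing tests
therefore speak to the *model*, not to field data: there are no network or
spatial structures, no persistent group membership (and hence no direct
reciprocity), no continuous or quantitative reputations, no heterogeneous
influence inside groups.  The norm set is the ten strategies above, not the
256-norm third-order space.

## Numerical choices and problem sizes

Statistics are time-averaged after a burn-in (default 10% of the rounds;
phase-grid sweeps use 20% of shorter runs).  Desk-scale defaults — chosen
once as the package's working scale and used by the acceptance script —
are: reputation scenarios $2\times10^4$ post-burn-in rounds and 10
replicates; criterion-evolution sweeps $2\times10^4$ rounds per composition;
phase grids $5\times10^3$ rounds per composition over $\alpha \in
\{0.3,\dots,1.2\}$ (step 0.1) and $\lambda \in \{0.1,0.3,0.5,0.7,0.9\}$.
The reference experiments behind the framework use $2\times10^5$ rounds and
50 replicates; the desk scale reproduces their qualitative structure with
Monte-Carlo noise of a few percent, which matters only where a quantity
sits exactly on a decision boundary (e.g. an equilibrium cooperation rate of
0.49 vs 0.50 at one grid cell).  Replicate $r$ of a scenario uses seed
$\mathrm{seed} + r$; every CSV row carries its seed, and a run manifest
(config echo, package version, MD5 checksums) makes outputs bit-reproducible.

The C++ engine and the pure-R reference engine consume the same RNG stream
in a documented draw order (group sampling → observation draws in player
order → misperception draws per donor, observer-ordered), so their
trajectories are bit-identical — this is a tested contract, not an
aspiration.  Degenerate inputs are rejected loudly: empty recipient groups,
$\lambda \notin (0,1]$, $k > N$, reducible transition matrices, $k = N$ for
$\alpha_c$.

## What the desk-scale phase diagrams do and do not show

The package reproduces, quantitatively, the reputation-dynamics layer
(good-reputation curves across $\lambda$ in mixed populations, including the
strict-society whitewashing of unconditional defectors by the forgiving
norms L3–L6), the critical payoff parameter, and the criterion-evolution
fixation structure.  On the equilibrium phase grids, the qualitative
structure — a cooperation pocket below $\alpha_c$ at moderate $\lambda$, a
defection phase at relaxed $\lambda$, dominance of unconditional
cooperation at strict $\lambda$ once $\alpha > \alpha_c$ — emerges clearly.
Exactly how deep the pocket reaches in $\alpha$ for a given norm is the
most convention-sensitive quantity in the whole framework: it compounds the
homogeneous-population collapse threshold in $\lambda$ (a nucleation-type
transition that is bistable near the boundary), the fixation balance
against unconditional defectors at strong selection (log-scale sums over 59
compositions), and Monte-Carlo error in each composition's behaviour.
Under this package's conventions the pocket for L1 reaches
$\alpha \approx 0.5$, while the pockets for L2, L7 and L8 bottom out higher
($\alpha \approx 0.9$–$1.2$): the collective-reputation threshold is
integer-valued in the count of good members (only $\lceil \lambda(k-1)
\rceil$ matters), so there is no intermediate strictness at which these
norms both keep their internal cooperation and fully punish defectors at
very low payoffs.  Users comparing against other implementations of the
same framework should expect this particular quantity to move with the
perception-error scope and the self-image convention, and should compare
the fixation tables (which are far more stable) first.

## Known limitations

* Equilibrium quantities on phase grids inherit Monte-Carlo error from the
  behaviour sweeps; near phase boundaries single cells can flip between
  "cooperating" and "defecting" across seeds.  The grid resolution (0.1 in
  $\alpha$) bounds how precisely boundary positions can be located.
* The rare-mutation equilibrium ignores mixed states; for large $\mu$ use
  `agent_based_evolution()`, which simulates the full chain but needs
  payoffs refreshed per composition and is orders of magnitude slower.
* The per-game payoff convention (conditional on participation) differs
  from a per-round convention by the constant factor $k/N$, which acts as a
  rescaling of $s$; comparisons across conventions should rescale
  selection strength accordingly.
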