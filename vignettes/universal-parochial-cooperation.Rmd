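---
title: "Methods: modelling the evolution of universal versus parochial cooperation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modelling the evolution of universal versus parochial cooperation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopevo)
```

## The model

A population of `N = k * n` agents is partitioned into `k` groups of equal
size `n`. Each generation has two stages.

**Stage 1 — nested contribution game.** Every agent holds an endowment
`e` and chooses one action: contribute to the *club good* of its own group
(cost `c_c`, benefit `b_CG` split equally over the `n` group members),
contribute to the population-wide *public good* (cost `c_c`, benefit
`b_PG` split equally over all `N` agents), or keep the endowment. Both
contribution options are social dilemmas: the marginal per-capita return
is below the cost (`b_CG/n < c_c`, `b_PG/N < c_c`) while the total benefit
created exceeds it (`c_c < b_CG < b_PG` in the baseline). Stage-1 earnings
are implemented in `stage1_earnings()` and conserve value exactly: total
earnings equal `N*e` minus total costs paid plus total benefits created.

**Stage 2 — reciprocal helping.** Every agent receives a second endowment
and acts once as a donor: it is paired with an in-group member with
probability `p` (uniform among the other `n - 1` group members) or an
out-group member with probability `1 - p` (uniform among the `N - n`
outsiders). The donor may pay `c_h` to confer `b_h` on the receiver.
Helping is the enforcement mechanism: it lets cooperators reward their own
kind. The three core strategies are universal cooperators **U** (public
contribution; help universal cooperators anywhere), parochial cooperators
**P** (club contribution; help in-group parochialists), and free-riders
**F** (keep; never help).

The closed-form expected payoffs (`expected_payoff()`) collect both
endowments, the non-excludable public-good return `n_U * b_PG / N`, the
group's club return `n_P^i * b_CG / n_i`, minus `c_c` for cooperators,
plus the net helping surplus `(b_h - c_h)` weighted by the probability of
meeting a partner of one's own kind. We stress one easy-to-misread point:
*everyone* — parochialists and free-riders included — collects the
public-good return, because no one can be excluded from it.

**Evolution.** After each generation one agent is selected uniformly at
random to adapt (equivalently: a group with probability `1/k`, then a
member with probability `n_ij/n`). With probability `mu` it adopts a type
drawn uniformly at random from the type space; with probability `1 - mu`
it imitates globally, adopting type `y` with probability proportional to
the total fitness mass `sum_i n_iy * exp(pi_iy)` of that type in the
pre-death population. This frequency-dependent Moran process defines a
Markov chain over population states.

## Parameters

| Parameter | Meaning | Default | Why |
|---|---|---|---|
| `k`, `n` | groups × members | 2 × 4 | the smallest population with genuine intergroup structure; exactly solvable (225 states) |
| `e` | endowment per stage (monetary units) | 1 | scale of all payoffs |
| `c_c`, `c_h` | contribution / helping cost | 1, 1 | full endowment at stake in both stages |
| `b_CG`, `b_PG` | club / public benefit | 2, 3 | per-capita returns 0.5 and 0.375: both dilemmas bind, the public good is socially more efficient |
| `b_h` | helping benefit | swept 0–9 | the strength of the reciprocity enforcement |
| `p` | in-group meeting probability | swept 0.5–1 | 1 = solid boundaries, 0.5 = fully fluid; the ABM extends to [0, 1] |
| `mu` | mutation rate | 1e-4 | rare-mutation regime: the chain spends most time near homogeneous states, and the stationary distribution reflects their relative stability |

These defaults *are* the study conditions of the baseline analysis; the
sweeps (`sweep_exact()` with 51 × 91 = 4641 cells; `abm_design()` with
352,000 run slots) reproduce the published grids.

## The exact engine

States are the per-group type counts; for equal group sizes the space has
`choose(n + T - 1, T - 1)^k` states, enumerated in lexicographic order on
the flattened (group-major) count vector. The order is deterministic and
recorded in every result manifest. Enumeration refuses to materialize more
than `1e6` states (configurable); the closed-form count remains available
at any size via `count_states()`.

Numerical choices:

* **Overflow-safe fitness.** Adoption probabilities are ratios of
  exponentials; we subtract the state's maximum payoff before
  exponentiating, which preserves ratios exactly and keeps `exp()` finite
  for any payoff scale.
* **Stationary backends.** The stationary vector is defined by `w M = w`,
  the left eigenvector for eigenvalue 1 of the row-stochastic `M`. For
  `mu > 0` the chain is irreducible, so Perron–Frobenius guarantees a
  unique nonnegative normalized solution — this is also the tie-break rule
  for the eigen backend. Three backends (dense LU null-space solve,
  eigendecomposition, power iteration by repeated matrix squaring) must
  agree to 1e-8; the LU solve is the default. Tiny negative entries from
  floating-point are clipped to zero before renormalizing.
* **Degenerate inputs.** Meeting fractions with zero denominators (a
  single-member group, or `k = 1` leaving no out-group) are defined as 0:
  no partner of that kind exists. `mu = 0` makes the chain reducible —
  homogeneous states absorb — so `stationary_distribution()` refuses it
  and points to absorption analysis via the simulator.
* **Absent types.** The printed payoff equations presume the focal agent
  exists. By default payoffs use counts as-is (a zero-count type never
  enters the adoption sums, which multiply by the count, so the convention
  is inert in the pipeline). For invasion analysis,
  `expected_payoff(..., as_resident = TRUE)` substitutes one hypothetical
  resident into the focal meeting terms only.
* **Mutation target.** "Adopt a new type randomly" is implemented as
  uniform over all `T` types *including* the current one (effective
  innovation rate `mu * (T-1)/T`); the dying agent also remains in the
  imitation pool (self-imitation is possible). Both follow the printed
  adoption formula, which uses the full pre-death counts.
* **Death probability.** The per-slot selection probability is
  `(1/k) * (n_ij / n)` throughout; welfare is the stationary expectation
  of the mean agent payoff per generation, including both endowments `2e`.

## The agent-based simulator

The simulator replays the same rules with *realized* pairing: every donor
draws an actual receiver, payoffs are accrued, and one Moran event follows
per iteration. The inner loop is compiled (Rcpp) and uses R's RNG, so runs
are exactly reproducible under a seed; sweep seeds derive deterministically
from a base seed, the cell index and the run index. Runs stop at
homogeneity or at 2000 iterations, in which case the composition is
averaged over the last 1000 — matching the published protocol.

**Realized versus expected fitness.** Imitation weights can use each
agent's realized payoff (default) or the closed-form expected payoff of
its type. The two are *not* equivalent in small populations: `exp()` is
convex, so payoff variance — a lucky agent helped by several donors —
inflates realized-fitness imitation toward help recipients. At the
baseline size (`N = 8`) this shifts steady states noticeably (e.g. at
`b_h = 2.5`, `p = 0.5` realized-fitness dynamics sustain cooperation where
the expected-payoff chain is free-rider-dominated). Cross-validation
against the exact engine therefore uses `fitness_payoffs = "expected"`,
which mirrors the exact update; the realized mode remains the default for
simulation studies because pairing is explicitly realized there.

**Extended strategies and standing.** Beyond the core triple, the
simulator supports nondiscriminating helpers (help any stage-1
contributor) and second-order free-riders (contribute but never help).
Conditional helpers withhold help from receivers in bad *standing*. We
deliberately implement standing rather than naive "helped last round"
discrimination: an agent falls into bad standing only by withholding help
from a stage-1 contributor in good standing, while justified withholding —
from a non-contributor, or from an agent already in bad standing — leaves
standing intact. A naive rule punishes helpers for correctly refusing
free-riders, triggering punishment cascades that destroy cooperation in
exactly the control conditions where it should be stable; the
standing form is the established resolution of this problem in indirect
reciprocity and uses only previous-round observable behaviour. In the
first round, standing is unknown and governed by a benefit-of-the-doubt
flag (default: treat unknown as good standing).

Receivers are drawn independently per donor (several donors may pick the
same receiver); the behavioural experiment's rule that one's receiver
cannot be one's donor is an anti-direct-reciprocity control of the
laboratory implementation and is not imposed here.

## What the simulators emulate — and what they do not

The generators produce populations under the model's own assumptions:
equal group sizes, uniform random initial strategies, payoff-driven
imitation with rare mutation. Passing tests therefore show internal
consistency of the model chain — they say nothing about finite-sample
behaviour of human groups, heterogeneous group sizes, migration, network
structure, or group-level events (fission/fusion), none of which are
modelled. The closed-form thresholds use mean-field meeting fractions
(`n_P/n`); in a finite group the payoff crossing sits within one agent of
the threshold because the focal agent cannot meet itself
(`(n_P - 1)/(n - 1)`).

## Validation strategy and problem sizes

* Stage-1 earnings reproduce the six worked monetary-unit examples
  (3, 3.625, 2.625, 2.5, 3.5, 1.5) and conserve totals to 1e-12.
* `expected_payoff()` is checked against an independent oracle that
  enumerates every possible stage-2 pairing with its probability
  (tolerance 1e-9, systems up to `N = 8`).
* The transition matrix is compared entry-by-entry with a scalar
  brute-force builder on the 36-state system (`n = 2, k = 2`), rows sum
  to 1 within 1e-12 across random parameter draws, and one-step
  reachability respects the single-agent-move bound `k*T*(T-1) + 1`.
* The three stationary backends agree within 1e-8 on systems up to 225
  states; two-state chains recover the textbook closed form.
* The simulator's long-run time averages (8 replicates × 2 million
  iterations, first half discarded as burn-in, expected-fitness mode) are
  compared with the exact stationary proportions at four `(b_h, p)` cells
  spanning all regimes, within 3 Monte-Carlo standard errors computed
  across replicates. Replicate counts and lengths are the package's
  choice of a design whose Monte-Carlo error honestly reflects the slow
  regime-switching at `mu = 1e-4`.
* Scaled-down sweeps (10% of the full 200 runs per cell, coarsened
  grids) verify the structural trends: universal cooperation increases
  with group size and decreases with fragmentation (rank correlations);
  undetectable second-order free-riders collapse helping cooperation
  relative to the detectable-condition control (paired one-sided test over
  100 runs). The full 352,000-run design is enumerated and guarded behind
  an explicit opt-in.

## Known limitations

* The exact engine requires equal group sizes; how to split `N` not
  divisible by `k` is unspecified in the underlying model, so unequal
  groups are refused rather than guessed.
* The closed-form payoffs are written for `k = 2`; for `k > 2` the
  out-group term generalizes to uniform choice among all out-group
  members, which the simulator uses.
* The published mean convergence time (1351 iterations) is a property of
  the full-scale sweep and is not asserted at desk scale.
* Stationary summaries near regime transitions vary smoothly but steeply
  in `b_h`; the continuity check flags rather than hard-asserts jumps.
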