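---
title: "Cost-optimal surveillance and intervention for a binary hidden-Markov system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cost-optimal surveillance and intervention for a binary hidden-Markov system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(binsurv)
```

## The model and its assumptions

`binsurv` treats a monitored system — a device under quality control, a
patient under clinical monitoring, a population under pathogen
surveillance — in its simplest binary abstraction:

* The **hidden state** `X_t ∈ {0 = normal, 1 = abnormal}` is a
  discrete-time Markov chain: `P(X_{t+1}=1 | X_t=0) = q01`,
  `P(X_{t+1}=0 | X_t=1) = q10`, both time-independent. The stationary
  distribution puts mass `a1 = q01/(q01+q10)` on the abnormal state;
  `a1` is the prior abnormality probability at any time, and all losses
  below are steady-state quantities (the one-step propagation
  `a1(t+1) = a1(t)(1−q10) + (1−a1(t))q01` contracts to `a1`
  geometrically at rate `|1−q01−q10|`, so stationarity is the long-run
  regime, not an extra constraint).
* The **detector** emits one bit per step, conditionally on the
  same-time state: `P(B_t=1 | X_t=0) = p01`, `P(B_t=1 | X_t=1) = p11`.
  While the state is constant the observations are a Bernoulli sequence.
* **Costs** are dimensionless, normalized by the cost `c` of one
  abnormal step without intervention: an intervention costs `K = k/c`
  per step it is applied (and replaces that step's abnormality cost —
  `k` bundles the intervention itself plus any residual harm);
  surveillance at window depth `n` costs `S_n = s_n/c` per step, with
  `S_0 = 0`. Costs do not couple across steps, and interventions do not
  alter the hidden dynamics.

**Strict validation** (the default) enforces the intended regime:
`0 < q01 < 1/2` and `0 < q10 < 1/2` (the system more often stays than
switches), `p11 > p01` (the detector is informative), and `0 < K < 1`
(intervention is cheaper than the harm it averts — otherwise there is
nothing to optimize). A `strict = FALSE` escape hatch exists because
every formula in the package is algebraically valid on the full
parameter ranges; it is used, for example, by phase diagrams that sweep
`K` across `[0, 1]` inclusive.

## Exact inference and the Δ statistic

For a window `b = (b_1, …, b_n)` (oldest bit first) the joint
probability of observing `b` with final hidden state `r` under the
stationary chain is computed by a forward filter — two running values,
one per hidden state, updated in `O(1)` per bit. The literal sum over
the `2^n` hidden paths is retained in the test suite as an independent
oracle, never in the package code path.

The decision statistic for a window is

```
Δ(b) = (1 − K) · P(b, abnormal) − K · P(b, normal),
```

the expected per-step cost of *not* intervening minus that of
intervening when `b` is observed. Two identities anchor the test suite:
`Δ(b) = P(b)·(posterior(b) − K)` (so thresholding Δ at 0 is exactly
thresholding the Bayesian posterior at K), and the telescoping sum
`Σ_b Δ(b) = a1 − K` over all `2^n` windows at every depth.

All arithmetic is double precision; at the intended depths (`n ≲ 20`)
the joints stay far from underflow for strictly valid parameters, so no
log-space bookkeeping is used. Windows of probability zero (possible
only with degenerate detectors under lenient validation) yield `Δ = 0` —
they can never contribute to a loss — while the posterior raises an
explicit error there.

## Losses and optimal policies

A depth-`n` strategy is a decision table over all `2^n` windows; its
exact steady-state expected cost per unit time is

```
L_n(Y) = a1 + S_n − Σ_{b : Y(b)=1} Δ(b).
```

The two depth-0 baselines are `L0(0) = a1` (never intervene) and
`L0(1) = K` (always intervene). Because `L_n` is linear in the table
with coefficients `−Δ(b)`, the per-depth optimum is the Heaviside rule
`Y*(b) = θ(Δ(b))`, confirmed in the tests by exhaustive enumeration of
all `2^(2^n)` tables for `n ≤ 3`.

**Tie rules.** `Δ(b) = 0` maps to action 0: both actions give identical
loss and the package prefers the minimal-action table. Across
candidates, exact loss ties resolve to the smaller depth, then the table
with fewer 1-entries, then the lexicographically smallest action string
— cheaper and simpler protocols win ties. Because "exact tie" is a real
concept here (e.g. the all-ones table equals always-intervene exactly
when `S_n = 0`) but floating-point sums carry ~1e−16 noise, candidate
ordering rounds losses to 10 decimal places before applying the tie
chain. 1e−10 is far below any meaningful cost difference and far above
accumulated rounding error; without this, boundary cells of a phase
diagram can leak spurious labels (an `n=1:11` cell beating `always` by
1e−17).

**Protocol selection** compares never, always, and the per-depth optima
for `n = 1 … max_n`. The candidate set does not need the `2^(2^n)`
enumeration: the Heaviside table is provably optimal at each depth, so
only one candidate per depth survives. At `max_n = 1` this is the
classic three-way comparison; at `max_n = 2` the winner lands in the
known five-strategy family (never / always / last-bit / both-bits /
either-bit) in randomized testing — the test logs rather than asserts
exhaustiveness of that family, since only the θ-rule itself is proven.

**Phase diagrams** classify each grid cell pointwise by re-running the
candidate comparison at that cell's parameters — no analytic boundary
tracing; exact arithmetic plus the tie rules make the pointwise label
reproducible, which the tests confirm by re-validating cells through
`select_protocol()`. In the `(K, S1)` plane the three regions are
contiguous and the surveillance region shrinks monotonically with `S1`
(raising `S1` penalizes only the surveillance candidate), vanishing once
`S1` exceeds the gap between the best baseline and the best-case value
of surveillance.

## A dominance claim that needs one more assumption

It is tempting to argue that `L1(0,1) ≤ L1(1,0)` always — intervening on
the *more* incriminating symbol should beat intervening on the less
incriminating one, because `p11 > p01` makes the posterior after a 1
larger than after a 0. The posterior ordering is true, but the loss
inequality is equivalent to `Δ_1 ≥ Δ_0`, i.e.

```
(1 − K) a1 (2 p11 − 1)  ≥  K a0 (2 p01 − 1),
```

and `p11 > p01` alone does not imply it. Counterexample (fully inside
the strict regime): `q01 = 0.1, q10 = 0.3, p01 = 0.8, p11 = 0.9,
K = 0.8` gives `L1(0,1) = 0.695 > L1(1,0) = 0.375`. Intuition: with a
detector that fires 1 most of the time in *both* states and an expensive
intervention, no window justifies intervening (both posteriors are below
K); between the two wasteful single-symbol rules, wasting K on the
*rarer* symbol (here 0) is less bad. The inequality **is** a theorem
under the natural extra condition `p01 ≤ 1/2 ≤ p11` — a detector at
least as good as a coin flip in each state — which makes the left side
nonnegative and the right side nonpositive. The dominance tests
therefore draw from the chance-bounded regime, and pin the
counterexample explicitly outside it. The second dominance,
`L0(Y) < L1(Y, Y)` whenever `S1 > 0` (paying for a bit you ignore is a
pure loss), is unconditional and is tested across the full strict
regime.

## The simulator: what it emulates and what a green test establishes

`simulate_chain()` draws the initial state from the stationary
distribution — not from a burn-in — so the steady-state premise of every
closed form holds exactly from step 1 and no burn-in length needs
tuning. States then advance by the `q`'s and bits are emitted by the
`p`'s; one integer seed drives the whole run, and identical
`(bundle, T, seed)` give bit-identical runs without touching the global
RNG stream.

`simulate_run()` applies a decision table to the observation stream
(action at `t` is the table entry for window `t−n+1 … t`; the first
`n−1` steps have no complete window, take action 0, and are excluded
from scoring) and records per-step costs: `K` when intervening, 1 when
abnormal without intervention, 0 otherwise, plus `S_n` on every scored
step. The mean scored cost converges to `L_n(Y)`, making the simulator
an *empirical oracle* for every exact loss in the package.

The reported standard error is the naive i.i.d. one. The chain is
serially correlated (lag-1 autocorrelation `1 − q01 − q10` for the
states), so the naive standard error understates the truth by up to
about `sqrt((2 − q01 − q10)/(q01 + q10))`; rather than implement a block
bootstrap inside an oracle, the acceptance tests use a generous 5-naive-σ
band, which keeps the per-comparison false-alarm rate low across the
strict regime at `T = 10^6`. A green Monte-Carlo test therefore
establishes agreement of the closed form with the generating process *of
this model* — it says nothing about model adequacy for any real data
stream, where transition and emission probabilities are neither known,
constant, nor binary-sufficient.

Defaults in the randomized-test world: switching probabilities in
`(0.02, 0.48)` (the full persistent regime, away from the frozen and
knife-edge boundaries), emission probabilities informative by at least
0.05, `K` in `(0.05, 0.95)`, and surveillance costs up to 0.05 per step
(a realistic "data is much cheaper than failure" ratio; dominance tests
widen it to 0.2 so surveillance sometimes loses). These are stated once
here and not tuned per test.

## Numerical and interface conventions

* Window strings are written oldest-bit-first everywhere (`"01"` = a 0
  then a 1, the 1 most recent), including strategy JSON
  (`{"n": 2, "table": {"01": 1, …}}`) and CLI labels (`n=2:0001`, actions
  in lexicographic window order).
* Probabilities are validated against exact `[0, 1]` bounds (no
  tolerance); complements (`q00`, `p10`, `a0`, …) are always derived,
  never stored, so normalization is exact by construction.
* Raw costs `(k, c, s_n)` are normalized to `(K, S_n)` at the config
  layer and never kept; all outputs are dimensionless.
* `S_n` is not required to be nondecreasing in `n` (nothing in the
  mathematics needs it); a decreasing sequence triggers a warning since
  it usually indicates a config slip.
* The config file is JSON (keys `q01, q10, p01, p11, K` — or `k` and
  `c` — and `S`); a YAML front end was dropped as no YAML parser is part
  of the package's dependency footprint.
* CLI exit codes: 0 success, 2 validation/configuration error, 1
  anything else. `--verbose` logs the resolved model and the tie-rule
  convention so runs are auditable.

## Known limitations

* Parameters are assumed known. Estimating `q`/`p` from historical data
  (or adaptively) is out of scope by design.
* The per-depth optimum is exact, but "best depth" is only searched up
  to `max_n`; surveillance costs must be supplied per depth.
* Brute-force strategy enumeration is capped at `n = 4` (65,536 tables)
  and exists as an oracle, not a production path.
* The five-strategy family at depth 2 is observed, not proven,
  exhaustive for the final comparison; randomized testing logs any
  escapee instead of asserting.
* Naive standard errors (see above); treat them as optimistic by a
  known, bounded factor.
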