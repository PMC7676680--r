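---
title: "The foodchainsim model: assumptions, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The foodchainsim model: assumptions, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foodchainsim)
```

This vignette is the package's own account of the science it implements:
the model and its assumptions, the parameters that matter, the estimators,
and the places where the design was genuinely open and a choice had to be
made. Nothing here states an empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The model

`foodchainsim` simulates a stylized food supply chain as a trading game on
a strictly layered directed network: producers sell crops to traders,
traders sell to consumers, and no other links exist. The model is
deliberately generic — no prices, no money, no space, no agent turnover —
so that the effect of *network structure* and *partner-selection behaviour*
on efficiency and resilience can be isolated.

Time is discrete at two scales. One **production cycle** ("year"): every
producer is assigned a crop uniformly at random, produces a fixed volume,
and sells the whole batch to a single trader. Within each cycle,
`Periods` **consumption rounds** ("months") take place: every consumer
selects one trader, and each trader splits its per-crop stock evenly among
the consumers buying from it that round, up to each buyer's remaining
cycle demand. Left-over stock persists to the next cycle scaled by
`StockPersistence`.

A run consists of a spin-up phase (discarded from analysis), a stationary
pre-shock phase, and a shock phase, each 100 cycles by default, plus an
optional post-shock recovery phase in which shocked agents regain their
remembered production and demand.

### Partner selection

Three interaction modes govern how producers and consumers pick traders.
All selection is a single weighted-random draw with probability
$w_t / \sum_u w_u$:

* **random** — $w_t = 1$: a baseline without economic reasoning;
* **weighted** — stock as an implicit price signal. For a producer of crop
  $c$: $w_t = \mathit{BasePreference} + (\max_u s_{u,c} - s_{t,c})$ (empty
  traders are assumed to pay the best price); for a consumer whose least
  fulfilled crop is $c^*$: $w_t = \mathit{BasePreference} + s_{t,c^*}$
  (full traders are assumed to ask the least);
* **preference** — the weighted-mode weight plus `ExpPreference` for every
  trader in the agent's ever-accumulating historic-partner set, a stylized
  form of trust.

The linear additive weight form is a design choice: the behavioural
description fixes only the *direction* of the stock dependence. Additive
weights reduce to a uniform draw when all stocks are equal, and make
`BasePreference` exactly the floor weight of every trader. A consequence
worth knowing: because every selected trader joins the historic set and the
set never shrinks, the preference mode's lock-in weakens over long runs as
the set saturates; preference behaviour then approaches a uniform draw
among historic partners. Stronger lock-in rules (multiplicative trust,
forgetting) are deliberately out of scope.

Within a round, selection is **simultaneous**: all producers (or all
consumers) observe the same start-of-round stocks, then all deliveries or
allocations are applied at once. This matches the model's
perfect-information assumption and avoids an arbitrary agent ordering; a
sequential implementation would make results depend on an undocumented
update order.

### Demand bookkeeping

Each consumer requires `TotalDemand / n_consumers` volume per cycle, split
equally over crops and spread equally over rounds. The demand a consumer
presents in round $p$ is its cumulative entitlement $p \cdot d$ minus what
it has already consumed, so unmet demand carries over *within* a cycle
(consumers can catch up when stock arrives late) and resets at the cycle
boundary. Several rounds per cycle are genuinely needed for consumers to
gather their requirement — sensitivity sweeps of `Periods` only show
effects at very small values.

### Shocks

At the onset of the shock phase, `round(ShockSeverity * n_level)` distinct
agents of the shocked level are drawn (round half up; the set stays fixed
for the whole shock):

* **producer** shock — shocked producers produce nothing ("failed
  harvest");
* **trader** shock — shocked traders' stocks are zeroed at every
  shock-cycle start ("stock loss"). Re-zeroing each cycle, rather than
  once, is a design choice consistent with a shock that *lasts* the whole
  phase rather than a one-off event;
* **consumer** shock — each shocked consumer moves the entire demand of one
  uniformly drawn crop onto another uniformly drawn crop ("preference
  change"); the original demand is remembered and restored afterwards.

With two crops the per-consumer uniform draw means about half the shocked
consumers shift one way and half the other, so aggregate demand per crop is
roughly conserved; a coordinated shift (all shocked consumers moving to the
same crop) would hit harder. We keep the per-consumer reading because it is
the minimal operationalization of an individual preference change; the
consequence — consumer shocks are mild, and can even *raise* mean
satisfaction because a single-crop consumer escapes the binding
minimum-over-crops — is reported honestly by the test suite rather than
patched.

## Output measures

**Satisfaction.** Per cycle,
$\bar H = \tfrac1{N}\sum_y \min_x (c_{x,y}/d_{x,y})$, with two numerical
conventions: ratios are capped at 1 (a consumer cannot be more than fully
satisfied, so over-consumption of one crop cannot mask shortfall in
another), and crops with zero requirement are excluded from the minimum
(a crop you do not want cannot lower your fulfilment; a consumer with no
demand at all counts as satisfied). Both conventions matter only in edge
cases (consumer shocks, zero-demand configurations) and are applied
uniformly.

**Impact.** $E = (\bar H_{p2} - \bar H_{p1}) / \bar H_{p1}$ over the
pre-shock and shock windows; negative when the shock lowers satisfaction.
$E$ is stored as a fraction; render percentages at presentation time.

**Flows and the information decomposition.** The flow $F_{ij}$ between two
agents is the mean traded volume per cycle over a declared window; pairs
that never trade in the window have $F_{ij} = 0$. Efficiency (ascendency)
$A$, resilience (reserve) $B$, and capacity $C = A + B$ follow Ulanowicz's
decomposition. Natural logarithms are used throughout — the identity
$C = A + B$ and the ratio $A\!:\!B$ are base-invariant, so no comparison
depends on this choice; units are nats·volume/cycle. Zero flows contribute
zero by the $x \log x \to 0$ limit; an all-zero window returns all-zero
metrics rather than an error so that severe-shock windows remain
computable. $C$ is always evaluated independently and cross-checked
against $A + B$.

Boundary flows (production entering the system, consumption leaving it)
are *not* added as extra compartments: only realized trade links between
agents enter the matrix.

### Why the cross-network comparison uses short windows

Two flow estimators coexist in the package, and the distinction is
scientifically important:

* `aggregate_flows()` over a full 100-cycle phase answers "what did the
  network trade, on average, over the whole phase";
* `windowed_ab_ratio()` evaluates $A$ and $B$ per 5-cycle sliding window
  inside the phase and averages them.

Under random partner selection, a long window realizes nearly *every*
potential link at least occasionally, so the full-window $B$ grows with the
count of potential links and the $A\!:\!B$ ratio degenerates into an
(inverse) measure of network size. The short-window estimator sees only the
links actually *operating* around each cycle — the quantity that matters
for how concentrated the living trade network is — and it is the estimator
under which the four structural types separate into the expected clusters
(hourglass most efficiency-skewed, diamond most reserve-skewed). Five
cycles is the package's standard diagnostic window length for within-run
time series, and the same length is used here; it is a parameter of
`windowed_ab_ratio()`, not a constant.

## Experiment drivers

* `factorial_design()` / `run_factorial()` cross 3 interaction modes × 7
  networks × 3 shock types (63 cells) with seeded replicates (default
  100, i.e. 6300 runs). Per-run seeds are all drawn up front from the base
  seed, so execution order is irrelevant and any single run can be
  reproduced from its recorded seed alone. Failures are recorded per row,
  never dropped.
* `run_ofat()` sweeps one of six parameters (`BasePreference`,
  `ExpPreference`, `Periods`, `ShockSeverity`, `StockPersistence`,
  `TotalDemand`) across a grid for each of 36 mode × network-type × shock
  combinations (the small representative of each structural type; the
  combination set is an argument). Default grids span each default
  symmetrically: e.g. `StockPersistence` 0–1 by 0.1, `TotalDemand` 60–240
  by 20.
* `classify_trend()` turns a sweep into a `-`/`0`/`+` sign: least-squares
  slope of the output against the min-max-normalized parameter, classified
  `0` unless the fitted total change is both *material* — at least `tau`
  (default 0.05) of a reference scale — and *statistically distinguishable
  from replicate noise* (slope significance at `alpha = 0.01`, fitted on
  the replicate-level points). The reference scale is pooled across the
  combinations of a sweep, so a flat-but-noisy combination is judged
  against the output's overall variation rather than against its own
  noise; the significance condition handles the remaining case of an inert
  parameter whose sweep contains nothing but noise (for which any
  range-relative threshold alone would misfire). An "eyeball" trend call
  is thereby replaced with a reproducible rule.

## Randomness and reproducibility

One seeded RNG stream per simulation drives, in fixed order per cycle:
crop assignment, producer partner draws, then one consumer draw block per
round; shock onset additionally draws the shocked set (and consumer crop
shifts) once. Identical configurations and seeds give bit-identical trade
logs; the tests assert this. All tie-breaks (focal crop, equal weights) go
to the lowest index. Weighted draws with an all-zero weight row (possible
when `BasePreference = 0` and stocks are flat) fall back to a uniform
draw.

## What the simulator does and does not emulate

The simulator *is* the data generator: its defaults (production 100,
demand 120, two crops, twelve rounds, persistence 0.95, 100-cycle phases,
severity 0.5) are the study conditions, and all tests and the acceptance
script generate their inputs by running it. It emulates the structural
mechanics of real supply chains — layered intermediation, stock buffering,
demand rationing, partner switching — but not prices, transport, agent
heterogeneity, entry/exit, or learning beyond the historic-partner set.
Passing tests therefore demonstrate properties of this model class, not of
any calibrated real-world chain.

## Problem sizes used by the tests and acceptance script

The shipped checks are desk-scaled so the whole suite runs in minutes on
one CPU: cluster comparisons use the small representative of each network
type with 10 replicates per mode; the acceptance script runs all seven
networks × 3 modes × 10 replicates; OFAT checks use 5-point grids, three
combinations (one per mode, covering all three shock levels), and 3
replicates averaged per grid point. Experiments that only report pre-shock
quantities set `ShockDuration = 0`; because the RNG is consumed strictly
in phase order, the pre-shock trajectory is bit-identical to that of a run
with a shock phase appended. The full-size design (100 replicates, full
grids, 36 combinations) is available through the same functions.

## Known limitations

* Preference-mode lock-in saturates over long horizons (see above), so the
  separation between preference and random modes is weaker than strong
  trust dynamics would produce.
* Consumer shocks with per-consumer random shift directions largely cancel
  in aggregate; coordinated preference shifts are not modelled.
* The trader-shock ledger intentionally destroys mass (stock loss); the
  exact per-cycle mass-balance identity tested by the suite applies to
  no-shock, producer-shock, and consumer-shock runs.
* A producer sells to exactly one trader per cycle and a consumer buys
  from exactly one trader per round; multi-link trading within a round is
  out of scope.
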