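# foodchainsim

An agent-based simulator for studying the trade-off between **efficiency**
and **resilience** in stylized food supply chains.

## The problem

Food supply chains that are highly optimized — few intermediaries, low
stocks, tightly matched supply and demand — deliver a large share of
production to consumers, but the same leanness removes the buffers and
alternative trade routes that absorb shocks (failed harvests, stock losses,
sudden shifts in consumer preference). `foodchainsim` provides a controlled,
fully synthetic laboratory for this question: a three-layer trade network of
**producers**, **traders**, and **consumers** exchanging crops under
explicit behavioural rules, exposed to stylized shocks, and scored with an
information-theoretic decomposition of the realized trade flows.

The package is aimed at researchers in socio-ecological modelling and
supply-chain resilience who want a reproducible, scriptable implementation
of this model class: every run is driven by a single seeded RNG stream, all
outputs are plain CSV/TSV/JSON, and the factorial and sensitivity drivers
ship with the package.

## The model in brief

Agents sit in a strictly layered directed network (producers sell only to
traders, traders only to consumers). Seven named topologies cover four
structural types:

| type | code(s) | producers/traders/consumers | potential links |
|---|---|---|---|
| block | `bs`, `bl` | 5/5/5, 20/20/20 | 50, 800 |
| inverse pyramid | `is`, `il` | 5/25/50, 10/50/100 | 1375, 5500 |
| hourglass | `h` | 25/5/50 | 375 |
| diamond | `ds`, `dl` | 5/50/25, 10/100/50 | 1500, 6000 |

Each production cycle ("year") every producer grows one randomly assigned
crop and sells it to one trader; within the cycle, `Periods` (default 12)
consumption rounds take place in which every consumer picks one trader, and
each trader splits its stock evenly among its buyers up to their remaining
cycle demand. Partner selection follows one of three interaction modes —
`random` (uniform), `weighted` (stock levels as an implicit price signal),
or `preference` (weighted plus extra weight for trusted, historic partners).
Unsold stock carries over with per-cycle persistence `StockPersistence`
(default 0.95). Supply deliberately lags demand (production 100 vs demand
120 per cycle).

A simulation runs 100 spin-up cycles, 100 pre-shock cycles, and 100 shock
cycles in which a severity-determined random subset of one layer is
perturbed: producers stop producing, traders lose their stock, or consumers
shift their demand from one crop to another.

**Consumer satisfaction** per cycle is
`H = mean_y min_x ( c_xy / d_xy )` — the mean over consumers of the
minimum-over-crops ratio of consumption `c` to requirement `d` (capped at
1). The **impact** of a shock is the relative change
`E = (H_p2 - H_p1) / H_p1` between the pre-shock and shock windows.

**Efficiency and resilience** are computed from the time-averaged flow
matrix `F(i,j)` with Ulanowicz's decomposition (natural logs):

    A = sum_ij F_ij log( F_ij F.. / (F_i. F_.j) )      (efficiency / ascendency)
    B = - sum_ij F_ij log( F_ij^2 / (F_i. F_.j) )      (resilience / reserve)
    C = - sum_ij F_ij log( F_ij / F.. ) = A + B        (capacity)

The ratio `A:B` summarizes how strongly a network channels flow through few
efficient routes versus keeping redundant alternatives.

## Worked example

```r
library(foodchainsim)

cfg <- sim_config("bs", ChoiceModel = "random", ShockType = "producer",
                  seed = 1)
run <- run_simulation(cfg)
run
#> Simulation run: network bs, mode random, shock producer
#>   H (pre-shock) = 0.6720, H (shock) = 0.1214, impact E = -0.8193
#>   mean pre-shock stock = 55.166
#>   pre-shock flows: C = 770.095, A = 138.101, B = 631.994, A:B = 0.2185
```

Reading: before the shock, consumers on average fulfil 67% of their dietary
requirement (the supply/demand imbalance caps the mean at 100/120 ≈ 0.83).
A producer shock of default severity 0.5 silences 3 of the 5 producers, and
mean satisfaction collapses to 12% — a relative impact of −82%. The
pre-shock flow network has capacity 770 (nats·volume/cycle) of which 18%
is channelled efficiency.

The windowed efficiency-to-resilience estimator used for comparing network
types evaluates the same decomposition in 5-cycle sliding windows of the
pre-shock phase, so rarely-used links do not accumulate into apparent
redundancy:

```r
windowed_ab_ratio(run)
#> $A
#> [1] 178.9203
#> $B
#> [1] 534.45
#> $ratio
#> [1] 0.3347745
```

The metric also works standalone on any weighted directed edge list:

```r
chain <- data.frame(source = c(1, 2), target = c(2, 3), flow = c(10, 10))
ulanowicz(chain)
#> Flow-network information metrics (nats * volume / cycle):
#>   C = 13.8629, A (efficiency) = 13.8629, B (resilience) = 0, A:B = NA
```

A single unbranched chain has zero reserve: cut any link and nothing can be
re-routed.

Batch experiments:

```r
design <- factorial_design(replicates = 10)          # 63 cells, 630 runs
table  <- run_factorial(design)
rec    <- run_ofat("StockPersistence", replicates = 3)
rec$signs
```

A command-line interface wrapping the same functions is installed at
`exec/foodchainsim` (subcommands `run`, `experiment`, `ofat`, `metrics`,
`fixtures`).

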