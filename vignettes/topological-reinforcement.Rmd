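---
title: "Topological reinforcement, Hebbian rewiring and proto-module amplification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological reinforcement, Hebbian rewiring and proto-module amplification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The model

TopoRewire studies how modular network architecture can *emerge* from a
local, density-preserving plasticity rule, and how that rule can be
realized by activity-dependent (Hebbian) plasticity in an excitable
network. All networks are simple undirected graphs with adjacency
$a_{ij} \in \{0, 1\}$, $N$ nodes and mean degree
$\lambda = 2|E|/N$; initial conditions are Erdős–Rényi graphs drawn with
a fixed edge budget $M = \mathrm{round}(\lambda N / 2)$ (the $G(n, M)$
flavour, so density $2M/(N(N-1))$ is exact and conserved, not merely
expected). The reference configuration throughout is $N = 100$,
$\lambda = 10$.

### Topological reinforcement (TR)

The similarity of two nodes' neighbourhoods is measured by the
topological overlap

$$ to_{ij} \;=\; \frac{\sum_k a_{ik} a_{kj} + a_{ij}}
                     {\min(d_i, d_j) + 1 - a_{ij}}, $$

a normalized common-neighbour count in $[0, 1]$, closely related to the
matching index. One rewiring step samples $\lfloor N/2 \rfloor$ distinct
*eligible* nodes (degree strictly between $0$ and $N-1$), connects each
sampled node to the non-neighbour with maximal TO (ties uniform), and
prunes as many links as were inserted, uniformly at random from the
post-insertion edge set. All insertions of a step are scored against the
step-entry adjacency ("simultaneous" batch semantics), and TO is
recomputed once per step, not within a batch. A run performs
$r = \mathrm{round}(\lambda K)$ steps, where $K$ is the mean number of
rewirings per link; $K = 3$ (hence $r = 30$ at $\lambda = 10$) keeps the
evolving networks connected while reaching a plateau of modularity.

```{r}
library(TopoRewire)
g  <- generateER(100, 10, seed = 1)
tr <- runTopologicalReinforcement(g, K = 3, nDetect = 5, seed = 2)
trajectoryRecords(tr)
```

### The SER model and functional connectivity

Each node carries one of three states — susceptible (S), excited (E),
refractory (R) — updated synchronously: S$\to$E if at least one
neighbour is excited, or spontaneously with probability $f$; E$\to$R
always; R$\to$S with probability $p$. The regime is *deterministic* when
$f = 0, p = 1$ (randomness only in the initial condition) and
*stochastic* otherwise. Functional connectivity is built from joint
excitation counts over a recorded history (the initial state at $t = 0$
included),

$$ c_{ij} = \sum_t \mathbf{1}_E(x_i^t)\, \mathbf{1}_E(x_j^t), \qquad
   fc_{ij} = \frac{c_{ij}}{\min(c_{ii}, c_{jj})}, $$

with $fc_{ij} = 0$ when the smaller excitation count is zero: a
never-excited node carries no co-activation evidence and must not
attract links.

Protocol defaults follow the two regimes. Deterministic: many short runs
(full protocol 5000 runs × 30 steps; the package's desk-scale default
for rewiring windows is 500 × 30), each starting from a random initial
condition; counts are averaged over runs *first* and normalized once —
per-run normalization is available (`perRunNormalize`) but is unstable
whenever single runs leave nodes unexcited. Stochastic: one long run
(full protocol 50 000 steps; desk scale 5000), starting from
$\mathrm{round}(0.1N)$ excited nodes with the remainder split between S
and R and assigned at random.

**Initial-condition law (deterministic protocol).** The state
proportions are "randomly generated, covering the full space": we draw
the integer composition $(n_E, n_S, n_R)$ uniformly among all
$\binom{N+2}{2}$ compositions of $N$ and assign states by a uniform
permutation. For $N = 100$ this is indistinguishable from sampling
continuous simplex proportions and rounding, but it has a clean
advantage: the sampling law is *exactly* uniform over compositions ×
uniform over assignments, which is the law the exhaustive-enumeration
test oracle integrates over, so the Monte-Carlo estimator can be checked
against the exact expectation without a rounding-cell bias term.

### The Hebbian rule

The Hebbian variant is the same engine with FC substituted for TO: at
each of the same $r = \mathrm{round}(\lambda K)$ steps, the SER model is
simulated on the *current* graph over the configured window, FC is
derived from scratch (no carry-over between windows), and one batch
rewiring step uses FC as its score. If FC is ever all-zero (dead
dynamics, never reached under the standard protocols) the step warns and
inserts uniformly at random, keeping the density bookkeeping intact.

The mechanism: whenever the dynamical regime makes FC positively
correlated with TO — common inputs promote correlated excitations — the
Hebbian rule acts as a noisy proxy of TR. Sparse-seed deterministic
settings (few excited nodes, mostly susceptible tissue) produce
propagation that traces the topology and TO–FC correlations around 0.5;
high-drive stochastic settings ($f$ near 1) decouple the dynamics from
the topology, the correlation collapses toward 0 and the rule degrades
to random rewiring with $\Delta Q \approx 0$. The package's
representative "modular regime" cell is the deterministic protocol with
proportions $(e, s, r) = (0.1, 0.8, 0.1)$ — chosen to mirror the
stochastic protocol's own 0.1 excited fraction — and the representative
"nonmodular" cell is $f = 0.9, p = 0.9$. `parameterSweep()` maps the
transition between the regimes.

### Consensus machinery and null models

Louvain community detection (resolution 1) is stochastic and, on
weak-signal graphs, highly degenerate; every Q reported by the runners
is a mean over `nDetect` independent detections, and module structure is
always read out through agreement matrices: $P$ from the final
partitions of repeated rewiring runs, $P_{init}$ from 500 detections on
the initial graph, consensus partitions from 100 weighted-Louvain
detections on the agreement matrix itself (one round of
detect–agree–detect; the procedure is not iterated). Three null models
calibrate the statistics:

* degree-preserving graph randomization (accepted double-edge swaps,
  one per link) for network-similarity comparisons;
* the size-preserving partition shuffle for agreement comparisons
  ($P_{null}$), whose off-diagonal expectation is the closed form
  $\sum_m s_m (s_m - 1) / (N(N-1))$;
* shuffled partitions for intramodule density, which centre the density
  of random node groups on the graph density (0.1 for the reference
  configuration).

Empirical p-values use the $(b + 1)/(n + 1)$ permutation convention.
NMI between partitions uses arithmetic-mean normalization
$2I/(H_1 + H_2)$; two trivial (single-module) partitions compare to 1
and a trivial-vs-nontrivial pair to 0, both flagged `degenerate` so
sweeps can exclude them.

```{r}
report <- protoModuleAnalysis(g, nRuns = 100, seed = 3)
reportStats(report)
```

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `K` | mean rewirings per link; `r = round(lambda K)` steps | 3 | reaches the modularity plateau while keeping ER(100, 10) connected; larger K fragments networks (`s5_disconnection`) |
| `batchSize` | nodes rewired per step | `floor(N/2)` | batch semantics: ~N links reallocated per step, statistically equivalent to single-pair updates but far cheaper |
| `f`, `p` | SER spontaneous-activation and recovery probabilities | — | position the dynamics between propagation-dominated (TO–FC correlated) and noise-dominated |
| `windowRuns` × `windowSteps` | deterministic FC window | 500 × 30 | desk-scale estimate of the 5000 × 30 protocol; FC ranking noise grows as windows shrink |
| `stochSteps` | stochastic FC window | 5000 | desk-scale version of the 50 000-step protocol |
| `nDetect` | Louvain runs per Q estimate | 5 | tames detection stochasticity at O(ms) per run |

## Numerical choices and degenerate inputs

* Density bookkeeping is exact: insertions are counted after duplicate
  collapse and exactly that many links are pruned, so the rational
  density $2M/(N(N-1))$ is identical (not merely close) at every step.
* Ties in the score argmax are broken uniformly at random; TO and FC
  ties are common on small or synchronized graphs and must not be
  resolved by index order.
* The TO diagonal is defined as 0 and never consulted; only
  non-neighbour pairs are ranked.
* Complete graphs have no eligible node: rewiring warns and returns the
  input unchanged. Edgeless graphs have undefined modularity: Louvain
  wrappers raise an error rather than returning a vacuous partition.
* In the deterministic high-drive corner $f = 1, p = 1$ the dynamics are
  fully deterministic and nodes phase-lock into their initial S/E/R
  classes, making FC a 0/1 phase block matrix; the input is legal, but
  tests of the "high-drive flattens FC" limit use $f = 1, p = 0.9$ where
  recovery noise genuinely mixes phases.
* Maslov–Sneppen randomization counts *accepted* swaps (one per link)
  with a bounded retry budget per swap; irreducible swaps are skipped
  with a message (relevant only for near-complete or lattice-like
  graphs).

## What the synthetic generators emulate — and what they do not

All experiments run on synthetic graphs the package generates. ER
graphs reproduce the paper-style initial condition: no planted
structure, only chance density fluctuations ("proto-modules") that the
rules amplify. Planted-partition (SBM) fixtures provide a ground truth
for recovery tests. Two caveats bound what passing tests show. First,
a 4-block SBM on 100 nodes is only alignable with any detected
partition when the signal is above the community-detectability
threshold ($(p_{in} - p_{out})N/k > \sqrt{d}$, roughly); the recovery
test therefore uses within/between = 0.25/0.05 at $\lambda \approx 10$
— weak but detectable — rather than undetectably faint blocks. Second,
none of the generators have geometry, weights, growth or pruning, so
these results isolate the purely topological contribution and do not
speak to spatially embedded or weighted connectomes; distance-dependent
wiring would itself seed clustered proto-modules.

## Problem sizes

Replicate counts are the package's own desk-scale choices: rewiring
trajectories use 10–20 runs, proto-module reports 100 rewiring runs with
500 initial-graph detections, 100 consensus detections and 100 null
draws, Hebbian comparisons 10 deterministic and 4 stochastic runs with
the 500 × 30 / 5000-step windows above. Paper-scale counts (500 runs,
5000 × 30 windows, 50 000-step chains, 150-run sweep cells) are plain
arguments away; `runExperiment()` exposes them through its `scale`
factor, which multiplies replicate counts only and never touches model
rules.

## Known limitations

* Louvain is the only community detector wired in; Q degeneracy is
  handled by consensus, not by alternative objectives or resolutions.
* The rules eventually disconnect networks for large K; no counteracting
  mechanism is modelled (the `s5_disconnection` experiment maps the
  effect, and K = 3 avoids it).
* Hierarchical or overlapping modules, weighted edges and spatial
  embedding are out of scope.
* The analytic scaling fit for the final module count is not
  implemented; the scaling sweep reports the raw surfaces only.
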