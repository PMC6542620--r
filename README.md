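# TopoRewire

Adaptive rewiring rules that evolve random networks toward modular,
small-world architectures — and the statistical machinery to show that the
emergent modules were already latent in the initial graph.

Modularity is a hallmark of structural brain networks, but the generative
principles behind it are unsettled. TopoRewire implements a minimal
candidate mechanism for computational neuroscientists and network
scientists: **topological reinforcement (TR)**, a density-preserving
plasticity rule that repeatedly connects non-neighbour nodes with high
neighbourhood similarity, plus its biologically interpretable counterpart,
a **Hebbian rule** driven by co-activation statistics of an excitable
(SER) network model.

## The model in brief

For a simple undirected graph with adjacency $a_{ij}$ and degrees $d_i$,
the topological overlap of a node pair is

$$ to_{ij} = \frac{\sum_k a_{ik} a_{kj} + a_{ij}}{\min(d_i, d_j) + 1 - a_{ij}} \in [0, 1]. $$

One TR step connects each of $\lfloor N/2 \rfloor$ randomly sampled
eligible nodes to its non-neighbour of maximal TO and prunes an equal
number of links uniformly at random, conserving density exactly; a run
performs $r = \mathrm{round}(\lambda K)$ steps (mean degree $\lambda$,
$K$ rewirings per link, default $K = 3$).

The Hebbian variant replaces TO by functional connectivity from the
three-state susceptible–excited–refractory automaton
(S→E on an excited neighbour or spontaneously with probability $f$; E→R;
R→S with probability $p$):

$$ c_{ij} = \sum_t \mathbf{1}_E(x_i^t)\mathbf{1}_E(x_j^t), \qquad
   fc_{ij} = c_{ij} / \min(c_{ii}, c_{jj}). $$

Whenever FC correlates with TO — propagation-dominated dynamics — the
Hebbian rule acts as topological reinforcement by proxy and modularity
(Newman–Girvan $Q$, maximized by Louvain) rises; when spontaneous drive
decouples activity from topology, it stalls.

Consensus utilities (agreement matrices $P$, $P_{init}$, size-preserving
partition nulls $P_{null}$, NMI, intramodule density, degree-preserving
graph nulls) quantify how the final modules amplify "proto-modules" —
chance density fluctuations of the initial Erdős–Rényi graph.

## Worked example

```r
library(TopoRewire)

g  <- generateER(100, 10, seed = 1)              # 500 edges, density ~0.1
tr <- runTopologicalReinforcement(g, K = 3, nDetect = 5, seed = 2)
tr
#> Trajectory (topological rule): 30 steps, density 0.1010
#>   Q: 0.259 -> 0.723;  modules: 6.8 -> 8.0
#>   final components: 1;  snapshots kept: 0

trajectoryRecords(tr)[c(1, 11, 21, 31), c("step", "q_mean", "n_modules_mean", "density")]
#>    step q_mean n_modules_mean density
#> 1     0  0.259            6.8   0.101
#> 11   10  0.492            7.2   0.101
#> 21   20  0.638            7.8   0.101
#> 31   30  0.723            8.0   0.101
```

Thirty rewiring steps ($r = \lambda K = 30$) triple the modularity of the
random graph (Q 0.26 → 0.72, averaged over 5 Louvain detections per step)
while the density column stays pinned at the initial value — the rule
only reallocates links. The evolved network is strongly small-world and
the deterministic SER regime ties FC to topology:

```r
smallWorldMetrics(finalGraph(tr), nNull = 10, seed = 4)$swIndex
#> [1] 4.85

fc <- simulateDeterministicFC(g, nRuns = 500, tSteps = 30,
                              proportions = c(0.1, 0.8, 0.1), seed = 3)
toFcCorrelation(g, fc)
#> [1] 0.495
```

`protoModuleAnalysis()` runs the full agreement pipeline (final-run
agreement P, initial-graph consensus P_init, null distributions and
empirical p-values), `runHebbian()` the FC-driven rule, `parameterSweep()`
the TO–FC/ΔQ transition map, and `runExperiment()` end-to-end experiment
pipelines with manifests. A thin CLI over these functions ships in
`inst/scripts/netforge.R`.

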