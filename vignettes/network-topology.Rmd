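---
title: "Topology analysis of curated molecular interaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topology analysis of curated molecular interaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agenet)
```

## The analysis object

A curated interaction database is a list of literature-derived records:
molecule A interacts with molecule B, with a free-text interaction type and
a provenance identifier. Such lists routinely contain duplicate records
(the same interaction reported by two papers) and self-interactions (a
molecule that aggregates with itself). `molecular_network()` keeps that
record list verbatim as the evidence trail, and derives from it the
*simple* graph — self-loops dropped, duplicates collapsed, undirected —
on which all topology is computed. The distinction matters: betweenness
and the other path-based centralities are only defined for networks
without multiple edges, and the "number of edges" a curator reports (the
record count) is deliberately allowed to exceed the number of distinct
neighbor pairs. Node identifiers are whitespace-trimmed but compared
case-sensitively, because curated molecule names are case-meaningful.

Compartment labels (`glycemic_control`, `fertility`, `immunity`) are
carried as node attributes when the database provides them; the package
never infers compartments from layout or clustering.

## The metric suite

Distances are unweighted hop counts from breadth-first search; the
interaction type never weights an edge. For each node the package
computes degree, clustering coefficient, betweenness, closeness, average
shortest path length, eccentricity, radiality, stress, neighborhood
connectivity and the topological coefficient. The conventions, chosen
once and applied everywhere:

* **Betweenness** is `Σ σ_st(n)/σ_st` over unordered pairs `s < t`
  excluding *n*, divided by `(N−1)(N−2)/2` where *N* is the size of
  *n*'s connected component — so values are comparable across components
  and lie in `[0, 1]`.
* **Closeness** is the inverse of the *mean* distance to *reachable*
  nodes. Unreachable pairs are excluded from every average rather than
  set to infinity: on a single-component network the choice is invisible,
  but it must be fixed for general inputs. Isolated nodes get 0.
* **Clustering** `CI = 2nI/(kI(kI−1))` is 0 for nodes of degree < 2, and
  those nodes are included in the network-level average by default. The
  alternative convention (averaging only over degree ≥ 2 nodes) is a
  documented option (`clustering_nodes = "deg2plus"`), since analysis
  tools differ silently on this point and the two can disagree
  substantially on hub-and-spoke networks.
* **Radiality** is `(Δ + 1 − avg L(n, m))/Δ` with Δ the component
  diameter; **stress** counts raw shortest-path memberships (interior
  only); **topological coefficient** is the mean number of shared
  neighbors with 2-step partners (plus 1 for direct links), divided by
  degree. These three and neighborhood connectivity follow the standard
  NetworkAnalyzer formulas, restated explicitly in the help pages so the
  tests are self-contained.

The implementation is deliberately plain: BFS with shortest-path counting
(`σ_st`), then direct evaluation of the defining sums. At the intended
scale (≤ a few hundred nodes) the all-pairs computation is instantaneous,
and the test suite holds it to an *independent* oracle — exhaustive
enumeration of all simple paths on 100 seeded random graphs of up to 8
nodes, at 1e−9 — plus an igraph cross-check on larger random networks.

## Scale-free classification

The degree distribution `N(k)` (raw counts of nodes with degree `k ≥ 1`;
no probabilities, no log-binning, zero-count degrees skipped) is fitted by
ordinary least squares on base-10 logs, giving `N(k) = a·k^γ` with the
Pearson `r` and `R² = r²` reported on the logged data. An exactly
power-law input is recovered with zero residual — a property the tests
assert for many random `(a, γ)` pairs.

The verdict "Barabási–Albert scale-free" requires three things at once: a
good power-law fit, degree-independent clustering, and the presence of
hubs. Published analyses report exemplar values for the first two (fit R²
well above 0.6, independence R² near zero) but no cutoffs; the defaults
`fit_threshold = 0.6` and `independence_threshold = 0.1` bracket typical
reported values, are configurable, and are always echoed in the
assessment so the verdict is a pure function of recorded inputs. The
degree–clustering R² is computed on untransformed values over all nodes
with degree ≥ 1, as a single OLS coefficient of determination.

## Key nodes

**Hubs** are nodes with `ND > μ + σ`. Whether σ is the sample (n−1) or
population (n) standard deviation is rarely stated in applied work; the
package defaults to the sample convention and records the choice in the
report, with the population convention one argument away. The inequality
is strict, so degree-regular networks have no hubs.

**Bottlenecks** follow the shortest-path-tree rule: for each root *s*,
`p_s(v) = 1` when more than `|V(Ts)|/4` root-to-node paths of the tree
contain *v*, and `BN(v)` sums `p_s(v)` over roots. Two decisions needed
fixing. First, "paths meeting at *v*" counts the path ending *at* *v*
itself (the count is then exactly *v*'s subtree size); the
strictly-interior alternative is available as `count_target = FALSE`.
Second, BFS trees are not unique, so each node's parent is its
lexicographically smallest neighbor at the previous level — a
deterministic tie-break recorded in the report. On trees the
shortest-path tree is unique, which is what lets the test suite verify
the scores against an exhaustive, tie-break-free enumeration oracle.

## PCA outliers

The node × 10-metric matrix (rows: the largest connected component;
columns in a fixed order) is analyzed by correlation-matrix PCA: the ten
metrics live on wildly different scales — stress is an unbounded count,
closeness sits in `[0, 1]` — so covariance-mode PCA would be dominated by
stress alone. Covariance mode remains available (`standardize = FALSE`).
Constant columns are dropped from the eigendecomposition and reported,
because zero-variance columns are degenerate under standardization. The
eigendecomposition is done on the correlation matrix directly (rather
than by SVD of the data), which keeps the explained-variance fractions
summing to exactly 1 even when there are fewer nodes than metrics, and a
deterministic sign convention (largest-magnitude loading positive) makes
runs reproducible.

A node is an **outlier** when its (PC1, PC2) score falls outside the
chi-square confidence ellipse of the 2-D score covariance — the region
that would contain 95% of nodes under a bivariate normal approximation.
The level is configurable; flags are monotone in it. A degenerate score
cloud (zero covariance) flags nothing.

## The synthetic generators

`generate_ba(n, m, seed)` is a standard preferential-attachment model
(clique seed of *m* nodes, first attachments uniform via a +1 degree
smoothing) used to test that the classifier accepts the reference
scale-free topology. `fixture()` provides small closed-form graphs (paths,
stars, cliques, a cycle, a two-star bridge) with hand-derivable metric
values.

`generate_afirnet_like(seed)` emulates the statistical structure of a
curated AGE–fertility–immunity network so every pipeline stage is
testable without the real database: 145 molecules in three labeled
compartments (55 glycemic control, 50 fertility, 40 immunity — roughly
the proportions such a curation produces, with glycemic control the
largest), bridged through AGE/receptor analogue nodes; 260 distinct
neighbor pairs plus one duplicate record and one self-loop, i.e. 262
records and a mean degree of 3.586; a preferential-attachment scaffold
giving a right-skewed, power-law-like degree distribution; and one
designated hub (the TRPV1 analogue) wired to exactly 36 neighbors.

The hub construction carries a structural guarantee worth spelling out:
every non-hub degree is capped at 6, and with the mean fixed at 3.586 the
hub's own contribution to the degree variance already forces
`μ + σ > 6.28`. The threshold therefore always lands strictly between the
cap and the hub degree, so hub detection returns exactly the designated
node for *every* seed — the emulator's single-hub property is a theorem
of its construction, not a tuned coincidence.

What the emulator does **not** reproduce: the degree sequence, diameter
(~9 here versus 16 in sparse tree-like curated networks), clustering
coefficient and bottleneck ordering of any particular real database.
Passing the pipeline on the emulator therefore demonstrates that the
machinery — ingestion, metrics, classification, key-node detection, PCA —
behaves correctly on data with the right global statistics; it does not
certify the biological conclusions drawn from any specific curated
network, which require that network's own workbook as input.

## Numerical choices and degenerate inputs

* All randomness flows through a single integer seed, and generators
  restore the caller's RNG state.
* Empty networks error in `network_summary()`; single-node components get
  eccentricity, radiality and closeness 0; the power-law fitter refuses
  fewer than two distinct degrees; PCA refuses fewer than 3 rows or 2
  non-constant columns.
* The pipeline (`run_pipeline()`) aborts with a stage-named error and
  keeps a MANIFEST of completed stages; re-running a config produces
  byte-identical CSVs.

The test suite's problem sizes — 100 random graphs of ≤ 8 nodes for the
enumeration oracle, preferential-attachment networks of 60–1000 nodes for
cross-checks and classification, the 145-node emulator for end-to-end
runs — were chosen so that the exhaustive oracles stay exact and the
whole suite completes in well under a minute, which is the scale at which
this class of curated network lives anyway.

## Limitations

Weighted or directed centralities, approximate betweenness, maximum-
likelihood power-law estimation (Clauset-style `xmin` selection,
bootstrap goodness-of-fit) and the other CytoHubba scores are out of
scope: the implemented methods are the log–log least-squares line and the
bottleneck rule precisely because those are the field-standard choices
for small curated networks, and their simplicity is what makes the
results auditable.
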