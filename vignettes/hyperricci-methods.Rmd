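---
title: "Curvature of weighted higher-order interaction networks: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curvature of weighted higher-order interaction networks: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperricci)
```

## The model

A protein-protein interaction (PPI) network is usually studied as a graph
$G = (V, E)$: proteins are vertices, pairwise interactions are edges.
Many interactions are not pairwise — complexes and regulatory motifs
involve three or more proteins at once. `hyperricci` models these
higher-order relationships with a 2-dimensional simplicial complex
$C = (V, E, F)$, where the faces $F$ are vertex triples whose three
pairwise interactions all exist. In a directed network, a triangle is
promoted to a face when its arcs can be arranged as a feedforward loop
(one protein driving a target both directly and through an intermediary)
or as a feedback loop (a directed 3-cycle), and the face records which.
Because every orientation of a triangle either contains a directed
3-cycle or has a single source and a single sink, any skeleton triangle
admits one of the two patterns once each pair carries at least one arc;
the classification applies feedback precedence when both patterns are
achievable with the available arc directions. Undirected networks promote
every triangle.

The two models share $V$ and $E$, so they differ precisely by the face
term of the Euler characteristic $\chi = |V| - |E| + |F|$.
`topology_summary()`, `degree_distribution()` (edge degree $k_e$ and face
degree $k_f$) and `fit_power_law()` ($P(k) \simeq a k^b$, ordinary least
squares on $\log P(k)$ vs $\log k$ over the occupied unit-width bins)
summarise a complex; `erdos_renyi_network()` provides the size-matched
random null whose expected triangle count is
$\binom{n}{3} (m / \binom{n}{2})^3$.

## Stochastic weights from expression

Expression values (normalised RNA-seq reads) act as proxies for protein
levels. Under the mass-action law the propensity of interaction $(i, j)$
is $x_i x_j$; restricting to the neighbours $N(i)$ of the skeleton and
row-normalising (the $x_i$ factor cancels) yields a Markov random walk

$$p_{ij} = \frac{x_j}{\sum_{k \in N(i)} x_k}.$$

This chain is reversible on an undirected skeleton, with closed-form
stationary distribution $\pi_i \propto x_i \sum_{k \in N(i)} x_k$
(detailed balance: $\pi_i p_{ij} \propto x_i x_j$ is symmetric in $i, j$).
`stationary_distribution()` uses this closed form by default and keeps a
damped power iteration (the lazy chain $(I + P)/2$, converged to a
$10^{-12}$ residual on $\|\pi P - \pi\|_\infty$) as an independent route;
the two agree to $10^{-10}$ on random networks in the test suite. The
damping matters: an undamped iteration oscillates on bipartite skeletons,
where the walk is periodic.

The entropy rate $SR = \sum_i \pi_i S_i$ with
$S_i = -\sum_j p_{ij} \log p_{ij}$ (natural log, unnormalised by default)
is the scalar heterogeneity measure; it is bounded by $\log k_{max}$ and
shrinks at a vertex when its neighbours' expression becomes more uneven.

Geometric weights follow a *resistance quasimetric*: likely interactions
should be short. The edge weight is the inverse of the symmetrised
transition probability, $w(e_{ij}) = 1 / \bar p_{ij}$ with
$\bar p_{ij} = (p_{ij} + p_{ji})/2$ by default (`min` and `max` are
options). Vertex weights default to $\pi_v$, so the measure that weights
the global curvature average and the vertex weights of the curvature
formula coincide; raw expression $x_v$ is available as an alternative and
the choice is results-sensitive. Face weights derive from the three
boundary-edge weights; the default $(w_1 w_2 w_3)^{2/3}$ is the squared
geometric mean, giving faces the dimension of an edge weight squared
(area-like). `product`, `mean` and `max` rules are provided. These
conventions (symmetrisation, vertex-weight source, face rule) are the
genuinely open design points of the weighting scheme; each is exposed in
`weighting_config()` rather than hard-coded, and the defaults are the
choices we consider most defensible, not the only reasonable ones.

A pseudocount (default $10^{-3}$, added after the optional
$\log(1 + \mathrm{CPM})$ transform in `normalize_expression()`) keeps
every expression value strictly positive, which guarantees positive
probabilities on all skeleton edges and hence finite positive weights
throughout.

## Forman-Ricci curvature

On a weighted complex, Forman's combinatorial curvature of an edge $e$
balances the weights of its faces and endpoints against its *parallel*
edges — edges sharing a face or a vertex with $e$, but not both:

$$\mathbf{F}(e) = w(e)\left[\sum_{f > e}\frac{w(e)}{w(f)}
  + \sum_{v < e}\frac{w(v)}{w(e)}
  - \sum_{e_i \parallel e}\left|\sum_{f > e, e_i}
      \frac{\sqrt{w(e) w(e_i)}}{w(f)}
  - \sum_{v < e, e_i}\frac{w(v)}{\sqrt{w(e) w(e_i)}}\right|\right]$$

The 1D (graph) form drops every face term, leaving vertex and
vertex-sharing parallel terms only; with unit weights it reduces to the
familiar $4 - \deg(u) - \deg(v)$.

Two structural facts simplify the 2D computation without changing its
value, and both are exploited by the optimised path and verified against
a naive literal evaluator in the tests:

* with triangular faces, two edges sharing a face always share a vertex,
  so the parallel set of $e$ is exactly the edges meeting $e$ in one
  vertex with no common face;
* for such parallels the inner face sum is empty, so each contributes
  $w(v_{shared}) / \sqrt{w(e) w(e_i)}$.

The shared-face inner sum $\sum_{f > e, e_i}$ is read as faces incident
to both edges. Adding a face can therefore only add positive face terms
and remove parallel terms from its boundary edges — a face strictly
raises the curvature of the edges it spans, which is the local form of
the observed positive shift of 2D relative to 1D curvature.

Per-edge values contract to vertices,
$\mathbf{F}(v) = \frac{1}{\deg(v)}\sum_{e_v \sim v} \mathbf{F}(e_v)$ with
$\deg$ the incident-edge count (the literal reading, since the sum runs
over incident edges; a face-degree or weighted-degree reading would
change only the scale of hub vertices), and then to the per-sample scalar
$\mathbf{F}_{GA} = \sum_i \pi_i \mathbf{F}(v_i)$.

Accumulation follows the lexicographically sorted edge order, so results
are deterministic and invariant to input permutation; numerical
comparisons in the tests use $10^{-9}$ absolute tolerance (oracle
equivalence is asserted at $10^{-10}$).

## Group statistics

`differential_table()` applies a two-sided Wilcoxon rank-sum test per
gene with BH correction. The per-gene test is our choice, made for
consistency with the group-level testing convention (rank-sum), not a
claim about any particular published analysis; the reported `delta` is
`mean(B) - mean(A)`. `roc_auc()` is the rank-based (Mann-Whitney) AUC
with ties counting one half, and `delong_compare()` tests the difference
of two paired AUCs with DeLong's covariance (via pROC). Gene-set
overrepresentation (`enrichment()`) is the one-sided hypergeometric tail
against any GMT collection, BH-corrected across sets, with the mean
curvature shift of the overlapping genes reported alongside; up- and
down-shifted hit lists are analysed separately in the CLI, and redundant
overlapping sets are reported as-is.

## Synthetic data

The generators exist so that every pipeline stage is testable without
external downloads; they do not emulate any specific dataset.

* `synthetic_network(n, k, t, d, seed)` draws
  $m = nk/2$ edges: a uniform $G(n, m)$ fraction and a wedge-closure
  fraction $t/(1+t)$ that picks an open two-path (centre chosen in
  proportion to its open-wedge count) and closes it. At $t = 0$ the
  output is exactly uniform $G(n, m)$, so the triangle count sits at the
  random-graph expectation; increasing $t$ raises triangles monotonically
  and concentrates closures on hubs, giving a right-skewed degree
  distribution. We chose this over a preferential-attachment growth
  process because it makes the zero-enrichment case coincide exactly with
  the Erdős–Rényi null that the topology comparisons use, at the cost of
  a milder degree skew than a scale-free generator would give.
* `synthetic_expression()` draws negative-binomial counts
  (overdispersion 0.3, log-normal baseline means, defaults 200 genes and
  50 samples per group) and multiplies the group-B mean of a planted gene
  subset by `effect_size` (default 4) *before* normalisation, so the
  normalisation path is exercised.

What passing tests show — and what they do not: recovery of planted
multiplicative shifts demonstrates that the weighting-curvature-testing
chain transmits localised expression changes into vertex-curvature
changes of the right neighbourhoods. Real single-cell data add dropout,
batch structure, correlated modules and much larger networks; none of
these are emulated, so power figures measured here do not transfer to
real data.

## Numerical choices and degenerate inputs

* Self-loops are dropped on load; duplicate pairs collapse to the
  maximum score; reciprocal arcs collapse to one skeleton edge (topology
  and curvature are computed per undirected edge; arc directions only
  classify face orientation).
* Isolated vertices: excluded from vertex curvature; the transition
  matrix flags them and the stationary solver refuses disconnected or
  isolated-vertex chains, directing the user to
  `restrict_network(keep_largest_component = TRUE)`.
* The power-law fit requires at least three occupied bins, drops zero
  bins, and reports $r^2 = 0$ for a constant response.
* STRING-style inputs: both tab- and space-delimited files parse; the
  score cutoff defaults to 400 (the conventional medium-confidence
  threshold) but the column and cutoff are explicit arguments, since
  score channels differ between releases.
* The 1D Euler characteristic is always computed from the definition
  $|V| - |E|$; printed summary tables are never taken over the identity.

## Problem sizes

The shipped tests run the full-scale random-graph comparison (11,888
vertices, 315,130 edges, three seeds) in seconds via sparse triangle
counting, and exercise the curvature pipeline end-to-end on synthetic
networks of about a hundred vertices with tens of samples, which we chose
as the smallest sizes at which the group-level statistics are
well-powered. All generators and analyses are deterministic given their
seed arguments.

## A worked example

```{r example, eval = FALSE}
net <- synthetic_network(100, 6, triangle_enrichment = 1.5, seed = 1)
net <- restrict_network(net, net$vertices)
cx <- build_complex(net)
topology_summary(cx)

spec <- synthetic_spec(n_per_group = 25, n_planted = 10, effect_size = 4,
                       seed = 2)
sim <- synthetic_expression(spec, genes = net$vertices)
expr <- normalize_expression(sim$matrix, "cpm_log1p")
prof <- curvature_by_sample(cx, expr)
head(prof$summary)

tab <- differential_table(prof$vertex_2d[, sim$labels$group == "A"],
                          prof$vertex_2d[, sim$labels$group == "B"])
head(tab[order(tab$q_value), ])
```

## Known limitations

* Faces stop at triangles: tetrahedra and larger cliques, and
  non-simplicial hypergraph cells, are out of scope.
* Ollivier-Ricci curvature and discrete Ricci flow are not implemented.
* The weighting scheme's open conventions (symmetrisation, vertex-weight
  source, face rule) change absolute curvature values; comparisons should
  hold them fixed.
* Expression is used as a proxy for protein abundance; no kinetic rate
  constants or post-transcriptional effects enter the model.
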