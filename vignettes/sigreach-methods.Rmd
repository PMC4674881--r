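---
title: "Characterizing probabilistic signaling networks by signal reachability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing probabilistic signaling networks by signal reachability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sigreach)
```

## The model

A signaling network carries a signal from receptor proteins at the cell
membrane, through intermediate proteins, to reporter proteins (typically
transcription factors). Interaction data are uncertain: whether a given
interaction is present may differ between cells, or in one cell over time.
`sigreach` therefore models a network as $G = (V, E, P)$ — a directed graph
with an edge existence probability $P : E \to [0,1]$ — together with a
source set $S \subseteq V$ (receptors) and a target set $T \subseteq V$
(reporters). Edges are assumed independent, so $G$ summarizes $2^{|E|}$
*deterministic instances*: each subset of present edges occurs with
probability $\prod_{e\,\text{present}} P(e) \prod_{e\,\text{absent}} (1 -
P(e))$.

The central quantity is the **reachability probability**
$P_{reach}(G, S, T)$: the total probability mass of instances that contain
a directed path from some node of $S$ to some node of $T$. A node in
$S \cap T$ counts as a zero-length path. Everything else in the package —
centrality, stability, functional characterization — is defined in terms of
this quantity.

## Exact reachability: the xy-polynomial

Naively summing over $2^{|E|}$ instances is hopeless beyond toy networks.
`reachability()` instead multiplies, one edge at a time, the binomial
$p_e x_e + (1 - p_e) y_e$ into a growing polynomial whose non-free terms
each record one partial configuration (the subset of *processed* edges
assumed present) with its probability, and whose two free coefficients $b$
and $c$ accumulate the mass of configurations already decided *reachable*
and *unreachable*. After every multiplication two collapse rules are
applied:

* **path rule** — if a term's present edges already contain an $S \to T$
  path, its coefficient moves to $b$ (later edges cannot un-reach it);
* **cut rule** — if a term's absent edges form a cut, i.e. even with every
  undecided edge present no path exists, its coefficient moves to $c$.

Total probability $b + c + \sum_i a_i = 1$ is conserved exactly at every
step, and after the last edge every instance is decided, so the answer is
$b$ with $b + c = 1$. The worst case is still exponential (a configurable
live-term cap, default $2^{22}$, turns pathological inputs into a clean
resource error), but collapsing keeps the polynomial small on
signaling-like topologies.

### Numerical and algorithmic choices

* **Edge order.** The product is commutative, so the result is
  order-invariant (a tested property, to $10^{-12}$). The default order is
  breadth-first from the sources with ties broken by input index, which
  lets path/cut decisions trigger as early as possible; this is purely a
  performance choice.
* **Pruning.** An edge whose tail is unreachable from $S$ (over all edges)
  or whose head never reaches $T$ cannot lie on any $S \to T$ path;
  marginalizing it out multiplies every term by $p_e + (1-p_e) = 1$.
  Such edges are dropped before the polynomial is built.
* **Set queries.** The path and cut checks are defined on node *sets*, so
  `reachability()` takes $S$ and $T$ directly. The classical reduction —
  a virtual super-source and super-sink wired with probability-1 edges,
  `augment_terminals()` — is also provided, and the test suite asserts the
  two routes agree; probability-1 edges can never change the answer.
* **Implementation.** `reachability()` holds the live terms as one
  term × edge presence matrix and computes the path/cut verdicts for all
  terms together by vectorized fixed-point sweeps over the columns. The
  exported step-by-step primitives (`xy_polynomial()`,
  `multiply_binomial()`, `collapse_polynomial()`) apply the same rules one
  term at a time; the test suite asserts that stepping them by hand
  reproduces the engine's result exactly.
* **Floating point.** Coefficients are doubles, not rationals; conservation
  is asserted to $10^{-12}$ in debug mode, and the enumeration oracle
  `reachability_bruteforce()` (full $2^{|E|}$ enumeration with a vectorized
  fixed-point closure, an entirely separate code path) agrees with the
  polynomial to $10^{-10}$ on random networks.

## Probabilistic node centrality

A node $v$ is *essential* for a pair $(s, t)$ in an instance if deleting
$v$ disconnects $s$ from $t$. Its essentiality probability is the
reachability drop on removal,
$C_v(G, s, t) = P_{reach}(G, s, t) - P_{reach}(G', s, t)$ with $G'$ the
network without $v$; removal can only destroy paths, so $C_v \ge 0$
(floating-point negatives within $10^{-9}$ are clamped, anything larger is
an internal error). The per-pair indicators are Bernoulli with these
parameters, so the number of pairs for which $v$ is essential follows a
Poisson-binomial distribution, and the centrality is its mean — by
linearity simply $E[X_v] = \sum_{s \in S, t \in T} C_v(G, s, t)$.

Pairs with $v \in \{s, t\}$ are **excluded** by default: essentiality
formalizes relay importance, and counting a receptor as essential for its
own pairs would give every terminal node a trivially inflated score. The
`include_terminal_pairs` switch restores them (counted at the pair's full
reachability) for users who prefer the inclusive convention.

For comparison, `deterministic_betweenness()` computes conventional
unweighted shortest-path betweenness on the directed topology with every
edge certain, normalized by $(|V|-1)(|V|-2)$, and `rank_disagreement()`
counts, per node, the fraction of other nodes whose relative order flips
between the two rankings (ties count as agreeing; rankings are made
deterministic by breaking score ties on the node identifier).

## Network stability

A network is stable if small random perturbations barely change its
capacity to deliver signals. The stability statistic is the mean
reachability change over all pairs,
$\frac{1}{|S||T|} \sum_{s,t} \left[ P_{reach}(G^\delta, s, t) -
P_{reach}(G, s, t) \right]$; the magnitude measures instability, the sign
its direction (negative: the cell goes unresponsive; positive:
over-sensitive). Two perturbation models are provided:

* **Probability model.** Each edge probability is independently redrawn
  uniformly on $[P(e) - \delta, P(e) + \delta] \cap [0, 1]$. This is a
  *truncated* uniform — the draw happens inside the intersected interval —
  not a draw-then-clamp, which would place point mass at 0 and 1. At
  $\delta = 0$ the interval is degenerate and the probabilities are
  unchanged exactly. For an edge with $p > 1 - \delta$ truncation pulls the
  expected value strictly below $p$, which is why all-high-confidence
  networks show strictly negative mean changes.
* **Topology model.** Degree-preserving edge shuffling: each swap picks two
  random edges $(u_1, v_1), (u_2, v_2)$ and replaces them with
  $(u_1, v_2), (u_2, v_1)$, reassigning the two old probabilities in random
  order. With $\delta$ the fraction of edges shuffled and two edges
  consumed per swap, `round(delta * |E| / 2)` swaps are performed
  (configurable via `swaps`). Swaps that would create a self-loop or
  duplicate edge are rejected and resampled, with a retry budget of 100 per
  requested swap; exhaustion is reported with the achieved swap count. In-
  and out-degree sequences and the probability multiset are invariant.

`stability_curve()` runs a replicate batch per $\delta$; the replicate
count is a free parameter (default 30, always reported in the output), and
each (grid point, replicate) gets its own RNG sub-stream derived from one
master seed, so curves reproduce bit-for-bit.

## Functional characterization

Annotation terms attached to the network's proteins describe candidate
functions. Two orthogonal statistics are computed.

**Enrichment among the most reachable targets.** Targets are ranked by
their set-source reachability $P_{reach}(G, S, \{t\})$ (ties broken by
identifier so the ranking is deterministic). For a term annotating $N$
targets, every cutoff $d \in \{1, \dots, |T|\}$ is tried: with $n$
annotated targets among the top $d$, the enrichment value at $d$ is the
hypergeometric upper tail $P(X \ge n \mid |T|, d, N)$, computed by direct
summation of the mass from $n$ to $\min(N, d)$; the reported enrichment is
the minimum over $d$. Terms at or below 0.1 are flagged highly enriched.
No multiple-testing correction is applied — the raw threshold is the
convention this analysis follows, and the planted-signal tests calibrate
against it.

**Term reachability.** A term $a$ annotating source subset $S_a$ and
target subset $T_a$ gets $P_{reach}(G, S_a, T_a)$; a term annotating no
source or no target is *not applicable* (`NA`), which is deliberately
distinct from a reachability of 0.

Shallow ontology terms are generic (they annotate nearly everything), so
`filter_generic_terms()` drops the top five levels — depths 0 through 4,
where depth is the shortest is-a/part-of chain from a root and roots have
depth 0. Level counting is not universal, so the boundary is a
`max_generic_depth` parameter; terms without depth information are kept
with a warning, making the filter an optional preprocessing step.
Annotations are used exactly as given — no propagation to ancestor terms is
performed.

The matrix views, `protein_term_matrix()` (every protein × every
target-annotated term) and `protein_protein_matrix()` (every ordered
protein pair), use the zero-length-path convention, so a protein reaches
itself and any term it is an annotated target of with probability 1.
`cluster_matrix()` clusters rows with Euclidean distance and average
linkage by default — generic hierarchical clustering choices, exposed as
parameters (`distance = "correlation"` is the common alternative) since no
single convention is canonical for reachability profiles.

## The synthetic generator

`generate_network()` emulates the receptor → intermediate → reporter
layering of a signaling pathway: three node layers, independent
between-layer edges at a configurable density (default 0.4), uniform edge
probabilities (default on $[0.2, 0.95]$, a spread comparable to normalized
interaction-confidence scores), and a connectivity guarantee that every
reporter is topologically reachable. A planted high-reachability signal can
be injected by boosting the in-paths of a chosen number of targets
($p \leftarrow p + \beta (1 - p)$, default $\beta = 0.5$);
`generate_annotations()` then assigns background terms (1–4 per gene from a
pool of 8) plus a planted term on the top-reachability targets and one
source.

What the generator does **not** emulate: cycles and feedback loops (the
reachability math does not require acyclicity, but the default topology is
a layered DAG), hub/scale-free degree structure, correlated edge
probabilities, and within-layer interactions. Passing tests therefore
demonstrate correctness of the computations and recoverability of planted
signals under clean layered conditions — not that real pathway data,
with feedback and correlated confidence scores, will behave as cleanly.

## Problem sizes and test design

The oracle suites compare the polynomial against exhaustive enumeration on
random directed networks with up to 10 nodes and 14 edges (200 networks),
where $2^{|E|}$ enumeration is itself exact; order invariance uses 50
networks × 5 random orders; hypergeometric tails are checked against
exhaustive subset enumeration for every configuration with up to 12
targets; planted-enrichment recovery uses 100 seeded network+annotation
pairs with 3 of 10 targets planted. These sizes make every reference value
exactly computable while exercising all code paths; the engine itself
comfortably handles the larger, pruned queries the synthetic pathways
produce.

## Known limitations

* Exactness is worst-case exponential; dense networks with wide cuts can
  hit the live-term cap. No Monte-Carlo fallback is provided.
* Edge independence is assumed throughout, as in the underlying model;
  correlated uncertainties are out of scope.
* All edges are treated as directed; undirected interaction data must be
  pre-expanded into edge pairs by the user.
* Deterministic betweenness is one comparison convention (directed,
  unweighted, $(|V|-1)(|V|-2)$ normalization); other conventions would
  shift ranks without affecting the probabilistic measure.
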