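---
title: "Spanning-tree brain network similarity and spectral clustering"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spanning-tree brain network similarity and spectral clustering}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mstClust)
```

## The problem

Resting-state fMRI reduces each subject to a functional connectivity
network: regions of interest as nodes, Pearson correlations of their
BOLD time series as edge weights. Disorders such as Alzheimer's
disease, schizophrenia and bipolar disorder are associated with
reorganization of this network — in particular with alterations of its
hubs — so one can ask whether subjects separate into diagnostic groups
*by network topology alone*. `mstClust` implements an unsupervised
answer: a pairwise network similarity that fuses a node-attribute view
with a topological view, followed by spectral clustering of the
subject-by-subject similarity matrix.

## The model

### Spanning-tree network construction

Thresholding a correlation matrix into a binary graph forces an
arbitrary cutoff, and different cutoffs give different graphs. We avoid
the choice by reducing each subject's full correlation network to a
spanning tree with descending-weight Kruskal: sort all off-diagonal
weights in decreasing order, link greedily, skip any edge that would
close a loop, stop at $n-1$ edges. The result is the maximum-weight
spanning tree of the correlation network — the strongest backbone that
still connects every region. Conventions fixed here, where the
procedure itself is silent:

* ties between equal weights are broken lexicographically by
  (smaller node index, larger node index), for determinism;
* negative correlations are kept as-is and simply sort last — no
  absolute-value transform;
* an exactly zero weight is treated as an absent edge (this is what
  the edge-list input format produces), so genuinely sparse inputs can
  be reported as disconnected rather than silently completed.

The 32-label preset `dmnRegions()` (16 bilateral AAL structures of the
default mode network) is shipped for node labeling only.

### Attribute similarity: betweenness profiles

On a tree, every pair of nodes has a unique path, and a node's
betweenness

$$b_i = \frac{1}{(n-1)(n-2)} \sum_{\substack{h \ne j\\ h,j \ne i}}
  \frac{\rho_{hj}^{(i)}}{\rho_{hj}}$$

is the fraction of ordered pairs of other nodes whose path crosses it.
The sum is taken over *ordered* pairs: with the $(n-1)(n-2)$
normalization this is the only reading under which the center of a star
scores exactly 1, which anchors the scale. The path-count denominator
$\rho_{hj}$ is retained (shortest-path counts via breadth-first search)
so the same function is correct on graphs with cycles; the test suite
exercises that on a 4-cycle. Betweenness is computed on the unweighted
tree topology — hop counts, not correlation weights.

Two networks are then compared by the cosine of their betweenness
vectors, which is in $[0,1]$ because betweenness is nonnegative, and is
invariant to common positive scaling. A tree with $n \ge 3$ always has
an internal node, so the vectors are never all-zero.

### Structure similarity: the sub-network kernel

The attribute view is global and can miss local rewiring, so it is
complemented by a kernel that compares the two networks node by node at
multiple scales. For node $i$ and radius $j = 1..h$, take the induced
subgraph on all nodes within hop distance $j$ of $i$ (these balls are
nested and reach the whole tree once $j$ exceeds the diameter). Each
ball with adjacency $W$ and node count $N$ is summarized by the
$d \times d$ sample covariance matrix of its normalized Krylov power
iterations

$$u_p = N\, \frac{W^p e}{\lVert W^p e\rVert_1}, \qquad p = 1..d,$$

covariances taken across node positions with denominator $N-1$. The
power-0 vector $e$ is constant and would contribute zero covariance, so
the descriptor uses powers $1..d$, giving the stated $d \times d$ shape.
The scaling by $N$ makes each $u_p$ average to one, so descriptors of
differently sized balls live on a common scale. Sub-network adjacency
is binary by default (the tree is an unweighted graph after
construction); a `weighted` switch carries the correlation weights
instead for users who want them.

Two same-node, same-radius balls are compared through log-determinants:
with $A = (C_G + C_H)/2$,

$$g(G_i^j, H_i^j) =
  \exp\!\left(-\tfrac12\big(\log|A| - \log|C_G| - \log|C_H|\big)\right).$$

This is the default `as_printed` form. Note its self-similarity is
$|C|^{1/2}$, not 1 — the exponent lacks the factors $\tfrac12$ that
would make it the symmetric S-divergence
$\log|A| - \tfrac12\log|C_G| - \tfrac12\log|C_H| \ge 0$. Both readings
are implemented (`variant = "s_divergence"` selects the second); the
default keeps the first because the subsequent normalization step makes
the two differ only mildly in practice: the kernel
$k(G,H) = \frac1n \sum_i \frac1h \sum_j g(G_i^j, H_i^j)$ is passed
through

$$s_{norm}(X,Y) = \frac{s(X,Y)}{\sqrt{s(X,X)\,s(Y,Y)}},$$

after which self-similarity is exactly 1 in either variant. For the
`as_printed` form the determinant inequality
$|A| \ge \sqrt{|C_G||C_H|}$ plus Cauchy–Schwarz over the node/radius
averages guarantees all normalized entries stay in $(0,1]$; the suite
checks this on random cohorts. No positive-semi-definiteness claim is
made for either variant — the kernel is used as a similarity score,
not fed to a kernel machine.

### Fusion and spectral clustering

The two (normalized, unit-diagonal) similarity matrices are fused as a
convex combination $s = \delta\, s_{att} + (1-\delta)\, s_{str}$; the
endpoints $\delta = 1$ and $\delta = 0$ are exactly the
attribute-only and kernel-only baselines. Clustering follows the
standard normalized spectral recipe: $L = D^{-1/2} S D^{-1/2}$ with $D$
the diagonal of row sums, top-$m$ eigenvectors stacked as columns,
rows renormalized to unit length, k-means on the rows.

The consistency of a clustering against diagnostic classes is the
maximum, over one-to-one cluster-to-class assignments, of the matched
count divided by $n$ — for $m = 2$ simply
$\max(T_{11}+T_{22},\, T_{12}+T_{21})/n$. The assignment is solved
exhaustively over injections, which is exact and instant for the small
$m$ used here (an assignment-algorithm backend would only matter for
$m$ well beyond 8).

`parameterSweep()` grids $\delta$, $h$ and $d$ and scores every point
by consistency. Because consistency consumes the diagnostic labels,
the sweep is a *supervised evaluation* protocol — useful for mapping
how the similarity behaves, circular if reported as unsupervised
performance. Single-parameter `clusterCohort()` is the primary
unsupervised mode, and the package keeps the two clearly apart.

## Parameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `delta` | weight of attribute vs structure similarity, dimensionless in $[0,1]$ | 0.5 | grid `seq(0.1, 0.9, 0.1)` in sweeps |
| `h` | maximum sub-network radius (hops) | 2 | grid 1..3; small radii emphasize local topology |
| `d` | Krylov power iterations (descriptor size $d\times d$) | 3 | grid 3..8; results are typically flat in $d$ |
| `ridge` | diagonal added to each descriptor | 1e-6 | see below |
| `m` / `clusters` | number of clusters | 2 | patients vs controls |
| `seed` | k-means / generator seed | — | fixes all randomness |

## Numerical choices

* **Ridge regularization.** Covariance descriptors of small or regular
  balls are exactly singular (a $k$-regular subgraph has constant
  power vectors, hence a zero covariance matrix), which makes the
  log-determinant undefined. Every descriptor therefore receives
  `ridge`·I, default $10^{-6}$: large enough to make Cholesky
  factorization reliable, small enough to leave non-degenerate
  covariances (typically of order $10^{-2}$ and larger) untouched.
* **Log-determinants** come from Cholesky factors, never from raw
  determinants (which underflow already at $d = 3$ for ridge-dominated
  matrices); a factorization failure is reported as a
  non-positive-definite descriptor with the advice to raise `ridge`.
* **Eigenvector ambiguity.** Eigenvalues are sorted in decreasing
  order and each eigenvector's sign is fixed so its first nonzero
  component is positive, making the embedding — and with a fixed seed
  the whole clustering — reproducible run to run. A row of the
  embedding that is exactly zero is left unnormalized (with a warning)
  instead of dividing by zero.
* **k-means** is `stats::kmeans` with 50 restarts, 300 iterations and
  a fixed seed. The restart count is the robustness knob; with the
  separable embeddings produced here, restarts agree.
* **Degenerate inputs** are rejected with named offenders: regions
  with zero variance, fewer than 3 time points, disconnected sparse
  graphs (components reported), similarity matrices with nonpositive
  diagonal, zero row sums.

## The synthetic cohort generator

`plantedTreeCohort()` emulates the statistical structure the pipeline
consumes — cohorts of spanning-tree networks with group-specific
topology — without simulating fMRI acquisition. Group templates are
hub-position/dispersion contrasts: group 0 keeps a star-like template
with a dominant hub; the last group relocates
$\mathrm{round}(\mathrm{effect}\cdot(n-1))$ hub edges into chains,
yielding a dispersed, path-like template ($\mathrm{effect}=0$ makes
all templates identical). This contrast was chosen because both halves
of the similarity — betweenness profiles and sub-network descriptors —
are sensitive to hub placement, mirroring the clinical finding that
brain disorders preferentially hit network hubs. Each subject then
applies independent per-edge relocations at rate `noise` (remove the
edge, reconnect the two components at a random cross pair, which
provably keeps a spanning tree). Defaults — 32 nodes, 2 × 20 subjects
— match the scale of a DMN study with tens of subjects per arm.

`plantedTimeseriesCohort()` adds the step before network construction:
node signals follow a Gaussian tree-Markov process in which each
template edge carries correlation `edgeCor` (default 0.7), so region
pairs correlate as $\mathrm{edgeCor}^{\mathrm{hop\ distance}}$ and the
maximum-weight spanning tree of the exact correlation matrix *is* the
template. Subjects draw $T = 5n$ time points (default) plus white
observation noise; with long series the sample-correlation pipeline
recovers the planted tree, which the suite verifies.

What the generator does **not** emulate: hemodynamics, motion and
scanner artifacts, spatially correlated noise, site effects, unbalanced
groups, and networks whose group difference is *not* tree-representable
(e.g. pure edge-weight shifts at identical topology). Passing the
planted-cohort tests therefore demonstrates the pipeline's correctness
and its sensitivity to topological contrasts, not clinical
performance on real cohorts.

## Validation scale

The bundled checks run the full pipeline on cohorts of 40 subjects at
32 nodes (five signal cohorts at effect 0.8/noise 0.05, ten null
cohorts at effect 0), with oracle comparisons — exhaustive path
enumeration for betweenness, exhaustive spanning-tree enumeration at
$n = 5$, a naive loop re-implementation of the kernel, brute-force
assignment for consistency — on networks up to 12 nodes. These sizes
make every oracle exact and keep a full run in the minutes range;
they are the package's validation design, and larger cohorts scale as
$O(N^2)$ pairs times $O(n \cdot h \cdot d^3)$ per kernel evaluation.

## Known limitations

* The `as_printed` kernel variant is not a proper normalized kernel
  before the cosine normalization step; interpret raw `subnetworkKernel()`
  values only relatively.
* The betweenness attribute is the package's only node attribute by
  design; degree, eccentricity or leaf fraction are out of scope.
* Spanning-tree reduction discards all edge-weight information beyond
  the tree (edge weights are retained in the output for inspection but
  not used by the similarity, except via the optional `weighted`
  subgraph switch).
* The supervised sweep optimizes consistency against the labels it is
  evaluated with; treat its argmax as exploratory, not as an unbiased
  performance estimate.
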