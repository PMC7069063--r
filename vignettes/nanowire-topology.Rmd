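---
title: "Simulating and measuring the topology of self-assembled nanowire networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and measuring the topology of self-assembled nanowire networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(asntopo)
```

## The model

Self-assembled nanowire networks are made by dropping metallic
nanowires onto a substrate; wherever two wires cross, the junction acts
as a synapse-like switching element. `asntopo` models this structurally
and only structurally: no junction conductance, no dynamics, no
training. A deposition is parameterised by

| parameter | meaning | unit | default |
|---|---|---|---|
| `n_wires` | wires dropped on the plane | count | — |
| `mean_length` | mean of the wire-length distribution | μm | 7 |
| `dispersion` | sd / mean of wire length, in [0, 1] | — | 0 |
| `plane_width`, `plane_height` | deposition plane | μm | 30 × 30 |
| `seed` | RNG seed | — | 1 |

Wire lengths are normal with mean `mean_length` and sd
`dispersion * mean_length`; "dispersion" as a sd-to-mean ratio only has
meaning for a location–scale family, which is why the normal is used,
with non-positive draws rejected and redrawn (at a dispersion of 50%
about 2.3% of draws are rejected, which inflates the realised mean
slightly — an accepted property of truncation by rejection). Midpoints
are uniform on the plane and orientations uniform on [0, 2π). Only
midpoints are constrained to the plane: wires may overhang the edge,
since clipping would distort the length distribution.

Every pairwise segment intersection becomes a junction (the simplifying
assumption of structural studies of these systems), and the network is
the graph with one node per wire and one edge per intersecting pair.
Two conventions cover measure-zero geometric events: endpoints touching
within 10⁻⁹ μm count as an intersection, and collinear overlapping
segments produce **no** junction (a contact line has no unique
intersection point) but raise a warning.

The expected junction count for a random deposition is the Buffon-type
crossing estimate

$$E[\text{junctions}] \approx \frac{n(n-1)\,\bar l^2}{\pi W H},$$

exact on an unbounded homogeneous plane. On a bounded plane wires
overhang the edge and realised counts fall ~10–13% short at the default
geometry; the test suite checks the simulated mean against this
estimate within ±15%.

## Reference families

* **Watts–Strogatz**: a ring lattice (`n` nodes, `k` neighbours per
  side) whose edges are independently rewired with probability β,
  rejecting self-loops and duplicates, so the edge count `n·k` is
  invariant. The generator is written in-package because a rewiring
  that can emit loops or multi-edges (and then simplifies) would break
  that invariant. β = 0 is the deterministic "grid-like" lattice; β = 1
  a random graph. Degree matching to a target network uses
  `k = round(mean degree / 2)` with banker's rounding and a floor of 1.
* **Layered ANN**: the undirected topology of a fully-connected
  feed-forward network — complete bipartite between consecutive layers,
  nothing within a layer. Triangle-free by construction, so every
  clustering coefficient is exactly 0.
* **Connectomes**: two-column edge lists or adjacency matrices,
  symmetrised, binarised, self-loops dropped. Weights are never used by
  the metrics. A `synthetic_connectome()` generator builds a connected
  modular graph of any requested size with a tunable hub minority; the
  bundled fixture (`inst/extdata/synthetic_connectome_edges.tsv`) is
  such a synthetic object, not biological data.

## Metric conventions

All global metrics are computed on the **largest connected component**
(LCC), and every result carries the excluded-node fraction. This
avoids infinite path lengths in fragmented graphs at the cost of
describing only the dominant fragment — which matters for sparse
depositions (see Limitations).

* **Path length**: BFS hop counts over all unordered LCC pairs; mean
  and SD over pairs.
* **Clustering**: node-wise local clustering (triangle fraction),
  degree < 2 scoring 0, averaged over nodes — not the global
  transitivity ratio.
* **Small-world propensity**:
  $\phi = 1 - \sqrt{(\Delta_C^2 + \Delta_L^2)/2}$ with
  $\Delta_C = (C_{latt}-C_{obs})/(C_{latt}-C_{rand})$ and
  $\Delta_L = (L_{obs}-L_{rand})/(L_{latt}-L_{rand})$. The lattice null
  is a ring lattice with matched node count and `k`; the random null
  averages `n_null = 10` Erdős–Rényi G(N, M) draws with matched node
  and edge counts. Ten draws keep the null mean's sampling error well
  below the 10⁻² scale at which φ is read. Both deltas are **floored at
  0 before clamping to 1**: a deficit is non-negative by definition,
  and without the floor a sparse network whose matched lattice is a
  bare cycle (k = 1, zero clustering) would be charged a *maximal*
  clustering deficit exactly when it out-clusters its lattice null.
  Exactly degenerate nulls (lattice = random) set the corresponding
  delta to 0 with a warning. A ring lattice input reproduces the
  analytic limit φ = 1 − 1/√2 ≈ 0.293 ($\Delta_C = 0, \Delta_L = 1$),
  and a random graph the mirror case — both verified in the tests.
* **Cartography**: Louvain modularity maximisation (resolution 1),
  seeded for determinism, module ids contiguous from 1. Participation
  coefficient $P_i = 1 - \sum_s (k_{is}/k_i)^2$ with isolated nodes at
  0; within-module degree z-score uses the **population** sd of
  within-module degrees, zero-variance modules giving z = 0 for all
  members — hence each module's (and the network's) mean z is exactly
  0. The seven-region classification is total and deterministic:
  hubs at z ≥ 2.5 split at P = 0.30 / 0.75; non-hubs at P = 0
  (ultra-peripheral), (0, 0.62), [0.62, 0.80), ≥ 0.80; boundaries
  belong to the upper region so every (P, z) point has exactly one
  label.

## Seeds and reproducibility

Every stochastic operation takes an explicit seed and restores the
caller's RNG state. Ensembles derive one seed per member from a master
seed by a counter-based modular recurrence (`derive_seed()`), so a
whole sweep is bit-reproducible and any single member can be
regenerated in isolation. β = 0 lattices and the layered ANN are
deterministic regardless of seed.

## Problem sizes used in the test suite

The suite exercises depositions of up to 500 wires and ensembles of 16
networks per size (the full 4 mean-lengths × 4 dispersions grid, one
replicate); `scripts/acceptance.R` uses two replicates (32 networks per
size). Oracle comparisons (brute-force pairwise intersection,
Floyd–Warshall all-pairs distances, exhaustive partition search) run on
graphs of ≤ 80, ≤ 50 and ≤ 9 nodes respectively, where the oracles are
exact and fast. These sizes were chosen to keep the suite quick while
leaving every code path and invariant covered; the simulator itself
handles thousands of wires (pairwise intersection is vectorised and
chunked).

## Limitations and observed behaviour

* **Percolation of sparse depositions.** For sticks of length *l* at
  density ρ (wires per unit area), connectivity percolates near
  ρl² ≈ 5.6. One hundred wires of length 6–7 μm on a 30 × 30 μm plane
  sit at ρl² ≈ 4.0–5.4 — below or at threshold — so their largest
  component holds only a few dozen wires. Ensemble means over a
  parameter grid that includes such corners mix fragmented,
  lattice-scoring networks (φ ≈ 0.29) with well-connected small-world
  ones (φ ≈ 0.6–0.75), and are therefore substantially lower and more
  seed-variable than means over uniformly dense ensembles. Path-length
  means react the same way: sparse 500-wire depositions (l = 6,
  dispersion 0) reach mean path lengths near 5.8 while dense ones
  (l = 9, dispersion 0.5) sit near 3.0.
* **Boundary effects** depress junction counts ~10–13% below the
  unbounded-plane estimate at the default geometry; no correction is
  applied because the deposition model is taken literally.
* **Partition dependence.** Participation-coefficient summaries depend
  on the granularity of the modularity partition; Louvain at
  resolution 1 on spatially embedded graphs yields compact modules and
  hence conservative (low) participation means. Comparisons across
  studies using different community detectors should expect offsets of
  order 0.1.
* Weighted variants of the metrics are deliberately out of scope: the
  deposition model is binary, and mixing conventions would make the
  family comparisons incoherent.
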