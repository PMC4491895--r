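---
title: "Joint-recurrence weighted residue networks: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint-recurrence weighted residue networks: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jrpnet)
```

## The model

Protein residue interaction networks rank residues by how central they
are to the flow of "information" through a structure: nodes are residues
(their Cα atoms), edges are interactions, and betweenness (*B*) and
closeness (*C*) centralities flag residues that control or efficiently
reach the rest of the network. Classical constructions define edges from
a static structure and a distance cutoff, which discards long-range and
solvent-mediated coupling. `jrpnet` instead defines the interaction
strength of a residue pair dynamically, as the number of time pairs at
which both residues *jointly recur* to previously visited states of
their own phase-space trajectories over an MD run.

The chain of operations per residue is:

1. **Delay embedding.** A scalar observable per residue and frame
   (typically the Cα RMSD after removing rigid-body motion) is embedded
   as states $X_i = (Z_i, Z_{i+d}, \dots, Z_{i+(m-1)d})$, giving
   $N_s = N - (m-1)d$ states.
2. **Recurrence matrix.** $R_{ij} = \Theta(\varepsilon - \|X_i - X_j\|)$
   with the Euclidean norm; $\Theta(0) = 1$, so a pair exactly at the
   threshold recurs. The recurrence rate is the fraction of the
   $N_s^2$ matrix cells equal to 1, line of identity included; the
   threshold $\varepsilon$ is calibrated per residue to a 3% rate.
3. **Joint recurrences.** For residues $x, y$, a joint recurrence at
   time pair $(i, j)$ means $R^x_{ij} = R^y_{ij} = 1$. Counts are
   accumulated over the strict upper triangle ($i < j$), excluding the
   self-recurring line of identity, which would add the same constant to
   every pair.
4. **Network.** Edge weight = joint-recurrence count / Cα–Cα distance of
   the pair in the reference structure; no cutoff. Comparison networks:
   unweighted with a 7 Å cutoff (edge weight 1), and contact-weighted
   (per-pair heavy-atom contact counts).
5. **Centralities.** Shortest paths on edge lengths derived from
   weights; raw *B* and *C* per residue, standardized to z-scores.
   Defaults flag $z_B > 2$ and $z_C > 1.5$, and the report annotates
   each significant residue with its significant or user-annotated
   first-degree neighbors.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `target_recurrence_rate` | 0.03 | per-residue recurrence rate the threshold is calibrated to |
| `cutoff_distance` | 7 Å | unweighted comparison network cutoff |
| `z_b_min`, `z_c_min` | 2, 1.5 | significance thresholds on centrality z-scores |
| `n_bins` | `min(16, ⌊√(N/5)⌋)` | bins per marginal for histogram MI |
| `max_lag` | `min(100, N/2 − 2)` | largest delay scanned for the MI minimum |
| `max_dim` | `⌊log10 N⌋ + 1`, in 2..10 | largest embedding dimension examined |
| `fnn_threshold` | 0.01 | FNN fraction below which the orbit counts as unfolded |
| FNN `r_tol`, `a_tol` | 15, 2 | distance-ratio and absolute-size false-neighbor criteria |
| `atom_cutoff` | 4.5 Å | heavy-atom contact distance for the contact network |
| RSA thresholds | 5%, 20% | buried / partially buried / exposed boundaries |

Notes on the less obvious defaults:

* **MI bins.** Mutual information uses equal-width bins over each
  marginal's observed range. The joint histogram has $k^2$ cells; with
  $k = \lfloor\sqrt{N/5}\rfloor$ (capped at 16) each cell expects ~5
  samples, and the positive bias of histogram MI for independent data,
  about $(k-1)^2/2N$ nats, stays near 0.02 — small against the MI
  scale that delay selection discriminates. Substantially larger $k$
  (e.g. $\sqrt N$) leaves ~1 sample per cell and a bias of ~0.1 nats,
  swamping the tail of the MI decay in estimator noise.
* **Delay fallback.** The first *strict* local minimum of the MI
  profile is used. Noise-dominated series can decay monotonically over
  the whole scan range; the conservative fallback is delay 1, flagged
  in the embedding table and the run manifest.
* **`max_dim` and the FNN fallback.** When the FNN fraction never falls
  below the threshold — the expected behavior for stochastic series —
  the selector returns `max_dim`, flagged. That makes `max_dim` the
  dimension noise-like residues are embedded at, so it must be a
  dimension at which neighbor statistics still mean something: with
  $N$ states, nearest-neighbor distances grow as $N^{-1/m}$ of the
  attractor size, and for $m$ beyond about $\log_{10} N + 1$ the
  "nearest" neighbors of a 1000-point noisy series sit at the scale of
  the data cloud itself (about two series standard deviations), at
  which point both the FNN criteria and a 3%-rate recurrence
  neighborhood have stopped being local.
* **FNN distance floor.** A neighbor is false when the one-dimension
  distance increment exceeds `r_tol` times the current distance, or the
  extended distance exceeds `a_tol` series SDs. Exactly periodic
  noiseless signals produce coincident states whose distances are pure
  rounding error; the ratio of two such numbers is meaningless, so the
  ratio test uses `max(distance, 1e-8 × SD)`.

## The synthetic generator

`synthetic_system()` emulates the statistical skeleton of per-residue
RMSD traces, not their physics: each residue is a stationary
unit-variance AR(1) process (default lag-1 autocorrelation 0.9, giving a
correlation time of ~10 frames and hence nontrivial embedding
structure), plus white observation noise (default SD 0.1). Members of a
coupled pair share a latent AR(1) driver with weight `coupling_strength`
$c$; the residue's own component is scaled by $\sqrt{1 - k c^2}$ ($k$ =
number of pairs the residue is in) so variance stays 1 and the induced
pair correlation is $c^2$. A shared driver produces *simultaneous*
recurrences — exactly the signal joint-recurrence counting detects.
Coordinates place residues on a straight line at 3.8 Å (the consecutive
Cα spacing of a real chain), which makes geometric expectations
analytic: the 7 Å network of a chain is a path graph, and pairs at equal
sequence separation have equal Cα distance.

What the generator deliberately does **not** reproduce: deterministic
low-dimensional dynamics (its series are stochastic, so FNN selection
lands, flagged, at `max_dim`), non-stationarity, folded-geometry
distance structure, or chemistry-specific contacts. Passing tests on
synthetic chains therefore validate the pipeline's statistical
machinery and bookkeeping, not biological hotspot accuracy on real
proteins.

Two behaviors of the synthetic nulls are worth understanding before
interpreting real data:

* **Autocorrelation inflates joint counts uniformly.** For independent
  residues, the expected joint-recurrence density is the product of the
  per-cell recurrence probabilities summed over cells. With
  autocorrelated series those probabilities concentrate near the matrix
  diagonal *for every residue alike*, so all pairs share an elevated
  background relative to the naive (rate)² product; with white-noise
  series the product null holds to within Monte-Carlo error. The
  background cancels in comparisons between pairs, which is how coupling
  detection is assessed.
* **Compare edge weights at like distances.** Weights divide counts by
  Cα distance, so on the straight chain the adjacent (3.8 Å) pairs top
  the raw weight distribution regardless of coupling. Coupled pairs are
  recovered by comparing each pair against uncoupled pairs at the same
  separation; at coupling 0.8 the coupled pairs exceed the
  same-separation 90th percentile in 4 of 5 generator seeds (the
  package's coupling-recovery acceptance check, 12 residues × 1000
  frames).

## Numerical choices

* **Calibration is exact quantile selection.** All $N_s(N_s-1)/2$
  pairwise state distances are (partially) sorted and $\varepsilon$ is
  the smallest distance whose inclusion brings the rate (diagonal
  included) to or above the target; ties at $\varepsilon$ recur. The
  achieved rate is recorded per residue in the manifest; with
  $N_s \approx 10^3$ it exceeds 3% by less than 0.01 percentage points.
  Degenerate trajectories (all states coincident) saturate at rate 1
  and are flagged with a warning.
* **Common window truncation.** Per-residue $(d, m)$ give different
  $N_s$; before joint counting all matrices are truncated to the first
  $N_{s,\min}$ states, preserving simultaneity of time indices. The
  common window is recorded in the manifest. A `global_embedding`
  option forces one $(d, m)$ (the per-column maximum) on all residues
  for exactly aligned windows.
* **Sparse counting.** At a 3% rate the upper-triangle recurrence
  indicators are ~1.5% dense, so each residue's recurrent cells are
  stored as index pairs and all-pairs joint counts are one sparse
  indicator cross-product ($10^6$-cell matrices × 165 residues in
  seconds; the full 165 × 1000 pipeline runs in under a minute on one
  CPU).
* **Weight → path length.** Shortest-path centralities need a length
  per edge; stronger interactions must be shorter. The reciprocal
  `1/weight` — the usual convention in this literature — is the
  default, isolated in `path_length_from_weight()` together with a
  `-log(w/max w)` alternative, because the choice is consequential and
  conventions differ.
* **Disconnected graphs.** Closeness for a node reaching only $r$
  others uses $(r-1)/\sum sd$ over the reachable set and the node is
  flagged; isolated nodes get 0. Betweenness counts paths within
  components. Ranking comparability across differently connected
  networks is limited in this regime — the flags are there to warn.
* **Boundary conventions.** Recurrence and the 7 Å cutoff both use
  $\le$ (Heaviside with $\Theta(0) = 1$); RSA class boundaries go to
  the upper class (5% is partially buried, 20% is exposed). Whether the
  joint count uses one triangle or the doubled full matrix only
  rescales every weight by 2 and cannot change centralities or
  z-scores; one triangle is used.
* **RSA denominators** are the theoretical Gly-X-Gly maxima of Tien et
  al. (2013), embedded as a constant table; values above 1 are allowed
  but flagged.

## Problem sizes used in validation

The test suite validates counting and centralities against naive
double-loop and exhaustive shortest-path-enumeration oracles (20 random
trajectories of ≤ 50 states; 20 random weighted graphs of ≤ 15 nodes),
checks analytic closed forms (path and star graphs, straight-chain
geometry), and exercises the calibration target, the coupling-recovery
and null-density properties (12 residues × 1000 frames), and one
full-scale run (165 residues × 1000 frames) end to end.

## Known limitations

* The method consumes per-residue scalar series; computing RMSD from
  trajectory formats (DCD/XTC) is out of scope.
* Contact counts from a PDB use a generic 4.5 Å heavy-atom criterion —
  not a surface-complementarity contact classification; supply a
  contact table for anything more refined.
* ASA computation from coordinates is out of scope; RSA needs an ASA
  table.
* No RQA line-based measures (determinism, laminarity), no cross- or
  multivariate recurrence beyond pairwise joint recurrence, no
  community detection or spectral analysis.
* Centrality z-scores inherit the usual caveats of comparing weighted
  networks with different weight scales; only within-network rankings
  are meaningful, which the z-standardization makes explicit.
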