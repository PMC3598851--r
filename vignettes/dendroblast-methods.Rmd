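---
title: "Alignment-free tree inference from bit scores: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Alignment-free tree inference from bit scores: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendroblast)
```

This vignette is the package's own account of the method it implements: the
score-to-distance model and its assumptions, the perturbation/consensus
machinery, the parameters that matter, what the synthetic-data generator
does and does not emulate, and the design decisions taken where more than
one reasonable choice existed.

## From local-alignment scores to distances

The method's premise is that for moderately diverged protein families the
pairwise local-alignment bit score is a usable, if crude, proxy for
evolutionary proximity, and that a full multiple sequence alignment — the
dominant cost of standard phylogenetics — can therefore be skipped
entirely.

For queries $A$ and subjects $B$, with $s(A,B)$ the bit score:

* **Repair.** Pairs with no hit are set to $s_{\min}(A)/2$. Any positive
  value strictly below the smallest observed score would do; half the
  minimum keeps the subsequent logarithm finite while placing non-hits
  firmly below every real hit. Repaired pairs do not join the hit sets, so
  they carry reduced weight but do not distort the overlap statistics.
* **Normalisation.** $\hat s(A,B) = s(A,B)/s_{\max}(A)$. Bit scores grow
  with query length and composition; dividing by the per-query maximum
  (always the self-hit) maps every row to $(0,1]$.
* **Overlap weighting.** $w(A,B) = 2n_{AB}/(n_A+n_B)$, the Dice coefficient
  of the two hit sets. Two sequences that "see" the same relatives get
  weight 1; modular proteins sharing only a domain get discounted. Disjoint
  hit sets abort the inference — there is no information connecting the
  pair. The alternative form $n_{AB}/\max(n_A,n_B)$ is available via
  `form = "max"`; both equal 1 exactly at perfect overlap, which is the
  constraint the similarity bound requires.
* **Similarity and distance.**
  $S(A,B) = \tfrac12\,(w_{AB}\hat s_{AB} + w_{BA}\hat s_{BA}) \in (0,1]$
  symmetrises the inherently asymmetric scores;
  $d(A,B) = -\log S(A,B)$. Natural log: the base rescales every distance
  by the same constant and cannot change the topology selected by NJ or
  balanced minimum evolution, so it is purely a reporting convention.

The distance is not guaranteed metric. On gap-free simulated families the
triangle inequality holds essentially always (the suite records violation
counts rather than asserting zero); on real, modular proteins it can fail
by construction, which is a known property of the approach, not a bug.

### Assumptions

* Bit-score ranking reflects proximity: true at low-to-moderate divergence,
  degrading as scores saturate toward the twilight zone.
* The hit threshold (15 bits by default) reproduces the hit/no-hit
  structure a database search would give. An exhaustive Smith-Waterman
  engine scores *every* pair, so some threshold is required; 15 bits
  roughly corresponds to default blastp reporting for short queries. The
  external-`blastp` input path (`parse_blast_tabular()`) sidesteps this
  choice; internal scores approximate but do not equal heuristic blastp
  scores.
* Only the best local alignment per pair is used; additional HSPs are
  ignored (simplest consistent definition).

## The perturbation model

A single distance matrix yields a single tree with no notion of support.
To find which bipartitions are robust, the input sequences are jittered
and the inference repeated:

* each BLOSUM62 row is remapped to replacement distances
  $B'(i,j) = B_{\max}(i) - B(i,j) \ge 0$; the diagonal is the strict row
  maximum for BLOSUM62, so distance 0 always means "keep the residue";
* a replacement for residue $i$ gets weight $f(B'(i,j);1,\theta)$ — the
  Gamma density with shape 1 and scale $\theta$, i.e.
  $\theta^{-1}e^{-x/\theta}$ — divided by the size of the tie group of
  amino acids sharing that distance, with the draw uniform inside a group;
* rows are normalised to proper distributions and every site resampled
  independently. The normalisation is the minimal completion of the
  weighting scheme: exactly one outcome per site is required, and only
  relative weights are specified. At the default scale about a quarter of
  sites change per replicate and "no change" is the modal outcome in every
  row (the suite verifies both the analytic row distributions and the
  realised-change histogram).

100 replicate families are generated (replicate $k$ seeded from a derived
stream of the master seed, so runs are bit-reproducible), one tree inferred
per replicate, and the strict majority-rule consensus (> 50%, exact halves
excluded — the standard definition, which also guarantees pairwise
compatibility) taken as the supported tree. A strictly bifurcating guide
tree from the unperturbed distances is always produced alongside, because
downstream uses such as progressive alignment need full resolution; the
guide tree is *not* a resolution of the consensus polytomies, which would
require arbitrary tie-breaking.

Ambiguity codes (B, Z, X, U) are tolerated on input, scored by the
substitution matrix's corresponding rows, and never mutated by the
perturbation — the remap is defined only on the 20 standard letters, and
leaving such positions fixed is the conservative completion.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `theta` | 1.9644 | remapped score units (Gamma scale) | calibrated optimum of the replacement scheme; 0 disables perturbation |
| `replicates` | 100 | count | replicate count of the consensus procedure |
| `hit_threshold` | 15 | bits | hit/no-hit boundary for the exhaustive engine |
| `gap_open`, `gap_extend` | 11, 1 | raw score | standard blastp penalties for BLOSUM62 |
| `lambda`, `K` | 0.267, 0.041 | — | gapped Karlin-Altschul constants for this scoring regime |
| `method` | `bme_nni` | — | balanced ME with NNI; `nj` for plain neighbour-joining |
| `form` | `dice` | — | overlap weight; `max` variant available |

`calibrate_theta()` re-derives $\theta$ for new conditions: scan a grid
(use 0 for the no-perturbation control), fit the mean RF distance with a
polynomial (degree 4 by default — enough curvature for a single-dip
profile without chasing noise; degree is configurable), and take the
minimiser of the fitted curve over the grid interval. A flat fitted curve
returns the interval's lower bound with a warning. The grid must have at
least `degree + 2` points so the fit has a residual degree of freedom.

## What the simulator emulates — and what it does not

`simulate_family()` draws a uniform random unrooted topology (sequential
addition), exponential branch lengths (default mean 0.3
substitutions/site — deep enough that distance methods make occasional
errors, shallow enough that homology is never in doubt), and evolves
sequences under a reversible substitution process with BLOSUM62-derived
exchangeabilities ($r_{ij} = 2^{B_{ij}/2}$, the matrix being in
half-bits), uniform stationary frequencies, and discrete-gamma rate
heterogeneity (shape 1, 4 categories). It deliberately omits:

* indels and alignment error (the method strips gaps on ingest anyway; an
  indel process would stress only the alignment engine);
* realistic amino-acid composition and site-specific profiles;
* domain shuffling — precisely the phenomenon that breaks the triangle
  inequality on real data.

Passing tests on these families therefore demonstrates internal
correctness and the method's behaviour under clean divergence, not
real-data accuracy. The test battery sizes were chosen to keep the full
suite in the minutes range on one core: 200 random tree pairs (≤ 12 taxa)
for the comparison oracle, 100 8-taxon families for recovery, 20 families
of 12 taxa × 300 residues with the full 100-replicate consensus for the
directional benchmark, and $10^6$ sampled positions for the perturbation
model.

## Numerical and design notes

* **Ties in NJ/BME.** Tree inference delegates to ape's `nj` and
  `fastme.bal` (the same NJ-start + NNI-refinement strategy FastME uses);
  both are deterministic, so equal-Q ties resolve by index order.
  Negative branch-length estimates are clamped to 0 after inference.
* **Balanced ME criterion.** `bme_length()` implements the Pauplin
  weighting $\sum_{i<j} 2^{1-p_{ij}} d_{ij}$ ($p_{ij}$ = path edges) so
  the refinement's monotone-descent property is checkable against the NJ
  start.
* **Degenerate distances.** Identical sequences give $d = 0$ and come out
  as zero-length cherries; the similarity bound $S \le 1$ is enforced with
  a tolerance guard before the log, and $-\log 1$ is normalised to a clean
  (non-negative) zero.
* **Undefined ratios.** Precision of a star tree (no inferred splits) is
  reported as 1 with a `precision_defined = FALSE` flag rather than `NaN`
  or an error, so batch summaries stay total; recall is handled
  symmetrically.
* **Consensus on one tree** returns that tree unchanged (unrooted), making
  the single-replicate, no-perturbation run collapse to the guide tree
  exactly.
* **Reduced-scale behaviour of the consensus.** On the 20-family benchmark
  the suite asserts the consensus does no worse than single-tree NJ on
  mean RF (a tie is admissible). At this scale families are easy enough
  that plain methods are near-perfect, so the filtering mainly
  demonstrates it does no harm; the pruning of weakly supported splits is
  expected to pay off on larger, noisier families than the suite builds.
* **SPR refinement** is deliberately out of the default path (NNI only);
  a config hook is reserved.

## Known limitations

* Internal engine scores are exhaustive Smith-Waterman, not blastp: bit
  values differ slightly from a real BLAST run, though ranks rarely do.
* No E-values, composition-based statistics, or multi-HSP handling.
* The distance admits no rate-variation correction (there are no alignment
  columns to model), so long-branch situations inherit NJ/ME's known
  weaknesses, amplified by score saturation.
* Consensus support frequencies are perturbation support, not bootstrap
  support; they are not comparable across data sets with different
  divergence.
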