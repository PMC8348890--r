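---
title: "Methods: hierarchical informational structure of protein sequences"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: hierarchical informational structure of protein sequences}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anis)
```

# The model

`anis` treats the pentapeptide — the contiguous 5-residue fragment — as the
unit of protein sequence information, and asks how the statistical
prominence of a protein's pentapeptides organizes the sequence into nested
segments across scales.

## From counts to a profile

Over a non-redundant protein collection, every overlapping 5-window is
counted; φ(A) is the occurrence count of fragment A. The *total frequency*

$$\Phi(A) = \sum_{J:\,d(A,J)\le\delta} \varphi(J)$$

sums over the Hamming ball of radius δ (default 1: the fragment itself
plus its 95 single-substitution neighbours), reading each pentapeptide in
a substitution-tolerant, evolutionary sense. Larger radii (δ = 2, 3 are
supported) widen that tolerance at the cost of statistical sharpness.

A query protein $I = i_1\ldots i_N$ then yields the profile
$f_I(j) = \Phi(I_j)$ over the window centres $j = 3,\ldots,N-2$, and its
Gaussian smoothing at scale $y$:

$$F_I(x) = \sum_{j=3}^{N-2} f_I(j)\, g(x-j, y), \qquad
  g(x,y) = \frac{1}{y\sqrt{2\pi}} e^{-x^2/2y^2}.$$

The sum runs only over existing window centres — there is deliberately no
renormalization at the sequence ends, so $F$ decays toward the termini and
terminal segments separate naturally from the core.

## The inscribed height field

At each scale the method fits Gaussians *under* the profile: $H_I(x,y)$ is
the largest amplitude $h$ such that $h\,e^{-(z-x)^2/2y^2} \le F_I(z)$
everywhere, i.e.

$$H_I(x,y) = \min_z F_I(z)\, e^{(z-x)^2/2y^2},$$

with $z$ on the integer grid $1..N$ and $(x, y)$ ranging over the
triangular domain $x\in[1,N]$, $y\in[1,N/2]$. A high inscribed height at
$(x,y)$ means a coherent frequency feature of width $\sim 2y$ centred at
$x$. The smoothing kernel and the inscribed Gaussian share the same $y$:
the field is a genuine one-parameter scale space, recomputed per level.

## The ELIS tree

For fixed $y$, the local maxima of $H(\cdot,y)$ are the cores of the
hierarchical elements alive at that scale. Scanning $y$ downward and
linking each maximum to the nearest maximum one level up produces a
tree: branches are ELIS (hierarchical ELements of Informational
Structure), and a branch that acquires two or more maxima below it splits
at a branch point $(x_0, y_0)$.

Linking and interval rules are not forced by the model, so the package
fixes them explicitly:

* a maximum at level $y-1$ is assigned to the nearest tracked maximum at
  level $y$ (equivalently, the one whose midpoint basin contains it), ties
  to the left;
* a plateau of equal values flanked by strictly smaller values is one
  maximum at its midpoint (rounded down); a domain endpoint qualifies when
  strictly above its single neighbour; zero-height maxima are ignored;
* the branch point is recorded at the parent's position on the last level
  where the sub-branches are still merged;
* a root's interval is its midpoint basin at the top level; at every
  split, the parent interval is partitioned at the midpoints between the
  children's positions *at the split level*. Tracked maxima can drift
  across levels, so each child's slot is additionally kept wide enough to
  hold one grid position per leaf of its subtree. Evaluating each
  partition at the level where the branches emerge makes the hierarchy
  exactly nested and the intervals alive at any level pairwise disjoint —
  properties that would not survive evaluating every branch's basin at its
  own terminal level, because basins from different levels need not nest.

## Entropy branch signal

Per level, the normalized row $H^{norm}(\cdot,y)$ (unit sum over the grid;
discrete sums stand in for the integrals at unit bin width) has Shannon
entropy

$$S_I(y) = -\sum_x H^{norm}(x,y)\,\log H^{norm}(x,y) \quad \text{(nats)},$$

compared against the model entropy $\log n$ of a uniform partition into
$n$ equal segments. The package takes $n$ = the number of ELIS branches
alive at level $y$ — the only protein-dependent count that makes the
deviation $\tilde S(y) = S(y) - \log n$ jump exactly where a lower-rank
element emerges. The forward difference $S'(y) = \tilde S(y+1) - \tilde
S(y)$ then peaks at branching scales; its *interior* strict local maxima
are reported (an endpoint rule would turn every monotone derivative into a
false detection). A central-difference option exists and, on the planted
fixtures, moves detections by at most one level.

## Cohort scales: correlation matrix and CSA

For a cohort, the vector $V_y$ collects $S'(y)$ across all proteins whose
triangle reaches level $y$. The level-by-level correlation is the
normalized inner product

$$r_{yy'} = \frac{\langle V_y, V_{y'}\rangle}
  {\sqrt{\langle V_y, V_y\rangle\,\langle V_{y'}, V_{y'}\rangle}},$$

the unique normalization with unit diagonal and $|r|\le 1$
(Cauchy–Schwarz). Proteins of different lengths contribute to different
level ranges, so each entry is computed over the pairwise-complete
intersection of contributors, with a minimum shared count (default 10)
below which the entry is undefined.

The matrix is thresholded (strictly: $r > t$; the diagonal is always on)
over a decreasing schedule, the diagonal is partitioned left-to-right into
maximal all-ones squares (continuous square areas, CSA), and the first
block structure repeated at two consecutive thresholds is declared stable;
the threshold where that happens is reported. If the structure never
repeats the final set is returned flagged unstable.

# Parameters

| parameter | default | meaning |
|---|---|---|
| `delta` | 1 | Hamming radius of the total-frequency ball (0–3); 1 admits single conservative substitutions |
| `min_len`, `max_len` | 50, 400 | residue bounds for database records; the window where single-domain statistics are cleanest |
| `y_levels` | 1..⌊N/2⌋ | integer scale grid (residues); the triangular domain's natural resolution |
| `truncate` | 8 | kernel support radius in units of y for the linear profile sum; relative dropped mass `exp(-32)` ≈ 1.3e-14 |
| `thresholds` | 0.9 … 0.001 | nine-value decreasing CSA schedule spanning the useful correlation range, with extra resolution below 0.1 where stabilization typically occurs |
| `min_proteins`, `min_pair` | 10, 10 | minimum cohort support per level and per matrix entry |

# Numerical choices

* **Log-domain evaluation.** The inscribed-height minimand multiplies
  $F(z)$, which decays like a Gaussian far from the profile support, by
  $e^{+(z-x)^2/2y^2}$, which grows just as fast. In linear arithmetic $F$
  underflows to 0 and the product degenerates to $0\cdot\infty$. All
  height-field evaluations therefore run in the log domain via
  log-sum-exp; smoothed profiles carry both the (truncated) linear values
  and the full log values. For a single-impulse profile the two exponents
  cancel exactly, which is what makes the closed form
  $H(j_0,y) = c/(y\sqrt{2\pi})$ hold to machine precision at every scale —
  a property the tests assert at 1e-9.
* **Determinism.** All maxima/minima use first-index (leftmost)
  tie-breaking; generator streams are pinned to a fixed RNG kind; output
  files carry no timestamps, so identical inputs and configuration
  reproduce identical bytes.
* **Degenerate inputs.** Windows containing residues outside the canonical
  20-letter alphabet are skipped during counting and profile lookup (their
  Φ is 0), with skip counts reported; an all-zero height field yields an
  empty forest with a warning; all-zero rows are skipped in the entropy
  curves; zero-norm level vectors mask their matrix row. When the
  normalization of a height row is rounded back to unit sum, the largest
  element absorbs the residual — absorbing into the last element can drive
  a nearly-zero tail entry negative.
* **Error convention.** 0·log 0 = 0 in the entropy; `exceeds` is strict in
  thresholding; bounds are inclusive in length filtering.

# The synthetic generators

The generators exist so every stage has a known-answer input:

* `random_database()` draws i.i.d. residues (optional composition bias,
  optional planted over-represented motifs) with lengths uniform in the
  50–400 window used for real frequency databases.
* `planted_profile()` builds impulse, two-impulse and multi-scale
  profiles. The two-impulse separation sets the merge scale (two equal
  Gaussians become unimodal at half their separation, so a pair planted
  $d$ apart merges near $y = d/2$); the multi-scale kind plants two pairs
  whose within-pair and between-pair spacings target two disjoint level
  bands, and **verifies at generation time** — by building the tree — that
  every branch point falls in a band, erroring otherwise. A returned
  fixture therefore certifies its own structure.
* `planted_cohort()` builds entropy-derivative curves directly: each
  protein belongs to one band and carries a common positive amplitude
  (|N(1, 0.25)|) across that band's levels, plus N(0, σ) noise everywhere
  (σ = 0.1 by default — a tenth of the signal, enough to perturb but not
  bury it). Because different bands live on disjoint protein supports, the
  noise-free correlation matrix is exactly block-structured, which pins
  down what the recovery tests must find.

What the generators do *not* emulate: residue autocorrelation, homology,
compositional drift along sequences, or any secondary-structure signal.
Passing the synthetic suite therefore demonstrates the machinery —
counting, scale-space geometry, tree extraction, entropy detection, matrix
algebra, stability logic — not biological validity on real proteomes,
which requires a real non-redundant collection.

# Problem sizes

The test suite exercises: exhaustive inscribed-height verification on 100
random profiles of 24–60 residues at every grid point and level; tree
invariants on 100 random profiles of 40–80 residues; cohort properties on
planted cohorts of 200 curves over 25 levels across 20 seeds; CSA oracle
equivalence on 200 random 20×20 masks; and an end-to-end run over a
100-protein synthetic database of 50–150 residues, executed twice and
compared checksum-for-checksum. These sizes keep every brute-force oracle
exact while covering the regimes (multiple spikes, drifting maxima,
variable lengths) where the edge cases live.

# Limitations

* The hierarchy is only as good as the frequency table; small or biased
  collections produce noisy profiles. The package does not perform
  homology reduction — the user must supply a non-redundant set.
* Branch points are reported on the integer level grid; sub-level
  precision is not attempted, and the entropy detector can add spurious
  low-level maxima on profiles with strong single features.
* Branches are not extrapolated beyond the triangular domain; terminal
  elements near the sequence ends are reported only where the domain
  supports them.
* Only diagonal CSA blocks are detected; off-diagonal correlation
  structure is visible in the exported matrix but not summarized.
* The linking rule (nearest maximum, leftward ties) and the interval rule
  (split-level midpoint partition) are explicit package choices among
  several defensible conventions; alternatives can shift interval
  boundaries by a few residues near basin edges.
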