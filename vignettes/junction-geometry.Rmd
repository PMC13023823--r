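---
title: "Predicting RNA three-way junction geometry from secondary structure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting RNA three-way junction geometry from secondary structure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Three-way junctions (3WJs) — loops where exactly three helical stems
converge — are the most common multi-branch motif in structured RNA, and
the relative orientation of their three helical arms largely fixes the
molecule's global 3D shape. `rna3wj` predicts the three inter-branch
angles of a 3WJ directly from sequence and pseudoknot-free secondary
structure, and provides the geometric machinery to extract ground-truth
angles from 3D coordinates and to reconstruct and score coarse-grained
junction skeletons.

## Geometric model

An RNA secondary structure is abstracted as a planar tree graph: loop
motifs (hairpin H, bulge B, internal I, multibranch M, external E) are
nodes, and helical stems are edges. A stem is a *maximal run of strictly
stacked nested pairs*: even a single-nucleotide bulge splits a helix into
two stems, so that loops always appear as nodes between stems. The
external loop is one node holding the 5' and 3' dangling ends (up to two
segments); zero-length loop segments are legal and recorded for
multibranch loops.

Spatial coordinates are assigned from C4' backbone atoms, which are
conformationally stable anchors:

* a non-junction loop node sits at the centroid of its members' C4'
  atoms;
* each junction branch has an *anchor*, the midpoint of the C4' atoms of
  the stem's closing base pair;
* the junction node sits at the *incenter* of the three anchors,
  `I = (aA + bB + cC)/(a + b + c)` with opposite side lengths as weights.
  If the anchor triangle is degenerate (area below 1e-6 sq.A) the anchor
  centroid is used instead, with a warning.

Branches are numbered 1..3 by their first nucleotide along the chain
5'→3'. Branch direction k points from the junction coordinate to the
*adjacent tree node's* coordinate (the anchor midpoint is available as an
alternative via `endpoint = "anchor"`); the angle convention is theta1 =
(1,2), theta2 = (2,3), theta3 = (3,1), each in (0, 180].

A junction's *rigid star* abstraction is its center plus the three branch
endpoints. Reconstruction from an angle triple places branch 1 along +x,
branch 2 in the xy-plane, and branch 3 with a +z out-of-plane component;
a triple violating the spherical constraints (each angle at most the sum
of the other two, total at most 360 degrees — equivalently a positive
semidefinite Gram matrix of the three directions) is projected onto the
feasible boundary and flagged rather than rejected. Skeleton RMSD uses
optimal proper-rotation superposition (Kabsch) over the four matched
points; because an angle triple does not determine handedness, both
mirror images are scored and the minimum reported. Unsuperposed RMSD
would be frame-dependent and ill-defined, which is why superposition is
built into the metric.

## Features and the dual-resolution network

Two graph resolutions are built from the same structure:

* **Nucleotide graph** — one node per nucleotide with an 11-dim one-hot
  feature (4 bases + 7 motif labels; `N` bases get an all-zero base
  block), and typed undirected edges: backbone, nested pair, pseudoknot.
  Pseudoknot pairs are excluded from the tree but kept here as a distinct
  edge channel.
* **Tree graph** — per-node 24-dim loop descriptors (8 groups of 3: raw
  segment lengths 5'→3', pairwise minima, sorted lengths, pairwise
  absolute differences, pairwise ratios, normalized fractions, maximum
  consecutive A/U run, maximum consecutive A run; groups padded to length
  3 with zeros) and per-stem 4-dim edge features (base-pair count and
  G-C/A-U/G-U fractions). Ratios with an empty denominator segment use
  `max(|Lj|, 1)`; sorting orders the *real* segment lengths before
  padding, because padding is a vectorization device, not data. Pairwise
  groups enumerate (1,2), (1,3), (2,3).

The network mirrors the dual-resolution design: a two-head
transformer-style attention convolution over the nucleotide graph (edge
features enter keys and values); independent affine+ReLU encoders for
tree node and edge features; mean-pooling of loop-member nucleotide
embeddings onto their tree node (stem nucleotides contribute through
message passing only — the pooling rule is this package's main
architectural interpretation, since cross-resolution alignment admits
several designs); gated fusion `h = z * h_nucleotide + (1 - z) * h_tree`
with `z = sigmoid(affine([h_nucleotide, h_tree]))`, per-dimension by
default (`gate_mode = "scalar"` available) — an input-conditioned gate,
since a fixed scalar could not "dynamically modulate" anything; then
LayerNorm, a two-head graph attention pass over the *tree* graph with a
residual connection, junction-node readout, and an MLP head emitting
`[sin, cos]` pairs for the three angles. Angles decode as
`|atan2(s, c)|`, which is magnitude-invariant per pair and folds the
uninformative sign (ground truth lies in (0, 180]).

The loss is the mean over valid junction samples of the summed squared
distances between predicted and ground-truth (sin, cos) pairs. Masking
of non-junction outputs is structural: only junction nodes are read out.

Ablation variants (exactly one active): `no_tree`, `no_nucleotide`,
`gcn_message_passing` (attention replaced by degree-normalized mean
aggregation, edge features unused, as in a standard GCN),
`concat_fusion` (gate replaced by concatenation + affine projection),
`len_only_features` (tree node features truncated to raw lengths).

### Training

Because no deep-learning framework ships with this package's ecosystem
constraints, the network and its reverse-mode differentiation are
implemented in-package (`R/autograd.R`) and verified against central
finite differences in the test suite. Training uses AdamW (decoupled
weight decay), full-batch: the training split is assembled into one
disjoint-union graph, so an epoch is a single vectorized forward/backward
pass. Chains are split at the chain level into training and validation
parts (junctions of one chain never straddle the split, nor do they
straddle cross-validation folds); the learning rate halves when the
validation loss plateaus (`plateau_patience` epochs, factor 0.5), and
training stops after `early_stop_patience` epochs without improvement,
returning the best-validation parameters. A single integer seed drives
initialization, splits and dropout; checkpoints round-trip weights
bit-exactly (17-significant-digit serialization).

Defaults: hidden width 64, 2 attention heads in both attention blocks,
dropout 0.2 on all hidden layers, lr 1e-3, weight decay 1e-2, at most
500 epochs. All are configuration-overridable.

## The synthetic benchmark

The generator emulates single-3WJ RNAs: complementary stems of 2–8 bp
(G-U wobbles at probability 0.1), junction loop segments of 0–8 nt,
hairpins of 3–8 nt, dangling ends of 1–4 nt, total length well under 500
nt. Ground-truth angles are planted by a fixed smooth rule — deviations
from the symmetric 120/120/120 triple driven by tanh of pairwise
segment-length differences and by pairwise stem GC-fraction differences —
plus Gaussian noise (sigma = 5 degrees by default, matching the scale of
natural per-angle variability), clipped to [5, 175] and projected onto
the feasible set. The projection shrinks toward (90, 90, 90): the
symmetric 120-triple lies *on* the coplanar boundary (sum 360), so it
cannot serve as a projection target.

Toy structure files are C4'-only PDB records in which the planted
geometry is exactly recoverable: closing-pair midpoints sit on the
planted branch directions, loop clusters centroid-match their node
targets, and the junction incenter follows. Branch lengths are set to
`80 + 2.8 * stem_bp` Angstrom — deliberately generous, so that the PDB
format's 3-decimal coordinate precision perturbs recovered angles by well
under the 1e-3 degree round-trip tolerance (at realistic ~10 A lengths
the rounding alone exceeds it). The generator does *not* emulate A-form
helical geometry, non-canonical pairs, tertiary contacts, or structural
disorder; passing tests therefore demonstrate the correctness of the
pipeline and the learnability of a planted structure-to-geometry map,
not predictive accuracy on experimental RNA.

### Benchmark configuration

The parameter-recovery benchmark trains on 300 synthetic chains and
evaluates on 60 held-out chains, with three model seeds, using a lighter
configuration chosen once for desk-scale runtimes: hidden width 32, lr
0.01, dropout 0.2, at most 150 epochs, plateau patience 15. Under these
conditions the full model reaches joint ACC(20 deg) around 0.85–0.90 and
dominates both single-resolution ablations (the tree-only variant is the
stronger of the two, the nucleotide-only variant the weaker), matching
the expected ordering for this kind of dual-resolution architecture.

## Evaluation metrics

* `acc()` — per-angle ACC(tau) (fraction of samples within tolerance),
  overall ACC (the 1/(3N) double sum over samples and angles), and joint
  ACC (all three angles simultaneously within tau); evaluated at 10, 15,
  20 degrees by default.
* Angular error is the plain absolute difference — no circular wrap,
  since both values live on the half-circle [0, 180]; 179 vs 1 is an
  error of 178 degrees.
* `mae()` — mean of the three per-angle deviations of one junction.
* `rmsd_report()` — skeleton RMSDs, mean, and 0–1 / 1–2 A histogram
  bins.
* `permutation_importance()` — mean drop in joint ACC(20) when one
  feature group's columns are shuffled across all tree nodes of the
  dataset (rows of the group kept together).

## Numerical choices and degenerate inputs

* Cosines are clipped to [-1, 1] before `acos`; branch vectors shorter
  than 1e-9 A are a degeneracy error.
* Near-collinear theta1 (sin below 1e-9) perturbs the branch-2 direction
  by 1e-6 degrees with a warning rather than failing.
* Attention logits are clamped at +-30 before the segment softmax as a
  saturation guard.
* Junctions with more than three branches raise an explicit
  unsupported-topology error; secondary-structure prediction and
  pseudoknot-aware tree construction are out of scope.
* A helix interrupted by a one-sided single-nucleotide bulge is kept as
  two stems (the loops-as-nodes convention); external loops with both
  dangling ends form one node.

## Limitations

The model is exclusive to three-way junctions; four-way and higher
junctions are rejected at parse time. Stem orientation rests on a single
closing base pair through the anchor construction, which is sensitive to
local distortion in real structures; multi-pair helical-axis fitting is
not implemented. The synthetic benchmark bounds what the shipped tests
can certify: performance on experimental structures requires a curated
3D dataset that this package does not download or redistribute.
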