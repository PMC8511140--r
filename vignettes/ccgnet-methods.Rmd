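---
title: "Co-crystal screening with graph networks and prior-knowledge descriptors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Co-crystal screening with graph networks and prior-knowledge descriptors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

A co-crystal is a single crystalline phase built from two neutral molecules
(coformers) held together by non-covalent interactions.  Whether a given
pair will co-crystallize is expensive to establish experimentally, so
virtual screening of candidate coformers against a target molecule -- an
active pharmaceutical ingredient, an energetic compound -- is of real
practical value.  `ccgnet` implements a graph-network classifier for this
task: it consumes a pair of molecules and returns two scores, one per
class, with the pair called a co-crystal former exactly when the positive
score exceeds the negative one.

## Sample representation

Each coformer becomes a molecular graph plus a descriptor vector:

* **Vertex matrix `V` (N x 31).**  One row per atom -- explicit hydrogens
  are graph nodes.  The row holds an element one-hot over
  (Cl, N, P, Br, B, S, I, F, C, O, H), a hybridization one-hot
  (SP2, SP3, SP, S), a CIP chirality one-hot, six binary flags (chiral,
  spiro, cyclic, aromatic, H-bond acceptor, H-bond donor), the explicit and
  implicit valence, formal charge, degree, attached-hydrogen count, atomic
  number, and the van der Waals radius.  The column layout is frozen and
  versioned; checkpoints refuse to load across layout versions.
* **Adjacency tensor `A` (N x N x 4).**  One symmetric 0/1 slice per bond
  type (single, double, triple, aromatic).  Slices are binary with no
  degree normalization.  The two coformers of a pair share no edges: only
  covalent bonds are represented.
* **Global state `U` (2 x 12).**  Twelve descriptors per coformer,
  capturing shape (principal-axis box extents S <= M <= L and their ratios,
  globularity), polarity (TPSA/SASA, Gasteiger point-charge dipole in
  Debye), composition (fraction of N/O atoms, fraction of aromatic atoms)
  and hydrogen-bonding capacity (acceptor, donor and rotatable-bond
  counts).

Molecular perception -- aromaticity, CIP labels, pharmacophore SMARTS for
donors/acceptors, seeded distance-geometry conformers with force-field
relaxation, Gasteiger charges, TPSA, solvent-accessible surface area, grid
molecular volume -- is delegated to RDKit through a small batched helper
process; all downstream numerics (the principal-axis box, the dipole
magnitude, descriptor assembly, graphs, the network itself) are computed in
the package.  Two conventions are worth noting because the literature
leaves them open: the enclosing box is the extent of the centred
coordinates along their covariance eigenbasis (rotation-invariant, no van
der Waals padding), and rotatable bonds/TPSA are computed on the
implicit-hydrogen form, where the standard SMARTS definitions apply (the
explicit-hydrogen form would, e.g., count ethanol as having two rotatable
bonds instead of none).

## The network

The classifier stacks four message-passing blocks.  Each block applies
three maps:

1. a **global-state update** `u' = ReLU(u W + b)`, independently per
   coformer row;
2. a **graph convolution** over the adjacency tensor.  With one scalar
   weight per (bond type l, input channel c, output filter f), the
   effective filter is `H^(c,f) = sum_l h_l^(c,f) A_l`, and the node update
   is `V_out = ReLU(V W0 + sum_c H^(c,f) V^(c) + b)` -- a self-loop term
   plus bond-type-resolved neighbor aggregation;
3. a **broadcast concatenation** that appends each coformer's updated
   global state to every one of its atoms, so prior knowledge re-enters
   message passing at every depth.

After the last block a **multi-head global attention** readout pools atoms:
each head scores every atom with a two-layer MLP, softmaxes the scores over
real (unmasked) atoms, and forms the attention-weighted sum of atom
embeddings; the K head outputs are concatenated.  The final global-state
rows are concatenated to this graph embedding and a dense head
(128-64-2 by default) produces the two class scores.  Softmax cross-entropy
is minimized with Adam; no class reweighting is used even though the
training data are heavily imbalanced -- robustness is expected to come from
the representation, and the balanced-accuracy metric (mean of per-class
rates) makes any majority-class bias visible.

The attention weights themselves are exposed (`attention_map()`): they sum
to one per head, align with input atom order, and mark the substructures
the readout relies on.

## Parameters and defaults

| parameter | default | meaning |
|---|---|---|
| `conv_widths` | 16, 16, 32, 32 | graph-convolution filters per block |
| `global_widths` | 24, 24, 24, 24 | global-state embedding width per block |
| `n_heads` | 2 | attention heads K |
| `att_hidden` | 16 | hidden width of each head's scorer MLP |
| `dense_widths` | 128, 64 | dense head (a 2-unit output layer is appended) |
| `epochs`, `batch_size`, `lr` | 60, 32, 1e-3 | Adam settings |
| `weight_decay` | 1e-3 | decoupled L2 decay per step |
| `dropout` | 0 | optional dropout on dense hidden layers |

The published architecture this follows reports its exact hidden sizes only
through an unpublished hyper-parameter search, so the widths here are this
package's own choices, sized so that the full cross-validation, ensemble
and transfer protocols run in minutes on one CPU core.  The global-state
path is kept at least as wide as the 12 descriptors at every depth -- an
early narrower configuration (width 8) measurably hurt held-out accuracy by
bottlenecking the descriptor signal before the head could use it.  All
widths are configurable and recorded in checkpoints.

Ties on the two-dimensional output (`a == b`) classify as negative, the
conservative choice for screening.  Ranking ties keep input order (stable
sort).  All randomness -- weight initialization, batch shuffling, dropout
-- derives from one integer seed, and two runs with the same seed are
bitwise identical.

## Feature-mode ablations

`feature_mode` selects which global-state columns the model sees: `"MG"`
(graph only, no global state), `"MG+2D"` (the five conformer-independent
descriptors), `"MG+3D"` (the seven conformer-derived ones), or the full
`"MG+2D+3D"`.  On the synthetic benchmark below, the graph-only ablation
scores consistently below the full model (5 of 5 seeds in the acceptance
suite), because the planted rule deliberately loads on conformer-derived
descriptors that the graph cannot reconstruct.

## The synthetic study system

Real training data for this problem come from licensed structural
databases, so the package ships a generator instead of data.  It emulates
the *structure* of the real task, not its chemistry:

* `molecule_library(n, seed)` builds distinct, neutral, screening-compliant
  small molecules from a fragment grammar (benzene / pyridine / furan /
  cyclohexane cores; hydroxyl, amino, carboxyl, amide, nitro, halide,
  alkyl, nitrile substituents), with guaranteed donor-rich and donor-free
  subpopulations.
* `planted_pairs(library, m, rule, seed)` labels sampled unordered pairs by
  a planted rule: a weighted sum of both coformers' descriptors plus a
  donor/acceptor complementarity term `min(HBD_a, HBA_b) + min(HBD_b,
  HBA_a)`, thresholded at `tau`, with 2% label noise.  Pairs scoring within
  `margin = 0.3` of the threshold are treated as chemically borderline and
  never sampled -- curated experimental collections also consist of
  clear-cut outcomes.  The default threshold `tau = 3.18` was calibrated
  once so that the recorded study set (120-molecule library, seed 7; 600
  pairs, seed 1) shows the 6.5:1 positive:negative imbalance of real
  co-crystal data, and is not adjusted per dataset.

The benchmark library holds 120 molecules for 600 pairs.  This is a
compromise: real datasets pair thousands of distinct coformers, and small
libraries let a high-capacity model memorize molecule identities instead of
learning the rule (we observed exactly this failure with a 50-molecule
library: perfect training accuracy, weak held-out accuracy).

What passing tests on this generator do show: the architecture can extract
a descriptor-plus-complementarity signal from paired molecular graphs,
augmentation symmetrizes its scores, and transfer learning adapts it to a
family with altered descriptor weights.  What they do not show: anything
about real crystal-packing physics, polymorphism, or the chemistry of any
particular coformer family.

### A known limitation, quantified

The acceptance suite asks for mean held-out balanced accuracy of at least
0.90 under 3-fold cross-validation at the recorded study conditions.  The
measured value is about 0.85.  Three reference points put this in context,
all computed on the same folds: the clean planted rule itself -- the Bayes
optimum -- scores 0.932 against the noisy labels (2% flips concentrate in
the small negative class: 11 of the 90 nominal negatives are mislabeled
positives); a logistic fit given the *true* descriptor vectors scores
0.886; a descriptor-only MLP scores about 0.89.  With only 79 clean
negatives in 600 samples, every learner tested sits 4-8 points below the
ceiling, and the network is within 4 points of oracles that skip
featurization entirely.  The 0.90 bar therefore appears unreachable at
these exact conditions for any method, not just this one; the test is kept
at its stated threshold rather than weakened, and reports the honest value.

## Training protocols

* **Augmentation.**  Each labeled pair enters training twice, once per
  coformer order, and the swapped twin always stays on its original's side
  of every train/validation split (folds are assigned before augmentation).
  Measured effect: mean |score(A,B) - score(B,A)| on held-out pairs drops
  roughly tenfold (about 0.003 vs 0.03).
* **Cross-validation.**  Stratified k-fold with round-robin dealing within
  class; per-fold models are evaluated on their untouched fold and
  summarized as mean +/- sd of TPR/TNR/BACC.
* **Ensemble screening.**  The fold models vote: pairs are ranked by the
  sum of positive-class scores across members, and labels follow the
  majority of member decisions.
* **Transfer learning.**  For a small domain-shifted dataset, every
  pretrained model keeps its message-passing blocks, attention heads and
  first dense layer; exactly the last two dense layers are re-initialized;
  all weights are then finetuned (reduced learning rate, default 1e-4).
  With 10 pretrained models and 5-fold cross-validation of the small set,
  50 candidates are produced and the 10 with the lowest validation loss
  form the screening ensemble, ties broken by (pretrained, fold) index.
  The pretrained feature scaler is kept, so inputs are standardized exactly
  as during pretraining.

## Numerical choices

* Atom features and descriptors are z-scored with statistics of the
  training set, stored in the model and re-applied at prediction; constant
  columns keep unit scale.
* Weights use He-normal initialization; biases start at zero.
* The attention softmax subtracts the row maximum before exponentiation
  and assigns padded nodes zero weight, which makes predictions invariant
  to padding width to at least 1e-6.
* The compiled engine walks adjacency slices as directed edge lists, so
  cost scales with bond count rather than N^2; its forward pass agrees with
  the plain-R reference layers to 1e-10 and its gradients with central
  finite differences to 1e-4 at non-kink points.
* Degenerate geometry: a planar molecule legitimately has a zero short box
  axis; only (near-)collinear coordinates raise the degenerate-geometry
  warning, and box-ratio divisions by a (near-)zero axis return 0.
* Problem sizes used by the shipped benchmarks: 120-molecule library, 600
  pairs, 3-fold cross-validation at 100 epochs; 240 finetuning plus 120
  test pairs for the transfer benchmark at 10 finetuning epochs.  These are
  the package's own desk-scale choices and scale up linearly.

## Limitations

* The chemistry of the synthetic generator is schematic; no claim about
  real co-crystal systems follows from its benchmarks.
* Conformer-derived descriptors depend on the embedded conformer; a
  different (e.g. crystal-derived) conformer would shift them.  The seed is
  recorded so any result can be reproduced exactly.
* Intermolecular interaction edges (hydrogen bonds, pi stacking) between
  the coformers are deliberately not modeled; the covalent-bond-only
  variant was reported to perform at least as well and keeps featurization
  free of geometry between molecules.
* The solvent blacklist shipped for dataset screening is a reasonable
  stand-in list of room-temperature liquids and common solvents; it is
  configuration, not ground truth, and can be replaced by a file path.
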