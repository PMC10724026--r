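---
title: "pairdock: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{pairdock: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Given a rigid protein binding pocket with known 3D coordinates and a ligand
in an arbitrary unbound (apo) conformation, `pairdock` predicts

1. the matrix of intra-ligand heavy-atom distances in the bound state,
2. the matrix of pocket-ligand heavy-atom distances, and
3. a scalar binding affinity on the pK scale (−log10 of a binding constant),

then reconstructs the ligand's bound pose in the pocket frame by minimizing
the discrepancy between a candidate pose's Euclidean distances and the
predicted maps. Predicting distances rather than coordinates makes every
network stage a function of interatomic distances and graph topology only,
so the whole pipeline is invariant under rigid motions of its inputs by
construction — a property the test suite asserts to machine precision.

## Model

**Featurization.** Only heavy atoms are used. Ligand atoms carry one-hot
blocks for element (11 buckets), degree (0–5), formal charge (−2..+2),
aromaticity, ring membership, and hybridization (sp/sp2/sp3/other); bonds
carry type (single/double/triple/aromatic), conjugation and ring flags,
with an all-zero vector for unbonded pairs. Pocket atoms carry element plus
a backbone flag. This vocabulary is a documented package choice — any
dimension-consistent vocabulary slots in, since all widths are derived from
`pd_feature_dims()`.

**Molecule encoder.** Atom embeddings start as a linear map of the one-hot
features. Pair embeddings start from a pair-type-aware Gaussian encoding of
interatomic distance: distance `d_ik` is passed through a per-element-pair
affine transform, then a bank of `n_gauss` learnable Gaussian densities,
projected to the pair width, plus an additive bond-feature embedding for
bonded pairs. Each of `n_blocks` encoder blocks then applies:

- *atom attention*: multi-head self-attention over atoms, with the pair
  embedding projected to a per-head additive logit bias; the per-head
  pre-softmax logits are projected back into the pair track (residual),
  and the atom track gets a feed-forward sublayer;
- *self-triangular update*: pair (i,k) aggregates
  `sum_l (a_il ⊙ b_kl + a_li ⊙ b_lk)` with gated projections `a`, `b` — the
  outgoing- and incoming-edge triangle terms summed inside one update, and
  the sum over `l` running over all atoms including `i` and `k`;
- *pair axial attention*: pair (i,k) attends over the third index `l` in a
  single fused softmax with logits
  `(1/sqrt(c)) q_ik·(k_il + k_lk) + b_kl + b_li`, aggregating
  `v_il + v_lk` under a sigmoid gate.

Pocket and ligand encoders share this architecture with independent
weights.

**Mutual interaction block.** The complex pair tensor `z_ij` (ligand atom i
× pocket atom j) is initialized from the outer product of the two atom
embeddings, linearly projected. `n_iter` iterations (untied weights) then
apply: a complex triangular update
(`sum_k t_ik ⊙ a_kj + sum_k' b_ik' ⊙ p_k'j`), complex axial attention, and a
complex-to-ligand communication step (`t_ik += g ⊙ Linear(sum_j z_ij ⊙
z_kj)`) followed by one ligand pair-attention layer owned by the
interaction block. The pocket pair tensor is read-only here; the pocket is
rigid throughout.

Because the fused axial-attention softmax of the square pair track has no
counterpart on a rectangular grid (no pocket-pocket or ligand-ligand
complex pairs close the triangles), complex axial attention is realized as
gated multi-head attention applied twice — along rows and along columns —
each with a residual add and no third-edge bias.

**Heads and loss.** Distances are per-pair linear projections; the
intra-ligand map is symmetrized as the average of the (i,k) and (k,i)
predictions, since a single linear readout of an asymmetric pair tensor is
itself asymmetric. The affinity head concatenates `(z_ij, m_i, n_j)`, passes
a gated linear unit, mean-pools over all M·N pairs and applies a final
linear scalar head (the pooled quantity is a vector, so a scalar projection
is implied). Training minimizes
`alpha·L_inter + beta·L_lig + gamma·L_affinity`, each term a mean smooth-L1
(Huber, delta = 1) over the full distance matrices — diagonal included, per
the 1/(M·M) normalizer — with `alpha = beta = gamma = 1` by default.

**Pose generation.** Coordinates are initialized from a Gaussian (s.d. 3 Å)
centred at the pocket centroid and optimized by Adam (step 0.1, 1000
iterations, 4 restarts) on
`delta1·mean|D̃_inter − D_inter| + delta2·mean|D̃_lig − D_lig|`,
the L1 distance-map discrepancy; the lowest-loss restart is returned, and
across the 10 conformer-conditioned predictions the one with the lowest
generation loss (ties to the lowest conformer index) is selected, together
with its predicted affinity. The pocket anchors both the frame and the
chirality of the solution: with four or more non-coplanar pocket atoms the
mirror pose has a strictly worse intermolecular term.

## Gradients

No automatic-differentiation framework for deep models is available in this
R stack, so the package ships a small reverse-mode tape engine
(`R/autodiff.R`): ~20 matrix primitives with hand-derived adjoints,
including fused kernels for the per-channel triangular contractions, the
block attention and the fused pair-axial softmax. Every primitive is
validated against central finite differences (tolerance 1e−6) in the test
suite, and every layer against an independent naive-loop implementation of
its defining equations. Pose generation uses closed-form analytic gradients
of the L1 discrepancy instead of the tape.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `d_atom`, `d_pair` | 128, 64 | atom / pair embedding widths |
| `n_gauss` | 16 | Gaussian distance-encoding channels |
| `n_heads` | 8 | attention heads (all attention layers) |
| `n_blocks` | 4 | encoder blocks per molecule |
| `n_iter` | 4 | interaction iterations (untied weights) |
| `alpha, beta, gamma` | 1, 1, 1 | loss weights (inter, intra, affinity) |
| `delta1, delta2` | 1, 1 | pose-generation loss weights |
| `lr` | 1e−3 | Adam learning rate |
| `pose_lr`, `pose_steps`, `pose_restarts`, `pose_init_sd` | 0.1, 1000, 4, 3 Å | pose optimization |

The widths, depths and optimizer settings are package defaults chosen as
typical for this model family; they are not tied to any published
configuration and are freely overridable (YAML config via
`pd_config_from_yaml()`). Worked examples and the test suite use reduced
sizes (`d_atom` 32–64, 2 blocks, 2 iterations) so that everything runs on
one CPU core in minutes: at that scale a full forward pass over an 8-atom
ligand and 14-atom pocket builds a tape of ~500 nodes and a training step
over three complexes takes well under a second.

Ablation switches (`use_self_triangular`, `use_pair_axial`,
`use_complex_triangular`, `use_complex_axial`, `use_complex_to_ligand`)
remove exactly their submodule everywhere it occurs: the corresponding
parameters are never created, so parameter counts strictly decrease and the
remaining architecture stays valid.

## Numerical choices

- Pre-LN residual plumbing with a ×4 feed-forward expansion on the atom
  track; residual-branch output projections initialized at 1/10 Glorot
  scale so the network starts near the identity while every parameter
  receives gradient from the first step.
- Gaussian kernel `sigma` values are clamped below at 1e−5 (with zero
  gradient in the clamped region); kernel means initialize on a 0–15 Å grid
  with s.d. 2 Å, covering the distance range of pocket-scale geometry.
- The pair tensor is not re-symmetrized after updates (the triangular and
  axial updates are not symmetric operations); only its initialization is
  symmetric by construction. Symmetry of the final distance prediction is
  restored in the head by averaging.
- Smooth-L1 is continuous and once-differentiable at its branch point
  (both branches equal 0.5 at |x−y| = 1).
- In pose generation, gradient contributions of coincident points
  (distance < 1e−9) are zeroed to avoid division by zero; non-convergence
  is not an error — the best pose found is returned with its loss.
- KMeans clustering of conformers uses the flattened pairwise-distance
  matrix as the feature vector (rotation/translation invariant), 5 random
  starts under a fixed seed, and the member nearest each centre as the
  representative. When fewer distinct geometries than clusters exist (rigid
  molecules), clustering is bypassed and members are recycled to the
  requested count.

## Conformer generation

Unbound conformers are produced by the package's own distance-geometry
embedder: bond lengths from covalent radii scaled by bond order, 1–3
distances from ideal angles by hybridization (109.47°/120°/180°), a 2.4 Å
lower bound on all other pairs, minimized by L-BFGS from seeded random
starts; torsional diversity comes from the random initialization, and an
embedding whose bond lengths deviate by more than 0.3 Å after five
restarts raises an error naming the molecule. A pool of 100 embeddings is
reduced to 10 representatives by the KMeans procedure above, mirroring the
preprocessing protocol the training loop expects.

## What the synthetic generator emulates — and what it does not

`make_synthetic_complex()` builds a random branched/ringed small molecule
(C/N/O, valence-capped, occasional double bonds and one ring closure), a
planted bound pose from the distance-geometry embedder, a pocket shell of
6–20 atoms sampled 2.5–5 Å from random ligand atoms (clash-rejected,
grouped into 4-atom residues), a pK label that is a smooth saturating
function of the planted contact count (atoms within 4 Å) plus Gaussian
noise (s.d. 0.2), and 10 apo conformers obtained by independent re-embedding
plus 0.3 Å jitter. Every quantity is a deterministic function of the seed.

This exercises all interfaces and learning mechanics, but real
protein-ligand data differs in ways the synthetic conditions do not probe:
genuine chemistry (aromatic systems, charges, realistic torsion
preferences), pockets with residue-level structure and chemically biased
contacts, labels generated by physics rather than a known smooth function,
and dataset-scale diversity. Passing the desk-scale checks therefore
demonstrates correctness of the machinery — SE(3) invariance, oracle-exact
layers, recoverable poses, a trainable objective — not benchmark-level
accuracy on crystal structures.

## Problem sizes used by the checks

The automated checks run, per invocation: 20 random complexes (4–8 ligand
atoms, 6–12 pocket atoms) for invariance; layer oracles at M, N ≤ 6; 20
plant-and-recover instances (M ≤ 10, N ≤ 20, 4 restarts × 1000 steps); a
500-step overfit of the reduced model (d_atom 64, 2 blocks, 2 iterations)
on three 8-atom/14-atom complexes; and 25 random proteins for the 6 Å
residue rule. These sizes are the package's chosen desk-scale study
conditions and are stated here so results are reproducible.

## Known limitations

- The engine is single-threaded dense R; it is meant for desk-scale models
  and correctness, not for training on tens of thousands of complexes.
- No batching across complexes inside one tape (complexes are summed
  sequentially); no GPU path.
- The distance-geometry embedder ignores stereochemistry and produces
  racemic conformer pools.
- Aromaticity perception for parsed ligands relies on ring perception of
  the kekulized input; exotic aromatic systems may fall back to the
  non-aromatic encoding.
- Affinity prediction at desk scale is only exercised as a loss component
  and an overfit target; calibrated pK prediction requires real training
  data.
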