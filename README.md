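# pairdock

Binding-pose and affinity prediction for protein–ligand complexes in R.
Given a rigid binding pocket (3D coordinates) and a ligand in any unbound
conformation, `pairdock` predicts the bound-state **intra-ligand** and
**pocket–ligand atom-pair distance maps** plus a scalar **binding affinity**
(pK = −log10 of a binding constant), then reconstructs the ligand's 3D pose
by gradient optimization against the predicted maps. It is aimed at
structural bioinformaticians and method developers who want a fully
inspectable, CPU-scale implementation of this model family — every layer is
oracle-tested against naive-loop reference code.

## The model in brief

Ligand and pocket are encoded over heavy atoms only. Atom embeddings
`m_i = W_h h_i` start from one-hot features; pair embeddings start from a
pair-type-aware Gaussian encoding of interatomic distance
`t_ik = concat_h G(A(d_ik, c_ik; a, b), mu_h, sigma_h) (+ W_e e_ik)`,
so every downstream quantity depends on distances and topology alone
(SE(3)-invariant by construction). Encoder blocks alternate atom
self-attention (pair-biased, logits fed back to the pair track), a
triangular multiplicative update

    t_ik <- t_ik + g_ik ⊙ Linear( Σ_l a_il ⊙ b_kl + a_li ⊙ b_lk )

and pair axial attention with third-edge bias. A complex pair tensor
`z_ij = Linear(m_i ⊗ n_j)` then co-evolves with the ligand pair tensor
through iterated triangular updates
(`Σ_k t_ik ⊙ a_kj + Σ_k' b_ik' ⊙ p_k'j`), row/column axial attention and a
complex-to-ligand communication step (`Σ_j z_ij ⊙ z_kj`). Linear heads read
out the two distance maps and a mean-pooled gated head the affinity. The
training objective is

    L = alpha · smoothL1(D_inter) + beta · smoothL1(D_lig) + gamma · smoothL1(pK)

and poses are generated by Adam descent of the L1 discrepancy between a
candidate pose's distances and the predicted maps, with restarts, conformer
conditioning and lowest-generation-loss selection.

Because no deep-learning autodiff framework exists in this R stack, the
package includes a compact reverse-mode tape engine with hand-derived,
finite-difference-verified adjoints for all ~20 primitives (see
`vignettes/pairdock-methods.Rmd`).

## Worked example

```r
library(pairdock)

# three small synthetic complexes with planted bound poses and pK labels
cxs <- lapply(1:3, function(i) make_synthetic_complex(M = 8, N = 14,
                                                      seed = 20 + i))
cxs[[1]]$ligand
#> <ligand_record> 8 heavy atoms, 7 bonds, 10 conformer(s), holo pose, pK = 5.98

# reduced model: 64/32-wide embeddings, 2 encoder blocks, 2 interaction iters
cfg <- pd_config(d_atom = 64L, d_pair = 32L, n_gauss = 16L, n_heads = 4L,
                 n_blocks = 2L, n_iter = 2L)
fit <- pd_train(cxs, cfg, steps = 500L, seed = 1L)
round(fit$history[c(1, 100, 500)], 3)
#> [1] 12.232  0.518  0.030

# predict: run all 10 apo conformers, keep the lowest-generation-loss pose
pred <- pd_predict(fit$model, cxs[[1]]$ligand, cxs[[1]]$pocket, seed = 9L)
pred$pose
#> <pose_result> 8 atoms, generation loss 0.1481 (conformer 2)
ligand_rmsd(pred$pose$coords, cxs[[1]]$ligand$holo_coords)
#> [1] 0.245363
```

The training loss falls by ~99.8% while the model learns to map any of the
10 unbound conformers to the bound-state distance maps; the reconstructed
pose lands 0.25 Å from the planted bound pose, and `pred$affinity` (5.986
here, against a 5.984 label) is the pK prediction attached to the selected
pose.

Real data goes through the same interface:

```r
lig <- parse_ligand("ligand.sdf")                      # or a SMILES string
poc <- extract_pocket(read_protein("protein.pdb"),     # 6 A residue rule
                      lig$conformers[[1]])
lig <- generate_conformers(lig, n_generate = 100, n_keep = 10, seed = 1)
```

A thin command-line interface (`inst/cli/pairdock`) wraps the same
functions: `preprocess` (PDB + SDF → JSON-lines complexes), `train`,
`predict` (writes the pose SDF and a CSV row with conformer index,
generation loss and predicted affinity) and `evaluate`. Exit codes: 0 ok,
2 ligand parse error, 3 empty pocket.

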