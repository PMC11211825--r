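# dtafuse

Multi-view graph learning for drug–target binding affinity (DTA) and
binary drug–protein interaction (DPI) prediction, for computational
chemists and method developers who want an inspectable, fully tested
reference implementation that runs anywhere R runs — no GPU, no
downloads.

## The model

A compound–protein pair is encoded from four views and fused by a
context-aware gate:

* **Atom–bond graph** of the compound: atoms as nodes, bonds as directed
  attributed edges (type + stereo); node features are provider atom
  embeddings (N×32) or a handcrafted descriptor set. Encoded by a stack
  of multi-head graph attention (GAT) layers in which bond features bias
  the attention logits:
  `e_ij = LeakyReLU(aᵀ[Wh_i ‖ Wh_j] + bᵀf_ij)`,
  `α_ij = softmax_j(e_ij)`, `h'_i = σ(Σ_j α_ij W h_j)`, heads
  concatenated.
* **Pharmacophore graph**: SSSR rings and acyclic bonds as coarse nodes,
  adjacent iff they share an atom; permutation-invariant unit features;
  GAT-encoded.
* **Residue contact graph** of the protein: an edge wherever the
  predicted contact probability strictly exceeds 0.5, weighted by that
  probability. Encoded by GCN → GCN → GAT, with
  `H⁽ˡ⁺¹⁾ = σ(D̃^{-1/2}(A+I)D̃^{-1/2} H⁽ˡ⁾ W⁽ˡ⁾)` on the weighted
  adjacency.
* **Sequence embedding**: provider residue embeddings (L×1280) averaged
  over positions, passed through an MLP.

Graph embeddings are max-pool readouts. The concatenated compound and
protein embeddings `D_com`, `P_com` are projected to a common width and
mixed per coordinate:

```
w = sigmoid(W₂ ReLU(W₁(D_com + P_com) + b₁) + b₂)
embedding = D_com ⊙ w + P_com ⊙ (1 − w)
```

An MLP head outputs a real-valued affinity (squared-error loss) or a
sigmoid interaction probability (cross-entropy). Atom-level attributions
come from gradient-weighted activation mapping over the final
atom–bond GAT layer. All layers, their analytic backward passes and the
Adam loop are implemented in the package and verified against
central-difference gradients and dense brute-force oracles.

Also included: k-fold / 8:1:1 / cold-start (unseen drug, unseen protein,
unseen pair) splitters; MSE, concordance index, rm2, Pearson, Spearman,
AUC/precision/recall/F1 and silhouette/Calinski–Harabasz/Davies–Bouldin
metrics; benchmark-layout readers/writers (with the Davis-style
`pKd = −log₁₀(Kd/10⁹)` transform); deterministic offline embedding
providers; a virtual-screening helper; and a synthetic benchmark
generator with a plantable structure→affinity signal.

SMILES parsing, ring perception and fingerprints are delegated to RDKit
through a bundled Python helper (`inst/python/mol_tools.py`); a Python
with `rdkit` on the PATH is the only system requirement.

## Worked example

Train the full model on a small synthetic benchmark (60 compounds × 20
targets, planted signal) and evaluate the held-out fold:

```r
library(dtafuse)

ds <- generateSyntheticBenchmark(synthConfig(nDrugs = 60, nProteins = 20,
                                             seed = 11))
ds
#> DTADataset: 60 compounds x 20 targets, 1200 measured affinities

cfg <- dtaConfig(hidden = 16, heads = 2, fusionDim = 32, seqDim = 64,
                 dropout = 0.1)
split <- makeKfoldSplit(ds, 6, seed = 2)[[1]]
fit <- trainModel(dtaModel(cfg, seed = 1), ds, split, seed = 3,
                  lr = 5e-3, epochs = 60, batchSize = 4000)
ev <- evaluateModel(fit$model, ds, testIdx(split), fit$features)
round(ev$metrics, 3)
#>      mse  pearson spearman       ci      rm2
#>    0.228    0.739    0.687    0.752    0.517
```

The test MSE (0.228) approaches the generator's noise floor (σ² = 0.09),
and a concordance index of 0.75 means three in four test pairs are
ranked correctly — the model has recovered most of the planted
fragment/motif/interaction signal from structure alone. Attribution
scores are per-atom, max-normalized to [0, 1]:

```r
pair <- featurizeDrugs("Cc1ccncc1", cfg)[[1]]
prot <- featurizeProteins(proteins(ds)[[1]], cfg)
round(gradAAM(fit$model, pair, prot), 3)
#> [1] 1.000 0.790 0.596 0.634 0.654 0.634 0.596
```

A thin CLI over the same functions (verbs `synth`, `featurize`, `split`,
`train`, `evaluate`, `screen`, `explain`) ships at
`inst/cli/dtafuse.R`.

## Package layout

* `R/` — S4 classes (`Molecule`, `AtomBondGraph`, `PharmacophoreGraph`,
  `ResidueContactGraph`, `DTADataset`, `SplitSpec`, `DTAModel`),
  encoders with backprop, fusion, training, metrics, splits, IO,
  synthetic generator.
* `vignettes/multiview-affinity.Rmd` — the methods vignette: model,
  assumptions, design decisions, what the synthetic benchmark does and
  does not show.
* `tests/testthat/` — unit and property tests per module plus the
  end-to-end acceptance suite (oracle equivalence, invariants,
  learnability, attribution sanity).
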