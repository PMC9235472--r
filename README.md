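# mlpathway

Multi-label prediction of the metabolic pathway classes a small-molecule
compound participates in, from its molecular graph alone — with the
pathway labels treated not as independent targets but as nodes of a
directed dependence graph learned from their co-occurrence statistics.

## Who this is for

Cheminformaticians and drug-discovery researchers who need to triage which
of a fixed set of metabolic pathway classes (e.g. the eleven top-level KEGG
metabolism categories: carbohydrate metabolism, energy metabolism, lipid
metabolism, ...) a compound is likely to attend, and who additionally want
bond-level attribution: which substructures of the molecule drove each
call.

## The model

Three jointly trained components:

**Compound encoder.** A SMILES string is parsed into a heavy-atom graph
G = (V, E) with adjacency A and 78-dimensional binary atom features
(44-d element one-hot, 11-d degree, 11-d hydrogen count, 11-d implicit
valence, 1 aromaticity bit). One multi-head graph-attention layer scores
each neighbor pair per head k as

    e_ij = LeakyReLU( a_k' [ W_k h_i || W_k h_j ] )

normalizes by a softmax over the neighborhood of atom i (self included),
aggregates with ReLU, and concatenates K heads. A graph-convolution layer
then propagates with the symmetric-normalized operator
D̃^(-1/2) (A + I) D̃^(-1/2), and a readout concatenating global max- and
mean-pooling yields the compound embedding z (1560-d at reference size).

**Pathway encoder.** From the training labels, pairwise co-occurrence
counts U and occurrence totals N give conditional probabilities
p_ij = u_ij / N_i (asymmetric: pathway crosstalk has direction). These are
hard-thresholded at τ into a binary dependence matrix M, column-normalized
into M_w, and combined with the identity as M_x = α·M_w + I. Two
graph-convolution layers with the row-stochastic operator D_x^(-1) M_x map
the pathway node features Q — word-vector means of the pathway names, in
GloVe text format — to the pathway embedding matrix O (C × B).

**Predictor.** A three-layer dense adapter maps z into the pathway
embedding space (1560 → 1500 → 1024 at reference size); logits are the
plain dot products Ŷ = O z̃, trained with mean per-label binary
cross-entropy. The head-and-direction-averaged attention coefficients of
each chemical bond provide the per-bond importance used for
interpretation.

Evaluation uses the eight standard multi-label metrics: micro accuracy,
precision, recall, F1, Hamming loss, ranking loss, coverage and one-error.

## Worked example

```r
library(mlpathway)

# a synthetic dataset: 500 compounds, 6 pathway labels, structure-determined
# memberships with a planted carbohydrate/energy co-occurrence
res <- run_learning_sanity(seed = 1)

res$initial_loss      # 0.691  -- mean BCE at initialization (~ln 2)
res$final_loss        # 0.174  -- after 50 epochs
res$metrics$f1        # 0.916  -- held-out micro-F1
res$metrics$coverage  # 2.26   -- labels to scan to cover all true ones
res$f1_random         # 0.364  -- random-score baseline

# bond-level attribution on held-out compounds
imp <- model_bond_importance(res$state, res$test_table)
head(imp[order(-imp$weight), c("compound_id", "symbol_i", "symbol_j", "weight")])
```

The held-out F1 of 0.92 against a 0.36 random baseline shows the encoder
recovers the planted substructure-label associations; sulfur/phosphorus
bonds (planted for the energy-like label) receive mean attention ~0.38
versus ~0.32 on carbon-carbon backbone bonds.

For a real dataset, prepare a CSV with columns `id`, `smiles` and one
binary column per pathway, then:

```sh
exec/mlpathway data stats compounds.csv
exec/mlpathway cv --data compounds.csv --k 10 --epochs 200
```

`cross_validate()` rebuilds the pathway dependence graph from each
training split only, so held-out co-occurrence never leaks into training.

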