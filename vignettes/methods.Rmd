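---
title: "Methods: multi-label pathway prediction over molecular and label graphs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multi-label pathway prediction over molecular and label graphs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(mlpathway)
```

## The problem and the modelling idea

A compound can participate in several metabolic pathway classes at once,
and those classes are not independent: pathways share metabolites and
enzymes, and upstream/downstream relationships make the dependence
*asymmetric* — observing membership in pathway *i* may strongly predict
membership in pathway *j* without the converse holding. Standard
multi-label classifiers over molecular descriptors ignore this label
structure. `mlpathway` couples two graphs: the molecular graph of each
compound, and a directed dependence graph over the pathway labels
themselves, estimated from label co-occurrence in the training data.
Prediction is by proximity: compounds and pathways are embedded into a
common space and scored by dot products, so a pathway's embedding acts as
a learned prototype that dependent pathways help shape.

## Compound encoder

Atoms are featurized with 78 binary indicators: a 44-slot element one-hot
(43 named elements plus an `other` slot; the list is frozen in
`atom_symbol_vocabulary()` because changing it silently changes feature
indices), 11-bucket one-hots for heavy-atom degree, attached hydrogens and
implicit valence (counts above 10 clamp into the last bucket — the finite
blocks force a choice and clamping preserves "many"), and one aromaticity
bit. Hydrogens are implicit: the graph contains heavy atoms only, and the
hydrogen count enters through the feature vector. We take the implicit
valence equal to the attached-hydrogen count, which coincides with the
usual convention for organic SMILES written without bracket atoms; the
chemistry toolkit used for parsing does not expose a separate
implicit-valence field.

The attention layer follows the standard graph-attention formulation:
per-head scores `e_ij = LeakyReLU(a' [W h_i || W h_j])` with negative
slope 0.2, softmax-normalized over each atom's neighborhood *including the
atom itself*. The self-loop choice matters for isolated atoms (their
neighborhood would otherwise be empty) and follows the original
graph-attention convention; without it, single-heavy-atom molecules such
as methane would have undefined attention. Head outputs pass through ReLU
*before* concatenation. The convolution layer that follows uses the
symmetric normalization `D̃^(-1/2)(A + I)D̃^(-1/2)`; note this deliberately
differs from the row normalization used on the label graph below — the
molecular graph is undirected, the label graph is not. The readout
concatenates column-wise max and mean pooling, making the embedding
invariant to atom order (verified by a permutation test).

## Pathway dependence graph and encoder

From training labels only: co-occurrence counts `U` (symmetric, zero
diagonal), occurrence totals `N`, conditional probabilities
`p_ij = u_ij / N_i`, a hard threshold τ giving the binary dependence
matrix `M`, and a column re-weighting `m_w_ij = m_ij / colsum_j(M)`.
Numerical guards: a label absent from a training fold (`N_i = 0`)
contributes a zero row rather than NaN — relevant for small folds; an
all-zero column passes through re-weighting unchanged. The diagonal of `U`
and `M` is forced to zero because self-dependence enters once, through the
identity term of the propagation operator `M_x = α·M_w + I`; keeping it in
`M` as well would double-count. The re-weighting is implemented as a
*column* normalization, read off the re-weighting scheme as printed in the
label-graph literature this design follows; since the printed notation is
typographically ambiguous between row and column sums, we chose columns
and verified the hand-worked 3-label example either way — the package
exposes the chain step by step (`count_cooccurrence`,
`conditional_probability`, `binarize_dependence`, `reweight_dependence`)
so the alternative is a one-line change for anyone replicating the other
convention.

Node features `Q` are means of word vectors over the tokens of each
pathway name (lower-cased, punctuation stripped). This encodes a useful
prior: pathway names that share tokens — e.g. *amino acid metabolism* and
*metabolism of other amino acids* — get similar initial embeddings, and
such name-similar pathways are exactly the ones that tend to co-occur.
Out-of-vocabulary tokens are skipped; a fully out-of-vocabulary name falls
back to a seeded Gaussian vector. The bundled
`inst/extdata/mini_word_vectors.txt` is a **synthetic** 10-dimensional
vector file for tests and examples, not trained embeddings: content
tokens are unit-norm and nearly orthogonal, function words are low-norm,
and the token pair *acid*/*acids* is nearly collinear so that the
name-similarity prior is expressible at test scale.

Two graph-convolution layers with the row-stochastic operator
`D_x^(-1) M_x` (row sums of `M_x` are positive for every α because of the
identity term, so the inverse always exists) and LeakyReLU activation with
slope 0.01 produce the pathway embedding matrix `O`. The trade-off α
scales how much a pathway's update draws on the labels it depends on;
α = 0 recovers independent labels.

## Predictor, loss, decisions

The adapter is a dense input–hidden–output network with ReLU hidden
activation (matching the compound encoder's activation; the choice is not
forced by anything and is recorded here as a convention). Logits are
bias-free dot products `Ŷ = O z̃`. The loss is the mean over labels of
binary cross-entropy with logits, computed via a log1p-based softplus that
is finite for logits beyond ±1e4; its gradient `σ(ŷ) − y` is verified
against finite differences in the tests. Binary decisions threshold the
sigmoid probability at 0.5 by default (exposed as a parameter); ranking
metrics never use the threshold.

## Metrics

Accuracy, precision, recall and F1 are **micro label-based**, pooling
(sample, label) cells. Under this definition accuracy and Hamming loss are
exact complements (`accuracy + HL = 1`, asserted in the tests), which is
the consistency argument for preferring it over subset accuracy when the
two could be confused. Coverage is reported 1-based by default with a
`zero_based` switch, since both conventions circulate. Ranking ties break
by ascending label index (`ties.method = "first"`), documented and tested;
samples with no (true, false) pair are excluded from the ranking-loss
average. Zero-denominator precision/recall return 0 with a warning.

## Training

Minibatch Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8) on analytically derived
gradients; every gradient path (attention, both convolutions, readout
max/mean split, adapter, label-graph layers) is validated against central
finite differences. No dropout, weight decay, gradient clipping, learning
rate schedule, or early stopping — none proved necessary at either scale,
and leaving them out keeps the optimization fully described by the seed,
which controls initialization (Glorot uniform) and batch order. Two runs
with the same seed agree to 1e-6 in final loss.

Reference (full-size) hyperparameters: K = 10 heads of width 78 (780
concatenated), compound convolution width 780 (1560-d embedding), adapter
1560–1500–1024, 300-d pathway features, two 1024-d label-graph layers,
τ = 0.5, α = 0.3, learning rate 5e-4, 200 epochs, batch 256. The
`reduced_config()` used by the reference experiments keeps every component
and shrinks widths (2 heads × 16, 32-d convolution, 64-d adapter hidden,
10-d pathway features, 32-d label-graph layers) with learning rate 5e-3 —
a smaller model tolerates and benefits from the larger step size.

## What the synthetic fixtures emulate — and what they do not

`generate_fixture()` draws label vectors from a thresholded Gaussian
copula whose pairwise correlations are calibrated (by numerically solving
the bivariate orthant probability) so empirical marginals and pairwise
co-occurrences converge to a requested specification; all-zero rows are
redrawn, since the data model contains only pathway-annotated compounds
(this redraw slightly inflates marginals — at the specifications used, by
well under the sampling noise at the test sizes). SMILES are assembled
from a curated vocabulary of ~40 valid fragments in six chemical families;
each positive label contributes a fragment of its assigned family with a
per-label probability (`structure_strength`), so membership is genuinely
structure-determined, the way real pathway annotation is. A label whose
name contains "energy" maps to the sulfur/phosphorus family, planting the
substructure-label association probed by the attention experiments.

Two named fixture specifications freeze the study conditions:

* `fixture_spec_structured()` — six labels, 0.3 marginals, one strongly
  co-occurring pair (conditional 0.9), all labels strongly
  structure-determined (0.9). Used for learning sanity (500 compounds,
  50 epochs, 80/20 split) and attention localization (300 compounds,
  40 epochs, 5 seeds).
* `fixture_spec_crosstalk()` — a rare label (marginal 0.2), nearly
  structure-free (strength 0.1) but strongly dependent on a common,
  strongly structured partner (p(partner | rare) = 0.9), with the pair
  sharing name tokens. This is the regime where label-dependence
  information is decisive: the rare label has too few positives to learn a
  prototype from scratch, so the dependence edge and the name-based
  initialization carry the signal. Used for the ablation study
  (200 compounds, 60 epochs, 5 seeds × 3 arms).

What the fixtures do **not** emulate: realistic molecular size and
diversity (fragment assemblies of at most three pieces versus real
metabolites), class imbalance at real-data severity, label noise from
incomplete annotation, and semantically meaningful word vectors. Passing
the reference experiments therefore demonstrates that the machinery
learns, that the dependence components help in the regime they target,
and that attention localizes planted substructures — not that real-data
accuracy figures will be reproduced.

## Known limitations and open choices

* Fold assignment is uniform at the compound level, not label-stratified;
  with rare labels and small folds a label can vanish from a training
  fold (handled by the zero-row guard, but the fold's model cannot
  predict that label well). Stratification was left out because plain
  k-fold is the stated protocol of the cross-validation experiments this
  package mirrors.
* The dependence graph is rebuilt per training fold by default (leak-free)
  rather than once from all data; the full-data variant is a one-line call
  (`build_dependence_graph` on the full table) for replication purposes.
* Open Babel's aromaticity perception may differ from other toolkits for
  edge-case ring systems, which shifts the aromatic bit and hence feature
  vectors; graphs are otherwise toolkit-stable.
* The grid-search utility trains one model per (τ, α) cell on a single
  80/20 split — a deliberately cheap mirror of the full grid experiment,
  not a tuning framework.
* Attention weights are reported as explanation, not validated
  attribution: no faithfulness benchmarking is attempted, and the
  min-max-rescaled display weights are provided alongside raw ones
  because either convention is defensible for visualization.
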