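---
title: "Predicting protein-protein interactions with stacked generalization over hybrid pair features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-protein interactions with stacked generalization over hybrid pair features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem and the model

Experimentally mapping protein-protein interactions (PPIs) is slow and
noisy, so computational predictors that label a candidate protein pair as
*interacting* or *non-interacting* are a standard complement to
high-throughput screens. ppistack implements a supervised predictor whose
two ingredients are (a) a hybrid, training-data-adaptive representation of
a protein pair and (b) a two-level stacked-generalization ensemble.

Three feature blocks describe a pair $\langle P_i, P_j\rangle$:

**F1 — sequence auto-covariance.** Each residue is mapped to the values of
14 physicochemical property scales (two hydrophobicity scales, a
hydrophilicity scale, net charge index, two polarity scales,
polarizability, solvent-accessible surface area, side-chain volume,
flexibility, accessibility, exposed fraction, a turns scale and antigenic
propensity; `physchem_scales()` ships the 20 x 14 table as a TSV). The
lagged auto-covariance of scale $i$ at gap $g$,
$$AC_{i,g} = \frac{1}{L-g}\sum_{j=1}^{L-g}
  (P_{i,j}-\mu_i)(P_{i,j+g}-\mu_i),$$
summarizes a length-$L$ sequence into $14 \times G$ numbers for gaps
$g = 1 \dots G$, so proteins of any length share one vector form. A pair
is represented by *both* concatenation orders
$[V(P_i)V(P_j)]$ and $[V(P_j)V(P_i)]$; training uses both as instances
with the same label, and prediction averages the two orders' class
probabilities, which makes `predict(m, A, B)` and `predict(m, B, A)`
identical by construction.

**F2 — LCA-indexed GO-term clusters.** For every training pair we find the
lowest common ancestor (LCA) of the union of the two proteins' GO
annotations, per subontology. The deduplicated LCAs, processed deepest
level first, greedily carve the subontology DAG into mutually exclusive
LCA-rooted clusters (each LCA claims its not-yet-claimed descendants). A
pair then encodes, per cluster, the number of distinct cluster terms on
the ascending paths from its annotated terms up to the cluster root. The
feature set therefore *adapts to the training data*: different training
pairs yield different clusters, in number and content.

**F3 — network topology.** Protein-level Resnik similarity (the maximum
information content over common ancestors of the annotation cross-product,
maximized over subontologies) scores all training protein pairs; a
threshold $\theta_R$, chosen so the thresholded graph's average degree
matches the reference graph built from positive training labels, defines
the network $N_{PPI}$. Five symmetric link-prediction features are read
off its neighbour sets: common-neighbour count, Jaccard index, Adamic-Adar
index, preferential attachment, and the Otsuka-Ochiai (cosine)
coefficient.

**Stacking.** Four base learners — random forest, Gaussian naive Bayes, a
single-hidden-layer neural network, and inverse-distance-weighted kNN —
are trained on the (normalized) feature rows. Their out-of-fold
interacting-class probabilities form the meta-data on which an RBF-kernel
SVM arbitrates; its cost and gamma are grid-searched by internal
cross-validated MCC. The decision threshold $\tau$ maximizes MCC on the
pair-level (order-averaged) out-of-fold training probabilities.

```{r}
library(ppistack)
ds <- generate_dataset(synthetic_config(seed = 1, n_pairs = 100))
model <- ppi_stack(ds, seed = 1)
glance(model)
predict(model, ds$pairs[1:5, ], proteins = ds$proteins,
        annotations = ds$annotations)
```

## Assumptions

* Interacting proteins tend to share biological process / component /
  function, i.e. annotations with a deep common ancestor, and sequence
  composition regularities; non-interacting pairs do not.
* Annotations and sequences available at prediction time are drawn from
  the same ontologies (and a comparable annotation regime) as the
  training data. Terms outside every training-derived cluster simply
  contribute nothing.
* Pairs are unordered; self-pairs are excluded.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `max_gap` (G) | 30 | AC gaps per scale; F1 length is $2\times14G$ per pair. Capped at the shortest training sequence length minus one (warned). The default follows the common auto-covariance convention for PPI sequence encodings; the value is a capacity knob, not a biological constant. |
| `rf_ntree` | 500 | random-forest trees |
| `ann_size`, `ann_decay`, `ann_maxit` | 16, 0.1, 200 | hidden units, weight decay and iteration cap of the `nnet` base learner. Weight decay plus an iteration cap is `nnet`'s idiomatic regularizer; a 100-unit layer with early stopping would be oversized for desk-scale data and `nnet` offers no early stopping. |
| `knn_k` | 5 | neighbours, inverse-distance vote weights |
| `svm_cost`, `svm_gamma` | {0.1, 1, 10, 100} x {default, 0.01, 0.001} | meta-SVM grid, selected by internal `grid_folds`-fold CV MCC; `NA` gamma = kernel default $1/n_{features}$ |
| `meta_folds` | 5 | internal stratified folds for out-of-fold meta-data |
| `base_learners` | rf, nb, ann, knn | any subset; a single base degenerates to a 1-feature meta-SVM |

## Numerical and procedural choices

* **Short proteins / large gaps.** $AC_{i,g} = 0$ when $g \ge L$ (empty
  sum), so every protein yields a full-length vector.
* **Normalization.** Features are standardized then min-max rescaled to
  $[0,1]$, fit on training rows only; zero-variance features use SD = 1,
  zero-range features map to 0, and test-time values outside the training
  range are clipped to $[0,1]$ (outlier suppression). F2 and F3 pass
  through the same fit-on-train scaling as F1 so the blocks are
  commensurate.
* **Non-standard residues** (B, Z, X, U, O, `*`): dropped with a warning
  by default (the scale table covers the 20 essentials); an `"error"`
  policy is available.
* **Hierarchical level** of a term is the longest path from the root (the
  standard GO depth convention on DAGs); LCA processing order is deepest
  first, ties by lexicographic term id. When a DAG admits several lowest
  common ancestors, the deepest (then lexicographically first) wins.
* **Ascending-path counts** are restricted to the cluster: a term whose
  every upward route leaves its cluster before reaching the cluster's LCA
  contributes nothing. Pairs are encoded over the union of both proteins'
  terms, which makes the encoding symmetric.
* **Information content** uses natural log, with annotation counts
  propagated to all ancestors over the training-split corpus (so the root
  always has IC 0); Adamic-Adar also uses natural log and skips degree-1
  common neighbours (log 1 = 0) with a warning.
* **Threshold $\theta_R$** is drawn from the observed similarity values
  (edges kept at similarity $\ge \theta_R$), the candidate with average
  degree closest to the reference network winning; ties resolve to the
  larger threshold (sparser network), an empty reference selects
  $+\infty$, and all-equal similarities warn.
* **Decision threshold $\tau$** searches the sorted unique training
  probabilities; MCC ties resolve to the smaller $\tau$ (higher
  sensitivity).
* **Out-of-fold grouping.** The two concatenation orders of a pair share
  an internal fold — they carry the same label and identical F2/F3 blocks,
  so splitting them would leak into the meta-data.
* **Prediction symmetry** is exact, not approximate: pairs are oriented
  canonically (lexicographically) before the instance matrix is built, so
  both argument orders produce bit-identical computations.
* **Degraded inputs.** Proteins without sequences (F1) or annotations
  (F2/F3) at prediction time encode to zeros with a warning; proteins
  absent from the training network are isolated nodes.
* **All-constant feature matrices.** When a feature block degenerates to
  an entirely constant matrix in some internal fold (e.g. every training
  pair isolated in a very sparse network), base learners fall back to the
  class-prior probability instead of being handed an uninformative matrix
  (which some tree implementations handle badly).

## The evaluation protocol

`ppi_cv()` runs repeated stratified k-fold CV (default 3 x 10; repeat $r$
assigns folds with `seed + r - 1`), refitting *every* training-derived
artifact — normalizer, partitions, IC table, $\theta_R$, base and meta
learners, $\tau$ — inside each training split. Per-run reports carry the
seven measures TPR, FPR, precision, accuracy, F-score, MCC and AUC (AUC by
the tie-corrected rank / Mann-Whitney form). The primary pooled summary is
the mean of per-run metrics; metrics of the pooled predictions are kept as
a secondary diagnostic. `ppi_ablation()` evaluates feature subsets on
identical fold assignments so `paired_metric_test()` (two-sided paired t;
zero-variance differences report p = 1 with a flag) applies;
`ppi_cross_test()` fits on one dataset and evaluates once on another,
optionally restricted to a single subontology.

## What the synthetic generator emulates — and what it does not

`generate_dataset()` draws proteins partitioned into latent functional
modules. Each module owns a disjoint branch of every random subontology
(the DAG generator allocates non-root terms to branches round-robin, each
term attaching to one or two earlier terms of its own branch), and a
protein's annotations are sampled from its module's branch. With
probability `go_signal` an interacting pair is drawn within one module and
a non-interacting pair across two modules; each module also owns a
sequence motif carried by its proteins with probability `motif_rate`.
Interacting pairs therefore share deep GO ancestors (elevated Resnik
similarity, shared LCA clusters, network proximity) and sequence signal by
construction, which is exactly the structure the predictor assumes.
Defaults (4 modules, three 40-term subontologies, 3 annotations per
protein per ontology, sequences 50-120 aa, `go_signal = motif_rate = 0.9`,
no annotation noise) represent this clean modular regime; `noise_terms`,
`noise_rate` and `go_signal = 0` degrade it down to the null case where
labels are independent of every feature.

Passing tests on these data show the pipeline recovers planted modular
signal and stays calibrated under the null. They do *not* show performance
on real interactomes: the generator has no scale-free degree
distribution, no annotation-depth bias, no evidence-code structure, no
homology between sequences beyond the motif, and module sizes far below
real proteome complexity.

## Problem sizes used by the shipped tests

The test-suite and acceptance experiments run the full pipeline at desk
scale, a deliberate configuration of the package rather than a statement
about the method: `max_gap = 3`, 100-150 random-forest trees, an 8-unit
neural network, a reduced SVM grid, 3 internal meta-folds, datasets of
60-200 pairs over 40-80 proteins, and 5-fold (single-repeat) CV for the
pipeline-level properties; the 3 x 10 protocol checks use the F2 block
alone. The defaults reported above remain the recommended settings for
real data.

## Known limitations

* The AC block is a weak detector of short shared motifs (it is a global,
  lag-limited summary); on motif-only signal it contributes little.
* A single $\theta_R$ over the max-over-subontologies similarity is used
  for the network; per-subontology networks are a possible extension.
* The IC corpus defaults to the training split's annotations; a large
  external corpus (e.g. a full GAF) can be supplied instead.
* With heavily tied similarity values, average-degree matching may only
  bracket the reference degree; the sparser side is chosen.
* The meta-SVM sees only four meta-features; with a single informative
  base learner the ensemble cannot exceed that base by much.
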