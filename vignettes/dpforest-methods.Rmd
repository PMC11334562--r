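---
title: "Predicting druggable proteins from sequence: descriptors, fusion and the cascade deep forest"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting druggable proteins from sequence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpforest)
```

## The problem

A druggable protein is one able to bind drug-like small molecules with
therapeutic effect. Deciding druggability experimentally is slow, so
sequence-based classifiers are used to triage candidate targets: given only
the amino-acid sequence (and, where available, its evolutionary profile),
predict the binary label druggable (1) versus non-druggable (0). `dpforest`
implements such a predictor end to end: three complementary sequence
encoders, serial feature fusion, a cascade deep-forest classifier, and a
stratified cross-validation harness. Every stage can be exercised on
synthetic data, so the package is fully testable without external databases
or profile searches.

## Sequence representations

### Evolutionary profile and its HOG descriptor

A position-specific scoring matrix (PSSM) is an $L \times 20$ table of
log-odds conservation scores produced by iterative database search
(PSI-BLAST's ASCII output is parsed directly; running the search itself is
outside the package's scope, and `synthesize_pssm()` provides a
sequence-consistent stand-in for testing). Raw scores are mapped into
$(0,1)$ by the logistic
$$f(a) = \frac{1}{1 + e^{-a}},$$
which is strictly increasing and bounded, so profiles of sequences with very
different conservation depths become comparable.

The normalized profile is then treated as a gray-scale image and summarized
with a histogram-of-oriented-gradients (HOG) descriptor. Gradients are
central differences in the interior with one-sided differences against an
implicit zero beyond the borders: along the 20-residue axis the first
column's gradient is $P_{\cdot,2} - 0$ and the last is $0 - P_{\cdot,19}$;
the sequence axis is treated identically. Magnitude and direction are
$$G = \sqrt{G_x^2 + G_y^2}, \qquad \Theta = \operatorname{atan2}(G_x, G_y),$$
where the two-argument arctangent is used because the plain ratio
$G_x / G_y$ is undefined when the sequence-axis component vanishes and loses
the sign quadrant.

The field is partitioned into a **4 × 4 grid of cells**: the 20 residue
columns split into four contiguous blocks of five, and the $L$ positions
into four contiguous blocks of $\lfloor L/4 \rfloor$ with the last block
absorbing the remainder (no padding, no truncation — every position's
evolutionary signal is kept). Each cell contributes a magnitude-weighted
orientation histogram with **16 equal bins over $(-\pi, \pi]$**, without
bilinear bin interpolation, L2-normalized per cell with floor
$\varepsilon = 10^{-12}$ (block-overlap normalization is deliberately
omitted); a cell with no gradient stays all-zero. Cells are concatenated
row-major (residue blocks outer, sequence blocks inner), giving
$4 \times 4 \times 16 = 256$ dimensions. The grid, bin count and floor are
all configurable through `hog_config()`; the minimum accepted length is
$L = 8$ so every cell spans at least two positions. Per-cell normalization
makes the descriptor invariant to a uniform rescaling of gradient
magnitudes, which the tests assert.

### Composition / transition / distribution (CTD)

Seven physicochemical properties — hydrophobicity, normalized van der Waals
volume, polarity, polarizability, charge, secondary-structure preference and
solvent accessibility — each partition the 20 residues into three groups.
Per property the sequence maps to a string over \{1,2,3\} and yields:
composition (fraction of residues per group, 3 values summing to 1),
transition (fraction of the $L-1$ adjacent pairs joining two *different*
groups, 3 unordered pairs), and distribution (for each group, the sequence
position — as percent of $L$ — of its first occurrence and of the residues
completing 25 %, 50 %, 75 % and 100 % of that group's occurrences; five
landmarks, with absent groups contributing zeros). The five-landmark
reading is the one consistent with the descriptor's
$7 \times (3 + 3 + 15) = 147$ dimensions. The residue-to-group tables
shipped in `inst/extdata/ctd_groups.tsv` are the standard Dubchak-style CTD
assignments; they are plain TSV so users can substitute their preferred
tables.

Feature matrices are standardized by the z-score
$y = (x - \bar{x})/\mathrm{std}(x)$ with the sample standard deviation
(denominator $n-1$), fitted on training samples only and re-applied to
held-out samples; constant features are flagged and zeroed with a warning.
A min–max $[0,1]$ mode is available (`standardize(X, method = "minmax")`)
for users who prefer range scaling; z-scoring is the default because tree
ensembles are scale-insensitive while the transform keeps linear baselines
usable.

### Composite physicochemical representation (CPSR)

A 71-dimensional concatenation, in fixed block order: amino-acid
composition (20), sequence length (1), ordered bigram frequencies over a
6-letter exchange-group alphabet (36 = 6²), electron-group frequencies (6),
rigidity, flexibility and irreplaceability means (1 each), and R-group
frequencies (5). Exchange groups default to the six Dayhoff-derived
substitutability classes \{HRK\}, \{DENQ\}, \{C\}, \{STPAG\}, \{MILV\},
\{FYW\}; electron groups to a six-class donor/acceptor scheme; R-groups to
the five standard side-chain families. Ordered (rather than unordered)
bigrams are used because only $6^2 = 36$ ordered pairs matches the block's
dimension. The scalar indices are per-residue scale values summed and
divided by $L$ — i.e. sequence means, which makes them obey a weighted-mean
identity under concatenation that the tests exploit. Group blocks are
length-normalized frequencies by default (raw counts via
`count_mode = "count"`), keeping features comparable across lengths.

The flexibility column of `cpsr_scales_synthetic.tsv` is the
Bhaskaran–Ponnuswamy average flexibility index; the rigidity and
irreplaceability columns are package-constructed default scales (hence the
`_synthetic` suffix) that order residues by side-chain conformational
stiffness and by evolutionary substitution tolerance. All tables are
editable TSVs, so swapping in a preferred literature scale requires no code
change.

## Hybrid fusion

Serial concatenation of per-record encodings, with block provenance kept in
a schema: Hybrid1 = CPSR ⊕ HOG-PSSM (327-D), Hybrid2 = NQLC ⊕ HOG-PSSM
(403-D), Hybrid3 = CPSR ⊕ NQLC ⊕ HOG-PSSM (474-D). Block order is fixed
(CPSR, NQLC, HOG-PSSM): tree ensembles are order-invariant, but a stable
schema makes slicing and feature audits reproducible, and the tests verify
that slicing a hybrid matrix recovers the single-view matrices exactly.
Standardization, when requested, is applied matrix-wide after fusion in
training mode and replayed from stored parameters at inference.

## The cascade deep forest

The classifier is a stack of layers, each an ensemble of four tree
learners: one gradient-boosted tree ensemble, one random forest and two
extremely-randomized-tree forests (the mix is configurable). Forest
learners sample $\lfloor\sqrt{d}\rfloor$ candidate features per node split;
the boosted learner's per-node column subsample rate is set to
$\sqrt{d}/d$, the same fraction expressed as a rate. Layer 1 consumes the
feature matrix; every later layer consumes the original features
*concatenated* with the previous layer's class-probability block (2
probabilities × 4 learners = 8 augmented columns — augmentation never
replaces the original features).

Two design points matter for honesty of the stacking:

* **Out-of-fold augmentation.** The probabilities a layer passes forward
  are produced by internal 3-fold cross-fitting — each sample's
  probabilities come from learners that never saw it. Without this, each
  layer would memorize training labels and the cascade would overfit
  trivially. Full-data refits of every learner are kept for inference,
  where the augmented block is rebuilt from them layer by layer.
* **Growth control.** A layer's validation score is the accuracy of its
  averaged out-of-fold probabilities. Growth stops when that score has
  failed to exceed the best seen for `patience` (default 1) consecutive
  layers, or at `max_layers`; inference uses layers up to the best-scoring
  one. Final probabilities are the mean of the last layer's per-learner
  probability vectors, and an exact 0.5/0.5 tie is resolved to the
  negative class.

Every source of randomness derives from one master seed
(`derive_seed(master, layer, estimator, fold)`), so a full fit-predict
cycle reruns bit-identically; serialization via `save_cascade()` /
`load_cascade()` preserves predictions exactly. With a single
random-forest learner and `max_layers = 1` the cascade provably degenerates
to that forest, which the tests use as an equivalence oracle. Default
budget is 100 trees per learner — enough for the synthetic problem sizes
below; users fitting real benchmarks can raise it in `cascade_config()`.

## Evaluation

From the confusion counts (positives = druggable):
$$\mathrm{ACC} = \frac{tp+tn}{tp+tn+fp+fn},\quad
  \mathrm{SEN} = \frac{tp}{tp+fn},\quad
  \mathrm{SPE} = \frac{tn}{tn+fp},$$
$$\mathrm{MCC} = \frac{tp\cdot tn - fp\cdot fn}
  {\sqrt{(tp+fp)(tp+fn)(tn+fp)(tn+fn)}},$$
with MCC defined as 0 when the denominator vanishes (the standard
convention for degenerate predictors). AUC uses the rank (Mann–Whitney)
formulation — the probability a random positive outscores a random
negative, ties counted ½ — which equals the trapezoidal area under the ROC
curve; `roc_points()` exports the curve.

Cross-validation is stratified k-fold (per-class fold sizes differ by at
most one): plain k-fold is the textbook protocol, but stratification
stabilizes MCC on finite samples and costs nothing. Any standardization and
all model fitting happen strictly inside the training folds. Because it is
unstated whether headline figures in this literature average per-fold
metrics or pool confusion counts, the report carries both: `mean_metrics`
(per-fold mean, the headline) and `pooled_metrics`, plus per-fold AUC mean
and the AUC of the pooled out-of-fold scores.

## What the synthetic generators emulate — and what they do not

`generate_synthetic_dataset()` draws residues i.i.d. from per-class
profiles; by default the druggable-like class is enriched roughly two-fold
in hydrophobic residues (C, F, I, L, M, V, W, Y) against a uniform
background, echoing the elevated hydrophobic content of drug-binding
pockets, with lengths uniform on a configurable range.
`synthesize_pssm()` plants a +8 log-odds signal on each position's own
residue with unit-variance rounded Gaussian noise, so the profile is
informative about the sequence the way a real profile of a conserved
protein is. `synthetic_blobs()` provides Bayes-separable Gaussian classes
for classifier-behavior bounds.

These generators produce i.i.d. residues and noise: they have no domain
architecture, no motif grammar, no phylogenetic correlation between
sequences, and the synthetic "evolutionary" profile carries no information
beyond the sequence itself. Passing tests therefore demonstrate that the
encoders compute their definitions exactly, that the cascade learns
separable structure, and that the pipeline is leak-free and reproducible —
they do not certify accuracy on real druggability benchmarks, which
additionally require true PSI-BLAST profiles and curated labels.

## Problem sizes and numerical choices

The shipped tests and the acceptance script run at sizes chosen to exercise
every code path on a single CPU in minutes: descriptor oracles on 100
random sequences (lengths 12–150), gradient oracles on 30 × 20 matrices
(agreement to $10^{-10}$), cascade bounds on a 400-sample, 20-feature blob
dataset, and an end-to-end 200-sequence Hybrid3 run under 10-fold CV.
Degenerate inputs are rejected early with informative errors: sequences
shorter than 2 (descriptors) or 8 (HOG), single-class label vectors,
non-finite PSSM entries, classes smaller than k. Tie-breaks and conventions
(MCC 0/0 → 0, prediction tie → negative class, ties in AUC → ½) are fixed
and tested rather than left to floating-point accident.

## Known limitations

* The residue group tables and the rigidity/irreplaceability scales are
  literature-standard or package-default stand-ins; results on real data
  will shift slightly under an author-specific table, which is why all
  tables load from editable TSVs.
* Only binary classification is supported; there is no multi-grained
  scanning front-end, no feature selection, and no GPU path.
* The PSSM reader targets the PSI-BLAST ASCII dialect; profiles from other
  tools must be converted to that layout (or supplied as matrices
  directly).
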