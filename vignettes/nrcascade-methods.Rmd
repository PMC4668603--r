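---
title: "Methods: alignment-free nuclear receptor classification"
author: "NRCascade"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alignment-free nuclear receptor classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NRCascade)
```

# The problem and the model

Nuclear receptors (NRs) are ligand-inducible transcription factors
organised into eight subfamilies (NR1–NR8 in the NucleaRDB scheme).
Because subfamilies share domain architecture but little sequence
identity, subfamily assignment by alignment is unreliable; NRCascade
classifies sequences from alignment-free composition features instead.

Prediction is a two-level cascade. Level 1 is a binary soft-margin SVM
with an RBF kernel `K(x, y) = exp(-γ ||x - y||²)` deciding NR vs
non-NR. Only sequences predicted NR proceed to level 2, an eight-class
SVM (one-vs-one, the native libsvm scheme, as implemented by `e1071`)
that assigns the subfamily. Both levels see the same encoding of the
sequence, computed once.

# Encoders

**AAC** — the normalized frequency `f_i = n_i / L` of each residue.
Component order is alphabetical by one-letter code; this is a free
convention and is fixed and documented so that matrices are comparable
across runs.

**CTF** — residues are first reduced to the seven dipole/volume classes
{AGV}, {ILFP}, {YMTS}, {HNQW}, {RK}, {DE}, {C}; the 343 ordered triads
of classes are counted over all `L - 2` sliding windows and normalized
by `L - 2`. The bin order is the lexicographic bijection
`(c1-1)·49 + (c2-1)·7 + c3` (`triadIndex()`), chosen because it is
self-documenting; any fixed bijection only permutes columns. Sequences
with `L < 3` have no windows and are rejected, so combined feature sets
containing CTF require `L ≥ 3`; AAC and CGR accept `L ≥ 1`.

**CGR** — vertex `k` of a regular 12-gon sits at
`(cos((k-1)π/6), sin((k-1)π/6))`; a 12-group residue partition assigns
each residue to a vertex, and the trajectory iterates the midpoint map
from the polygon center. Each point is a strict convex combination of
an interior point and a unit vertex, hence has norm < 1. The summary
feature is the fraction of points in each of 24 segments.

Two CGR conventions are genuinely open and were fixed as package
design choices:

* *Segment geometry.* The 24 segments are equal angular sectors of
  width π/12, sector `k` covering `[(k-1)π/12, kπ/12)` counter-clockwise
  from the positive x-axis. A point exactly on a boundary ray goes to
  the lower-index adjacent sector, with angle 0 owned by sector 1 —
  boundary points belong to *some* neighbouring sector; fixing which one
  makes the encoding total and reproducible. Numerically, "exactly on a
  ray" means within 1e-12 radians: `atan2` of points on the coordinate
  axes is exact, and the tolerance covers ray hits produced by rounded
  vertex coordinates. Any other sector labelling only permutes the 24
  columns.
* *Vertex grouping.* No complete published 12-group assignment is
  available, so the default (`cgrAlphabet()`) is a
  conservative-substitution partition — {A}, {G}, {P}, {C}, {S,T},
  {D,E}, {N,Q}, {H}, {K,R}, {M}, {I,L,V}, {F,Y,W} on vertices 1–12 —
  and every CGR function accepts any 12-group `AminoAlphabet`
  replacement (`readAlphabet()` loads one from a text file).

All encoder outputs are frequencies in [0, 1] whose blocks each sum
to 1; no further standardization is applied, and the SVMs consume the
values unscaled.

# Hyperparameters

Each feature set carries tuned `(γ, C)` defaults
(`defaultSVMParams()`), e.g. γ = 0.0159, C = 10.3440 for the
subfamily level of AAC+CTF and γ = 0.1899, C = 10.1197 for its binary
level. These optima were tuned on real NR data and are
dataset-specific: the useful range of γ depends on the typical squared
distance between encoded sequences. `gridSearch()` re-tunes them for
any dataset by exhaustive search over user grids, scored by mean
k-fold CV accuracy on folds shared across grid points; ties break
towards the smaller `C`, then the smaller γ (prefer the smoother
model). The binary level of the other six feature sets has no
published optimum, so their subfamily values double as binary defaults.

No class weighting is applied at either level.

# Evaluation protocol

Binary performance is summarized by sensitivity `TP/(TP+FN)`,
specificity `TN/(TN+FP)`, accuracy `(TP+TN)/total` and the Matthews
correlation coefficient, with MCC defined as 0 whenever a factor under
its square root vanishes (the limit is otherwise undefined; 0 is the
uninformative value). The AUC is the Mann–Whitney probability that a
random positive outscores a random negative, ties counted 1/2,
computed from mid-ranks; the ROC curve lists (FPR, TPR) at every
distinct threshold.

Multiclass performance uses one-vs-rest counts per class
(`TP(i) = N⁺(i) - misses out`, etc.). Overall sensitivity is the
pooled correct-classification rate `Σ TP(i) / Σ N⁺(i)`. Overall
specificity, accuracy and MCC pool the one-vs-rest counts over classes
(micro-pooling) — a single defensible convention, recorded here because
"overall MCC" has no unique definition. Multiclass AUC is not defined
and not computed.

Cross-validation is stratified by default: each class is shuffled under
the seed and dealt round-robin, so per-class fold counts differ by at
most one. Stratification matters because the smallest subfamilies (7
and 10 members) would otherwise vanish from training folds entirely; a
plain-random option exists. For binary tasks the per-fold metrics are
averaged arithmetically over folds *and* the pooled-prediction metrics
are reported, since published protocols are often ambiguous between
the two; for multiclass tasks per-class tables are computed from the
pooled predictions (per-fold per-class metrics are undefined whenever a
small class misses a fold). `k = N` is the jackknife, also available
directly (`jackknifeCV()`): deterministic, seed-free and invariant to
input order.

# Feature significance

`rankFeatures()` applies a two-sided Wilcoxon rank-sum test per feature
between the two groups, using the normal approximation with mid-rank
tie correction and no continuity correction. The approximation is the
default because frequency features contain massive zero ties and the
relevant p-values lie far below the reach of the exact distribution; an
exact option exists for groups of ≤ ~10 samples. Constant features get
p = 1. The census of features with p < 0.01 is reported raw, matching
the conventional presentation; a Bonferroni-adjusted census is attached
as a clearly labelled extension. `selectTopK()` / `ablateTopK()`
partition the feature set for any k (for CTF and k = 50: 50 + 293), and
`projectFeatures()` restricts a matrix to a subset while preserving
column order, so simplified and ablated models run through the same
training and CV code paths.

# The synthetic benchmark

`generateCollection()` draws sequences residue-by-residue from a
background distribution (default uniform over the 20 residues) and
plants class-specific 3-mer motifs: a motif of weight `w` is written
`round(w · L / 100)` times at positions sampled without replacement,
so `w` is the expected number of copies per 100 residues and the
corresponding CTF component scales monotonically with it. Motifs may be
literal 3-mers or reduced-class triads (`"C-RK-AGV"`), the latter
expanded to a random consistent literal at each insertion.

`defaultBenchmark()` mirrors the shape of the real training data: 474
positives over the eight subfamilies in proportions
162/140/82/23/29/7/21/10 plus 500 negatives, lengths uniform on
120–400. All positives carry four shared reduced-class triads
(weight 2 per 100 residues) — the NR signature that level 1 and the
Wilcoxon ranking should recover — and each subfamily carries two
subfamily-specific triads (weight 3), the level-2 signal. Negatives are
pure background. These values were fixed once, at design time, to make
the classes separable by construction while keeping the planted
components small against the frequency background.

What the generator does *not* emulate: real domain architecture (zinc
fingers, ligand-binding-domain helices), realistic residue composition,
homology structure within classes, or length–class correlations. The
planted signal is strictly compositional and far cleaner than real
data, so passing tests demonstrate that the machinery recovers planted
structure correctly — not that real-data accuracies are reproduced.
Consequently the published hyperparameter optima, tuned on real
distance scales, underfit the synthetic collection at level 2 (its
classes differ in only ~6 triad bins of magnitude ~0.03, so
γ ≈ 0.016 makes the kernel nearly constant and one-vs-one voting
collapses to the majority class); the benchmark protocol therefore
re-tunes `(γ, C)` with `gridSearch()` over a coarse logarithmic grid —
exactly the per-dataset tuning step of the original protocol. Level 1
passes with its published default.

# Problem sizes

The test suite exercises the full 974-sequence benchmark for the
end-to-end recovery checks (10-fold CV at both levels, 20-seed ranking
replicates) and down-scaled replicas (`scale` argument) everywhere a
structural property rather than a headline number is under test.
`scripts/acceptance.R` runs the full benchmark once per invocation;
grid searches use k = 3 folds on a 6 × 3 logarithmic grid.

# Known limitations

* Real-data accuracies depend on the original benchmark datasets and
  CD-HIT redundancy reduction, which are outside the package's scope;
  `runFeatureSetComparison()` reproduces the protocol structure on any
  supplied FASTA + label file, but numeric agreement with published
  tables is not asserted anywhere.
* The CGR vertex grouping is a stand-in for an incompletely published
  scheme; with a different grouping the 24 CGR columns change meaning
  (though not their normalization or geometry).
* The Wilcoxon normal approximation is anti-conservative for very
  small groups; use `exact = TRUE` there.
* Jackknife training rounds grow linearly with N and are intended for
  datasets of at most a few hundred sequences.
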