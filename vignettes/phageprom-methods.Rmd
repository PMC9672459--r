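---
title: "Methods: two-layer promoter classification for phage genomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-layer promoter classification for phage genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the model

Phage genomes are transcribed by two machineries: the host RNA polymerase,
which recognizes bacterial sigma-factor promoters, and (in many phages) a
phage-encoded single-subunit polymerase with its own promoter specificity.
Annotating a phage genome therefore poses two nested questions about a
candidate 99-bp sequence: *is it a promoter at all?* and, if so, *is it a
phage-type or a host-type promoter?*

`phageprom` answers them with a two-layer cascade of binary classifiers.
Layer 1 scores promoter vs non-promoter; only sequences whose layer-1
probability reaches the decision threshold (0.5 by default) are passed to
layer 2, which scores phage vs host. Each query yields `p_promoter`,
optionally `p_phage`, and a three-way call. The positive convention of
layer 2 is *phage*; because the curated corpora this design targets label
host promoters as the majority ("positive") class, the output header states
the mapping explicitly in both directions.

Both layers are the same compact one-dimensional convolutional network over
one-hot encoded sequence:

    Conv1D(16 filters, kernel 5, ReLU, "same")  -> MaxPool(4, stride 2) -> Dropout(0.5)
    Conv1D(16 filters, kernel 5, ReLU, "same")  -> MaxPool(4, stride 2) -> Dropout(0.5)
    Flatten -> Dense(64, ReLU) -> Dropout(0.5) -> Dense(1, sigmoid)

with L2 penalties of 1e-4 on every kernel *and* bias, binary cross-entropy
loss, and Adam at batch size 20 for 85 epochs. The input is fixed at 99
rows; shorter sequences are zero-filled (positional encodings only), longer
ones rejected rather than truncated, since the classifier's positional
weights are meaningful only on a fixed coordinate frame.

The network, its backpropagation and the Adam optimizer are implemented
directly in base R (an im2col formulation of the convolution); the
implementation is small enough to audit line by line, and its gradients
were verified against central finite differences during development.

### Training choices

* **"Same" convolution padding.** Two stages of pool(4, stride 2) applied
  to 99 rows require the convolutions not to shrink the sequence; "same"
  padding keeps the arithmetic `99 -> 48 -> 23` valid. Border handling is
  otherwise immaterial to the model.
* **Adam learning rate 0.003** (configurable). The step size is not part of
  the published architecture. With three dropout layers at rate 0.5 and
  only 16 filters, a smaller conventional step leaves the network visibly
  under-fitted within the fixed 85-epoch budget; 0.003 trains to
  convergence on the package's tasks without instability. Epsilon is 1e-7,
  beta1/beta2 the conventional 0.9/0.999.
* **Glorot-uniform initialization**, zero biases, seeded; initialization,
  per-epoch shuffling and dropout masks all draw from one seeded stream, so
  training is bit-reproducible on a single thread.
* **No early stopping, no validation split**: the training schedule is a
  fixed 85 epochs. A `class_weight` flag exists for the imbalanced layer-2
  problem (111 phage vs 382 host by default) but is off by default, keeping
  the plain objective.
* **Threshold 0.5** for both layers; per-layer thresholds can be set on the
  cascade object.

## Hard negatives by partial block shuffling

Sampling negatives from non-coding regions makes the two classes trivially
separable and inflates apparent accuracy. Instead, layer-1 negatives are
manufactured from the positives themselves: each promoter is cut into 8
contiguous blocks, 5 randomly selected blocks are moved to new positions,
and the remaining 3 stay where they were, conserving roughly 35-40% of the
sequence in place.

Two details make this construction exact rather than approximate:

1. **The five selected blocks are deranged, not merely permuted.** A
   uniform permutation of five items leaves one of them in place on
   average, which would push the expected conserved fraction to
   (3+1)/8 = 50%. A uniform random derangement (no fixed point, sampled by
   rejection) moves all five, and the conserved fraction is governed by the
   three deliberately fixed blocks: 3/8 = 37.5% in expectation.
2. **Blocks exchange positions only with blocks of equal size.** 99 is not
   divisible by 8, so the partition is front-loaded: three 13-bp and five
   12-bp blocks. Swapping blocks of unequal sizes would shift the absolute
   coordinates of every downstream "fixed" block, silently destroying
   position conservation. Restricting the derangement to equal-size classes
   keeps every unmoved base at its exact coordinate. Selections in which one size class has a
   single member (which could not move) are resampled; in degenerate
   configurations where no valid selection exists, the generator falls back
   to an unrestricted derangement after a bounded number of attempts.

For 99-bp input the per-sequence conserved fraction is then exactly 36, 37
or 39 of 99 positions (0.364-0.394) and the mean over random sequences is
37.2% -- inside the intended 35-40% band. `conserved_fraction()` measures
this by comparing block content per slot, so negatives equal to their
positive score 1.

One RNG substream per record (derived from the dataset seed and the record
index) makes `build_negative_set()` order-independent: generating negatives
for a subset yields the same sequences as for the full set.

## Feature encodings

Ten schemes are provided behind one dispatcher (`encode_sequence()`,
`encode_dataset()`). Two are positional (one-hot; nucleotide chemical
properties b/c/p) and produce zero-filled 99-row matrices; the remaining
eight are composition- or correlation-based vectors computed on the
*unpadded* sequence, because zero-filling would corrupt frequency
statistics. Matrices are flattened row-major (position-major) when fed to
vector-input baseline models.

Definitions follow the standard forms: overlapping k-mer frequencies
normalized by window count `L - k + 1` (so they sum to 1; normalizing by
sequence length `L` would not); PseEIIP as summed mononucleotide
electron-ion interaction pseudopotentials (A 0.1260, C 0.1340, G 0.0806,
T 0.1335) times trinucleotide frequencies, with a `mode = "mean"` switch
for the averaged convention; the Pse family (PseDNC, PseKNC, PCPseDNC,
PCPseTNC) as normalized oligonucleotide frequencies extended by lambda
correlation factors `theta_j` -- mean squared differences of standardized
physicochemical index profiles at sequence distance `j` -- weighted by `w`;
DACC as the concatenation of auto- and cross-covariances of those profiles
at lags `1..LAG` (dimension `N^2 x LAG`); and Moran autocorrelation of each
index profile with the zero-variance convention `I = 0`. The Moran
descriptor is defined here on dinucleotide physicochemical profiles -- the
natural DNA analogue of its amino-acid-property origin.

Ambiguous bases (N) are accepted on input: positional encoders emit
all-zero rows, composition counts skip windows containing N (renormalizing
over valid windows), and correlation sums treat N-containing windows as
zero deviations.

### Index tables

The correlation encoders standardize every physicochemical index to mean 0
and population SD 1 across its 16 (or 64) oligonucleotides before use, so
only the relative geometry of an index enters any feature. Three tables
ship as versioned TSV files under `inst/extdata`:

* `dinucleotide_indices_core6.tsv` -- six strand-symmetric helical step
  parameters (twist, tilt, roll, shift, slide, rise), the default set for
  PseDNC, PseKNC, DACC and Moran.
* `dinucleotide_indices_38_synthetic.tsv` -- the default for PCPseDNC: the
  six step parameters plus 32 deterministic **synthetic** pseudo-indices
  (fixed-seed standard-normal draws). This file is an explicitly labeled
  synthetic stand-in for a curated 38-index collection, not literature
  data; on synthetic benchmarks only the dimensionality and standardized
  geometry matter.
* the trinucleotide table for PCPseTNC is *derived*, not shipped: each
  trinucleotide inherits the mean of its two constituent dinucleotide
  steps.

Any `phys_index_set` can be supplied through `encoder_params()` to replace
these defaults.

### Encoder hyperparameters

| parameter | meaning | default | notes |
|---|---|---|---|
| `lam` | highest correlation rank (Pse family) | 2 | must satisfy `lam + 2 <= L` (`+3` for trinucleotides) |
| `w` | correlation weight in `[0,1]` | 0.1 | `w = 0` reduces Pse vectors to plain frequencies |
| `lag` | maximum lag (DACC, Moran) | 2 | must satisfy `lag + 2 <= L` |
| `k` | tuple size (kmer, PseKNC) | 3 | dimension `4^k` grows quickly |

The defaults are deliberately small: on 99-bp sequences higher orders add
dimensions faster than information. Every encoder is checked against an
independently written brute-force oracle (literal loop transcription of the
defining sums) on random 20-mers at tolerance 1e-9.

## Baseline models and the selection grid

`baseline_fit()` gives ten classical algorithms the same
fit/`predict`-probability contract as the CNN: AdaBoost (SAMME over
decision stumps, implemented in-package), multinomial naive Bayes
(count-based, in-package; rejects negative features with a pointer to
non-negative encodings), XGBoost, gradient boosting (GBM-style settings on
the same backend), logistic regression, k-nearest neighbours, a CART
decision tree, an RBF-kernel SVM, a single-hidden-layer perceptron, and a
bagged SVM ensemble (10 bootstrap resamples, probabilities averaged; the
ensemble composition is a package default, as no canonical one exists).
Hyperparameters are pinned defaults, overridable per spec through
`baseline_spec(params =)`.

`benchmark_grid()` crosses encodings with models (the CNN participating as
an eleventh model on positional encodings) under stratified k-fold
cross-validation and returns one metrics row per cell, sorted by accuracy;
incompatible cells (CNN on a composition vector, multinomial NB on signed
features) become `status = "failed"` rows rather than errors.

## Evaluation

Accuracy, sensitivity, specificity, MCC, precision and recall are computed
from confusion counts in their standard forms, with MCC defined as 0 when
its denominator vanishes. ROC curves sweep the observed scores as
thresholds (score >= threshold predicts positive) and AUROC is the rank
(Mann-Whitney) statistic with ties counted half, which equals the
trapezoidal area under the tie-aware curve. Cross-validation is stratified
(fold sizes within a class differ by at most one), seeded, and summarized
by the unweighted mean across folds; per-fold reports are retained. The
test suite checks the metrics exhaustively against counting and pairwise
oracles on all short outcome vectors, and AUROC additionally against an
independent reference implementation.

## The synthetic data generator

Real phage promoter corpora are small, curated, and not redistributable
here; the package instead tests every stage on synthetic data whose
*structure* matches what the method assumes: two promoter subclasses
distinguished by short degenerate motifs at loosely constrained positions,
plus hard negatives built by the block-shuffle generator.

Defaults, chosen once and frozen:

* 99-bp sequences, uniform A/C/G/T background (an AT-rich background can be
  set through `background`; phage genomes are often AT-rich, but no
  composition figure was available to copy, so uniform is the neutral
  default).
* Host-type promoters implant a -35 box `TTGACA` (start window 22-26) and
  a -10 box `TATAAT` (window 35-39); phage-type promoters implant a T7-like
  polymerase consensus `TAATACGACTCACTATAGGG` (window 21-26). Layer-1
  positives are a 25% phage / 75% host mixture, matching the share of
  phage-typed promoters in the benchmark corpus this emulates; layer-2
  defaults are 111 phage vs 382 host.
* Per-base motif mutation rate 0.03: each implanted consensus base is
  replaced by a random other base with 3% probability (a consensus+noise
  model rather than a PWM, for transparency of the test assertions).
* **Every motif window straddles a block boundary** of the default 8-block
  partition (boundaries after positions 13, 26, 39, ...). This is the
  property that makes the generated negatives *hard in the intended sense*:
  a hard negative should disrupt the promoter elements while conserving
  local composition. A 6-bp box crossing a boundary survives shuffling only
  if both flanking blocks stay in place; retaining *both* host boxes would
  require four conserved blocks, which the three fixed blocks cannot
  provide; and the 20-bp phage consensus spans three blocks, so it can
  never survive whole. With in-block windows instead, a single conserved
  block frequently carries an intact box into the "negative" class -- such a
  sequence is functionally a promoter mislabeled as a negative, and the
  achievable accuracy of the task collapses accordingly.

With these defaults a CNN trained on 500 sequences per class separates
held-out data at above 0.90 cross-validated accuracy and the full cascade
calls a mixed held-out set (non-promoters, phage and host promoters) at
above 0.85 (both checked by the end-to-end tests) -- learnable but far from
saturated, which is the regime in which the pipeline's moving parts are
actually exercised.

What the generator does **not** emulate: positional nucleotide biases
outside motifs, motif co-occurrence statistics, PWM-shaped degeneracy,
sequence phylogeny (near-duplicate promoters across related phages), or
class-conditional composition differences. Passing the end-to-end tests
therefore demonstrates that the machinery -- encoding, training, gating,
evaluation -- works as specified, not that the model attains any particular
accuracy on real phage genomes.

## Numerical and interface conventions

* Coordinates are 1-based inclusive throughout, the R convention.
* Sequences of any length 1-99 are accepted (real promoter fragments below
  99 bp exist in the corpora this emulates); positional encoders zero-fill,
  and the composition encoders require only the lengths their formulas
  need.
* Stratified splitting rounds the per-class test count and clamps it to
  keep at least one record on each side; classes with fewer than two
  members refuse to split.
* Model artifacts are single RDS files carrying a schema version, the full
  configuration and the weight tensors; loading verifies the schema and
  reproduces predictions bit-for-bit.
* The command-line interface (`exec/phageprom`) is a thin dispatcher over
  the exported functions with exit codes 0 (ok), 1 (usage), 2 (data error);
  every tabular artifact it writes carries the effective configuration in a
  `#` header line, and existing outputs are never overwritten without
  `--force`.
* Test-suite problem sizes are chosen to keep the default run complete yet
  brief: the end-to-end check uses 500 sequences per class with 5-fold
  cross-validation, the generator's distributional checks use 10,000
  sequences, and the remaining unit tests use small fixtures.

## Known limitations

* The headline accuracies published for this class of tools on curated
  phage-promoter benchmarks are not reproduced here: those corpora and the
  associated trained weights are not redistributable, and the synthetic
  generator makes no claim of matching their statistics.
* The 38-index PCPseDNC table is a synthetic stand-in (see above); results
  that depend on the identity of specific physicochemical indices should
  substitute a curated `phys_index_set`.
* The CNN runs on a single CPU thread; training the default configuration
  on 1,000 sequences takes on the order of half a minute, which is adequate
  for 99-bp promoter corpora but not for genome-scale scanning --
  genome-wide sliding-window prediction is explicitly out of scope.
* `svm_bagging` composition and all baseline hyperparameters are pinned
  package defaults, not tuned values.
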