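---
title: "Drug-likeness classification with autoencoder-pretrained networks: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Drug-likeness classification with autoencoder-pretrained networks: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(druglikeness)
```

## The problem

Most candidate compounds never become drugs, and a large share of the
attrition traces back to properties summarized as *drug-likeness*.
Binary classifiers that separate drug-like from non-drug-like
molecules, trained on large curated compound collections encoded as
numeric 2D descriptors (several hundred per molecule), are a standard
screening tool. This package implements one such modelling recipe end
to end: SDF curation, descriptor-matrix post-processing, class
balancing, a fully connected classifier initialized from a pre-trained
autoencoder and trained with a class-weighted cross-entropy loss,
selection of the class weight at the sensitivity/specificity crossing,
and five-index evaluation — together with a synthetic-data generator
so every stage is testable without proprietary compound databases
(the reference collections in this field — MDDR, WDI, ACD and the
like — are commercial).

## Data curation

Real compound sets arrive as SDF files and are cleaned in a fixed
order:

1. **Element filter.** Hydrocarbons (heavy atoms all carbon; hydrogens
   ignored) are removed, as is any molecule containing an element
   outside C, H, O, N, P, S, Cl, Br, I, Si. The element set is read
   from the InChI formula layer so implicit hydrogens count.
2. **Mixture removal.** A record whose bond graph has more than one
   connected component (salts, solvates, true mixtures) is removed
   whole; no fragment keeping.
3. **Deduplication.** Identity is the standard InChI, which includes
   the stereochemistry layer. Within a set the first occurrence wins;
   a structure present in both classes is dropped from the negative
   set only, on the argument that membership in the positive (drug)
   set is the more reliable annotation.

The source data do not dictate an order for these rules; the order
above is a convention of this package. Because each rule is a pure
filter, the pipeline is idempotent, and the cleaning report's counts
always reconcile (`input = output + removals + parse failures`).
Broken SDF records are counted and skipped rather than aborting the
run — bulk exports routinely contain a few. A structure-normalization
hook (`normalizer` argument of `clean_molecules()`) is provided but
defaults to the identity; workflows that neutralize/tautomerize with
commercial standardizers before deduplication will merge slightly more
duplicates than this package does. That fidelity gap is deliberate and
documented rather than half-emulated.

## Descriptor post-processing

Descriptor calculators emit `N/A` or infinities for molecules they
cannot handle; any row containing such a value is dropped
(`drop_error_rows()`). Descriptors constant across all molecules are
dropped (`drop_constant_columns()`) using exact equality — "the same
value" means the same value, and a column differing in one entry is
kept. Features are then z-scored. Two choices here were genuinely
open:

* **Fit scope.** Standardization statistics are fitted on the training
  rows only and applied to held-out rows with those frozen statistics.
  Pooled fitting would leak held-out information into training; the
  package never does it.
* **SD convention.** The population form (divide by *n*) is used.
  The choice is arbitrary but fixed, and the tests' oracles use the
  matching convention.

## Class balancing

Screening collections are heavily imbalanced (the regimes emulated
here run from about 1:1.2 to 1:59 positive:negative). Two balancing
schemes are provided, both applied to training data only:

* **Duplication** — minority rows are resampled with replacement and
  appended as exact copies until counts are equal.
* **SMOTE** — synthetic minority rows `x_i + u (x_nn − x_i)` with
  `u ~ U(0,1)` and `x_nn` one of the `k = 5` nearest minority
  neighbours by Euclidean distance (neighbour search within the
  minority class only, distance ties broken by row index for
  determinism). Every synthetic point therefore lies on a segment
  between two minority points, hence inside the minority convex hull,
  and a minority class sitting on an affine subspace stays on it —
  both properties are asserted in the tests.

The default `k = 5` is the classic SMOTE setting; it shrinks to
`minority size − 1` for tiny classes.

Cross-validation interacts with balancing: oversampling the full
training set *before* cutting folds plants near-copies of each fold's
test rows in its training rows and inflates fold-test scores. The
default here balances inside each fold's training portion. The
historical protocol is available as `leaky_balance = TRUE` for
fidelity comparisons.

## Network, pre-training, and the weighted loss

The classifier is a fully connected network — by default one hidden
layer of 512 ReLU units, L2 penalty 1e-4, dropout 0.14, batch size
128, Adam (lr 1e-3, β₁ 0.9, β₂ 0.999), truncated-normal initialization
(sd 0.05, truncated at ±2 sd) — with a single sigmoid output unit.
An autoencoder with the same hidden architecture is first trained to
reconstruct the standardized descriptors under mean squared error;
its encoder weights initialize the classifier's hidden layers
(`transfer_weights()`), the decoder is discarded, and the output layer
is freshly initialized. Multiple hidden layers are pre-trained
greedily, each autoencoder learning to reconstruct the codes of the
layer below. Pre-training acts mainly as a regularizer on this kind of
data: descriptor columns have no grid structure for a deep stack to
exploit, and in our experiments (as in the experience this design
encodes) one hidden layer classifies at least as well as two.

Fine-tuning minimizes the class-weighted binary cross-entropy

$$L = -\sum_k \big(w\, y_k \log a_k + (1-w)(1-y_k)\log(1-a_k)\big),$$

where `w ∈ (0,1)` is the weight of the positive-sample term; `w = 0.5`
recovers exactly half the plain cross-entropy. The definition is the
sum; mini-batch optimization uses the batch mean of the same quantity
for step-size stability, and both reductions are exposed by
`weighted_bce()`. Probabilities are clipped at 1e-7 before logs.
Early stopping monitors classification accuracy on the held-out fold
(patience 10 epochs by default) and restores the best-accuracy
weights. Gradients are computed by backpropagation and verified
against central finite differences to better than 1e-5 relative error
in the test suite. Dropout is active in both pre-training and
fine-tuning (whether the original recipe scoped it to one stage is
unknowable from its description; one rate, both stages, is the simpler
reading) and always off at inference, so predictions are bit-stable.

## Choosing the positive weight

`scan_weights()` retrains the classifier at each value of a weight
grid — 21 points from 0.5 to 1.0 in steps of 0.025 ("20 intervals"),
with the top point nudged to 1−1e-6 because the loss is undefined at
`w = 1` — reusing one autoencoder pre-training and one seed so the
scan isolates the effect of `w`. Raising `w` trades specificity for
sensitivity; the balanced operating point is where the SE and SP
curves cross. If the sign of SE−SP flips between adjacent grid points
the crossing is linearly interpolated; if the curves never cross, the
grid point with the smallest |SE−SP| is selected (ties to the smaller
weight) and the fallback is recorded in the result. An optional
refinement pass (`refine = TRUE`) rescans at one fifth of the step
around the selection; it is off by default.

## Evaluation

Five indexes: ACC, SE (= TP/(TP+FN)), SP (= TN/(TN+FP)), MCC, and the
rank-based (Mann–Whitney) AUC with half-weight ties. Ties at the
decision threshold are called positive. MCC's denominator is evaluated
in log space so large counts cannot overflow, and the usual convention
MCC = 0 applies when any denominator factor vanishes. A set with no
positives at all yields SE = NA with a warning — deliberately distinct
from SE = 0. One source formula prints SE with TN in the numerator;
that is treated as a typographical slip and the standard definition is
implemented (its own denominator, and every reported table consistent
with it, support this reading).

## The synthetic benchmark

`simulate_descriptors()` draws latent factors
`z ~ N(±δ/2 · 1, I_r)` per class, maps them through a fixed random
loading matrix into `n_features` ambient descriptors, adds isotropic
noise, and optionally injects constant columns and missing entries.
It emulates what the method exploits — strongly correlated columns,
low intrinsic dimension, a class shift distributed across latent
directions — and deliberately does **not** emulate real descriptor
marginals (integer counts, heavy tails, block correlation). Passing
tests on it demonstrate the machinery is correct, not that any given
accuracy transfers to real compound collections. With `noise_sd = 0`
the matrix has rank exactly `r`, which is what lets a linear
autoencoder be checked against the PCA reconstruction optimum. The
Bayes error of the optimal linear rule is available in closed form
(`bayes_error()`), giving the separability oracle for the accuracy
tests.

The acceptance benchmark uses `n_pos = 200`, `n_neg = 10,000`,
`r = 10`, `δ = 3`, `noise_sd = 0.5`, 100 features — a scaled analog of
the most imbalanced (~1:59) drug vs purchasable-compound regime — with
five seeds, a 64-unit hidden layer, at most 15 epochs and patience 3.
These sizes are the package's own scaling choice: large enough that
split stratification, SMOTE geometry and the weight scan all operate
in their intended regime, small enough that the full five-seed
pipeline (two balancing arms of 5-fold CV plus a 21-point weight scan
per seed) runs on one CPU in minutes. At `δ = 3` across 10 latent
dimensions the Mahalanobis separation is ≈ 9.5, so near-ceiling
accuracy is the *correct* answer, and the weight scan's interesting
behaviour is concentrated near `w → 1` where the negative-class term
vanishes and specificity collapses.

## Numerical and degenerate-input choices

* Probability clipping ε = 1e-7; truncated-normal init sd 0.05
  (the initializer family is prescribed, its scale was not).
* Zero-sd columns inside a CV fold's training rows are dropped for
  that fold before standardization.
* Single-row z-score fits, single-class balancing inputs, empty
  post-deduplication sets, and single-class folds are all hard errors
  with messages naming the offender, not silent degradations.
* SMOTE with a one-row minority errors and points to duplication.
* Model JSON serializes weights with 17 significant digits, which
  round-trips IEEE doubles exactly; a reloaded model predicts
  bit-identically.
* Everything stochastic (init, shuffling, dropout, resampling,
  splits) flows from explicit seeds; a whole experiment is
  reproducible bit-for-bit given its configuration.

## Known limitations

* No structure standardization (charge/tautomer normalization) before
  InChI comparison; see the curation section.
* Descriptor computation itself (MOLD2/PaDEL) is out of scope; the
  package consumes precomputed matrices.
* The generator's Gaussian latent model understates the messiness of
  real descriptor distributions, so real-data accuracies will be lower
  than synthetic-benchmark ones.
* Training is plain R matrix arithmetic on CPU: adequate for
  descriptor-scale networks (hundreds of inputs, one or two hidden
  layers), not for image-scale ones.
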