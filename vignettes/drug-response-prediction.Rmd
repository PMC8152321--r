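---
title: "Predicting drug response from multi-omics profiles with triplet-loss encoders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting drug response from multi-omics profiles with triplet-loss encoders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(tripletdr)
```

## The model

For one drug we observe three co-indexed omics matrices over the same
samples — gene expression $X_e$, somatic mutation $X_m$ (binary) and
copy-number aberration $X_c$ — and a binary response vector $y$ with
$y_i = 1$ for *sensitive* (low ln(IC50)) and $0$ for *resistant*. The
predictor is built in three independently trained stages.

**Stage 1 — variance-threshold feature selection.** Low-variance features
carry little discriminative information and inflate the sample/feature
imbalance, so each layer is reduced to its high-variance features,
$X'_o = F(X_o)$. The threshold is chosen per layer at the knee of the
variance scree: variances are sorted in decreasing order, index and value
are min–max scaled to the unit square (making the rule unit-invariant),
and the knee is the point with the largest perpendicular distance to the
chord joining the first and last points. The threshold is the variance of
the point immediately *before* the knee, so the knee point itself is the
first feature excluded; ties go to the smaller index, which keeps fewer
features. Two degenerate cases are handled explicitly: an all-equal or
collinear scree has no knee, and the mask then falls back to keeping every
feature. A fixed top-$k$ per layer can override the elbow rule when a
preset feature budget is wanted. Masks are fit per training split, never
globally — fitting on pooled data would leak held-out variance into
selection — and a unit test asserts that perturbing held-out samples
cannot change a fitted mask.

**Stage 2 — supervised triplet-loss encoders.** Each reduced layer is
encoded by one fully connected layer with ReLU,
$\tilde X_o = \mathrm{relu}(X'_o W_o)$, trained so that same-class samples
embed closer than opposite-class samples by a margin $\alpha$:

$$L(a, p, n) = \max\big(d(a, p) - d(a, n) + \alpha,\ 0\big),$$

with $d$ the (non-squared) Euclidean distance; a squared-distance variant
is selectable by configuration. Within each mini-batch *all* valid
(anchor, positive, negative) index triples are enumerated — batch-all
mining, with anchors drawn from both classes — and the loss is the mean
over them. Averaging rather than summing makes the reported loss invariant
to batch composition; it rescales gradients uniformly and does not change
the minimisers. Zero-loss triplets stay in the average, so the loss value
is interpretable as a margin-violation rate weighted by violation size.

**Stage 3 — sigmoid classifier head.** The embeddings are concatenated in
fixed order, $\hat X = \tilde X_e \oplus \tilde X_m \oplus \tilde X_c$,
and a single-layer classifier $\hat y = s(\hat X w + b)$ is trained with
binary cross-entropy. The encoders are frozen: a deliberately simple head
cannot overfit representations that were already shaped by the supervised
triplet loss, and independent training keeps the embedding objective
uncontaminated by the classification loss. An intercept is fitted by
default; the pure linear-score variant ($z = \hat X w$) is available with
`include_bias = FALSE`.

**Ablation modes.** `expression_only` and `mut_cna` restrict the active
layers; `no_encoder` skips stage 2 entirely and feeds the selected,
standardised features to the classifier — the natural baseline for
quantifying what the encoders add.

## Training procedure and its parameters

Both trainable stages use mini-batch Adam (step size `learning_rate`,
default 0.01), L2 weight decay (`weight_decay`, default $10^{-4}$, added
to the gradient), dropout (`dropout_rate`, default 0.1) and early
stopping. Dropout is applied to the ReLU output in the encoders — the only
position consistent with a single-layer architecture — and to the input of
the classifier; it is never applied at prediction time, so encoding and
prediction are deterministic. Weights are initialised uniformly in
$[-1/\sqrt{m}, 1/\sqrt{m}]$ with $m$ the input dimension, from the
configured seed.

Early stopping monitors the batch-all triplet loss over the full
validation split for the encoders and the validation AUC for the
classifier, with patience 5 and 15 epochs against budgets of 50 and 150
(defaults); the weights of the best validation epoch are returned. AUC is
chosen for the classifier because model selection throughout the protocol
is AUC-based; monitoring validation BCE instead would optimise a
calibration the protocol never measures.

Class imbalance is handled by oversampling: the minority class is
duplicated by seeded sampling with replacement until the classes balance,
every original sample appears at least once, and the majority class is
never duplicated. The index multiset is drawn once per training run (not
per epoch) so that validation comparisons across hyperparameter sets see
the same training distribution, and it is applied when forming both
encoder and classifier batches, which also keeps mini-batches
class-mixed — a single-class batch contains no triplet and is skipped.

Per-layer embedding dimensions default to 64/32/16 for
expression/CNA/mutation and must satisfy
$\tilde M_e > \tilde M_c > \tilde M_m$, mirroring the layers' relative
information content; the constraint is enforced when a hyperparameter set
is constructed. The margin defaults to $\alpha = 1$. These defaults are
package choices tuned for the simulated panels used in the tests, not
values with independent empirical backing; on real panels they are
precisely the quantities the nested protocol is meant to select.

Continuous layers (expression, CNA) are standardised per feature with
training-split statistics after masking; the binary mutation layer is left
untouched. This keeps the encoder optimisation well-scaled without
affecting what the masks select.

## Evaluation protocol

`nested_split()` builds, per repeat, a stratified $k$-fold partition and,
within each training fold, a stratified validation slice: with 5 folds and
a 20% validation fraction each cell trains on 64%, validates on 16% and
tests on 20% of the samples. Stratification is not optional: with ~15%
sensitive samples, unstratified folds can end up single-class, leaving the
AUC undefined. Per-fold class ratios stay within one sample of the global
ratio.

`cross_validate()` fits every hyperparameter set in every (repeat, fold)
cell and reports, per cell, the test AUC of the set with the highest
validation AUC (ties to the first set). A configuration switch selects the
alternative reading — one set for all cells by argmax of the mean
validation AUC; both are legitimate interpretations of per-set validation
tables and neither is asserted as canonical. `external_validate()` trains
on $k-1$ folds of one panel with the held-out fold as validation and tests
every model on a full independent panel, reporting the external AUC of the
set with the best mean validation AUC.

AUC is computed by the Mann–Whitney rank formulation with average ranks,
i.e. ties get half credit — exact, threshold-free, and invariant under
strictly increasing score transforms. Sensitive is the positive class; any
consistent choice leaves comparisons unchanged.

**Seed policy.** A master seed is hashed with small integer tags
(`repeat`, `fold`, `set`, stage) into per-stage seeds below $2^{31}$, so
any cell of the protocol can be re-run in isolation and two runs with the
same master seed are bit-identical single-threaded. The determinism check
in the acceptance script compares the CSV output of two full `cv` runs
byte for byte.

## ln(IC50) binarization

Continuous ln(IC50) tables are converted to labels by a three-step
procedure: each cell line's value is resampled `draws_per_sample` = 100
times from a normal centred on it; the pooled draws are smoothed by a
fixed-bandwidth (0.5) Gaussian KDE on a 512-point grid spanning the data
±3 bandwidths; and the threshold is the grid point of minimum density
strictly between the two highest local maxima. Cell lines below the
threshold are sensitive.

Two interpretation choices are explicit configuration rather than silent
defaults. First, the resampling spread: the "interval" parameter (0.5) is
used directly as the normal's standard deviation; the alternative reading
— a 95% confidence interval of that width, $\sigma = 0.5/3.92$ — is
selectable. Second, the unimodal fallback: when the pooled density has a
single mode there is no between-modes minimum, and the threshold falls
back to pooled mean − 1 sd, placing the sensitive boundary in the low-IC50
tail. The between-modes rule is isolated in `find_threshold()` so it can
be swapped without touching resampling or density estimation. A flat
density, or an input with all values identical, is a degenerate-density
error rather than an arbitrary threshold.

The threshold is equivariant under a common shift of the inputs (the grid
shifts with the data), and labels depend on the values only through the
comparison with the threshold; both are asserted as tests.

## The simulator

`simulate_dataset()` generates the structure the pipeline is designed to
exploit: a small planted set of informative features per layer —
expression/CNA informative features are unit-variance Gaussians whose
sensitive-class mean is shifted by `effect_size` (default 1.5, in noise-sd
units); mutation informative features are Bernoulli with rate 0.4 in
sensitive samples against a 0.05 background — among a large majority of
low-variance noise features (variance in [0.01, 0.25], below the
informative variance so the scree has a detectable knee), with 15%
sensitive samples by default to mirror the imbalance of real cell-line
panels and exercise the oversampling path. Informative features sit at
known indices and are returned in metadata, so feature-selection recovery
is a direct assertion rather than a statistical one. Default dimensions
are 400 samples and 1000/300/500 features.

What the simulator does *not* emulate: gene–gene correlation, batch and
platform effects between panels, dose–response measurement noise, or any
nonlinear genotype–response relationship. Passing the recovery tests
therefore shows that the machinery works as specified on data matching its
assumptions — near-ceiling AUCs on the simulation say nothing about
real-panel performance, where signals are far weaker and partially
redundant across layers. `simulate_ic50()` draws from a two-component
normal mixture (defaults: 20% at −3, 80% at +1, sd 0.5) recording true
component membership, which makes binarization accuracy directly
measurable.

## Numerical choices and degenerate inputs

* Triplet distances below $10^{-12}$ contribute a zero gradient direction
  (the hinge subgradient at coincident points), avoiding division blow-up.
* BCE probabilities are clipped to $[10^{-7}, 1-10^{-7}]$ before the log.
* Encoder/classifier improvement tolerances for early stopping are
  $10^{-10}$ — strictly-better bookkeeping, not a convergence criterion.
* Validation splits must contain both classes; single-class training or
  validation inputs are errors, not warnings, because every downstream
  quantity (triplets, AUC) is undefined.
* Empty triplet batches yield loss 0 with a warning; `max_epochs = 0`
  returns the seeded initial weights, which gives tests a handle on the
  untrained model.
* Sample alignment across layers sorts IDs in C-locale (radix) order, so
  fold membership cannot depend on the locale of the host system.

## Problem sizes used in tests

The test suite and acceptance script run on simulated panels of 100–400
samples with 120–1000 expression features (10–30 informative), encoder
budgets of 10–50 epochs, and 1×3- to 5×5-fold protocols; oracle
comparisons use 100–200 random instances of up to 30 samples. These sizes
were chosen so the planted signal is comfortably detectable while the full
suite runs in minutes on one core; they are stated here so results are
read at the scale they were computed.

## Known limitations

* Single-layer encoders only; no deep variants, and no semi-hard or
  hard-negative mining — batch-all enumeration is quadratic-cubic in batch
  composition and is the only strategy implemented.
* The between-modes threshold rule is a documented stand-in for threshold
  selection on top of pooled KDE; published per-drug thresholds derived
  from dose-response confidence intervals will not be reproduced exactly.
* No normalization, homogenization or batch correction: inputs are assumed
  preprocessed and cross-panel feature spaces reconcilable by name.
* `cross_validate()` retrains every stage per cell and hyperparameter set;
  cost grows as repeats × folds × sets × (encoders + head).
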