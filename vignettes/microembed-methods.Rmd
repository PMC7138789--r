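---
title: "Methods: representation learning and leakage-free evaluation for microbiome disease prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: representation learning and leakage-free evaluation for microbiome disease prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`microembed` treats disease prediction from microbiome profiles as a
two-stage problem. Stage one learns an unsupervised low-dimensional
representation `z = f(x)` of the profile vector `x` with an autoencoder
trained to reconstruct its input; stage two trains a supervised
classifier on `z`. The premise is that strain-level marker profiles
(binary, often ~10^5 features) and species-level abundance profiles
(compositional, rows summing to 1) are generated by community structure
of much lower effective dimension, and that classifiers tuned on a
compact representation generalize better from cohorts of a few hundred
samples than classifiers fit to the raw matrix.

### Autoencoder families

All four families minimize mean squared reconstruction error (the VAE
adds a KL term) and are trained by Adam (learning rate `1e-3`,
`beta1 = 0.9`, `beta2 = 0.999`, `epsilon = 1e-7`) on mini-batches of 32
with early stopping: training halts once the validation loss has not
improved for 20 consecutive epochs (`patience`), and the weights of the
best epoch are restored. `max_epochs` defaults to 2000, a ceiling that
early stopping rarely reaches.

* **SAE** — one linear encoding layer to the latent dimension and one
  linear decoding layer back. The latent grid spans dimensions
  {32, 64, 128, 256, 512} (`enumerate_ae_grid("SAE", p)` = 5 points).
* **DAE** — inserts 1 or 2 symmetric hidden ReLU layers on each side;
  hidden widths double outward from the latent layer, so
  `dae_layer_schedule(512, 2)` is 2048/1024/512/1024/2048 (5 hidden
  layers total). Grid: 5 latent sizes x {1, 2} insertions = 10.
* **VAE** — the encoder emits the mean and log-variance of a diagonal
  Gaussian posterior; training maximizes the evidence lower bound with
  the closed-form KL `-0.5 * sum(1 + lv - mu^2 - exp(lv))` against a
  standard-normal prior (`vae_objective()`), using the reparameterization
  trick. Validation loss, and therefore early stopping, is evaluated at
  the posterior mean so that model selection is deterministic, and
  `encode()` likewise returns the posterior mean. Grid: 5 latent sizes x
  intermediate layer {absent, 256, 512} = 15.
* **CAE** — the profile vector is reshaped row-major into a `d x d` grid
  with `d = floor(sqrt(n)) + 1` and zero padding
  (`reshape_to_square()`); the encoder stacks 2 or 3 convolutional
  layers whose filter counts halve (`cae_filter_schedule(64, 3)` =
  64/32/16), the decoder mirrors them with transposed convolutions, and
  the flattened last encoder layer is the representation. Layer
  geometry is derived from the grid size: the first layer uses filter
  size `floor(0.1 d)` and stride `floor(0.25 f)`, later layers
  `floor(0.1 s_prev)` and stride `floor(0.5 f)`, each floored at 1;
  inputs with fewer than 100 features (`d < 10`) are rejected as a
  configuration error. Grid: first filters {32, 64, 128, 256, 512} x
  {2, 3} layers = 10.

Two non-neural baselines calibrate the value of the autoencoders:
`pca_reduce()` keeps the smallest number of principal components
explaining 99% of training variance, and `rp_reduce()` applies a
Gaussian random projection at the Johnson–Lindenstrauss dimension
`jl_min_dim(n, eps = 0.5)` = `floor(4 log(n) / (eps^2/2 - eps^3/3))`
(221 at n = 100). When that dimension is not below the input width the
data pass through unchanged with a warning.

### Classifiers and selection

Hyper-parameters are chosen by stratified 5-fold cross-validation on the
training portion only, maximizing mean fold accuracy; ties go to the
first grid point in enumeration order, making selection deterministic.

* **SVM** (via `e1071`): linear kernel with `C` in `2^{-5, -3, ..., 5}`
  plus RBF with the same `C` range crossed with `gamma` in
  `2^{-13, -11, ..., 3}` — 6 + 54 = 60 points. Test scores are signed
  decision values, oriented so larger means the positive class.
* **RF** (via `ranger`): trees {100, 300, 500, 700, 900} x minimum leaf
  size {1, 2, 3, 4, 5} x features per split {sqrt(p), log2(p)} x split
  criterion {gini, hellinger} = 100 points. Test scores are out-of-bag-free
  probability-forest votes.
* **MLP** (native engine): hidden layers {1, 2, 3} with first-layer
  widths {10, 30, 50, 100} halving per layer, dropout {0.1, 0.3},
  training epochs {30, 50, 100, 200, 300} as an explicit axis — 120
  points. Scores are sigmoid outputs.

On the split-criterion pair: the classical reference grid pairs Gini
impurity with Shannon-entropy splitting. No random-forest backend
available to R in this stack implements entropy splitting, so the grid
pairs Gini with Hellinger-distance splitting instead — a published
criterion with similar intent (sensitivity to minority-class structure)
that preserves the grid's cardinality and its "two contrasting
criteria" design. This is the one deliberate deviation from the
reference grids and it is surfaced here rather than hidden.

### Evaluation protocol

`stratified_split()` draws, per class, 20% of samples as the test set
(rounded) and 20% of the remainder as the validation set, yielding the
64/16/20 layout and class counts within one sample of proportional;
classes with fewer than 5 samples are rejected. For each seed,
`run_once()`:

1. splits the samples;
2. fits the reducer on non-test rows only (autoencoders train on the
   training rows with the validation rows driving early stopping; PCA
   and RP fit on all non-test rows);
3. encodes the non-test rows and runs 5-fold cross-validated grid
   selection on them;
4. refits the winning specification on all non-test rows and scores the
   test rows by AUC (rank statistic, tie-aware), AUPRC (step-wise
   average precision) and accuracy.

`repeat_evaluation()` repeats this over `n_repeats` consecutive seeds
(default 5) and reports per-seed rows plus means. The test suite
verifies by instrumentation that test indices never reach stages 2–3.

## The synthetic generator

Real cohort benchmarks require external data, so the package ships a
generator with known ground truth. `generate_synthetic()` draws a latent
`z ~ N(0, I_k)`, labels samples by a random hyperplane through the
latent space (`label = 1` when `w'z + noise > 0`), and builds features
from `t = z_perp + effect_size * label * u`, where `z_perp` is the
component of `z` orthogonal to `w`. At `effect_size = 0` the features
are therefore exactly independent of the label — pipelines must score at
chance — while increasing `effect_size` plants a recoverable signal.
Marker features are Bernoulli draws through per-feature logistic links
whose intercepts are calibrated by bisection so the realized positive
rate matches `sparsity` (default 0.1); abundance features are a row-wise
softmax of linear readouts plus noise, giving rows that sum to one. The
generator is a scope-limited instrument: it produces low-rank logistic
structure, not ecological realism (no phylogenetic correlation, no
zero-inflation beyond the Bernoulli links, no compositional bias), and
conclusions from it transfer to real cohorts only as smoke-level
evidence.

## Numerical choices

* The neural-network engine is written in vectorized base R:
  convolutions use im2col index gathers and `rowsum` scatter-adds, so
  all heavy arithmetic is BLAS matrix multiplication. Gradients for
  every layer type are checked against central finite differences in
  the development suite; recorded invariants (loss decrease, early
  stopping behaviour, seeded determinism) guard them in the shipped
  tests.
* AUC is computed by the rank (Mann–Whitney) formula with midranks, so
  ties are handled exactly; the tests compare it to an independent
  pairwise-concordance oracle at 1e-9.
* All stochastic entry points take explicit seeds and use a
  save/restore discipline for the R random-number state, so library
  calls never perturb a caller's stream.
* Profile round-trips write full precision (17 significant digits).

## Problem sizes and runtime

The package targets desk-scale problems: hundreds of samples and up to a
few thousand features run in seconds to minutes on one CPU. The heaviest
shipped check — the full SAE(32) + random-forest pipeline, 100-point
grid, on generated 400 x 2000 marker cohorts at three effect sizes, five
seeds each — takes about ten minutes. The ~10^5-feature marker matrices
of real strain-level profiling are outside comfortable range for the
native CAE and MLP (dense base-R convolutions), though SAE/DAE/PCA/RP
paths remain tractable.

## Limitations

* Binary classification only; no multi-class or survival endpoints.
* The native engine is CPU-bound and single-threaded; no GPU path.
* Random-forest entropy splitting is unavailable (see above).
* The synthetic generator validates machinery, not biology; claims
  about real cohorts require real cohort data.
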