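---
title: "Attentive convolutional autoencoders with boosted trees for multi-omics subtype classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Attentive convolutional autoencoders with boosted trees for multi-omics subtype classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Molecular subtypes of a cancer — subgroups with distinct prognosis and
treatment response — leave signatures across several omics layers at once:
gene expression, miRNA expression, DNA methylation. Each layer is wide
(hundreds to tens of thousands of features) while cohorts are small
(on the order of a hundred samples), so direct classification overfits
badly. `caemgbdt` implements a two-stage supervised pipeline: a
per-omics 1D convolutional autoencoder compresses each layer into a
low-dimensional latent code, a convolutional block attention module (CBAM)
re-weights that code, and a gradient-boosted decision-tree ensemble (GBDT)
classifies samples from the attention-refined latents concatenated with the
decoder reconstruction.

## Preprocessing

Each omics table arrives as features x samples. Blocks are concatenated by
sample ID (not column position) and every *sample* is standardized to mean
0 and population standard deviation 1:

$$x'_{ij} = \frac{x_{ij} - \mu_i}{\sigma_i}, \qquad
\sigma_i = \sqrt{\tfrac{1}{n}\sum_j (x_{ij}-\mu_i)^2}.$$

Two points deserve emphasis. First, the divisor is $n$, not $n-1$: the
transform is a per-row population z-score, and `standardize()` is tested to
reject the sample-variance alternative. Second, scaling per *sample* rather
than per feature means the transform uses no cross-sample statistics at
all, so it cannot leak information from test samples into training — the
whole matrix can be standardized once, before splitting. A conventional
per-feature option exists (`per_feature = TRUE`) but is off by default.
Rows with zero variance map to zeros rather than erroring, since a
constant row is plausible in sparse omics data.

Train/test splitting is stratified by subtype (`split_samples()`): with
cohorts of ~100 samples and 4 classes, unstratified folds routinely lose a
class from a partition. Two schemes are provided — five folds of near-equal
size, and a single 3:1 split holding out `floor(n/4)` samples, the scheme
used for the multi-omics configuration at full scale.

## The autoencoder

Each omics block gets its own encoder/decoder branch:

* **Encoder** — dense layer(s) with GELU, reshape to a single-channel
  sequence, then Conv1D blocks (kernel 3, stride 2, "same" padding, GELU)
  each followed by max-pooling. "Same" padding means the output length is
  `ceiling(L / stride)`; `conv_out_len()` and `shape_trace()` expose the
  arithmetic.
* **Attention** — the branch latents, which share a channel count, are
  concatenated along the position axis and passed through CBAM (below);
  the attention block sits on the gradient path between encoders and
  decoders and is trained jointly under the same loss.
* **Decoder** — per block in reverse: upsampling by the pool size, then a
  transposed convolution (kernel 3, stride 2) with an output padding of
  `stride - 1` so each block exactly doubles the length (the bare
  transposed-convolution formula `stride*(L-1) + kernel - 2*padding`
  yields `2L - 1` at kernel 3 / padding 1; the trailing output pad restores
  the exact mirror). A final single-filter transposed convolution
  collapses the channels and a dense layer restores the exact input width.

Two wide blocks (gene expression, methylation at BRCA-like widths) use
Dense 512 → Conv(16 filters)+Pool 2 → Conv(4 filters)+Pool 4; narrow
blocks use Dense 128 → Conv(4)+Pool 4. Every preset ends at a latent of
16 positions x 4 channels, a ~1000-fold reduction for the widest block.
The `"auto"` preset extends the same pattern down to blocks of at least 16
features so that arbitrary simulated widths are usable.

Hidden dense layers use GELU for uniformity with the convolutional stack;
the single width-restoring output layer is linear, because standardized
data is unbounded in both directions while GELU is bounded below.

The training objective is

$$J = \frac{1}{2N}\sum_{i=1}^{N} \lVert x_i - \hat x_i\rVert^2
      + \lambda \sum_W \lVert W \rVert_2^2,$$

half the mean (per-sample) squared reconstruction error plus an L2 penalty
on the trainable *weights* (biases excluded). Applying the penalty to
weights rather than to the (constant) input matrix is the only reading
under which the term has a gradient and can regularize. Optimization is
minibatch Adam (step size `1e-3`, batch 16, $\lambda = 10^{-4}$ by
default; all exposed in the run configuration). The full-scale setting is
100 epochs. Forward and backward passes are written directly in R on top
of BLAS matrix products, with hand-derived gradients; the test suite
verifies every parameter's analytic gradient against central finite
differences, which is the strongest single check such an engine can have.
The decoder is purely sequential (no skip connections from the latent into
the decoder input); the skip-connection variant is not implemented.

## Attention (CBAM)

Channel attention first: the latent `(positions x channels)` is average-
and max-pooled over positions; both pooled vectors pass through one shared
two-layer MLP (hidden width `max(channels/ratio, 1)`, ReLU, second layer
linear, no biases), the results are summed and squashed by a sigmoid into
per-channel weights in (0,1). Spatial attention second: the per-position
channel mean and channel max are stacked into a two-channel sequence and
convolved (same-padded, single output filter, length-7 kernel, no bias)
into per-position weights. Each stage multiplies its weights into the
tensor, so attention only ever attenuates and output shape equals input
shape. The 2D 7x7 kernel of image CBAM becomes a length-7 1D kernel here
because the latent is a sequence, not an image.

The channel-then-spatial order is fixed in the API; the reversed order
exists only behind the `spatial_first` ablation flag. The reduction ratio
defaults to 8 — a convention, not a published value — and with 4-channel
latents the hidden width floors at 1.

## Classifier features

The classifier input concatenates, per sample, the flattened
attention-refined latent (positions fastest within each channel) and the
decoder reconstruction, e.g. 3x16x4 + 41,262 = 41,454 columns for a
three-block run at BRCA-like widths. Including the reconstruction makes
the feature matrix wider than the input; it is implemented this way
because that is the stated construction, and `latent_only = TRUE` offers
the compact alternative. `slice_features()` recovers either part
losslessly.

## Boosted-tree classifier

Multi-class prediction is one-vs-all: one binary deviance-boosted ensemble
per class, so `M` stages and `K` classes yield `M*K` trees. Each stage
fits a depth-limited regression tree to the loss gradient on a random 80%
of rows (stochastic gradient boosting). Per-class raw scores are
softmax-normalized into probabilities. The reference configuration is
learning rate 0.1, at most 300 estimators per class, depth 3, at least 5
samples per leaf, subsample 0.8, log-loss. Optional early stopping holds
out a stratified 15% of the training samples and stops a class ensemble
after 10 non-improving rounds (the strategy is stated in the source
method; the 15%/10 numbers are this package's defaults).

xgboost is the boosting engine behind `fit_gbdt()`. Its extra regularizers
are disabled (leaf L2 = 0, gamma = 0, no column subsampling) so the fit
matches the classical stochastic-GBDT configuration, and the
minimum-samples-per-leaf constraint is enforced through the hessian bound:
a binary-logistic hessian is at most 0.25 per sample, so
`min_child_weight = 5 * 0.25` guarantees at least 5 samples in every leaf.
`min_samples_split = 5` is recorded but is dominated by the leaf
constraint (a split needs two 5-sample children, hence 10 samples).
Note that with per-stage subsampling a monotone full-training-set loss is
an empirical regularity, not a theorem; the suite asserts it with a 1e-6
numerical tolerance on the fixtures it uses.

Metrics are accuracy plus macro-averaged precision, recall and F1
(per-class one-vs-rest, F1 as the per-class harmonic mean before
averaging), reported as percentages to one decimal. A class never
predicted contributes precision 0. Macro averaging is chosen because it is
the reading consistent with recall falling below accuracy on imbalanced
data.

## Synthetic data

`generate_multiomics()` plants subtype structure in Gaussian blocks:
baseline feature means ~ N(0,1); an `informative_frac` subset of features
receives per-class shifts of magnitude `effect_size * noise_sd` with
random signs (if all classes happen to draw the same sign the feature
would carry no contrast, so one class is flipped — every planted feature
then separates at least one class pair); i.i.d. Gaussian noise on top;
labels follow the configured proportions (balanced by default, since real
subtype counts for the reference cohorts are unpublished) with
largest-remainder rounding. The generator returns the informative-feature
mask so tests can check that the largest observed class contrasts sit on
planted features.

Named fixtures pin the study conditions: `tiny` (40 samples,
200+30+300 features, K = 3, effect size 3 — the fast CI fixture),
`strong4` (120 samples, K = 4, effect size 4 — the recovery benchmark),
and `brca_shaped` / `gbm_shaped` with the reference dimensionalities
(17,814+354+23,094 x 104 and 12,042+534+1,305 x 213), K = 4, effect size
2 on 5% of features. K = 4 is this package's choice; the reference cohorts
do not publish subtype counts.

What the generator does *not* emulate: real covariance structure between
features and between omics layers, bounded methylation beta values, batch
effects, platform artifacts, class imbalance. Passing tests therefore
demonstrate that the pipeline recovers planted additive mean-shift
structure under Gaussian noise — a necessary sanity property — not that it
attains any particular accuracy on real tumors.

## Pipeline protocol

`run_train()` standardizes once (per-sample, leakage-free by
construction), then *retrains the autoencoder inside every split on
training samples only*; test samples are only ever encoded with the
trained model. The source method is silent on whether feature extraction
saw test samples; the leakage-free protocol is the defensible choice. For
five-fold runs the headline metric is the across-fold mean (with sd).
Every artifact (`metrics.json`, loss curves, the ablation table) carries
an MD5 hash of the scientific configuration, and a manifest records the
full configuration and derived per-fold seeds, so a manifest determines a
bit-identical rerun in single-threaded mode.

`run_ablation()` reruns the identical seeds/splits with `no_cbam`
(attention removed), `spatial_first` (stage order swapped) and/or
`latent_only` (reconstruction dropped from the classifier features).

## Numerical and scale choices

* All randomness flows through R's RNG from explicit seeds; per-fold seeds
  are `seed + fold`. Same configuration + seeds reproduce `metrics.json`
  byte-for-byte under a fixed BLAS thread count.
* Max-pooling breaks ties toward the earlier position; pooling uses floor
  division and the builder rejects geometries whose decoder cannot mirror
  back onto the encoder dense width.
* Training reports the per-epoch mean batch loss including the L2 term
  (the weight norm is maintained incrementally by the optimizer kernel);
  a non-finite loss aborts with the epoch number.
* Problem sizes used by the test suite: the descent and determinism checks
  run the `tiny` fixture; recovery and chance-level checks run `strong4`
  geometry over 5 seeds at 20 and 8 epochs respectively; one full-scale
  `brca_shaped` run (41,262 features x 104 samples, 100 epochs, 3:1
  split) uses batch size 32, the setting chosen for single-core runs at
  full scale (per-sample GEMM and optimizer cost drop markedly between
  batch 16 and 32 with no measurable effect on the fixtures' accuracy);
  smaller studies keep the default batch 16.
* The effect-size monotonicity study asserts a strong overall rise and
  tolerates 5-percentage-point dips between adjacent means, because near
  chance level the ordering of two 5-seed means is itself noise.

## Known limitations

* No missing-data imputation (missing cells are an error), no batch
  correction, no probe-to-gene mapping, no download client for public
  cohorts.
* The autoencoder runs on CPU only; wall time at full scale is minutes,
  not seconds.
* Only the tanh-approximate GELU is provided. It is faithful to its
  defining formula — including the small dip (minimum ≈ −0.17 near
  x = −0.75), i.e. the activation is not globally monotone.
* Hyperparameters are taken as given; there is no search facility.
* The one-vs-all ensembles are calibrated only through the softmax over
  raw margins; probabilities are rankings, not calibrated posteriors.
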