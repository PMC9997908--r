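---
title: "Autoencoder feature extraction for spike sorting: models, data and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autoencoder feature extraction for spike sorting: models, data and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spikeAE)
```

## The problem

Spike sorting assigns each detected extracellular action potential to the
neuron that generated it. Because clustering quality is driven mainly by
the feature space the spikes are embedded in, the step this package is
about is **feature extraction**: mapping fixed-length spike waveforms
(here 79 samples at 24 kHz, about 3.3 ms) into a low-dimensional space in
which K-Means can separate units. spikeAE implements ten autoencoder
variants as non-linear feature extractors, the classical baselines they
are compared against (PCA, ICA, Isomap), the preprocessing that all of
them need (alignment, scaling, shuffling), a ground-truth simulator, a
threshold detection front-end, and a six-metric evaluation suite with
Borda rank aggregation.

## The autoencoder model

All dense variants share one symmetric architecture: an encoder of
strictly decreasing fully connected layers, a bottleneck *code* layer,
and a mirrored decoder. Hidden layers use the rectifier; the code and
output layers use the hyperbolic tangent, which admits the negative
values needed to reconstruct biphasic waveforms and bounds codes to
$[-1,1]$. Training minimises the mean squared reconstruction error with
Adam (learning rate $10^{-3}$) over full passes of shuffled mini-batches;
after training, the code-layer activations are the extracted features.
No train/test split is used: the autoencoder is a representation learner,
not a predictor, so the whole dataset both trains the model and is
embedded by it.

The variants differ as follows.

| variant | encoder widths | code | distinguishing element |
|---|---|---|---|
| `shallow` | 60, 40, 20 | 2 | smallest dense model |
| `deep` | 70, 60, 50, 40, 30, 20, 10, 5 | 2 | 17 weight-bearing layers in total |
| `tied` | as deep | 2 | decoder matrices are transposes of encoder matrices, maintained after every optimiser step |
| `pca_hybrid` | 70, 60, 50, 40, 30 | 20 | 20-D code projected to 2-D by PCA afterwards |
| `pretrained` | as deep | 2 | greedy layer-wise pretraining initialises all weights |
| `lstm` | 60, 40, 20 (recurrent) | 2 | waveform read as a scalar sequence; code = final state |
| `ft` / `wft` | deep schedule, capped | 2 | inputs are the real part of the (Blackman-tapered, for `wft`) half-spectrum |
| `orthogonal` | as deep | 2 | penalties pushing $W^\top W$ to $I$ and code covariances to diagonal |
| `contractive` | as deep | 2 | loss adds $\lambda\,\lVert J_f(x)\rVert_F^2$, the squared Frobenius norm of the encoder Jacobian |

Parameter conventions worth noting:

* **Code L1.** The regularisation strength is quoted in the source
  convention "10e-7"; read literally that is $10^{-6}$. The default is
  $10^{-7}$ (`code_l1`), and the literal reading is one keyword away.
  The penalty acts on code *activations* (the sparse-code reading); the
  alternative weight-decay reading is not implemented.
* **Epochs.** The default is 500, which corresponds to the main
  comparison tables; 50 is the fast preset used in the examples and
  tests, and is where the epochs sweep finds the best internal scores.
* **Contractive penalty.** Summed (not averaged) over the batch, as the
  defining sum suggests; $\lambda$ is unstated in the source, defaulting
  here to $10^{-4}$ (`contractive_lambda`). The Jacobian of the ReLU +
  tanh encoder is computed analytically; ReLU masks are treated as
  locally constant (their derivative is zero almost everywhere) while
  the tanh diagonal is differentiated exactly. Tests verify the penalty
  against central finite differences to $10^{-4}$ relative error and the
  full loss gradient to ~$10^{-10}$.
* **Orthogonal penalties.** Both weights are unstated in the source;
  defaults are 0.01 each, applied to every encoder *and* decoder matrix
  (orthogonality) and to the off-diagonal batch code covariance
  (decorrelation). A decorrelation term needs at least two samples; a
  trailing batch of size one simply skips it.
* **Greedy pretraining.** Each stage trains a one-hidden-layer
  autoencoder (ReLU hidden, tanh at the code stage) and passes its codes
  on. Stage outputs use a linear layer: stages after the first consume
  unbounded ReLU codes, which a tanh output could not reconstruct.
  Stage epochs default to 20 (`pretrain_epochs`).
* **LSTM.** The source gives no sequence convention; each waveform is a
  length-79 sequence of scalars, intermediate recurrent layers return
  sequences, the code layer returns its final hidden state, and the
  decoder repeats the code at every timestep before a per-timestep tanh
  output unit.
* **ft/wft input width.** The real-part half-spectrum of a 79-sample
  waveform has 40 bins, so encoder widths that no longer compress
  (≥ input dimension) are dropped from the deep schedule for these
  variants. Fourier features are min-max rescaled to $[0,1]$ before
  training, for the same reconstruction-range reason as the waveforms.

## Preprocessing

**Alignment** shifts every waveform so its reference peak (maximum by
default, minimum optionally) sits at a common index:
`new_start = old_start − (index_align − peak)`. The default target is the
window middle, which keeps information from both the rising and falling
phases. When only extracted waveforms exist, the shift happens within the
fixed window with edge-value replication; when the continuous signal is
available, windows are re-cut from it and spikes pushed outside the
signal are skipped and counted. Alignment is idempotent and label-
preserving; both properties are tested.

**Scaling** maps the whole dataset through one global min–max affine map
onto $[0,1]$ — global, not per spike, because per-spike scaling would
erase the amplitude differences that separate clusters. (The tanh output
can reach $[-1,1]$; the data only needs the upper half.) The fitted map
is stored so later data from the same recording can be transformed on the
same scale. **Shuffling** breaks the by-cluster ordering of simulation
files before mini-batch training; it permutes waveforms and labels with
one seeded permutation.

## The synthetic generator

The public benchmark simulations cannot be redistributed, so
`generate_labeled_spikes()` / `generate_recording()` emulate their
statistical structure procedurally:

* one biphasic template per single unit (difference-of-Gaussian-lobes
  family with stratified peak width, trough delay/width/depth, pre-peak
  dip and after-bump, so units differ along several shape axes), peak at
  the window middle, 79 samples at 24 kHz;
* per-unit mean firing rates uniform in 0.1–2 Hz, independent Poisson
  spike trains, events thinned to at least 0.3 ms separation;
* single-unit amplitudes spanning 0.9–2: unit means spread across the
  interval (emulating distinct electrode distances, which is what makes
  amplitude an informative feature in the originals) with per-spike
  normal variation of sd `amplitude_sd = 0.05`, truncated to the
  interval. A strictly dataset-global normal rescaling was tried first
  and rejected: it makes every unit span the full amplitude range, and
  then even K-Means on the raw 79-dimensional waveforms cannot recover
  the clusters that the source material demonstrably contains;
* a multi-unit background cluster (label 0) mixing 20 shapes at fixed
  amplitude 0.5, each component at 0.25 Hz — a 5 Hz composite;
* additive Gaussian noise (`noise_sd`, default 0.1; the source does not
  specify the simulations' noise model, so the level is exposed rather
  than fixed) and optional uniform peak jitter to exercise alignment.

What the generator does **not** emulate: real recorded spike shapes (the
originals use a library of several hundred), electrode drift, bursting,
temporally overlapping spikes, or multi-channel geometry. Tests passing
on this generator therefore certify the pipeline's mechanics and the
qualitative phenomena (alignment benefit, learning-rate failure,
contractive sensitivity), not performance on real tissue.

## Detection front-end

`detect_spikes()` band-pass filters (300–7000 Hz Butterworth, order 3,
forward–backward so the phase is zero and peaks do not move), thresholds
the absolute filtered signal at `threshold_k` standard deviations
(default 4, within the conventional 3–5), groups suprathreshold samples
separated by at most the refractory lockout into one event, and cuts a
centred window at each event's absolute peak. The default lockout equals
the generator's minimum separation (0.3 ms); wider spikes whose trough
also crosses threshold are better served by a lockout near half a window.

## Evaluation

Three external metrics compare predicted with ground-truth labels — the
adjusted Rand index (pair counting, chance-corrected via the contingency
table), adjusted mutual information (with the *exact* hypergeometric
expected-MI term, chosen over Monte-Carlo for determinism), and the
V-Measure (harmonic mean of the entropy-based homogeneity and
completeness, $\beta = 1$). Three internal metrics score geometry:
Davies-Bouldin (lower is better), Calinski-Harabasz and Silhouette. On
labeled data the internal metrics are computed on the *ground-truth*
labels — they then measure the feature space itself, not K-Means.
Degenerate cases are pinned down explicitly because the formulas are
silent: two trivial partitions give ARI 1; two zero-entropy labelings
give AMI 1; AMI is clipped into its documented $[0,1]$ range (chance
agreement can produce tiny negatives); zero-entropy sides of the
V-Measure score 1; coincident centroids (Davies-Bouldin) and zero
within-cluster dispersion (Calinski-Harabasz) are errors; singleton
clusters contribute 0 to the Silhouette. Every metric is tested to
$10^{-9}$ against naive enumeration/entropy/distance-loop oracles.

Clustering uses Euclidean K-Means (Lloyd) from k-means++ seeds,
deterministic per seed, with `k` set to the number of ground-truth
clusters on labeled data (the source never states its choice; this is
the only value that makes external comparison meaningful) and
user-supplied on unlabeled data. A collapsed embedding with fewer
distinct points than `k` yields a flagged degenerate clustering instead
of an error — this is precisely the high-learning-rate failure mode, and
it must be measurable (it scores ARI ≈ 0) rather than fatal.

Method comparison across metrics uses Borda rank aggregation
(per-metric ranks to points, ties averaged — the tie policy is a choice,
the source states none) and Bonferroni-corrected paired t-tests.

## Numerical and design choices

* Sample indices are 1-based throughout, as in R; the alignment formula
  is index-origin invariant. K-Means labels are returned 0-based in
  $[0, k)$, and label 0 is reserved for the multi-unit cluster.
* PCA components fix their sign by making each component's
  largest-magnitude loading positive, so printed values are stable.
* ICA is FastICA (symmetric decorrelation, `logcosh` contrast, tolerance
  $10^{-5}$, iteration cap 1000 — ample for convergence); no installed
  package provides it in this stack, so it is implemented here and
  tested by unmixing known sources.
* Isomap is the classical composition kNN graph → shortest-path
  geodesics → classical MDS. A disconnected graph embeds its largest
  component and reports the dropped spikes; downstream evaluation
  subsets the ground truth accordingly. The geodesic matrix is verified
  against both a Floyd–Warshall oracle and an independent
  implementation.
* Grid search for embedding parameters scores every combination with a
  chosen metric (ARI by default when ground truth exists, Silhouette
  otherwise; minimum for Davies-Bouldin) and returns the full score
  table for audit. The source describes its grids only qualitatively,
  so default ranges are the user's choice.
* MAT simulation containers are read by a minimal MAT v5 reader
  (numeric, char and cell arrays; zlib-compressed elements), since no
  installed package reads the format here; variable names are mapped
  through a configurable `field_map` whose defaults are a documented
  guess, and unknown layouts fail naming the missing variable.
* Training is deterministic given (seed, config, data): the seed fixes
  initialisation and batch order, and there are no stochastic layers.

## Problem sizes in the tests and acceptance script

The test suite and `scripts/acceptance.R` run the full experiments at
reduced but representative sizes, chosen so the whole suite completes in
a few minutes of one CPU: recovery and learning-rate experiments use
5-unit sets of roughly 1,000–5,000 spikes (50 training epochs), the
alignment experiment 10 generator seeds of ~600 spikes (30 epochs), and
module tests use 31-sample waveforms with narrow layer schedules. The
printed comparison tables of the source material are computed from the
95-simulation public corpus and are not reproduced at these sizes; the
qualitative orderings (alignment helps; lr 0.1 collapses; shallow/deep
variants beat unaligned PCA on easy sets) are.

## Known limitations

* Training variance is real: the deep variant occasionally converges to
  a partially collapsed code on an unlucky initialisation, exactly as
  run-to-run variability analyses of such models show; medians over
  seeds are therefore the reported statistic.
* The LSTM variant is computationally the heaviest and is exercised at
  small sizes in the tests; it is functional, not tuned.
* The contractive Jacobian treats ReLU masks as locally constant (exact
  almost everywhere, approximate at kink crossings within a
  finite-difference step).
* Single-channel waveforms only; no tetrode handling, no drift model,
  no overlapping-spike synthesis.
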