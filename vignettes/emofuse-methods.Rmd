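---
title: "Bimodal EEG/facial-video emotion recognition with DCCA fusion: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bimodal EEG/facial-video emotion recognition with DCCA fusion: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(emofuse)
```

## The problem and the model

Emotion recognition from a single signal is brittle: facial expressions
can be acted, and scalp EEG is noisy and partly subject-specific. This
package implements a two-stage bimodal pipeline. Stage one extracts
per-modality features with convolutional networks; stage two projects both
feature sets into a joint space where they are maximally correlated (deep
canonical correlation analysis, DCCA), fuses them by a convex weighted
sum, and classifies three emotion categories with a softmax layer.

Labels come from 1–9 self-assessment manikin (SAM) ratings of valence and
arousal. A deciding rating $r \ge 5$ maps to *happy*, $r \le 4$ to *sad*,
and $4 < r < 5$ to *neutral*. The source protocol thresholds valence and
arousal jointly in one place and a single "rating" elsewhere without
stating how disagreeing ratings were resolved; `label_from_ratings()`
therefore uses the mean of valence and arousal by default and exposes a
valence-only policy. Neither policy is asserted as the original authors'
choice; the generator draws ratings consistent with both.

## Video preprocessing

For $T$ frames, the $T-1$ difference frames are the element-wise absolute
differences of consecutive frames (colour frames are first averaged over
channels). Each difference frame is scored by its mean

$$m_t = \frac{\sum_{x}\sum_{y} |d_t(x,y)|}{M \times N},$$

which is zero exactly where consecutive frames match. The *absolute*
difference is deliberate: a signed difference could cancel and violate the
zeros-iff-matched property the scoring relies on. Within every 1-second
block (anchored at frame 0, non-overlapping, a trailing partial block
scaled proportionally) the scores are ranked in descending order, ties
broken toward the earlier index for determinism, and the frames adjacent
to the top $\lceil 0.4 \cdot \mathrm{fps} \rceil$ scores are retained —
40% of each second, so a 60-fps second keeps 24 frames. Which neighbour
of a difference frame is kept is not derivable from the protocol text; the
default keeps the *later* frame (the one that introduced the change), with
`retain = "earlier"` available. Conditioning is a centered largest-square
crop (no face detector is bundled; a crop box can be supplied), an
optional mean-intensity rescale, and a bilinear resize to a square (224
for the residual backbone).

## EEG preprocessing

The band of interest is 4–45 Hz, removing slow ocular drift and utility
interference. The filter is a 5th-order Butterworth band-pass applied
forward and backward (`signal::filtfilt`), i.e. zero phase: the doubled
magnitude response still attenuates 1 Hz and 0.9 × Nyquist by far more
than 20 dB while keeping the pass band within a fraction of a dB, and
zero phase avoids latency skew between EEG windows and video windows.
Whether filtering preceded channel selection in the original protocol is
unstated; the two commute (the filter is per-channel), which the
test-suite asserts.

Ten electrodes over the frontal and temporal lobes — FP1, FP2, AF3, AF4,
F3, F4, F7, F8, T7, T8 — are selected by name (case-insensitive) and
reordered; a missing electrode is an explicit error naming it. Windowing
is non-overlapping with a 5-s window and the trailing remainder dropped:
a 60-s trial yields exactly 12 windows, which is also why no overlap is
used — an overlapping scheme could not reproduce that count.

ICA-based head-motion removal is out of scope here (its unmixing choices
are dataset-specific); the preprocessing accepts a user-supplied artifact
hook in its place, and band-passing is the only conditioning applied to
synthetic data.

## The EEG 1-D CNN and its parameter accounting

Each 5-s window (10 channels × 640 samples at 128 Hz) is flattened
channel-major into one 1-D sequence. The network is then, in order:

| stage | layers | parameters |
|---|---|---|
| 1 | BN(1) → Conv1D 1→64, k=3, stride 1, valid → ReLU | 2 + 256 |
| 2 | BN(64) → Conv1D 64→64, k=3 → ReLU → MaxPool 2/2 | 128 + 12,352 |
| 3 | BN(64) → Conv1D 64→32, k=3 → ReLU → MaxPool 2/2 | 128 + 6,176 |
| head | global average pool → dropout 0.5 → linear softmax | (99, excluded) |

The feature extractor totals **19,042** learnable scalars. Two published
statements are mutually inconsistent with that count: a fully connected
feature layer would make the count depend on the input length, and
depth-wise separable convolutions would give a different tally. The
arithmetic is only reproduced by *standard* convolutions, a
global-average-pool feature head, and batch-norm layers counted as two
learnable scalars per channel (running statistics are buffers). That
convention is what `build_eeg_network()` implements and
`count_parameters()` verifies; the count is asserted to be identical at
input lengths 640 and 1280. The 32-dimensional pooled activations (tapped
before dropout and the head) are the EEG-side DCCA input.

## The video backbone

The adapted residual backbone follows the standard 50-layer bottleneck
layout (stem 7×7/2 + 3×3/2 max pool; stages of 3/4/6/3 bottlenecks with
widths 64/128/256/512), with the terminal global *average* pool replaced
by a global *max* pool, the original classification layer removed, and
dropout 0.5 plus a 3-class softmax head added. The feature tap is the
2048-wide pooled vector. Pretrained weights are optional and never
required by any test; for desk-scale work a tiny 3-stage backbone
(8/16/32 filters, batch-normalised, global average pool, 32-wide tap)
fills the same contract. How per-frame outputs become per-window features
is not specified in the source; the package takes the within-window
*mean* of frame features (order-invariant, tested as such), and
classifies features rather than aggregating per-frame decisions, matching
a feature-level fusion design. Video windows are formed from each frame's
*source* index, so frame selection never shifts window boundaries, and
per trial the video window count always equals the EEG window count.

## DCCA

With paired feature matrices $I_1 \in \mathbb{R}^{M\times n_1}$ (EEG) and
$I_2 \in \mathbb{R}^{M\times n_2}$ (video), two transforms
$O_i = f_i(I_i; H_i)$ are trained to maximise
$\mathrm{corr}(f_1(I_1), f_2(I_2))$, implemented as the sum of singular
values of $\Sigma_{11}^{-1/2}\Sigma_{12}\Sigma_{22}^{-1/2}$ with
$1/(M-1)$ covariance normalisation and a ridge $r$ on the auto-covariance
diagonals. The analytic gradient follows the classic DCCA derivation and
is validated against finite differences (relative error below $10^{-4}$)
in the test-suite; the closed-form linear CCA (`cca_closed_form()`) is
the module's independent oracle, and linear transforms trained on the
objective are required to reach its optimum within 0.05.

Choices that the source leaves open, resolved here:

* The printed "regulation parameter 1e5" is read as $r = 10^{-5}$: a
  ridge of $10^5$ would swamp unit-scale feature covariances and make the
  objective degenerate, while $10^{-5}$ is the conventional DCCA
  stabiliser. The value is config-exposed (`dcca_r`).
* The transform stack (128/256/512 kernels of sizes 3/5/3, each with 2/2
  max pooling, dropout 0.4) is described ending in a softmax layer; a
  probability-simplex output would destroy correlation structure inside a
  correlation-maximising transform, so the transform tap is placed after
  the dropout stage and a linear projection to the output dimension —
  consistent with describing the CCA layer as "two projections and a
  loss".
* The transformed dimension $n$ is never printed; it defaults to 32
  (matching the EEG feature width) in `dcca_transform_spec()` and to 8 in
  the desk-scale pipeline, config-exposed.
* The objective uses all $n$ directions ($k = n$), because the fusion
  $O = \alpha O_1 + \beta O_2$ (equal weights by default,
  $\alpha+\beta=1$ enforced) consumes the full transformed vectors.
* Optimisation is full-batch: at desk scale the singular-value objective
  on mini-batches is too noisy to be a reliable early-stopping signal.

Because the correlation objective is scale-invariant, transformed
features carry arbitrary scale; the downstream softmax classifier
(`classify_fused()`) therefore z-normalises columns with training-split
statistics before fitting.

## Baseline fusion rules

* **Concatenation**: per-column z-normalisation of each modality with
  training-split statistics, then column-wise joining; zero-variance
  columns are dropped with a warning.
* **Kernel combination**: a convex combination of Gram matrices (weights
  on the simplex, uniform by default). Kernel-weight *learning* is out of
  scope; only the combination rule is provided.
* **MAX rule**: the class whose maximum probability over classifiers is
  largest; ties break to the lowest class index.
* **Choquet integral** with a Sugeno λ-measure: densities $g_i \in (0,1)$
  define λ as the unique root $>-1,\ \ne 0$ of $\prod_i(1+\lambda g_i) =
  1+\lambda$ (additively, λ = 0 when the densities sum to 1), subsets
  built by the recursion $\mu(A\cup\{i\}) = \mu(A) + g_i + \lambda g_i
  \mu(A)$. The original reference fits λ by quadratic programming against
  training data whose layout is not recoverable from the text; the
  package instead uses the standard density construction with each
  source's validation accuracy as its density (user-supplied densities
  are accepted). The integral sorts scores ascending and accumulates
  $(h_{(i)} - h_{(i-1)})\,\mu(A_i)$; under an additive measure it reduces
  exactly to the weighted mean, and it always interpolates between
  $\min h$ and $\max h$.
* **Adaptive rule**: the typeset formula in the source text is corrupted;
  the implemented reading,
  $y = (y_F + (1 + (y_E - 0.4)/100)\,y_E)/2$ for $y_E > 0.4$ and the
  plain average otherwise, is the unique nearby form that is continuous
  at the 0.4 threshold and gives EEG "more weight" above it. Continuity
  at the threshold is asserted in the tests; the reading is a documented
  convention, not a claim about the original.

## Evaluation protocol

Leave-one-subject-out: each subject is the test set exactly once; the
remaining trials are split 90/10 into training and validation, stratified
by class at the *trial* level so windows of one trial never straddle the
split. Normalisation statistics, DCCA fitting and classifier training see
only train/validation rows. Decisions are made per 5-s window and
aggregated to trials by majority vote (ties broken by the highest mean
score); because the aggregation level of published per-subject accuracies
is unstated, both window-level and trial-level metrics are reported.
Accuracy, macro recall and macro precision are reported on the 0–100
scale and F1 on the 0–1 scale, matching the mixed convention of the
field's result tables; per-class one-vs-rest metrics are included, and a
never-predicted class takes precision 0.

## The synthetic generator

`generate_dataset()` emulates the *structure* of paired affective trials,
not their physiology:

* EEG: sinusoidal oscillations at 6/10/22 Hz (theta/alpha/beta, inside
  the 4–45 Hz band) whose amplitude profile depends on the class, on the
  ten selected frontal/temporal channels only — so channel selection is
  consequential — over AR(1)-shaped 1/f-like background noise with a
  per-subject offset.
* Video: a Gaussian blob on a grayscale canvas whose intensity and motion
  speed depend on the class, with runs of near-duplicate frames (exact
  copies plus low-amplitude sensor noise) making difference-frame ranking
  non-trivial but unambiguous.
* One latent class per trial drawn from `class_probs`; `effect_size`
  scales class separation (0 removes all signal); `cross_modal_corr`
  splits the trial-level amplitude modulation into shared and
  modality-private parts; `complementary_noise` attenuates the class
  signal in one randomly chosen modality per trial, so each modality errs
  on different trials and fusion has genuine headroom — the construction
  behind the fused-versus-unimodal comparison.
* Ratings are drawn so that the label derived from them reproduces the
  latent class under both labelling policies.

What passing tests on these data do **not** show: robustness to real EEG
spectra, artifacts, face pose and lighting variation, or dataset shift —
the generator makes no attempt at photorealism or physiological realism
beyond band-limited class structure.

## Numerical and desk-scale choices

* All networks run on the package's own engine (shift-and-add BLAS
  convolutions, exact backpropagation, Xavier initialisation, zero
  biases); gradients of every layer type are checked against finite
  differences.
* Training is plain SGD with cross-entropy, batch 32, learning rate
  0.001, at most 40 epochs and early stopping after 15 non-improving
  validation evaluations by default (`train_config()`), with the best
  validation-loss weights restored. The desk-scale pipeline configuration
  deviates deliberately: classical momentum 0.9, larger learning rates
  and single-digit epoch budgets, because a handful of gradient steps on
  a few dozen windows is otherwise too noisy to converge. Momentum is
  off by default everywhere else.
* Desk-scale study sizes, chosen once: 3 subjects × 6 trials of 10 s at
  128 Hz and 8 fps on 24×24 canvases for the leave-one-subject-out
  properties; 5000 rows for canonical-correlation recovery; tolerance
  0.05 against the closed-form CCA oracle.
* Determinism: every stochastic stage draws from a seed derived from one
  top-level seed; fixed seeds give bit-identical datasets, fits and
  result tables.
* Ties: frame-score ties break to the earlier index, decision ties to the
  lower class index, majority-vote ties to the highest mean score —
  all deterministic.

## Known limitations

* EDF/BDF containers are not parsed (no reader ships in this
  environment); the canonical interchange format is a CSV array with a
  JSON sidecar, behind the same reader contract.
* The bidirectional-LSTM fusion variant of the source's baseline list is
  delegated to its own reference and is not implemented; kernel-weight
  optimisation for the kernel-combination rule is likewise out of scope.
* The residual video backbone is built and differentiable but is not the
  test workhorse; without pretrained weights, training it at desk scale
  is not meaningful.
* Published full-corpus accuracies require the gated datasets and
  GPU-scale training and are out of reach of this package's synthetic
  studies; the pipeline's claims are therefore structural (oracle
  agreement, leakage-free protocol, fused-versus-unimodal ordering under
  constructed complementarity), not absolute accuracy claims.
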