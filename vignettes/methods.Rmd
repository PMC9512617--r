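---
title: "Methods: parameter-shared 2D CNNs for multi-position activity recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: parameter-shared 2D CNNs for multi-position activity recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wearcnn)
```

## The problem and the model

Human activity recognition (HAR) from body-worn sensors classifies short
segments of multi-channel time series into activity labels. A subject wears
tri-axial accelerometers at `P` body positions; each sensor reports
acceleration along its device axes x, y, z in units of g, so a recording is a
`(3P + S) x n` channel array (plus `S` optional scalar channels such as a
heart-rate-like stream) with an activity label per timestamp, including a
NULL/background class.

The modelling idea implemented here is an input reorganization. One-dimensional
convolutions over individual channels capture only temporal structure. A 2D
convolution could mix channels, but channels of *different axes on the same
device* are weakly dependent, while channels of the *same axis across
positions* co-vary (limbs and trunk accelerate together under gravity and
whole-body motion). The package's `axis_correlation_report()` measures exactly
this: absolute Pearson correlations of same-axis cross-position pairs versus
cross-axis within-position pairs, with `|r| < 0.3` counted as weak. Grouping
channels by axis therefore puts the exploitable spatial dependence inside each
2D input:

* each sliding window of `T` timestamps is rearranged into three **action
  pictures** — `P x T` matrices, one per axis, whose row `p` is position `p`'s
  channel for that axis — plus an `S x T` scalar picture when scalar channels
  exist ("3 or 4 action pictures" per window);
* each picture passes through a stack of four valid (no-padding) convolutions
  with ReLU activations; the flattened branch outputs are concatenated into a
  single dense softmax layer trained with cross-entropy.

Two axis-branch wirings are provided. In the **independent** variants (`"T"`,
`"M"`) each axis picture has its own convolutional stack. In the **shared**
variants (`"TS"`, `"MS"`) one parameter store serves all three axis branches:
the branches are literally one object, so their weights are identical at
initialization and after every update, and the store's gradient is the *sum*
of the three per-branch gradients (the chain rule over shared parameters; a
mean would only rescale the learning rate). The scalar branch always keeps its
own 1D (time-axis-only) stack — its geometry differs, so it cannot join the
share. A `"1D"` baseline treats all channels as one `(3P+S) x T` picture
convolved with height-1 kernels at matched depth, representing the per-channel
1D-CNN organization.

## Parameter accounting

For a layer with `K_in` input maps, `K_out` output maps and a `K_h x K_w`
kernel, the trainable-parameter count is

```
P_num = K_in * K_out * K_h * K_w + K_out .
```

The reference stack uses kernels 3x3 (1 to 64 maps), 3x3, 5x1, 5x1 (64 to 64),
giving 640, 36928, 20544, 20544 parameters per layer; three independent
per-axis stacks total 235,968 while the shared stack totals 78,656 — the
threefold reduction that motivates sharing. `count_conv_params()` reproduces
these totals and the x3 identity holds for arbitrary stacks (property-tested).
Dense-layer parameters are excluded from this accounting by convention: the
comparison concerns the convolutional layers, where sharing acts. Note the
counts are invariant to kernel orientation, so writing the late kernels `5x1`
(position axis) versus `1x5` (time axis) changes geometry but not accounting.

## Convolutional core and its verification

The forward pass of map `k` at output position `(i, j)` is the strided valid
cross-correlation

```
z[i,j,k] = sum_{k_in} sum_{u,v} a[u,v,k_in,k] * x[(i-1)h_s+u, (j-1)w_s+v, k_in] + b[k]
```

with output height `floor((h_in - K_h)/h_s) + 1` (internally 0-based,
implemented by patch unrolling and one matrix product). The activation is ReLU
with derivative 0 at the kink. Backpropagation follows the two standard
residual identities: the previous layer's delta is the full correlation of the
current deltas with the 180-degree-rotated kernels (the adjoint of the strided
forward map) times the activation derivative, and the weight gradient is

```
dL/da[u,v,k_in,k] = sum_{i,j} x[(i-1)h_s+u, (j-1)w_s+v, k_in] * delta[i,j,k] ,
```

with the bias gradient the per-map delta sum. Max pooling over disjoint tiles
is implemented with argmax recording for backward routing (first index on
ties) but is not part of the default stacks, which are all-convolutional; the
"unified" step after the four convolutions is the flatten.

Verification is two-route throughout: forward convolution and pooling are
checked against explicit nested-loop oracles on random geometries, and the
full analytic gradient (convolutional stores plus dense head) is checked
against central finite differences (`eps = 1e-6`) on batches of random small
networks, including the shared-stack summed gradient. Finite differences are
only valid where no ReLU kink is crossed between the two evaluations, so the
check suite redraws any network whose pre-activations pass within `10 * eps`
of zero; the relative-error denominator is floored (`1e-3`) so that near-zero
gradients are compared absolutely — otherwise the FD roundoff floor
(about `1e-10` here) would dominate their quotient.

## Geometry of the stacks

Valid convolution shrinks maps, so the reference stack (two 3x3 then two 5x1
kernels) needs input pictures at least 13 rows tall — fine for recordings with
many sensors, impossible for a 4-position picture, where the height is 2 after
the first 3x3 layer. Rather than pad (padding changes the formulas being
implemented), `compact_stack()` keeps the reference pattern at small heights:
layers 1–2 use `min(3, h) x 3` kernels, layers 3–4 use 5x1 when at least 5
rows remain and 1x5 (time-axis) otherwise. For `P = 4, T = 24` this gives
3x3, 2x3, 1x5, 1x5 and map sizes 2x22, 1x20, 1x16, 1x12. The reference stack
remains the accounting object; the compact stack is the runtime default for
the synthetic tasks.

## Training

Plain mini-batch SGD (no momentum — none is part of the reference procedure)
minimizes mean cross-entropy. Defaults: learning rate 0.01 (the reference
setting), batch size 32, He-scaled Gaussian initialization with zero biases
from a seeded generator. Training stops when the epoch budget is exhausted or
when the largest absolute parameter change over an epoch falls below a
threshold (default 0, i.e. budget-only). The default budget of 12 epochs is
where the synthetic task's loss has plateaued (mean loss below 0.1 from about
epoch 5); a non-finite loss aborts with the offending epoch named. Windows
are labeled by their final timestamp, the sliding step is
`round(window * (1 - overlap))` with a floor of 1, and the defaults are a
24-sample window at 50% overlap.

## The synthetic data generator

No recorded dataset ships with the package; the simulator generates
recordings with the structural features the models rely on, built on the
static accelerometer gravity model: a resting device reports `+/- g` on the
axis pointing away from the ground — `(g,0,0)` lying on its left side,
`(-g,0,0)` on its right, `(0,g,0)` upright, `(0,-g,0)` head down, `(0,0,g)`
screen up, `(0,0,-g)` screen down — so every pose has Euclidean norm `g`
(represented as 1.0; readings are in units of g).

A recording is a concatenation of labeled activity segments. Within a
segment, position `p`, axis `a` reads

```
gravity_a(pose_p) + A * [ kappa * shared_a(t) + (1-kappa) * private_pa(t) ] + noise
```

where `shared_a` is one sinusoid per axis (axis-specific incommensurate
frequency multipliers 1, 1.31, 1.73 keep different axes uncorrelated),
`private_pa` has the same frequency but a random phase per position, and the
noise is Gaussian. The coupling `kappa` directly encodes the same-axis
cross-position dependence: at `kappa = 1` with no noise, same-axis channels
are perfectly correlated; at the default `kappa = 0.8` the same-axis mean
`|r|` (about 0.56 on the default task) clearly exceeds the cross-axis mean
(about 0.14) — the premise behind axis-wise pictures holds by construction.
Scalar channels are smoothed Gaussian random walks, deliberately
class-uninformative.

The default task emulates the scale of multi-position benchmark recordings:
`P = 4` positions, five oscillatory activities plus a NULL class with distinct
frequencies (0.05–0.27 cycles/sample), amplitudes 0.45–0.9 g, pose signatures
per activity, noise 0.08 g, and an imbalanced label share (25% NULL down to a
6% rare class) split into interleaved segments of roughly 600 samples. A
24,000-sample recording yields about 2,000 windows at the default window
settings. These defaults were fixed once as a plausible mid-difficulty
regime: the noise-free task is separable by nearest centroids (so failures
indicate model defects, not an impossible task), while the default noise and
private-phase components leave headroom below a perfect score.

What the simulator does **not** model: biomechanical limb kinematics,
gyroscope/magnetometer physics, sensor drift or dropout, sampling-rate
conversion, and between-subject variability. Passing tests on this data show
the pipeline learns the spatial/temporal structure it targets; they do not
certify benchmark accuracy on recorded datasets.

## Evaluation

`weighted_f1()` scores a confusion matrix as `sum_i w_i * 2 P_i R_i /
(P_i + R_i)` with `w_i` the class's share of true samples (a uniform-weight
switch exists), `P_i` column precision, `R_i` row recall, and a 0/0 class
contributing 0 rather than erroring. The NULL class is included by default;
an `exclude` argument renormalizes the weights over the remaining classes.
Worked example: the 2-class matrix `[[5,5],[0,10]]` gives per-class F1
(2/3, 4/5) and weighted F1 `11/15 = 0.7333...`. Accuracy is trace over total.

## Splits, normalization, reproducibility

Train/test splitting is by contiguous time blocks (70/30), not shuffled
windows: 50%-overlapping windows share half their samples, so a shuffled
split would leak. Channels are z-scored (population SD; constant channels map
to zero) with statistics from the training block only, applied to both
blocks before windowing — raw g-units with pose-dependent gravity offsets
would otherwise dominate early learning. At small recording lengths (a
handful of segments per class) held-out scores degrade sharply — each class
is then seen under too few random phases to generalize — which is why the
default recording length matters for the end-to-end result.

All randomness (simulation, initialization, epoch shuffling) is seeded;
identical seeds give bit-identical recordings, weights and training
trajectories, and checkpoints reload to bit-identical forward outputs. Runs
write their resolved config (YAML) and a manifest (JSON, with class counts
and the config file's MD5) next to their outputs.

## Design choices on open points

* **Activation and loss.** ReLU and categorical cross-entropy; the reference
  formulation leaves both abstract, and these are the field-standard choices
  that keep the backward formulas exactly as implemented.
* **Window label rule.** The label at the last timestamp, as specified for
  the reference procedure; no majority voting, NULL kept as-is.
* **Boundary handling in the backward pass.** Full-correlation boundary for
  the rotated-kernel convolution — the choice under which finite differences
  agree, which is the arbiter used here.
* **Shared scalar branch.** Not shared with the axis stacks in `"MS"`: the
  scalar picture's height differs, so one parameter set cannot serve both
  geometries.
* **Sharing gradient = sum.** The literal chain rule; see above.
* **Window-48 variant.** Supported by `run_config(window = 48)`; 24 is the
  default.
* **Problem sizes in tests.** The gradient suite uses 4x12 two-layer
  networks (about 200–300 parameters each, 20 networks); the end-to-end
  check trains the shared variant with 8 maps on roughly 1,400 training /
  600 held-out windows. These sizes make the full two-route verification
  cheap enough to run on every test invocation.

## Limitations

The from-scratch core is pure R and single-threaded: it trains thousands of
small windows in minutes but is not a platform for 64-map stacks on long
recordings. There is no padding, dilation, batch normalization, dropout or
momentum, by design — the package implements and verifies the reference
formulas, not a general deep-learning framework. Scores on synthetic tasks
should be read as verification of the method's mechanics, not as benchmark
claims.
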