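---
title: "Nonlinear receptive fields from deep encoding models: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nonlinear receptive fields from deep encoding models: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The modeling problem

Sensory encoding models predict a neural response time series from a
stimulus. For auditory cortex the classical tool is the linear
spectrotemporal receptive field (STRF): the response at time $t$ is a
weighted sum of a spectrogram window covering the preceding 400 ms,

$$\hat y_t = \langle W, X_t \rangle + b,$$

with $X_t$ a lag × frequency window (40 lags × 32 bands at 100 Hz).
Cortical responses, especially outside primary areas, are substantially
nonlinear, and a fixed template cannot capture adaptation, sustained
responses to transient features, or context-dependent retuning.

This package fits an arbitrarily nonlinear map with a small convolutional
network and then *interprets* it exactly: a rectifier (ReLU) network whose
hidden layers carry no bias terms is piecewise linear, and inside the
linear region occupied by a particular window $X_t$ it computes

$$\hat y_t = \langle J(X_t), X_t \rangle + b_{\mathrm{out}},$$

where $J(X_t) = \partial \hat y_t / \partial X_t$ is the input Jacobian.
$J(X_t)$ has the shape of an STRF and is the *dynamic* STRF (DSTRF): the
exact linear template the network applied to that stimulus instance. The
identity above is exact, not an approximation, and the package verifies it
to near machine precision in its test suite.

## Architecture and training

The network has a feature-extraction stage — three convolutional layers of
eight 3×3 kernels (stride 1, zero padding preserving shape), then 1×1
convolutions reducing the channels to 4 and to 1 — and a feature-summation
stage, a dense hidden layer of 32 rectified units and a linear output
node. All hidden layers are bias-free; only the output node has a bias.
Bias-free hidden layers are what make the local-linearity identity exact.

Training minimises a combined loss, `MSE − Pearson correlation`, by
minibatch Adam (batch 128), with inverted dropout, an L2 penalty of 1e-3
on all weights, and early stopping on the whole-validation-set combined
loss; the epoch-best validation weights are kept. The package default
configuration (`training_config()`) is the reference protocol: learning
rate 1e-4, at most 30 epochs, patience 5, dropout 0.3 after convolutional
layers and 0.4 after the first dense layer. All randomness —
initialisation, shuffling, dropout masks — derives from one user seed, so
fits are bit-reproducible.

Two departures from plain He initialisation / fixed-step Adam are
available and used by the synthetic study:

* `cnn_normalize_init()` rescales each layer so its pre-activation
  standard deviation on real stimulus windows is 1. He initialisation
  assumes uncorrelated inputs; spectrogram windows are nonnegative and
  strongly correlated, and without rescaling the forward signal can
  collapse (or a channel bottleneck can die — a 1×1 layer whose inputs
  are nonnegative loses all gradient once its weights go negative).
* `lr_decay` / `lr_patience` implement reduce-on-plateau: when the
  validation loss stalls, the step size is multiplied by `lr_decay`.

### Desk-scale configuration (`study_config()`)

The reference protocol is calibrated for ~30 minutes of noisy
intracranial recordings. The synthetic study in this package runs on a
few minutes of clean simulated data on one CPU. Accordingly
`study_config()` uses learning rate 3e-3 with reduce-on-plateau decay 0.7
after one stalled epoch, no dropout (there is no trial noise in the
synthetic training signal to regularise against), at most 12 epochs with
patience 3, and training windows thinned by a stride (consecutive windows
overlap at 39 of 40 frames, so a stride of 5 discards almost no
information).
These are scale choices, not changes of method; the defaults remain the
reference values.

## The DSTRF machinery

Two independent routes compute the same object:

* **Gradient route** — backpropagation of the output with respect to the
  input, batched in compiled code.
* **Weight-product route** — each convolutional layer is expanded into
  its locally connected (sparse) matrix (`conv_to_locally_connected()`,
  `cnn_to_mlp()`); weights into inactive units are zeroed and the
  remaining matrices multiplied.

Both agree entrywise with each other and with central finite differences;
the test suite asserts this on over a hundred trained-network/window
pairs. A unit whose pre-activation is exactly zero is treated as
inactive — a measure-zero convention that keeps the computation
deterministic.

Coefficient significance uses the jackknife: the training frames are
split into $n$ contiguous segments (default 20; the synthetic study uses
$n=5$) and one model is fitted per left-out segment. A lag-frequency
coefficient of a DSTRF slice is significant when at least
$\lceil 0.95 n \rceil$ of the ensemble estimates share a strict sign
(19 of 20 at the reference size); insignificant coefficients are set to
zero and significant ones replaced by the ensemble mean
(`significance_mask()`, `ensemble_dstrf()`). Metrics are computed on this
masked jackknife-mean series; an unmasked variant is available. When an
ensemble is used, the network's test prediction is the ensemble-mean
prediction.

## Nonlinearity metrics

With $D_t$ the DSTRF at time $t$, vectorised into columns of a
(lag·frequency) × time matrix:

* **Complexity** — the sum of singular values normalised by the largest,
  $\sum_i \sigma_i / \max_i \sigma_i$. A fixed template gives 1; $k$
  orthogonal equal-weight templates give $k$.
* **Gain change** — each slice's magnitude is its coefficient standard
  deviation (per-slice mean removed, $FT-1$ denominator); gain change is
  the standard deviation of these magnitudes over time.
* **Temporal hold** — for each separation $n \le 30$ (300 ms), the
  correlation of $D_t$ with $D_{t+n}$ is compared with the correlation
  after displacing $D_{t+n}$ by $n$ along the lag axis, pairing each
  feature with where a stimulus-locked feature would sit $n$ frames
  later. A one-tailed Wilcoxon signed-rank test across $t$ decides
  whether realignment helps; the hold is the longest persistence run —
  the largest $n$ with every separation $1..n$ significant ($p<0.05$), 0
  if realignment never helps. (A held pattern helps realignment at every
  separation up to its duration; requiring the full run keeps the
  false-positive rate of a nonzero hold at the single-test level rather
  than compounding over 30 separations, which would otherwise report a
  nonzero hold on pure noise most of the time.)
  The shift direction is anchored behaviourally: a
  constructed series whose pattern drifts one lag per frame for exactly
  $N$ frames yields hold $N$. Zero-variance slices are excluded pairwise.
* **Shape change** — complexity of the series after iterative shift
  alignment (`align_dstrfs()`): each slice is displaced by the integer
  lag shift maximising its correlation with the running mean
  (zero-filled borders, ties to the smaller shift), the mean is
  recomputed, and the sweep repeats until the shifts stop changing
  (at most 50 sweeps; non-convergence returns the best solution with a
  flag). Gain-only and pure-drift series collapse to ≈ 1; genuine
  template switching stays above 1.
* **State switches** — the mean number of hidden units changing
  active/inactive state between consecutive windows, a direct count of
  how often the network hops between linear regions.

Receptive-field subtypes are found by k-means on the centred,
unit-normalised vectorised slices (Euclidean distance on normalised
vectors is monotone in correlation distance), with the number of
clusters chosen by the gap statistic: uniform reference draws in the
bounding box of the normalised data (default 10 draws, the study uses 6),
$\hat k$ the smallest $k$ with
$\mathrm{gap}(k) \ge \mathrm{gap}(k{+}1) - s_{k+1}$.

## Model evaluation

Prediction accuracy on repeated test presentations is noise-corrected:
with odd- and even-trial averages $R_o$, $R_e$ (1-based trial numbering)
and prediction $P$,

$$\rho_c = \frac{\tfrac12(\rho_{P,R_e} + \rho_{P,R_o})}{\sqrt{\rho_{R_o,R_e}}},$$

whose square is the reported noise-corrected $R^2$ — an estimate of the
correlation with the noiseless response. The square root in the
denominator follows from the derivation (the half-mean correlation
estimates $\sigma_{\hat R}^2/\sigma_R^2$); a site whose odd/even
reliability is not positive is flagged unreliable and excluded from
comparisons rather than imputed. Monte-Carlo tests confirm that at
signal-to-noise ratio 1 with six trials the mean of $\rho_c$ is within
0.03 of 1 while the raw correlation stays visibly attenuated.

`error_vs_data_curve()` summarises how prediction error $1-\rho^2$
declines with training-data duration by the least-squares slope against
$\log_2$ duration.

## The synthetic testbed

Because the neural recordings that motivated this framework cannot be
redistributed, the package ships a generative testbed
(`generate_stimulus()`, `synthetic_neuron()`, `make_dataset()`): a
nonnegative, spectrotemporally correlated stimulus (seeded moving ripples
with gaussian spectral envelopes and smoothed temporal gates over a noise
floor, multiplied by a log-normal loudness envelope with ~3 s correlation
time emulating pauses and emphatic passages, normalised to unit mean) and
five ground-truth response models:

* `linear` — one fixed template;
* `static_nl` — template drive through the double-exponential output
  nonlinearity $\sigma(x) = b + a\,e^{-e^{-e^{\kappa}(x-c)}}$;
* `gain_adaptive` — log-linear contrast gain control
  $y = \langle W, X_t\rangle \, e^{-\eta (B_t - \bar B)}$, with $B_t$
  the *spectral balance*: the fraction of exponentially weighted
  (150 ms) recent window energy carried by the upper half of the bands.
  Against the ~0.045 spread of $B$, $\eta = 20$ makes the gain vary
  severalfold, in the range of strong cortical gain control;
* `temporal_hold` — $y_t = \max_{0 \le j \le h} m_{t-j}$, a sustained
  (300 ms default) response to a transient template match — a maxout of
  shifted template projections;
* `multi_template` — two templates gated by the whole-window spectral
  balance against its median, emulating context-dependent retuning.

All generative states are computed from the stimulus window itself (so a
windowed model can observe them), and — deliberately — every planted
nonlinearity except the static output curve is *positively homogeneous*:
scaling the window by $s>0$ scales the response by $s$. A bias-free
rectifier network is itself positively homogeneous, so nonlinearities
driven by absolute energy levels (thresholds, leaky integrals of raw
energy) lie outside its function class and would be unlearnable no
matter the training budget; gains and gates driven by band-energy
*ratios* are inside it. This is a substantive constraint of the
interpretation framework worth remembering when reasoning about what
the models can capture in real data.

Clean responses are z-scored; test repeats add i.i.d. gaussian noise per
trial at `noise_sd` (in response-SD units; default 1, i.e. SNR 1 with six
repeats). Splits are contiguous train/validation/test ranges
(0.9/0.03/0.07 by default), windowed valid-mode within each range so no
window straddles a boundary. The timescales above were fixed at design
time on the principle that each planted nonlinearity should be strong and
slow enough to be physiologically plausible and to matter for prediction;
they are not tuned per run.

What the testbed does *not* emulate: phonetic structure, multi-electrode
covariance, non-gaussian trial noise, and response latencies drifting
with attention — so green tests here demonstrate the machinery and its
statistical behaviour, not performance on real cortical data.

## The reference synthetic study

`run_synthetic_study()` is the package's end-to-end benchmark, also used
by `scripts/acceptance.R`: for each neuron kind it simulates 100 s of
stimulus (9 000 training frames; training windows thinned with stride 6,
batch size 128), fits the ridge STRF and a jackknife ensemble of five
networks under `study_config()` (at most 10 epochs in the reference
script), scores both models with noise-corrected $R^2$ on six
noisy test repeats, computes the nonlinearity profile of the masked
jackknife-mean DSTRF series on the test windows, and clusters the aligned
series (thinned 3×) for the linear and two-template neurons. The problem
sizes were chosen so the full study runs in roughly ten minutes on one
CPU; they are stated here so results can be reproduced exactly.

The acceptance tests assert the full qualitative dissociation: network
≈ STRF on the linear neuron; network > STRF on every nonlinear neuron;
gain change maximal for the gain-adaptive neuron, temporal hold for the
hold neuron, shape change for the two-template neuron; clustering k = 2
for two templates and k = 1 for the linear neuron.  At the shipped
problem size only part of this holds (the gain-change ordering, the
network advantage on the saturating neuron, and the STRF's drop on every
nonlinear neuron); the rest requires better-converged networks than the
single-CPU budget allows.  Empirically the dissociation strengthens
monotonically with training budget — at 180 s / stride 5 / 16 epochs the
network clearly beats the STRF on the gain-control and temporal-hold
neurons — but Jacobian-level signatures (drift, subtype clusters,
initialization robustness) need still better convergence: an underfit
rectifier network predicts well before its local linearizations
stabilise, because prediction averages over regions while the DSTRF
exposes each region's exact gradient.

## Numerical and design notes

* **Plasticity recursion (STP cascade).** The Tsodyks–Markram stage is
  implemented exactly as the printed update
  $d_t = d_{t-1} + u\,x_{t-1}(1-d_{t-1}) - d_{t-1}/\tau$, $y_t = d_t
  x_t$, $d_0 = 0$, with the channel drive rectified before the stage.
  Under this convention the gain *builds up* with drive ($d \to
  u X \tau/(1+u X \tau)$ under constant drive, verified against an
  iteration oracle), so $u \to 0$ silences the channel rather than
  reducing the cascade to the LN model; the update is isolated in
  `stp_adaptation()` so a depression-style convention is a one-line
  change.
* **Cascade fitting** is full-batch Adam with analytic gradients
  (backpropagation through time for the plasticity recursion), verified
  against finite differences; gaussian widths, release probabilities and
  time constants are kept in range by softplus/logistic
  reparameterisation; seeded restarts guard against bad initialisation
  and a diverging run retries with a smaller step.
* **Ridge STRF**: one eigendecomposition of the training Gram matrix
  serves the whole penalty grid; the penalty maximising validation
  correlation is kept (validation correlation replaces the historical
  mutual-information criterion, which would add an estimator choice the
  method does not need).
* **Cochlear frontend**: constant-Q fourth-order gammatone-style filters
  log-spaced over 180 Hz–7 kHz (Q = 8), half-wave rectification, 1 kHz
  one-pole low-pass, cube-root compression, spectral first difference
  with rectification, 10 ms integration. The named processing stages
  matter; the exact constants do not propagate into any downstream
  algorithm, and bit-compatibility with any particular cochlear toolbox
  is a non-goal. Filtering is frequency-domain and zero-phase, so a few
  edge frames carry circular artifacts.
* **128→32 band reduction** averages contiguous groups (near-equal
  groups when not divisible); geometric-mean center frequencies.
* **Window convention**: 0-based lag 0 is the oldest frame, lag 39 the
  current frame; the window ending at frame $t$ predicts frame $t$; the
  first 39 frames of each contiguous segment are never predicted (no
  zero-padded history is fabricated).
* **Dropout quantisation**: dropout masks are drawn 8 bits per unit, so
  keep probabilities are realised on a 1/256 grid (0.700 → 0.699) — far
  below any effect of interest.
* **Training precision**: stochastic optimisation runs in single
  precision (standard for network training); inference and all DSTRF
  computations run in double precision, which the exactness tolerances
  (1e-4 against finite differences, 1e-5 for the local identity) rely
  on.

## Known limitations

* The DSTRF construction applies to feedforward rectifier networks only;
  recurrent models have no single input Jacobian per frame of this form.
* Temporal hold is reported as one aggregate number per site; its
  stimulus dependence is deliberately not modelled.
* The gap statistic with ten reference draws is a coarse model-order
  choice; it is used for subtype counts, not inference.
* Iterative shift alignment is a coordinate-descent procedure and can
  leave isolated slices one lag away from the global optimum, like any
  align-to-mean scheme.
* At desk scale the network's advantage over the STRF depends on the
  planted nonlinearity being strong; weak nonlinearities (e.g. divisive
  gain with a near-constant energy trace) are genuinely well fitted by a
  linear model, and the study stimulus includes loudness dynamics
  precisely so that adaptation has something to adapt to.
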