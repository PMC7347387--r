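# dstrf — nonlinear sensory receptive fields from deep encoding models

`dstrf` fits encoding models that predict a neural response time series
from an auditory spectrogram, and *interprets* the nonlinear one exactly.
It is written for auditory/computational neuroscientists who want more
than a linear spectrotemporal receptive field (STRF) without giving up
the STRF's interpretability.

The core idea: fit a small convolutional network whose hidden rectifier
layers carry **no bias terms**. Such a network is piecewise linear, and at
every stimulus window `X_t` it applies an exact linear template

    y_hat(t)  =  < J(X_t), X_t >  +  b_out,

where `J(X_t)` — the input Jacobian, shaped lag × frequency like an STRF —
is the **dynamic STRF (DSTRF)** at time `t`. The package extracts DSTRF
series (two independent routes: backpropagation and masked weight-matrix
products over a locally connected expansion, agreeing to machine
precision), attaches jackknife sign-agreement significance masks, and
summarises the series with four nonlinearity metrics:

* **complexity** — sum of max-normalised singular values of the
  DSTRF-by-time matrix (1 = one fixed template);
* **gain change** — spread of the DSTRF magnitude over time
  (adaptation-like rescaling);
* **temporal hold** — how long a spectrotemporal pattern persists while
  its latency shifts to stay stimulus-locked (Wilcoxon signed-rank over
  shifted vs unshifted slice correlations);
* **shape change** — complexity after shift alignment (template
  switching).

Around the core it provides: ridge STRF fitting, linear–nonlinear (LN)
and Tsodyks–Markram short-term-plasticity (STP) cascade models fitted
with analytic gradients, noise-corrected evaluation on repeated trials
(`rho_c = (cor(P,Re)+cor(P,Ro)) / (2*sqrt(cor(Ro,Re)))`), receptive-field
subtype clustering by the gap statistic, a cochlear-style spectrogram
frontend for WAV audio, and a fully seeded synthetic testbed with five
ground-truth neuron types (linear, static nonlinearity, divisive gain
adaptation, temporal hold, template switching).

## Worked example

Run the synthetic dissociation study — five ground-truth neurons, ridge
STRF vs a jackknife ensemble of networks, noise-corrected scores and the
DSTRF nonlinearity profile per site (this is also what the acceptance
script does; ~10 min on one CPU at this scale):

```r
library(dstrf)
study <- run_synthetic_study(duration_s = 100, seed = 1, jackknife_n = 5,
                             train_stride = 6,
                             config = study_config(1, max_epochs = 10))
print(study$summary, digits = 3)
```

```
            kind rho_sq_lin rho_sq_cnn improvement complexity gain_change
1         linear      1.006      0.818     -0.1883       29.3    0.000756
2      static_nl      0.698      0.765      0.0671       34.4    0.000579
3  gain_adaptive      0.638      0.606     -0.0329       27.9    0.002118
4  temporal_hold      0.836      0.822     -0.0143       32.3    0.000130
5 multi_template      0.603      0.592     -0.0110       34.3    0.000180
  temporal_hold shape_change mean_switches clusters
1             0         29.3          2347        4
2             0         34.4          2223       NA
3             0         27.9          1624       NA
4             0         32.3          2123       NA
5             0         34.3           436        4
```

Reading the table: the ridge STRF scores a noise-corrected R² near 1 on
the linear neuron (linear data, clean training signal), and drops on
every nonlinear neuron (0.60–0.84 — the planted nonlinearities are
real).  The network out-predicts the STRF on the saturating neuron and
shows the gain-change signature most strongly for the gain-control
neuron (0.0021, 3–16× the other kinds).  At this desk scale — 100 s of
stimulus and ten training epochs per jackknife member, versus tens of
minutes of data in a full-scale application — the network ensemble
underfits, so it does not beat the STRF on every nonlinear kind, the
DSTRF series is dominated by Jacobian noise (complexity ~30 for every
site), and temporal-hold drift is not yet detectable.  The methods
vignette discusses exactly what scales with training budget here and
why.  With more compute, the same calls at
`duration_s = 180, train_stride = 5, max_epochs = 16` give the network a
clear advantage on the gain-control (+0.10 clean-signal R²) and
temporal-hold (+0.08) neurons.

`study$fits$<kind>$dstrf` holds the masked jackknife-mean DSTRF series
(one lag × frequency template per test frame); a slice can be drawn with
any image function, e.g. `image(matrix(series[100, ], 40, 32))`.

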