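---
title: "Coherence-based graph convolutional networks for motor-imagery EEG: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coherence-based graph convolutional networks for motor-imagery EEG: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the scientific model implemented by `cgcn`, the
assumptions behind it, the numerical choices made, and the limitations a
user should keep in mind. Code chunks are illustrative and not evaluated
when the vignette is built.

## Scientific problem

Imagining a movement of the left or the right hand desynchronises
sensorimotor rhythms — the mu rhythm (8–13 Hz) and the beta rhythm
(13–30 Hz) — over the contralateral motor cortex, and reorganises the
*functional coupling* between scalp sites. `cgcn` decodes the imagined
side from single EEG trials by (1) quantifying inter-electrode coupling
with band-limited magnitude-squared coherence, (2) treating the resulting
coherence matrix as a weighted graph over the 10–20 montage, and
(3) classifying trials with a spectral graph convolutional network defined
on that graph.

## Coherence estimation

For two channels $x$ and $y$ the magnitude-squared coherence at frequency
$f$ is

$$C_{xy}(f) = \frac{|P_{xy}(f)|^2}{P_{xx}(f)\,P_{yy}(f)} \in [0, 1],$$

where the auto- and cross-spectra are Welch estimates: the signal is cut
into 1 s segments with 50 % overlap, each segment is mean-detrended,
tapered with a periodic Hann window and Fourier transformed, and the
per-segment cross-periodograms are averaged. Density scaling uses
$1/(f_s \sum_t w_t^2)$ with one-sided doubling of all bins except DC and
Nyquist. Band-level connectivity is the unweighted mean of $C_{xy}(f)$
over the frequency-grid points inside a closed band, computed for every
channel pair by `coherence_matrix()`.

Numerical conventions:

* **Diagonal set to 0.** Self-coherence is trivially 1; the matrix is
  used as a graph adjacency without self-loops.
* **Dead channels.** Bins where either auto-spectrum is numerically zero
  get coherence 0 rather than 0/0.
* **Estimator bias.** With $L$ averaged segments the coherence of two
  independent signals has expectation of order $1/L$, not 0. With the 1 s
  window and a 4 s imagery segment ($L = 7$) this floor is roughly 0.14;
  comparisons between conditions therefore matter more than raw values.
* **At least two segments are required**; single-segment coherence is
  identically 1 and is rejected with an error.

## Preprocessing

Recordings are average-referenced (`rereference_average()`) and band-pass
filtered with a fifth-order Butterworth design applied forward and
backward (`bandpass()`), giving zero phase shift and a squared magnitude
response $|H(f)|^2$. Edge effects are controlled by odd-reflection
padding, and each filter pass starts from its steady state with respect
to the first sample, so constant inputs map exactly to their steady-state
output. Trials are cut around event markers into a 3 s rest and a 4 s
imagery segment (`segment_trials()`), and `split_rhythms()` produces the
mu, beta and combined mu+beta band copies used throughout.

## Graph machinery

Given the symmetric non-negative coherence matrix $A$ with zero diagonal
(degree matrix $D$), the package provides the combinatorial Laplacian
$L = D - A$ and the normalized Laplacian
$L_{norm} = I - D^{-1/2} A D^{-1/2}$, whose spectrum lies in $[0, 2]$.
An isolated node keeps a diagonal entry of 1 by convention. For the
convolutional layers the Laplacian is rescaled to
$\tilde L = 2L_{norm}/\lambda_{max} - I$ with spectrum in $[-1, 1]$.
$\lambda_{max}$ is computed by a dense symmetric eigensolver for graphs up
to 64 nodes (exact to machine precision, and cheap at EEG sizes) and by
power iteration beyond that.

A filter with coefficients $\theta \in \mathbb{R}^K$ acts on a node signal
$x$ as

$$y = \sum_{k=0}^{K-1} \theta_k \, T_k(\tilde L)\, x,$$

where $T_k$ are Chebyshev polynomials generated by the recursion
$T_0 = I$, $T_1 = \tilde L$, $T_k = 2\tilde L T_{k-1} - T_{k-2}$. This
equals filtering in the graph-Fourier (eigenvector) basis with the
polynomial evaluated at the eigenvalues, and is $(K-1)$-localized: the
output at a node depends only on its $(K-1)$-hop neighborhood. Both
properties are verified against independent oracles in the test suite.

## Network architecture and training

The classifier (`cgcn()`) is a two-layer Chebyshev graph convolutional
network:

* two convolution layers with $K = 3$ and 32 and 64 feature maps,
  each followed by ReLU and graph max pooling;
* pooling uses a greedy heavy-edge matching that halves the node count
  per level (21 → 11 → 6 for the standard montage); a node without an
  unmatched positive-weight neighbor survives as a singleton supernode
  whose features pass through unchanged;
* the pooled maps are flattened and fed through inverted dropout
  (rate 0.50) into a fully connected softmax layer.

The loss is the two-class cross-entropy summed over both class terms
(so a maximally uncertain prediction costs $2\ln 2$), averaged over the
batch, plus an L2 penalty $\lambda \sum \|w\|^2$ on convolution and FC
weights (biases excluded) with $\lambda = 0.001$. Defaults: 100 epochs,
batch size $\min(512, n_{train})$, Adam with learning rate 0.01 (plain
SGD available). Gradients are computed by hand-written backpropagation,
including the adjoint of the Chebyshev recursion, and are verified
against central finite differences to $10^{-5}$ relative error.

Node features (`build_features()`) are configurable because the mapping
from a trial to per-node inputs is the least standardized part of this
family of models:

* `"timeseries"` (default): the band-filtered imagery segment decimated
  to 200 samples per channel, per-channel standardized;
* `"psd"`: the standardized log Welch power spectrum over the band grid;
* `"coherence"`: each channel's row of the trial's own band-averaged
  coherence matrix, i.e. its connectivity profile. Per-channel features
  cannot express pairwise synchronization, which is exactly the quantity
  this model family is built around; this mode exposes it to the
  classifier directly and is what the packaged end-to-end analyses use.

All randomness (initialization, shuffling, dropout) derives from the
config seed, and training restores the caller's RNG state, so runs are
bit-reproducible.

## Evaluation

`cgcn_cv()` performs stratified 10-fold cross-validation. Fold
assignment is a pure function of the labels and the seed. The
connectivity graph fed to the network is recomputed inside each fold from
the *training* trials only, so no information from held-out trials leaks
into the model structure. Reported metrics are accuracy and macro-F1
(the unweighted mean of the per-class F1 scores; with balanced classes it
coincides with the usual F1 up to class symmetry), validated against an
independent reference implementation in the tests.

## Synthetic data generator

Because suitable clinical recordings cannot be redistributed, the package
ships a generator (`make_dataset()`) that emulates the *coupling
structure* the pipeline is designed to detect: 21-channel 10–20 trials of
3 s rest plus 4 s imagery at 250 Hz. All channels carry independent unit
white noise; during the imagery segment the three hub channels of the
trial's class (left: C4, T8, P4; right: C3, T7, P3) additionally share a
band-limited latent source, scaled so that `coupling_snr` is the in-band
source-to-noise power ratio.

For two channels sharing a source with power ratio $r(f)$, the coherence
is $r(f)^2 / (1 + r(f))^2$ — 0.25 at $r = 1$. The generator's
band-averaged ground truth (`ground_truth_msc()`) accounts for the
source-shaping filter roll-off near the band edges, where $r$ falls below
its nominal value. This closed form is what the acceptance checks
recover empirically.

What the generator deliberately does **not** emulate: 1/f background
spectra, volume conduction, eye/muscle artifacts, non-stationarity within
trials, per-subject electrode variability, or amplitude asymmetries
(per-channel feature standardization removes amplitude cues on purpose —
the decodable class signal is the coupling pattern, nothing else).

## Problem sizes and numerical choices in the packaged analyses

* Closed-form recovery uses a 48 s imagery segment (95 Welch segments) so
  the coherence estimate's bias ($\approx (1-C)^2/L$) and spread are small
  against the ±0.05 check, and evaluates over 11–25 Hz, the interior of
  the 8–30 Hz source band where the equal-power premise actually holds.
* The end-to-end decoding analysis uses 200 trials per class,
  `coupling_snr = 2`, `feature_type = "coherence"`, 40 epochs and
  10-fold cross-validation — about four minutes on one CPU. With
  `coupling_snr = 0` the identical pipeline stays at chance, which guards
  against information leaking through the pipeline itself.
* Welch defaults (1 s periodic Hann, 50 % overlap) trade frequency
  resolution (1 Hz) against segment count on 4 s trials.
* Eigendecompositions use the symmetric solver with a deterministic sign
  convention (largest-magnitude component positive) so decompositions are
  reproducible across runs.

## Limitations

* The classifier is a faithful but compact reimplementation in base R;
  it is practical at EEG scale (tens of nodes, hundreds of trials), not
  at image/mesh scale.
* Coherence is undirected and linear; directed or nonlinear coupling
  measures are out of scope.
* The synthetic benchmark demonstrates correctness of the machinery, not
  clinical performance; numbers obtained on it do not transfer to real
  recordings.
* Only two-class problems are supported end to end.
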