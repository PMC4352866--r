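---
title: "Self-information saliency from spiking V1 responses: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Self-information saliency from spiking V1 responses: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`v1saliency` implements a bottom-up visual attention model built on a
population of model V1 simple cells. The working hypothesis is statistical:
locations that attract attention are those whose local image content evokes
*rare* neuron responses. The pipeline has four stages.

**1. Receptive-field learning.** A single population of `K` leaky
integrate-and-fire neurons is trained on whitened image patches with purely
local plasticity (the SAILnet family of rules). Per patch presentation the
membrane potential of neuron $i$ evolves for $T$ steps as

$$u_i \leftarrow (1-\eta)\,u_i + \eta\Big(Q_i \cdot x - \sum_j W_{ij} s_j\Big),$$

spiking and resetting when $u_i > \theta_i$. The spike count $n_i$ is the
neuron's response. After each batch,

* lateral inhibition: $\Delta W_{ij} = \alpha (n_i n_j - p^2)$, clipped at
  $W \ge 0$ with zero diagonal (anti-Hebbian decorrelation),
* feedforward weights: $\Delta Q_i = \beta\, n_i (x - n_i Q_i)$ (an Oja-like
  rule whose fixed point makes $n_i Q_i$ the least-squares contribution of
  neuron $i$ to the patch),
* thresholds: $\Delta\theta_i = \gamma (n_i - p)$ (homeostasis driving each
  neuron's mean count to the target rate $p$).

These rules jointly shape the two quantities the model cares about: response
sparseness and the error between a patch and its reconstruction
$\hat x = g \sum_i n_i Q_i$ (with a single least-squares gain $g$ fitted
after training). On natural-statistics input the learned rows of $Q$ are
localized, oriented, Gabor-like filters.

**2. Colour decomposition.** An RGB image is expanded into 13 channels:
gray-scale plus the separated channels of RGB, CIELAB, HSI and YIQ
(`split_channels()`). The four spaces sample the three classical families of
colour representation (mixture, luminance/chrominance,
hue/saturation/intensity), so a target that pops out in any of them can be
found. The network is trained once, on gray-scale patches; each channel is
min-max rescaled to [0, 1] before encoding so that the same receptive
fields and whitener apply to every channel.

**3. Self-information saliency.** For each channel, the patch centred at
each pixel is encoded into a K-vector of spike counts $r_k(x,y)$. Treating
the dimensions as independent (lateral inhibition actively decorrelates
them), the saliency of a pixel is the summed self-information

$$S(x,y) = \sum_{k=1}^{K} -\log p_k\big(r_k(x,y)\big),$$

where $p_k$ is estimated per dimension from the *current image* — rarity is
defined relative to the scene being viewed. The default estimator is a
1000-bin equal-width histogram; a generalized Gaussian fit
(moment-matched; Laplacian at shape 1, Gaussian at shape 2) is available as
an alternative since response histograms are zero-peaked and heavy-tailed.

**4. Entropy selection and fusion.** Each of the 13 sub-maps is scored by
the Shannon entropy of its 256-level quantized histogram. A useful saliency
map concentrates mass in a small focus against a suppressed background, so
*low* entropy is good. The lowest-entropy sub-map is selected from each
colour space; the four winners plus the gray-scale map are min-max
normalised and combined with normalised reciprocal-entropy weights
$O_j = (1/E_j) / \sum_i (1/E_i)$.

## Parameters that matter

| parameter | default | meaning / rationale |
|---|---|---|
| `side` | 14 px | patch side; 196-dimensional stimuli |
| `K` | 128 | population size (≈ 0.65× overcomplete on 196 dims) |
| `n_steps` (T) | 50 | LIF steps per presentation |
| `eta` | 0.2 | leak/update rate; T·η ≈ 10 effective integration windows |
| `p` | 0.05·T = 2.5 | target spikes/patch/neuron (5% firing probability per step) |
| `alpha, beta, gamma` | 0.1, 0.01, 0.02 | learning rates for W, Q, θ; β is deliberately small because the Oja term scales with $n_i^2$ and large counts otherwise destabilise training (the fitter aborts if any \|Q\| exceeds 100) |
| `bins` | 1000 | response-histogram bins |
| `eps` | 1 | add-one smoothing per bin; bounds self-information, since $-\log 0$ is undefined |
| `m` | 256 | entropy quantisation levels — saliency maps are image-valued, so 8-bit levels are the natural choice |
| `stride` | 1 | response-grid stride; stride 2 quarters the work, and derived maps are bilinearly upsampled |

Natural logarithms are used throughout; the base cancels in the normalised
fusion weights and only rescales absolute S and E values.

## What the synthetic fixtures emulate — and what they do not

The package trains and tests itself entirely on generated data:

* **1/f images** (`make_pink_noise_images`): Gaussian noise with the
  amplitude spectrum of natural scenes. They reproduce the second-order
  (covariance) statistics that the whitening stage consumes, but *not* the
  higher-order sparse structure (edges, contours) of real photographs.
  Consequently a network trained on them shows the correct response
  *statistics* (zero-peaked, heavy-tailed counts; contrast-driven totals)
  but its receptive fields are not expected to converge to clean Gabors,
  and training cannot reduce reconstruction error below what a random
  frame achieves on such data — whitened Gaussian input has no preferred
  sparse basis. Claims about learning are therefore tested on the
  dictionary fixture below. A directory of real photographs can be
  substituted for full-fidelity receptive fields.
* **Sparse-dictionary patches** (`make_sparse_patch_set`): patches with a
  known ground-truth code — `s` Gabor atoms per patch, signed Laplacian
  coefficients, small Gaussian pixel noise. Here learning has a right
  answer, and the package tests that training recovers ≥ 80% of atoms at
  \|correlation\| > 0.8, that homeostasis hits the target rate, and that
  reconstruction error falls from its untrained baseline.
* **Pop-out scenes** (`make_popout_scene`): achromatic 1/f background
  texture plus one colour-shifted square target with an exact mask. The
  background texture is 1/f rather than white so that its spectrum matches
  the training ensemble; whitening amplifies spatial frequencies by the
  inverse of the *training* spectrum, and a white-noise background would be
  amplified into the dominant signal. These scenes exercise colour pop-out
  only — not orientation or motion pop-out, and not object-level saliency.

## Numerical and design choices

* **Colour constants.** The RGB→XYZ matrix uses sRGB primaries rescaled so
  white maps exactly to the D65 whitepoint (95.04, 100.00, 108.89); YIQ uses
  the NTSC matrix with luminance row (0.299, 0.587, 0.114); CIELAB uses the
  standard cube-root compression with linear segment below (6/29)³.
  Gray-scale is NTSC luminance, so the gray channel coincides with Y. RGB is
  *not* gamma-linearised before the XYZ matrix by default (the raw [0, 1]
  values enter the matrix); `linearize = TRUE` enables an sRGB decode.
* **Hue at S = 0** is undefined; it is set to 0 to keep histograms NaN-free.
* **Whitening** is symmetric (ZCA) with a relative eigenvalue floor
  (1e-10 of the largest eigenvalue). For data confined to a low-dimensional
  subspace plus tiny noise — the dictionary fixture — exact whitening would
  amplify the noise floor to unit variance; `var_retain = 0.999` projects
  out the trailing variance instead, and the dictionary experiments use it.
* **Target rate per experiment.** The default `p = 2.5` matches a 5%
  per-step firing probability. For dictionary recovery the target is set so
  that the `s = 3` truly active atoms among `K = 128` neurons can absorb the
  code without saturating the 50-step counter: `p = 0.3` ≈ s·(T/3)/K.
  Forcing 2.5 spikes from every neuron on 3-atom stimuli produces a dense,
  nonselective code.
* **Degenerate rules**, all deterministic: a constant channel normalises to
  zeros; a degenerate response dimension has probability 1 (zero
  self-information); a constant saliency map has entropy 0; a zero-entropy
  winner takes the whole fusion weight (shared uniformly if several);
  entropy-selection ties go to the first channel in the frozen order
  `gray, R, G, B, L, A, B*, H, S, I, Y, I*, Q`.
* **ROC ties**: thresholds are the unique saliency values with a `>=` call,
  so tied pixels switch together; AUC then equals the pairwise
  Mann–Whitney statistic with half-credit for ties (tested against brute
  force).
* **Per-pixel responses** use the patch *centred* at the pixel, stride 1,
  reflect padding; neither the stride nor the assignment rule is dictated
  by the model, and centred stride-1 is the symmetric choice. At stride
  > 1 the fused map is computed on the grid and bilinearly upsampled.
* **Histogram scope**: probability models are fitted per image and per
  channel — the current scene defines rarity. A cross-image reference model
  can be passed explicitly to `self_information_map()`.

## Problem sizes used by the shipped experiments

The test-suite and acceptance experiments train on 20,000 patches
(12 epochs for the 128-neuron natural-statistics network, 30 epochs for
dictionary recovery) and evaluate pop-out on twenty 96×96 scenes at
stride 2. These sizes give stable statistics on a single CPU in a few
minutes; the 1000-patch setting reported for strict replication of the
original configuration, and larger ensembles (the 50,000-patch default of
`train_v1_network()`), are available through the same interfaces.

## Known limitations

* Bottom-up only: no target priors, no centre bias, no objectness — the
  Bayesian decomposition's prior-knowledge and location terms are dropped
  deliberately.
* The spike code is non-negative; representing signed structure requires
  neuron pairs of opposite polarity, which is why dictionary experiments
  train 2× as many neurons as atoms.
* Entropy selection assumes a compact salient region; on images whose
  correct saliency map is genuinely diffuse, the lowest-entropy channel can
  be the least informative one.
* JPEG input is not read natively (PNG/TIFF only); convert beforehand.
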