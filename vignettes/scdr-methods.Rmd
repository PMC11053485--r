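---
title: "Supervised contrastive deep regression for biomass prediction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Supervised contrastive deep regression for biomass prediction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Above-ground biomass (AGB) — the fresh mass of vegetation per plot or
per square metre — is a continuous crop trait usually measured
destructively. Regressing AGB directly from RGB canopy images replaces
harvesting with photography, but plain deep regression ignores the
structure that continuous labels impose on a batch: two plots with
nearly equal biomass should map to nearby points in feature space, and
plots with very different biomass that the model currently *confuses*
(similar predictions) are precisely the pairs worth pushing apart.
`scdr` implements a supervised contrastive loss built on that idea
(SCDR) together with a purpose-built convolutional/mixer backbone
(BioUMixer) that produces, per image, an embedding $v$ for the
contrastive term and a scalar prediction $\hat y$.

## The SCDR loss

Each of the $N$ images in a batch is augmented twice (random crop,
horizontal/vertical flip, colour-contrast jitter, per-channel
standardization), giving $2N$ views that inherit their source's label
unchanged. For views $i \ne j$ with labels $\tilde y$ and predictions
$\hat y$, a pair is

* **positive** if $|\tilde y_i - \tilde y_j| \le \omega$,
* **negative** if $|\tilde y_i - \tilde y_j| > \omega$ and
  $|\hat y_i - \hat y_j| \le \omega$,
* **unpaired** otherwise.

A view with at least one negative partner is an *anchor*. For anchor
$j$ with positive set $P_j^+$ and negative set $P_j^-$,

$$
L^{j} \;=\; -\log
\frac{\tfrac{1}{N_j^+}\sum_{i \in P_j^+} e^{v_j \cdot v_i/\tau}}
     {\sum_{p \in P_j^+} e^{v_j \cdot v_p/\tau}
      \;+\; \sum_{q \in P_j^-} S_{j,q}\, e^{v_j \cdot v_q/\tau}},
$$

non-anchors contribute exactly $0$, and the batch loss is the mean of
$L^j$ over all $2N$ views. The total training objective is
$L_{\mathrm{sum}} = \alpha L_{\mathrm{reg}} + \beta L_{\mathrm{scdr}}$
with a focal-L1 regression term by default. The $1/N_j^+$ factor sits
*inside* the logarithm (a single log of the positive-average ratio);
the averaged-log alternative exists in the contrastive literature but
is not what this loss specifies, so we implement the printed form and
note the alternative here for sensitivity analysis.

### Thrust on negative pairs

The multiplier $S_{j,q}$ ("thrust") controls how strongly a negative
pair is pushed apart. It must grow with the weight coefficient $\eta$
and shrink when the pair's labels or features are already similar —
that is what damps the effect of mislabelled pairs. The functional
forms of the two similarities and of the combination rule are design
choices of this package (the requirement fixes only the
proportionalities):

$$
S_{j,q} = \min\!\Big(\frac{\eta}{\mathrm{Sim}_l \cdot \mathrm{Sim}_f},\; S_{\max}\Big),
\qquad
\mathrm{Sim}_l = e^{-|\tilde y_j - \tilde y_q|/\sigma_l},
\qquad
\mathrm{Sim}_f = \max\!\Big(\frac{1 + \cos(v_j, v_q)}{2},\; \varepsilon_f\Big).
$$

$S_{\max}$ (default 100) caps the blow-up as both similarities approach
their floors; $\varepsilon_f$ (default 0.05) keeps $\mathrm{Sim}_f$
positive at anti-parallel embeddings. $\eta$ is a single global scalar
(default 0.01), not a per-anchor quantity.

When differentiating the loss, $S_{j,q}$ and the pair assignment are
treated as constants (stop-gradient): gradients flow only through the
dot-product logits. This mirrors standard practice for sample-pair
weighting in contrastive regression — the weights steer the geometry
but are not themselves optimization targets — and it keeps the
per-batch gradient a closed-form expression that the test suite checks
against finite differences.

### Parameters, units, defaults

| parameter | meaning | unit | default |
|---|---|---|---|
| $\omega$ | pairing threshold | label units | 10% of training-label SD |
| $\tau$ | softmax temperature | — | 0.2 |
| $\eta$ | thrust coefficient | — | 0.01 |
| $\alpha, \beta$ | loss weights | — | 1, 3 |
| $\sigma_l$ | label-kernel scale | label units | 25% of training-label SD |
| $\varepsilon_f$ | feature-similarity floor | — | 0.05 |
| $S_{\max}$ | thrust ceiling | — | 100 |

$\tau$, $\eta$, $\alpha$, $\beta$ follow the ablation optima of the
method this package implements. $\omega$ and $\sigma_l$ have no stated
values anywhere, so they default to fractions of the training-label
standard deviation — scale-free choices that make the pairing rules
behave identically across datasets measured in different units; both
are resolved once at run start and frozen. Embeddings are
L2-normalized before dot products (`normalize_embeddings = TRUE`):
bounded logits keep $e^{v\cdot v/\tau}$ stable at $\tau = 0.2$.
Degenerate batches ($N = 1$) are legal — the two sibling views form one
positive pair, there are no negatives, and the loss is exactly 0.

## The BioUMixer backbone

Images enter through a non-overlapping patch embedding (default 4 px
patches) and pass through three stages of width 32/64/128 (the `tiny`
preset; `standard` uses 224 px inputs). Each stage holds, per block
pair:

* a **FeatureBlock** (ConvNeXt lineage): depthwise 3×3 conv →
  BatchNorm → pointwise expansion ×4 → GELU → global response
  normalization (GRN) → pointwise reduction → DropPath → residual add;
* a **BioBlock** (sandwich layout): pointwise FFN (ReLU) → depthwise
  3×3 token mixer with SimAM attention → pointwise FFN, every sub-layer
  residual.

Stage transitions apply SimAM and a strided 2×2 convolution that halves
the resolution and doubles the width. The **U-like hierarchical
residual** pairs same-kind block groups across the depth: the stage-1
FeatureBlock output is average-pooled, projected 1×1 and added before
the stage-3 FeatureBlock, and likewise for the BioBlocks (with three
stages the middle stage has no partner). Fusion is additive rather than
concatenating so that the ablation toggles compare networks of similar
width. The head flattens the final map into tokens, applies one
token-mixing + channel-mixing MixerBlock, global-averages, projects to
the embedding $v$ (default 128-d), and a small MLP maps $v$ to the
scalar prediction.

**SimAM** weights every position of every channel by
$\mathrm{sigmoid}(E)$ with energy
$E = (x-\mu)^2 / (4(\hat\sigma^2 + \lambda)) + 0.5$, where $\mu$ and
$\hat\sigma^2$ (the $n-1$ corrected spatial variance) are per-channel
statistics; $\lambda$ defaults to $10^{-4}$. A spatially constant
channel is scaled by $\mathrm{sigmoid}(0.5)$ exactly, and all weights
approach that value as $\lambda \to \infty$ — both closed forms are
asserted in the tests. **GRN** divides each channel's response by its
global L2 norm relative to the mean over channels, with a
zero-initialized affine and an identity residual, so it starts as the
identity.

Exact depths, widths, patch size, head sizes, and the sub-layer order
inside the blocks are not fixed by the method description, which is
schematic on these points; the orders above are the canonical ones for
their block families (ConvNeXt for the FeatureBlock, the
sandwich-layout family for the BioBlock), the "attention" at stage
transitions is implemented as SimAM, and every count lives in
`bioumixer_config()` so none of these choices is hard-wired.

## Training protocol

Adam with cosine-annealed learning rate (default $10^{-3}$ down to
$10^{-5}$; the rate itself is a package default, as no value is
specified by the method), default 80 epochs, batch size 16 (32 views).
Labels are z-scored on the training set; predictions are mapped back to
grams for every reported metric. 20% of the training pool is held out
and the parameters with the best validation MAE are kept. Runs are
bit-reproducible from a single seed, which drives initialization,
shuffling, augmentation and DropPath through derived sub-streams.
Metrics are RMSE, MAE and MAPE (reported as a fraction, with the mean
over the $n$ evaluated samples; MAPE is flagged undefined when a label
is 0).

### The neural-network core

No deep-learning framework is used: forward passes, analytic
backpropagation, Adam and the schedule are implemented in vectorized R,
with the depthwise 3×3 convolution — the one loop-bound kernel — in
compiled C++ (checked against a pure-R reference). Every layer's
backward pass and the whole-model parameter gradients are verified
against central finite differences in the test suite. GELU uses the
sigmoid approximation $x\,\sigma(1.702x)$, indistinguishable from the
exact form at network precision and substantially cheaper.

## The synthetic scene generator

`render_scene()` emulates the structure of plot-level biomass datasets:
green foliage blobs (thresholded superpositions of Gaussian bumps, so
plants merge and occlude) over textured brown soil, red fruit ellipses
drawn on top of foliage, and a label
`a_veg * visible foliage pixels + a_fruit * fruit pixels + N(0, noise_sigma)`
floored at `label_floor`. Coverage is drawn from a rescaled
Beta(1.3, 2.6), producing a continuous, right-skewed label distribution
— the imbalanced-regression regime the contrastive loss targets.
Defaults put labels in roughly 400–4000 g, the plot-scale regime
implied by pepper-crop biomass work (MAE ≈ 200 g at MAPE ≈ 0.11
corresponds to labels of order 2000 g).

What the generator does *not* emulate: perspective and lens geometry,
illumination variation, leaf texture, species mixtures, and label noise
correlated with appearance. Passing desk-scale tests therefore shows
that the implementation learns a monotone pixel-to-biomass signal under
occlusion and label noise — not that it reaches field-grade accuracy on
real imagery, which requires the full-size preset, real data and far
longer training.

## Desk-scale evaluation sizes

The test suite and the acceptance script run the complete protocol at
sizes chosen for a single CPU: 250 synthetic 64×64 scenes (200 train /
50 test), the `tiny` preset (~0.5 M parameters), 10 epochs, three seeds
for each of the SCDR ($\beta = 3$) and baseline ($\beta = 0$) variants.
The comparison criterion was fixed before running it: mean SCDR test
MAE must not exceed 110% of the baseline's, SCDR predictions must reach
Spearman ≥ 0.7 against the test labels, and the Spearman correlation
between pairwise embedding distances and pairwise label distances must
be higher after training than at initialization (the testable form of
the claim that the feature space becomes ordered by label). Structural
unit tests use even smaller 32×32 configurations.

## Known limitations

* CPU-bound: the `standard` 224×224 preset is provided and functional
  but realistic training on it wants GPU-scale resources, which is out
  of scope here.
* The thrust similarity forms are reasonable defaults, not canonical:
  alternatives (e.g. Gaussian label kernels, raw cosine) slot into the
  same interface.
* Unpaired views appear in neither the numerator nor the denominator of
  the per-anchor loss; including them in the denominator is a plausible
  variant we deliberately did not adopt.
* The generator's fruit placement is uniform over foliage; real fruit
  clustering (and hence the fruit-pixel/label relationship) is more
  structured.
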