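---
title: "Probing classifier representations with neural mutual-information estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing classifier representations with neural mutual-information estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question the package answers

A classifier trained only on a binary diagnostic label — here, severe left
ventricular hypertrophy (SLVH) read off chest-radiograph-like images — may
nonetheless internalize clinically meaningful covariates it was never shown:
patient age and sex, and the echocardiographic dimensions that define the
label (interventricular septal diameter IVSDd, posterior wall diameter
LVPWDd, internal diameter LVIDd, all in cm). This package quantifies that
*expressivity*: the mutual information (MI) between a layer's feature
representation $F \in \mathbb{R}^{n \times d}$ and a scalar attribute
$A \in \mathbb{R}^n$, estimated neurally and reported in nats.

## The estimator

MI is the KL divergence between the joint law of $(f, a)$ and the product of
its marginals. Direct estimation is intractable for high-dimensional $f$, so
the package maximizes the Donsker–Varadhan (DV) lower bound

$$ I(F;A) \;\ge\; \mathbb{E}_{P_{FA}}[T_\theta(f,a)]
   \;-\; \log \mathbb{E}_{P_F \otimes P_A}\!\left[e^{T_\theta(f,a)}\right], $$

over a critic network $T_\theta$ — a multilayer perceptron on the
concatenated $(d{+}1)$-vector, by default two hidden layers of 256 and 64
units with ELU activations and Xavier initialization — trained to score
matched pairs high and mismatched pairs low. Both expectations are estimated
on mini-batches of $b = 100$ pairs: the joint term from the matched batch,
the marginal term from mismatched pairs built by a seeded random derangement
(a cyclic shift of a shuffled order), which guarantees $i \neq j$ for every
pair while using each feature row and each attribute value exactly once.
Optimization is Adam at learning rate $10^{-3}$.

Two stabilization choices matter in practice:

* **EMA-corrected gradient.** The mini-batch log-term denominator is noisy;
  the gradient path divides by an exponential moving average (decay 0.99) of
  the batch mean of $e^{T}$ instead of the raw batch mean. The EMA is held in
  log space, so arbitrarily large scores cannot overflow. Reported bounds
  always use the raw term — the EMA only damps gradient noise.
* **Held-out plateau detection.** The DV bound evaluated on the very data the
  critic trains on keeps climbing as the critic memorizes pairs; at
  $d = 16, n = 5000$ with truly independent inputs it reaches several tenths
  of a nat and never plateaus. The trainer therefore holds out a 20%
  monitoring split (`val_fraction`): the per-epoch bound on those held-out
  pairs drives plateau stopping (patience 20 epochs, cap 200) and selects the
  checkpoint. The reported estimate is then the full-data DV bound of the
  selected network, computed in one pass with a fresh derangement. Setting
  `val_fraction = 0` restores training-data monitoring.

One fit is one seed; the headline estimate averages $M = 10$ independent
fits (seeds $s_0, \dots, s_0 + 9$), reporting mean and standard deviation.
Raw per-seed values are kept: slightly negative estimates are legitimate
evidence about estimator noise and are flagged, never clipped to zero.

Units are nats (natural logarithm) everywhere. Inputs are z-scored by
default (features columnwise, continuous attributes; binary attributes stay
0/1): MI is invariant under invertible affine maps, so this changes nothing
about the target quantity while keeping Xavier-initialized training in a
sane regime. Zero-variance feature columns are left centered but unscaled,
and `extract_features()` flags them for exclusion.

## Validation against analytic oracles

The estimator is certified on channels whose MI is known exactly:

* **Bivariate Gaussian**: $a = \rho x + \sqrt{1-\rho^2}\,\varepsilon$ has
  $I = -\tfrac12 \ln(1-\rho^2)$. `bivariate_gaussian_mi_check()` runs the
  full procedure against this closed form for $\rho \in \{0.3, 0.6, 0.9\}$.
* **Linear-Gaussian feature channel**: `make_linear_gaussian_features()`
  injects each attribute into its own coordinate,
  $f_k = g_k\, z(\text{attr}_k) + \varepsilon$, giving
  $I = \tfrac12\ln(1 + g_k^2/\sigma^2)$ for continuous attributes. For the
  binary sex attribute (injected as $\pm g$) there is no closed form; the
  oracle integrates the two-component Gaussian mixture entropy by adaptive
  quadrature (`binary_channel_mi()`, relative tolerance $10^{-10}$,
  integration range $|g| + 12\sigma$; the ceiling is $\ln 2$).
  `gain_for_mi()` inverts either family, so experiments can be specified
  directly in nats.
* **Ordering recovery**: `ordering_experiment()` injects the five attributes
  at well-separated targets (defaults 1.0, 0.6, 0.35, 0.2, 0.05 nats,
  mirroring the clinically expected hierarchy age > sex > IVSDd > LVPWDd >
  LVIDd) and checks that the estimated ranking matches the injected one,
  including under the shallow (256) and deep (512–256–64) critic variants.
  These experiments draw the cohort from `independent_cohort_config()` —
  anatomical age/sex coefficients zeroed — because with physiologically
  coupled attributes the other coordinates leak correlated information and
  the per-channel closed form is only a lower bound on the true MI, not an
  oracle.

Validation problem sizes are $n = 5000$ with $M = 10$ seeds for the point
estimates and the independence null, and ten independent repetitions with
single-seed fits per attribute for the ordering experiments; rankings at
these separations are already stable across single fits, and the repetition
count, not the within-repetition averaging, is what the success criterion
counts.

## The synthetic cohort and renderer

`sample_cohort()` draws age from a truncated normal (mean 62 y, sd 14 y, on
[18, 95]), sex as Bernoulli(0.5), and the three LV dimensions as linear
functions of age and sex plus Gaussian noise; SLVH is 1 exactly when IVSDd
or LVPWDd exceeds its sex-specific threshold. All coefficients and
thresholds are explicitly synthetic conveniences chosen to give plausible
ranges (wall thicknesses around 1 cm, cavity diameter around 5 cm) and a
label prevalence usable for balanced training; nothing is estimated from
real data.

`render_images()` draws a toy radiograph: a centered cardiac silhouette
whose radius grows with z(age), an annular wall whose thickness grows with
z(IVSDd) + z(LVPWDd) and whose inner radius grows with z(LVIDd), a lateral
intensity ramp encoding sex, soft (logistic) edges so sub-pixel geometry
survives rasterization, and three nuisance processes: i.i.d. pixel noise and
per-image brightness/contrast jitter emulating exposure variation. The
jitter is what makes the representation question non-trivial at desk scale:
early pooled conv features are nearly linear in exposure and get diluted,
while a trained classifier learns to discount it, so label-relevant
information concentrates with depth — the qualitative pattern expected of
radiograph classifiers. What the renderer does *not* emulate: anatomy beyond
one annulus, projection physics, scanner heterogeneity, comorbidities.
Passing tests certify the estimator and the pipeline mechanics, not clinical
performance on real radiographs.

`make_balanced_subset()` implements class-balanced subsampling with a fixed
seed: per split the minority class is kept whole and the majority class is
down-sampled without replacement to exact equality; an optional patient
grouping draws majority images patient-by-patient (topping up with part of
the last patient) so balance stays exact.

## Desk-scale backbones and layer taps

The conv family is a stem plus `n_stages` 3×3 stride-2 convolutions
(ReLU, widths doubling from `base_width`), global average pooling, and a
128–64–1 fully connected head with dropout 0.3, trained end to end with
binary cross-entropy and Adam (weight decay $10^{-5}$). The full-size
configuration mirrors the reference protocol (256-px inputs, Adam at
$10^{-4}$, suitable for fine-tuning a pretrained encoder loaded through
`pretrained_weights`); the desk default trains a `base_width = 16` stack
from random initialization on 64-px images, where $10^{-3}$ converges within
the 10-epoch budget. Grayscale images are replicated to three channels and
normalized with ImageNet statistics before the stem.

The transformer family is a small ViT (8-px patches, learned position
embeddings, a [CLS] token, pre-norm blocks) used exactly as in the reference
protocol for such encoders: frozen, with only an MLP head (default
512–128–1) trained on the [CLS] representation under warmup + cosine decay.
Because the encoder is never updated, only the forward pass is implemented;
requesting `freeze_encoder = FALSE` errors rather than silently training.

Layer taps: conv `early`/`mid` are global-average-pooled stage outputs
(first and second-to-last stage), `pool` is the penultimate encoder vector,
and `final` is the head's last hidden (pre-logit) activation; transformer
taps return the [CLS] vector after block $\lceil L/6 \rceil$,
$\lceil L/2 \rceil$, and the final block (after the closing layer norm),
with mean-pooled tokens available as an option. Global average pooling was
chosen for intermediate conv taps because it matches the network's own final
pooling and keeps $d$ modest for the critic. Extraction always runs in
evaluation mode (dropout off), so repeated calls are bit-identical.
Classifier training keeps the checkpoint with the best validation AUROC.

## Metrics

AUROC is computed exactly as the Mann–Whitney statistic via midranks (tied
pairs get half credit). AUPRC is stepwise average precision with tied scores
grouped into one threshold and no interpolation — at small $n$ this choice
visibly changes values, so it is fixed and documented. Confidence intervals
are seeded nonparametric percentile bootstraps over (score, label) pairs
(default 2000 resamples; single-class resamples are redrawn and counted).
Bootstrapping is at image level; a patient-cluster option was considered and
left out of scope for the desk-scale artifact.

## Reproducibility model

Every stochastic component keys off one integer: the C++ training engines
use an internal splitmix64 generator seeded explicitly, and R-side
randomness runs under a save/restore wrapper, so package calls never disturb
the session RNG. The pipeline fans a single global seed out to per-stage
seeds via a string-labeled hash; stages are cached by config hash and output
checksums, reruns are no-ops, a corrupted intermediate is detected by
checksum and recomputed, and two runs under the same configuration produce
byte-identical reports (manifests carry the only timestamps).

## Known limitations

* DV-bound estimates carry finite-sample bias; with held-out plateau
  detection the residual bias at $n = 5000$ is within the tolerances used in
  the validation suite, but attribute-to-attribute comparisons remain more
  trustworthy than absolute values — which is also why the package's
  headline analyses are orderings and layer trends.
* Binary attributes cap at $\ln 2$ nats; comparing a binary attribute's
  expressivity against a continuous one near or above that ceiling conflates
  entropy budgets, a caveat inherent to any MI-based score.
* The renderer's simplicity means desk-scale results demonstrate estimator
  correctness and pipeline behavior, not transferability to clinical data.
* The transformer backbone is frozen-encoder only; end-to-end transformer
  fine-tuning and self-supervised pretraining are out of scope.
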