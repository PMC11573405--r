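---
title: "Guided conditional diffusion classification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Guided conditional diffusion classification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The method

`condiff` classifies a two-class image — the motivating application is
deciding whether a photographed diabetic foot ulcer looks infected — by
*generative contrast* rather than by a discriminative head:

1. **Partial noising.** The input ("guide") image $x_0$ is pushed part-way
   through a variance-preserving forward diffusion process. The noise
   strength $t_0 \in (0, 1]$ is the fraction of the $T$-step horizon that
   is applied: the guide is mapped to
   $x_s = \sqrt{\bar\alpha_s}\,x_0 + \sqrt{1-\bar\alpha_s}\,z$ with
   $s = \mathrm{round}(t_0 T)$ and $z \sim \mathcal N(0, I)$.
2. **Conditional resynthesis.** The perturbed image is denoised twice with
   a deterministic DDIM sampler, once per class condition
   $y \in \{\text{uninfected}, \text{infected}\}$. At every rung of the
   sampling ladder the conditional denoiser
   $\epsilon_\theta(x_t, t, y)$ is combined with its unconditional branch
   by classifier-free guidance,
   $\tilde\epsilon = (1-\omega)\,\epsilon_\theta(x_t, t) +
   \omega\,\epsilon_\theta(x_t, t, y)$. The same perturbation $z$ is shared
   by both conditions, so the *only* difference between the two syntheses
   $\hat x_0^{(y)}$ is the condition itself.
3. **Distance decision.** A triplet-loss-trained embedding $f_\phi$ maps
   the guide and both syntheses to a $d$-dimensional space; the predicted
   label is
   $\arg\min_y \lVert f_\phi(x_0) - f_\phi(\hat x_0^{(y)}) \rVert_2^2$.
   Ties go to "uninfected", the conservative choice for specificity.

The intuition: a synthesis conditioned on the *correct* class only has to
restore what the noise destroyed, while a synthesis conditioned on the
wrong class must also pull the image towards the other class's appearance
— so the correct-class synthesis stays closer to the guide.

Training happens in two stages. Stage 1 fits the conditional denoiser by
denoising score matching: steps are sampled uniformly, Gaussian noise is
added by the closed-form marginal, and the mean squared error between true
and predicted noise is minimised; each label is replaced by the
unconditional token with probability `p_uncond` so that classifier-free
guidance has an unconditional branch to mix with. Stage 2 trains the
embedding on triplets $(x^{(a)}, x^{(p)}, x^{(n)})$ with the hinge
$\big(\lVert f(a)-f(p)\rVert_2^2 - \lVert f(a)-f(n)\rVert_2^2 +
\alpha\big)_+$, margin $\alpha = 1$. Anchors are always real images; with
probability $p_{gen}$ the (positive, negative) pair is drawn from the pool
of conditional syntheses of the training guides, which exposes the
embedding to exactly the kind of images it must rank at inference time.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `omega` | 0.75 | guidance scale; 0 ignores the condition, 1 is fully conditional, larger values extrapolate |
| `t0` | 0.8 | fraction of the forward horizon applied to the guide (unitless) |
| `n_steps` | 30 | DDIM ladder length at sampling time |
| `T_total` | 1000 | training-time forward horizon; linear $\beta \in [10^{-4}, 0.02]$ |
| `eta` | 0 | DDIM stochasticity; 0 makes inference bit-reproducible |
| `p_uncond` | 0.1 | label-dropout rate during Stage 1 |
| `p_gen` | 0.2 | probability that a triplet's pair is synthetic in Stage 2 |
| `margin` | 1 | triplet hinge margin $\alpha$ |
| `d` | 128 (`embed_config`), 32 in `condiff_fit` | embedding dimension |

Two values of `omega` appear in the source literature for this method
(0.75 for synthesis-time guidance, 7.5 for the noise-strength sweep); both
are accepted through `sampler_config()`, the default is 0.75, and the
discrepancy is left unresolved as configuration.

The noise strength trades identity preservation against conditional
freedom: at small $t_0$ the two syntheses barely differ and the decision
margin collapses; at $t_0 \to 1$ the guide is destroyed and both syntheses
drift far from it. `divergence_vs_t0()` measures the mean pixel-space
squared distance between the two conditional syntheses as a function of
$t_0$ — it vanishes identically at $\omega = 0$ and grows with $t_0$ —
and `sweep_t0()` re-scores the same images (a paired design: identical
per-image seeds across rows) at several noise strengths.

## Design choices

**Noising convention.** The guided-editing literature writes the guide
perturbation in variance-exploding form ($x + \sigma(t_0) z$) while the
training objective is variance-preserving. The package uses the
variance-preserving realisation throughout, with the correspondence
$\sigma(t_0) \leftrightarrow \sqrt{1-\bar\alpha_s}/\sqrt{\bar\alpha_s}$ at
$s = \mathrm{round}(t_0 T)$ (round half away from zero). One consistent
parameterisation for training and sampling removes a family of unit bugs.

**Denoiser.** The noise predictor is a two-hidden-layer fully connected
network on the flattened image, concatenated with a sinusoidal step
embedding and a class-token one-hot (two classes + the unconditional
token), plus two analytically scaled learnable pathways:

* a class-prototype pathway $-\sqrt{\bar\alpha_t(1-\bar\alpha_t)}\, M_y$
  with one learnable image $M_y$ per condition token. Under a Gaussian
  prior around a class mean, the posterior clean-image estimate is
  $\sqrt{\bar\alpha}\,x_t + (1-\bar\alpha)\,\mu_y$, and its noise-space
  contribution carries exactly this $\sqrt{\bar\alpha(1-\bar\alpha)}$
  scale — vanishing at both ends of the schedule and peaking mid-way,
  where conditional synthesis needs it. Without this pathway the class
  condition reaches the network only as 3 of ~3100 inputs, its gradient
  at the high-noise steps is weighted down by
  $\sqrt{\bar\alpha} \approx 0.04$, and the two conditional syntheses
  come out nearly identical;
* an inversion pathway $a_2\, x_t/\sqrt{1-\bar\alpha_t} -
  \sqrt{\bar\alpha_t}/\sqrt{1-\bar\alpha_t}\; Q_y$ with a learnable
  clean-image estimate $Q_y$ per token. With $Q_y$ at the class mean and
  $a_2$ at the posterior weight this is the exact inversion
  $(x_t - \sqrt{\bar\alpha}\,x_0)/\sqrt{1-\bar\alpha}$, whose
  $1/\sqrt{1-\bar\alpha}$ Lipschitz constant at low noise is out of reach
  for a generic network; at high noise it degenerates to the standard
  $x_t$ skip. The two factors are separate parameters so each receives a
  direct, ungated gradient, and the pathway parameters train under a
  higher Adam learning-rate multiplier (they are few, with clean
  gradients).

The output head, $a_2$, $M$ and $Q$ are all zero-initialised, so an
untrained model predicts zero noise (its loss sits at the
$\mathbb E\lVert\epsilon\rVert^2 = 1$ per-element baseline). A U-Net would
be the natural choice at clinical resolution; at the 32×32 desk scale this
model trains in minutes on one CPU and preserves every contract the
sampler needs.

**Embedding.** One 3×3 convolution (stride 1, zero padding), ReLU,
non-overlapping average pooling, a linear head, and L2 normalisation onto
the unit sphere. Normalisation keeps squared distances in $[0, 4]$, so the
margin $\alpha = 1$ remains an active constraint no matter how separable
the raw features are — without it, an easily separated dataset satisfies
the hinge at initialisation scale and training stalls. The convolutional
stage exists not only for parameter sharing but because Score-CAM needs
genuine spatial activation maps. Distances are squared Euclidean
everywhere; the argmin decision is unaffected by the square.

**Score-CAM for similarity.** Classic Score-CAM weights a channel's
activation map by the class logit of the masked input. Here there is no
logit; the analogous score is the *negative squared embedding distance*
between the guide and the candidate masked by the channel map
(zero-baseline masking, candidate-side masking). Softmax over channel
scores weights the maps; the result is min-max normalised, with the
convention that a constant map normalises to all zeros.

**Determinism.** All inference randomness is the single perturbation draw,
seeded per image by a 31-bit hash of (pipeline seed, image id) — so batch
composition and order never change a prediction, and every result row
carries the seed and sampler settings needed to reproduce it bit-exactly.

**Metrics.** "Infected" is the positive class. F1 is computed from PPV and
sensitivity (harmonic mean), which is the same identity used when auditing
published results from their printed rates; a ratio with zero denominator
propagates as `NA` with a warning rather than silently becoming 0. K-fold
evaluation folds the *evaluation* set subject-wise and reuses the fixed
trained models; fold dispersion is the population (divide-by-k) standard
deviation. Fractional confusion counts are permitted because
reconstructing a published row from sensitivity/specificity and the class
composition yields non-integer counts.

## The synthetic wound generator

Real clinical wound datasets are access-controlled, so the package ships a
generator that emulates the *statistical structure* the pipeline cares
about, not dermatology: per subject, a skin-toned background with a smooth
low-frequency texture field and an elliptical lesion; three captures at
magnification crop ratios 1.0/0.8/0.6 (the "natural augmentation" that
makes sample-wise splitting leak); and a class signature of amplitude
$\delta$ — infected lesions get a red-shifted rim and a darkened core.
Intra-class variation comes from per-subject geometry, colour jitter, a
multiplicative signal jitter, and pixel noise. At $\delta = 0$ the classes
are distributionally identical, which gives the chance-level null control.
The default $\delta = 2$ is calibrated so a three-pixel-statistic linear
probe exceeds 0.95 held-out accuracy — the generator's definition of a
"plainly separable" study condition; at $\delta \approx 1$ the jitter
tails overlap and the probe sits at its boundary.

Splits are subject-wise (all captures of a subject in one split),
stratified by label, with largest-remainder rounding of the 70/15/15
fractions; `audit_subject_leakage()` verifies the invariant and flags the
historic sample-wise mistake. In the leak-free protocol only the middle
magnification is emitted.

What passing tests on this generator do *not* show: robustness to the
imaging-condition variation, fine-grained texture cues, annotation noise
and class imbalance of real wound photographs. The published accuracies on
the clinical dataset are not reproducible from this package and are not
claimed.

## Desk-scale study sizes and numerical choices

The end-to-end study used by the test suite and the acceptance script
runs at 32×32×3 with 60 subjects (42 train / 9 validation / 9 test after
stratified rounding), Stage 1 for 2500 Adam steps at batch 48 (learning
rate $10^{-3}$), Stage 2 for 500 steps at batch 24, validation-selected
checkpointing every 50 steps, and subject-wise 5-fold scoring of the 18
held-out images. These sizes are the package's choice of a study that a
laptop CPU completes in minutes.

Other numerical conventions: the final synthesis is clamped to $[-1, 1]$,
but the *running* $\hat x_0$ estimate is not clipped at intermediate DDIM
rungs by default — at high noise strengths the $1/\sqrt{\bar\alpha}$
amplification puts the estimate far outside the pixel range, and per-rung
clipping saturates away most of the conditional signal (it empirically
reverses the growth of inter-condition divergence in $t_0$ above 0.6);
per-rung clipping remains available as `clip_denoised = TRUE`; the DDIM
ladder is the
rounded even spacing from the start step to 0 with duplicate rungs
dropped; $\omega < 0$ or $\omega > 1$ are allowed as extrapolation with a
warning above 20; the Adam update runs through a small compiled kernel
because the parameter-wise update was the single hottest spot in pure R;
triplet mining is uniform within the label constraints (no semi-hard
mining); the positive of a real-pool triplet never reuses its anchor.

## Known limitations

* The denoiser is a fully connected network: adequate at 32×32, not a
  substitute for a U-Net at clinical resolution, and it has no spatial
  weight sharing — synthesis quality degrades for lesion geometries far
  outside the training distribution.
* Inference costs $2 \times 2 \times$ `n_steps` denoiser evaluations per
  image (two conditions × two guidance branches per rung) — orders of
  magnitude more than a discriminative classifier.
* `eta > 0` sampling draws its rung noise per batch, so stochastic-DDIM
  outputs are reproducible per call but not guaranteed identical between
  batched and single-image execution paths; the deterministic default
  (`eta = 0`) is.
* The embedding validation metric is distance-classification accuracy on
  a small validation split; with few validation subjects checkpoint
  selection is coarse.
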