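---
title: "Expanding scarce POCUS training data: models, phantoms and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Expanding scarce POCUS training data: models, phantoms and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(pocusda)
```

## The problem

Point-of-care ultrasound (POCUS) devices are cheap and portable, which makes
them attractive for breast-cancer triage in settings without cart-based
scanners — but their images are darker and noisier than standard B-mode
images, and labelled POCUS breast data are scarce. A classifier trained only
on a small POCUS set performs poorly; a classifier trained on plentiful
standard-ultrasound images suffers from the domain gap. `pocusda` implements
the full comparison study for this situation: expand the scarce POCUS
training set with standard-ultrasound images — raw, histogram-matched,
histogram-equalized, or translated into the POCUS domain by cycle-consistent
adversarial networks — train one fixed CNN per expansion strategy (sixteen
canonical training-data combinations), and compare the resulting classifiers
with ROC/AUC statistics designed for correlated model comparisons.

Because clinical breast-ultrasound data cannot be redistributed, the package
ships a seeded synthetic phantom generator that reproduces the *statistical
structure* of such a study, so the entire pipeline is testable end to end.
All empirical statements below are computed by the test suite or by
`scripts/acceptance.R`; none are imported from external data.

## The phantom generator

`generate_phantom()` renders one grayscale B-mode-like image in four stages:

1. **Echogenicity map.** A background level (default 0.55) with
   low-frequency horizontal banding. A *benign* lesion is a smooth ellipse,
   wider than tall, whose interior echogenicity is multiplied by 0.45, with a
   brightened column band underneath (posterior enhancement). A *malignant*
   lesion is an irregular region — radius r(θ) = r₀(1 + a·Σⱼ sin((j+1)θ + φⱼ)
   with 5 harmonics of total relative amplitude 0.25 — taller than wide,
   interior multiplied by 0.30, with a darkened band underneath (acoustic
   shadowing, attenuation 0.55). Enhancement and shadowing are column-band
   multipliers, not ray-traced; that is sufficient for the class-separability
   contract and keeps rendering fast.
2. **Speckle.** The squared magnitude of a complex Gaussian scattering field
   smoothed by a Gaussian point-spread function (σ = 1.5 px), i.e. a Rayleigh
   envelope, multiplied by the echogenicity map.
3. **Log compression** to the displayed dynamic range, then rescaling to
   [0, 1].
4. **Domain operator** (`apply_domain_shift()`): the *standard* domain adds
   mild acquisition noise (σ = 0.01); the *POCUS* domain applies gamma
   compression with exponent 1.8 — which pushes histogram mass into the dark
   range, the defining feature of the POCUS domain — followed by additive
   Gaussian noise (σ = 0.04) and clipping. The POCUS noise level is a free
   parameter: the device difference it emulates is only known qualitatively (POCUS is "noisier"),
   so σ = 0.04 was fixed once as a visually plausible value and is exposed in
   `phantom_config()`. With a small probability (0.10) bright caliper-like
   glyphs are burnt in, emulating residual annotations that survive
   preprocessing.

Cohorts (`generate_cohort()`) are patient-grouped: each patient carries one
primary finding class (largest-remainder apportionment of the requested class
mix, default 57/21/22% normal/benign/malignant as in a triage population) and
1–4 images; lesion patients occasionally contribute one contralateral normal
image. Every image derives its seed from the cohort seed, so cohorts are
bit-reproducible.

**What the phantom does *not* emulate:** real speckle texture statistics of
tissue, BI-RADS morphology subtypes, operator variability, colour annotations,
or any acoustic wave physics. Passing tests therefore demonstrate that the
*pipeline and statistics* behave correctly and that the qualitative study
conclusions re-emerge under a controlled domain gap — they are not evidence
about clinical images.

## Preprocessing

`crop_margins()` removes device metadata margins (margins are configuration
per domain; synthetic images need none), `zero_pad_square()` pads to a square
with the content centred at offset ⌊(N−h)/2⌋, and `resize_to_input()` scales
to the network input side — exact block averaging for integer-factor
downscaling, anti-aliased bilinear otherwise. Padding precedes resizing; the
order is fixed by this package.

## Intensity transforms

Histogram specification (`match_image_to_histogram()`) maps each pixel
through `Q_target(F_image(v))` with `F` the image's empirical CDF and
`Q_target` the right-continuous quantile function of a pooled 256-bin class
histogram; one target histogram per class, pooled over POCUS *training*
images only. A degenerate single-intensity image maps to the target median.
Histogram equalization (`equalize()`) uses `round(255·F(v))`; a constant
image maps to 255 since its CDF is 1 everywhere. Both transforms are
monotone and never leave the 8-bit range. In the combinations that use
equalization it is applied to training *and* test data, so the classifier
sees and is evaluated on the same representation.

## Augmentation

Two policy groups (`augment_policy()`), drawn independently per image per
epoch: *spatial* — zoom, shear and shifts within 10%, rotation within 30
degrees, horizontal flips, composed into a single affine (one resampling
pass, bilinear, zero fill); *brightness/noise* — a brightness factor from
U(0.7, 1.3) on the [0, 1] scale plus Gaussian noise of variance 0.01. The
brightness convention here is the plain one (factor > 1 brightens); the
sampled distribution is symmetric about 1, so this is statistically
equivalent to the inverted convention some toolkits use. The "10%" shear is
interpreted as a shear *factor* of 0.10 (toolkit conventions differ; the
value is exposed in the policy). Noise follows brightness scaling. Default
study policy is spatial-only, the variant that a three-way comparison of
augmentation types favours.

## The classifier

`build_cnn()` constructs the fixed network: five 3×3 convolution stages
(filters 32, 64, 128, 128, 128), each ReLU → 20% dropout → 2×2 max pooling
with stride 2; after the last pooling a 50% dropout; then dense layers of 512
and 3 with 50% dropout between them and a softmax output. Convolution padding
is not dictated by the architecture's description; this package fixes 'same'
padding, which yields the spatial trace 180→90→45→22→11→5 (odd sizes pool
with floor), flatten width 3200, and exactly 2,028,291 trainable parameters —
locked by a test so refactors cannot silently change the network. Training
uses Adam (lr 10⁻⁴), class-weighted categorical cross-entropy with weights
`w_c = N/(3·n_c)` computed on the full assembled training combination, 50
epochs, batch 32, no validation split or early stopping. Pixels are scaled
to [0, 1] at the network input. The engine underneath is an internal CPU
implementation (im2col convolutions in C++, hand-derived backpropagation,
verified against finite differences in the test suite); given one seed,
training is bit-reproducible.

## Domain translation

`train_cyclegan()` trains the two-generator/two-discriminator model with the
least-squares adversarial loss, L1 cycle consistency (λ = 10) and an identity
term at 0.5·λ; discriminators see generated images through a 50-image replay
buffer and the learning rate (2·10⁻⁴) decays linearly over the second half of
training. Generators are ResNet-style (7×7 stem, two strided downsampling
stages, residual blocks, nearest-neighbour-upsample + convolution decoding,
tanh output); all convolutions are single-channel. An epoch sweeps
the larger domain once, recycling the smaller, so scarce classes still
receive a full complement of updates. `train_regime()` covers the two
designs: one model for all classes (*cyclegan1*) or one per class
(*cyclegan3*). Trained models (classifiers and translator pairs) checkpoint
through `save_model()`/`load_model()` — serialized parameters plus a JSON
sidecar with the configuration and loss history. Translated records keep their class label and patient id —
the labelling assumption for generated images — and carry a per-image
mean-darkening statistic, a cheap monitor for the collapsed-dark-area
artifact this family of models can produce (no structural correction is
attempted).

## Evaluation

The malignant class is compared against normal and benign combined
(`binarize_malignant()`): missing a cancer matters more than confusing the
benign subtypes. `auc()` is the Mann–Whitney statistic (ties half-weighted);
`constrained_youden()` maximizes J = sensitivity + specificity − 1 subject to
sensitivity ≥ 90%, with ties broken toward higher specificity then higher
threshold, and falls back to the unconstrained maximizer only when no
threshold meets the floor (impossible with at least one positive).
Percentile bootstrap CIs (B = 1000, image-level resampling with replacement;
patient-level resampling available as a flag since test images share
patients) cover AUC and balanced accuracy; sensitivity/specificity CIs hold
the operating threshold fixed across resamples. `fid()` computes the Fréchet
distance ‖μ₁−μ₂‖² + Tr(Σ₁+Σ₂−2(Σ₁Σ₂)^{1/2}) between Gaussians fitted to
image features; the default extractor is a fixed-seed random-convolution
embedding requiring no pretrained weights (distances are comparable only
within one extractor, whose id is recorded; a pretrained backend can be
plugged in through the same interface). `delong_paired()` implements the
placement-value test for two correlated AUCs — all sixteen networks share
one test set — with ½-weight tie handling; identical score vectors return
p = 1 by convention. `significance_matrix()` adjusts all pairwise p-values
jointly with the Holm–Bonferroni stepdown (family = all C(k,2) comparisons,
120 for the full study; the family size is recorded in the report) and marks
cells `**` (< 0.01), `*` (< 0.05) or `ns`.

Numerical conventions worth knowing: the matrix square root inside the
Fréchet distance is computed through the symmetrized product
Σ₁^{1/2}Σ₂Σ₁^{1/2} with eigendecompositions, clipping small negative
eigenvalue noise (the clip magnitude is attached to the result); bootstrap
resamples on which a metric is undefined (single-class draws) are redrawn and
counted; probabilities on the true class are floored at 10⁻⁷ inside the
cross-entropy.

## The study harness and its two scales

`run_study()` orchestrates everything: patient-exclusive splitting
(`patient_split()` assigns whole patients greedily to the test fold),
histogram targets from POCUS training images only, translator training on the
two training sets, assembly of each combination (`assemble_combination()`,
sizes follow the n_P / n_P + n_S / n_P + 2·n_S arithmetic at any scale), one
classifier per combination, and the report tables. A leakage audit
fingerprints every test image and asserts that none entered histogram
pooling, translator training or classifier training, and that no patient id
spans both folds. The final-epoch model is evaluated (no checkpoint
selection), matching the fixed-epoch training design.

Two presets (`study_config()`):

* **full** — 180-pixel inputs, the full network, 50 classifier epochs,
  200 translation epochs, clinically realistic cohort sizes (436 standard /
  105 POCUS patients). This is the faithful configuration; it is not
  intended for interactive use on one CPU.
* **desk** — the package's own reduced study, chosen so the complete
  16-combination pipeline runs on one CPU in minutes: 48-pixel images,
  40 standard patients (~120 images) and 40 POCUS patients (~120 images)
  with test fraction 0.7 (≈ 36 POCUS training images — target-domain
  scarcity is the premise of the study — and ≈ 84 test images, which buys
  usable CI width and DeLong power at this scale); classifier filters
  (8, 16, 32, 32, 32) with dense width 64, 20 epochs, batch 16, lr 3·10⁻⁴,
  dropout reduced to 0.05/0.25/0.25 (the full-scale dropout rates are tuned
  to fifty epochs over hundreds of images and leave a desk-scale run stuck
  at the chance-level plateau); translation width 8 with one residual block
  and 3 epochs (each epoch sweeps the larger domain once, recycling the
  smaller). Under this preset, across seeded replicates, the expanded
  combinations beat the POCUS-only baseline in median AUC, translated
  cohorts score lower FIDs to the POCUS training set than raw standard
  images, and the POCUS-only network is flagged against the strongest
  combination by the Holm-adjusted DeLong test — the qualitative content of
  the full-scale study. The test suite asserts exactly these properties.

```{r desk-example}
report <- run_study(study_config("desk", seed = 1,
                                 combinations = c(1, 2, 6)))
report$metrics
report$fid
report$significance$stars
report_tables(report, "study-results")
```

## Known limitations

* The phantom's class geometry is deliberately simple; absolute desk-scale
  AUCs say nothing about clinical performance.
* Desk-scale adversarial training (tens of images, five epochs) learns the
  global intensity transform between domains, not fine texture; FID
  improvements quantify that limited goal.
* The default FID extractor is random — stable and download-free, but its
  absolute values are not comparable with published Inception-based numbers.
* Image-level bootstrap ignores within-patient correlation in the test set;
  the patient-level flag is provided; the image-level default matches the
  common practice of resampling the test images directly.
* `run_study()` recomputes rather than caches; at desk scale a full rerun is
  cheaper than artifact management.
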