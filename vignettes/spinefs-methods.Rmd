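---
title: "Synthesizing fat-saturated spine MRI and measuring its diagnostic value"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing fat-saturated spine MRI and measuring its diagnostic value}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(spinefs)
```

## The problem

T2-weighted fat-saturated (T2-w fs) sequences make fluid and edema
conspicuous by removing the adipose signal that dominates T1-w and
conventional T2-w images. They are pivotal for grading bone-marrow edema,
spondylodiscitis, inflammatory (type 1) Modic endplate changes, acute
fractures, cord lesions and paravertebral abnormalities — and they are the
sequence most often missing from routine spine examinations. `spinefs`
implements a conditional adversarial model that synthesizes a T2-w fs
contrast from a co-registered (T1-w, non-fs T2-w) pair, together with the
agreement statistics used to quantify whether the synthetic contrast
actually improves grading, and a phantom simulator that makes the whole
pipeline trainable and testable at desk scale without patient data.

## The model

The generator \(G\) is a U-Net: it maps a two-channel sagittal slice
\((x_{T1}, x_{T2})\) to a one-channel candidate \(\hat y\) squashed to
\([-1, 1]\) by `tanh`. The patch discriminator \(D\) sees the channel
concatenation \((x_{T1}, x_{T2}, y)\) and emits a grid of per-patch
real/synthetic scores, so its judgment is conditional on the inputs and
localized. Training alternates one \(D\) update with one \(G\) update per
batch. \(D\) minimizes patch-averaged binary cross-entropy,
\(\mathrm{BCE}(1, D(y_{real})) + \mathrm{BCE}(0, D(\hat y))\), while \(G\)
minimizes the joint loss

\[
\mathcal{L}_G \;=\; \bigl(1 - \mathrm{SSIM}(y_{real}, \hat y)\bigr)
\;+\; \lambda \cdot \mathrm{BCE}\bigl(1, D(\hat y)\bigr), \qquad \lambda = 50 .
\]

SSIM rather than an L1/L2 term makes the reconstruction target tolerant of
small residual misregistration, since it compares windowed luminance,
contrast and structure rather than individual pixels. Both networks use
Adam (learning rate \(2\times10^{-4}\), betas 0.5/0.999) for 25 epochs,
each epoch one pass over all training slices in a freshly drawn random
order.

Everything above — the networks, backpropagation (including the analytic
gradient of windowed SSIM), Adam, and the training loop — is implemented in
this package over small compiled convolution kernels, so the whole model is
inspectable and deterministic given the config seed.

### Architecture sizes

The encoder/decoder depth and widths are free parameters of the method; the
package defaults are sized for single-CPU desk-scale experiments
(64 × 64 slices, a few hundred slice pairs):

| parameter | default | meaning |
|---|---|---|
| `depth` | 3 | down/up-sampling levels; input padded reflectively to a multiple of \(2^{depth}\) |
| `base_channels` | 16 | channels at the finest level, doubled per level |
| `dropout_rate` | 0.5 | decoder dropout (all blocks except the finest), off at inference |
| discriminator | 3 stride-2 blocks | ~30 px receptive field, 8 × 8 patch grid on 64 × 64 input |
| `batch_size` | 8 | slices per update |

At these sizes, the 200-slice / 25-epoch reference run used throughout the
tests and the acceptance script completes in minutes on one CPU and reaches
a held-out volume-mean SSIM above 0.8 — that threshold is this package's own
learning oracle for the desk-scale setting, not a clinical claim.
Deeper/wider settings are available through `generator_spec()`.

Dropout in the decoder emulates the noise-injection role it plays in
image-to-image translation models. At inference it is disabled by default so
synthesis is bit-reproducible; `synthesize_volume(stochastic = TRUE)`
re-enables it for readers who want stochastic synthesis.

### SSIM

`ssim()` uses an 11 × 11 Gaussian window (sd 1.5) over valid positions with
the standard stabilizers \(C_1 = (0.01 L)^2\), \(C_2 = (0.03 L)^2\) and
dynamic range \(L = 2\) for \([-1, 1]\) images. The loss gradient uses the
closed-form derivative of the SSIM map with respect to the synthetic image,
verified against finite differences in the tests.

## Preprocessing

The preprocessing chain mirrors what a clinical pipeline would do before
slice-wise inference:

1. **In-plane resampling** to 1 × 1 mm (`resample_inplane()`), bilinear on a
   voxel-center grid: an input of in-plane extent \((n-1)s\) mm yields
   \(\lfloor (n-1)s \rfloor + 1\) voxels, so a 2 mm grid of \(H\) voxels
   becomes \(2H - 1\). This convention is stated because the output shape
   depends on it.
2. **Rigid co-registration** (`rigid_register()`): in-plane rotation +
   translation minimizing mean squared intensity difference over a central
   window, coarse grid search then Nelder–Mead refinement, applied to the
   slice-averaged image and propagated to all slices. The T2-w volume is
   treated as the fixed image. Registration is implemented in-package so the
   pipeline has no binary dependency; `misalign()` provides ground-truth
   transforms for parameter-recovery tests (0.5°/0.5 mm tolerance).
3. **Intensity capping and scaling** (`cap_and_scale()`): intensities are
   clipped at the 1st and 99th percentile — computed per volume with the
   linear-interpolation percentile convention — and mapped affinely to
   \([-1, 1]\). Per-volume (rather than per-slice or per-cohort)
   normalization is the assumption here; the returned
   `normalization_record` inverts the scaling for display. A constant
   volume maps to all zeros with a degenerate flag rather than dividing by
   zero.
4. **Slice extraction** (`extract_sagittal_slices()`): one record per
   sagittal index, two input channels and one target channel.

Augmentations during training: horizontal flips and small rotations applied
identically to inputs and target; Gaussian smoothing and additive noise
applied to the input channels only — the target is the ground truth being
regressed and should not be corrupted. (Whether intensity augmentations
should also touch the target is genuinely open; inputs-only is this
package's choice.)

## The phantom

`make_phantom()` emulates the *statistical structure* the model must learn,
not anatomy: stacked vertebral bodies and discs flanked by cord, CSF,
paravertebral fat and muscle, each tissue a three-compartment signal source
(fat fraction, fluid fraction, base signal). Per-contrast signal is a fixed
linear mixture:

| contrast | fat | fluid | base |
|---|---|---|---|
| T1 | 1.00 | 0.20 | 0.60 |
| T2 | 0.80 | 1.00 | 0.50 |
| T2FS | 0.00 | 1.00 | 0.50 |

The fat weight of zero for T2FS makes fat suppression exact by
construction, and the identical fluid/base weights for T2 and T2FS make the
two contrasts equal on fat-free voxels — both properties are asserted as
invariants in the tests. The linear mixture is chosen for analytic
testability, not biophysical fidelity: no relaxation-time physics, no
scanner or coil effects, no metal artifacts, and no 3-D spinal curvature.
Consequently a model that passes the phantom learning oracle has
demonstrated the mechanics of conditional fat-suppression synthesis, not
clinical image quality.

Pathologies are ellipsoids clipped to their parent structure (the simplest
shape supporting extent computation), with an edema flag that swaps fat for
fluid inside the mask — bright on both T2-w contrasts, iso-to-dark on T1-w.
Grades follow the six-pathology clinical schema: bone-marrow abnormalities
0–4 (absent / focal / one-third / two-thirds / whole body),
spondylodiscitis 0–3 by thirds, Modic type 1 and cord lesions
present/absent, fractures acute (edema) vs chronic, paravertebral
abnormalities by category. The schema names thirds but not the
focal-vs-one-third boundary; this package places "focal" below 10% of the
vertebral body, a documented choice. Severity-to-grade mapping is monotone
in lesion extent, and scene generation is bit-reproducible from its seed.

Default generator conditions used by the reference experiments: 64 × 64
in-plane, 10 sagittal slices, 4 vertebrae, acquisition noise sd 0.02 on
unit-scale signals, 200 training slice pairs, 25 epochs.

## Simulated readers and the statistics layer

`simulate_readers()` emulates the two-protocol reading experiment: each
reader misgrades a finding with a kind-specific probability, moving to an
adjacent legal grade (the plausible clinical confusion). Under the
two-sequence protocol (no fat saturation) fluid-sensitive findings carry a
0.30 error probability (fractures 0.15); with the synthetic contrast added
the error probability drops to 0.10 for everything. These rates are the
package's study conditions — chosen once to put simulated agreement in the
moderate-to-substantial range reported for human readers — and are not
fitted to any published number.

`summarize_study()` pools both readers' gradings as independent rows per
pathology (the pooling rule is a documented choice; per-reader kappas
averaged would be the alternative) and computes:

- **Cohen's kappa** (unweighted — the grades are treated as categorical, not
  ordinal) with the large-sample standard error
  \(\sqrt{p_o(1-p_o)/(n(1-p_e)^2)}\) for a 95% CI.
- **Accuracy** as exact grade agreement with ground truth.
- **Wilcoxon signed-rank** across the six pathology-wise kappa pairs: zero
  differences discarded, mid-ranks for ties, asymptotic two-sided normal
  p-value *without* continuity correction. This convention is part of the
  contract: on the published kappa pairs it yields p = 0.043, while exact
  enumeration of the 32 sign assignments yields 0.0625. Both are exposed
  (`method = "asymptotic"` / `"exact"`).
- **McNemar's test** per pathology on paired correctness indicators: exact
  two-sided binomial for fewer than 25 discordant pairs, else
  continuity-corrected chi-square; zero discordance gives p = 1 by
  convention.

No multiple-testing correction is applied, and 0.05 is the significance
threshold throughout, mirroring the evaluation design the statistics
reproduce.

## Numerical choices and degenerate inputs

- Percentile convention: linear interpolation between order statistics
  (type 7), so `{0, ..., 100}` has p1 = 1, p99 = 99 and the midpoint maps to
  exactly 0.
- BCE is computed in a numerically stable logit formulation inside the
  training loop; the public loss functions take post-squashing scores in
  (0, 1) and reject anything outside.
- Registration refuses constant images ("registration undefined") and
  evaluates its objective on a central window so border fill-in cannot bias
  the optimum.
- Kappa is flagged undefined when chance agreement is 1 (both raters
  constant and identical); Wilcoxon when all differences are zero.
- All randomness flows from explicit seeds through `derive_seed()`, a
  stable integer hash that decouples stages: consuming more random numbers
  in one stage never shifts another stage's stream.

## Limitations

- The phantom's realism ceiling (above) bounds what passing tests show
  about clinical data; the model's clinical value was established on
  patient images and human readers, which this package does not ship.
- Registration is rigid and in-plane; deformable motion and through-plane
  rotation are out of scope.
- The reader error model is symmetric and adjacent-grade only; real readers
  have asymmetric, experience-dependent confusions.
- Checkerboard-type synthesis artifacts are mitigated (nearest-neighbour
  upsampling + convolution rather than transposed convolution) but not
  studied here.

## Reproducing the reference numbers

```{r, eval = FALSE}
# mean kappas and Wilcoxon p from the published per-pathology pairs
aggregate_kappa_pairs(reference_kappa_pairs())

# the desk-scale learning oracle
ds <- phantom_slice_dataset(n_slices = 200, seed = 1)
fit <- train(ds, train_config(epochs = 25, seed = 1), verbose = TRUE)
plot_training_history(fit$history)
```

`scripts/acceptance.R` runs both, plus the registration-recovery and
cap/scale contracts, and writes all quantities as JSON.
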