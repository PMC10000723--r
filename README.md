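# spinefs

Synthetic T2-weighted fat-saturated (T2-w fs) spine MRI from conventional
contrasts, with the statistics to measure whether it helps.

T2-w fs sequences suppress the adipose signal so fluid and edema stand out —
which is exactly what grading bone-marrow edema, spondylodiscitis,
inflammatory (type 1) Modic changes, acute fractures, cord lesions and
paravertebral abnormalities depends on. In routine practice the sequence is
often missing. `spinefs` implements:

- a **conditional adversarial network** that synthesizes a T2-w fs slice
  stack from a co-registered (T1-w, non-fs T2-w) pair: U-Net generator,
  patch discriminator conditioned by channel concatenation, and the joint
  generator loss

  *Loss<sub>G</sub> = (1 − SSIM(real, synthetic)) + λ · BCE(1, D(synthetic))*,  λ = 50,

  trained with Adam (2 × 10⁻⁴) for 25 epochs, slices in random order each
  epoch. Networks, backprop (including the analytic SSIM gradient) and the
  training loop are implemented in-package over compiled convolution
  kernels — no deep-learning framework required;
- the **preprocessing chain**: in-plane resampling to 1 × 1 mm, in-plane
  rigid registration (MSE, grid search + Nelder–Mead), 1st/99th-percentile
  capping and scaling to [−1, 1], sagittal slice pairing;
- a **multi-compartment spine phantom** (fat / fluid / base signal per
  tissue; fat weight zero on T2FS) with graded pathologies and ground-truth
  grades, plus simulated readers, so everything trains and tests at desk
  scale without patient data;
- the **agreement statistics** of a two-protocol reader study: unweighted
  Cohen's κ with 95% CI, exact-match accuracy, Wilcoxon signed-rank on
  pathology-wise κ pairs (zero-discard, asymptotic), and McNemar's test on
  paired correctness — the protocol comparison layer of
  `summarize_study()`.

Audience: researchers in medical image synthesis and evaluation who want a
fully inspectable, deterministic reference implementation of the
SSIM-plus-adversarial synthesis recipe and its reader-agreement evaluation.

## Worked example

Aggregate the published per-pathology κ pairs of the reference reader study
(bundled as `inst/extdata/reader_study_reference.csv`) into protocol means
and the protocol comparison:

```r
library(spinefs)
agg <- aggregate_kappa_pairs(reference_kappa_pairs())
agg$mean_kappa
#>       two_sequence synthetic_protocol
#>          0.5633333          0.6450000
round(agg$wilcoxon$p_value, 3)
#> [1] 0.043
```

Mean κ against consensus ground truth rises from 0.56 (reading T1-w and
non-fs T2-w only) to 0.65 once the synthetic fat-saturated contrast is
added, and the Wilcoxon signed-rank test across the six pathology-wise κ
pairs puts the difference at p = 0.043 — the fluid-sensitive findings are
graded more reliably with the synthetic contrast on the screen.

Generate a phantom with a pathology and read off its ground-truth grades:

```r
sc <- make_phantom(seed = 8, shape = c(64, 64, 10), n_vertebrae = 4,
                   pathology_spec = list(list(kind = "modic_type1", severity = 1)))
grade_from_scene(sc)
#> # A tibble: 6 × 2
#>   kind                       gt_grade
#>   <chr>                         <int>
#> 1 bone_marrow_abnormality           0
#> 2 spondylodiscitis_expansion        0
#> 3 modic_type1                       1
#> 4 vertebral_fracture                0
#> 5 cord_lesion                       0
#> 6 paravertebral_abnormality         0
```

Train at desk scale and synthesize a held-out volume:

```r
ds  <- phantom_slice_dataset(n_slices = 200, seed = 1)   # 200 paired 64x64 slices
fit <- train(ds, train_config(epochs = 25, seed = 1), verbose = TRUE)
#> ...
#> epoch 25  G 34.9319 (ssim 0.1992, adv 34.7327)  D 1.3903

t1 <- cap_and_scale(render_contrast(sc, "T1",   0.02, seed = 8))$volume
t2 <- cap_and_scale(render_contrast(sc, "T2",   0.02, seed = 8))$volume
fs <- cap_and_scale(render_contrast(sc, "T2FS", 0.02, seed = 8))$volume
res <- synthesize_volume(t1, t2, fit$checkpoint, reference = fs)
res$mean_ssim   # held-out volumes reach ~0.83 at these settings
plot_slices(res$volume)
```

The structural-dissimilarity term of the generator loss falls from ~0.98 to
~0.20 over 25 epochs while the discriminator hovers near 2·ln 2 ≈ 1.386
(patches indistinguishable), and held-out synthetic volumes reach a
volume-mean SSIM above 0.8 against the true phantom T2-w fs — with fat
regions correctly suppressed relative to the input T2-w.

A full phantom-to-report pipeline (simulate → preprocess → train →
synthesize → simulate readers → evaluate, with per-stage caching) is
available as `run_end_to_end(pipeline_config(...))`, and a thin CLI over the
same functions ships in `inst/cli/spinefs`.

## Package layout

| where | what |
|---|---|
| `R/phantom.R`, `R/readers.R` | phantom scenes, contrast rendering, misalignment, grading, simulated readers |
| `R/preprocess.R` | resampling, registration, cap/scale, slice pairing |
| `R/ssim.R`, `R/network.R`, `R/losses.R`, `R/train.R` | SSIM (+gradient), networks, losses, training loop |
| `R/synthesis.R` | slice-wise volume synthesis and SSIM evaluation |
| `R/kappa.R`, `R/stat-tests.R`, `R/summarize.R` | κ, accuracy, Wilcoxon, McNemar, study reports |
| `R/pipeline.R` | end-to-end pipeline with caching |
| `src/` | compiled conv/pool/resampling kernels |
| `vignettes/spinefs-methods.Rmd` | model, assumptions, parameter choices, limitations |
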