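# csvdseg

Segmentation of the four conventional-MRI signs of cerebral small vessel
disease (CSVD) — lacunes, white matter hyperintensities (WMH), recent small
subcortical infarcts, and cerebral microbleeds — with one compact 2D U-Net
per sign, plus everything required to exercise the pipeline end to end
without clinical data.

CSVD severity is still mostly graded by hand on MRI, which is slow and
reader-dependent. The pipeline implemented here follows the
four-segmentor design used for automated CSVD masking: each disease has its
own encoder–decoder network reading only the sequences the sign is visible
on (infarcts from DWI b1000, WMH from T2-FLAIR, microbleeds from
T2*-weighted GRE, lacunes from T1 + FLAIR), trained independently and
combined so that WMH, lacune and infarct labels are mutually exclusive at
the voxel level.

The package is aimed at method developers: every stage is a tested, seeded,
reusable function, and a synthetic phantom generator stands in for the
private clinical cohorts such pipelines are normally trained on.

## What is inside

* **Phantoms** — `generate_study()` / `generate_cohort()` render
  three-compartment ellipsoidal brains in all four sequences and carve in
  lesions following the standard radiological contrast table (e.g. lacunes
  CSF-like hypointense on T1, infarcts hyperintense on DWI), with
  diameters inside the clinical ranges (lacune 3–15 mm, infarct ≤ 20 mm,
  microbleed 2–10 mm), in-plane spacing 0.36–1.44 mm and slice spacing
  6–8 mm.
* **Preprocessing** — `pad_to_square()`, `resize_slice()`, and
  `normalize_wm()`, which aligns the white-matter histogram peak on a
  reference value with a purely multiplicative map (exactly invariant to
  global intensity rescaling).
* **Segmentors** — `segmentor_spec()`, `build_unet()`, `train_segmentor()`,
  `predict_volume()`. The U-Net (3×3 conv + ReLU encoder blocks with 2×2
  max-pooling, transpose-convolution decoder with skip connections, sigmoid
  1×1 head) and its full backward pass are implemented in the package with
  RcppArmadillo. Training accuracy is mean per-slice Dice, and training
  stops by the overfitting rule *train > 0.98 and train − val > 0.15*,
  returning the best-validation weights.
* **Combination** — `combine_masks()` subtracts infarct from WMH, raw
  lacune from WMH, and infarct from lacune, guaranteeing pairwise-disjoint
  masks; microbleeds are never touched.
* **Evaluation** — `dice()`, `patch_dice()` (max-pooled patch grids),
  `region_f1()` (lesion-level detection scores on connected components),
  `froc_curve()`, and `evaluate_cohort()`, which returns tidy tibbles with
  per-patient rows and per-class/overall aggregates.
* **Pipeline commands** — `cmd_simulate()`, `cmd_train()`, `cmd_predict()`,
  `cmd_evaluate()`, plus a shell dispatcher at
  `inst/cli/csvd-dls.R` (`simulate | train | predict | evaluate`).

## The metrics, precisely

For predicted and reference voxel sets P, R:

* Dice = 2|P∩R| / (|P| + |R|), per patient, arithmetic-mean aggregated.
* Patch Dice: both masks are discretized into square patches (a patch is
  positive iff ≥ 1 pixel is positive — a max-pooling), then Dice is taken
  on the patch grids; patch edge ≈ √(image edge). At patch = image it
  degenerates to presence/absence agreement.
* Region F1: connected components (8-conn in 2D, 26-conn in 3D) matched by
  any overlap; precision = TP/(TP+FP), recall = TP/(TP+FN), F1 their
  harmonic mean.

## Worked example

```r
library(csvdseg)

# a reproducible 8-patient phantom cohort, every class present
cfg <- phantom_config(grid_shape = c(8L, 64L, 64L),
                      in_plane_spacing_range = c(1, 1), seed = 42)
cohort <- generate_cohort(cfg, 8, positive_fractions = c(
  LACUNE = 1, WMH = 1, INFARCT = 1, MICROBLEED = 1))

# train the infarct segmentor (DWI b1000 -> mask) on a tiny U-Net
spec <- segmentor_spec("INFARCT", depth = 2L, base_channels = 8L,
                       input_size = 64L, max_epochs = 25L, seed = 1)
fit <- train_segmentor(spec, cohort)
glance(fit$state)
#> # A tibble: 1 × 6
#>   epochs train_accuracy val_accuracy best_val_accuracy best_epoch stopped
#>    <int>          <dbl>        <dbl>             <dbl>      <int> <lgl>
#> 1     25          0.962        0.968             0.978         23 FALSE

# predict a held-out phantom and score it
new <- generate_study(phantom_config(grid_shape = c(8L, 64L, 64L),
                                     in_plane_spacing_range = c(1, 1),
                                     seed = 77))
pred <- predict_volume(fit$model, new$study)
dice(pred$values, new$truth$masks$INFARCT$values)
#> [1] 0.9295775
```

`glance()` summarizes the run: after 25 epochs the mean per-slice Dice is
0.96 on the training slices and 0.97 on held-out-patient validation slices
(empty-vs-empty slices count as 1), the stop rule has not fired, and the
returned weights are those of the best validation epoch (23). The final
call scores the whole predicted 3D mask of an unseen phantom against its
ground truth — Dice 0.93 here.

## Scope notes

Inputs are assumed co-registered (NIfTI, one grid per patient); phantom
realism is deliberately minimal — see the methods vignette
(`vignettes/csvdseg-methods.Rmd`) for the model, its assumptions, parameter
meanings and limitations.
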