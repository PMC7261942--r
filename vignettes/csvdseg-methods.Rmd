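---
title: "Methods: phantom-validated deep segmentation of cerebral small vessel disease"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-validated deep segmentation of cerebral small vessel disease}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Cerebral small vessel disease (CSVD) shows up on conventional brain MRI as
four segmentable signs: lacunes (3–15 mm CSF-like cavities, hypointense on
T1), white matter hyperintensities (WMH, variable confluent extent,
hyperintense on T2-FLAIR), recent small subcortical infarcts (≤ 20 mm,
hyperintense on DWI b1000), and cerebral microbleeds (2–10 mm, hypointense
on T2*-weighted GRE). Quantifying lesion load currently relies on manual
reading, which is slow and subjective. `csvdseg` implements a four-segmentor
pipeline — one compact 2D U-Net per sign, each reading only the sequences the
sign is visible on — together with everything needed to exercise it without
clinical data: a synthetic phantom generator, preprocessing, mask
combination, and an evaluation suite.

The package is organized so that real NIfTI studies and synthetic phantoms
flow through the same code path; the phantoms exist so every contract in the
pipeline is testable on a laptop.

## Phantom model

`generate_study()` renders a three-compartment ellipsoidal brain — a white
matter core, a gray matter shell, and two CSF ventricle ellipsoids — in all
four sequences, with per-compartment base intensities chosen so the
orderings match each contrast (CSF dark on T1/FLAIR/DWI, bright on T2*; WM
the dominant compartment by volume in every sequence). Lesions are carved in
afterwards: each (class, modality) pair has a contrast direction from the
standard radiological table, and lesion voxels are set to 0.35× (hypointense),
1.6× (hyperintense) or 1.0× (neutral) the white matter base value — except
lacunes, whose hypointensity is rendered at the CSF level (0.2× WM on T1),
the "CSF-like" signature that distinguishes them from the plain T1
hypointensity of acute infarcts — before
i.i.d. Gaussian noise (`noise_sd`, default 5 intensity units against a WM
level of 200–300) is added.

Ambiguous "hypointense-or-neutral" entries of the table are resolved to a
single deterministic direction (NEUTRAL) per pair so that tests are exact;
the table is a plain configuration matrix and any entry can be overridden.

Lesion footprints are pixel-exact ellipses: the maximal in-plane extent in
pixels is chosen so that extent × in-plane spacing always lies inside the
class's diameter range (lacune 3–15 mm, infarct ≤ 20 mm, microbleed
2–10 mm). WMH footprints are unions of 2–4 overlapping blobs, emulating
confluent irregular lesions, and carry no diameter constraint. In-plane
spacing is drawn from 0.36–1.44 mm and slice spacing from 6–8 mm, the ranges
conventional stroke-protocol MRI occupies; with 6–8 mm between slices most
lesions live on one slice (infarcts may span two).

What the phantoms deliberately do **not** emulate: anatomy beyond the
three-compartment ellipsoid, partial volume effects, bias fields, k-space
artifacts, or scanner-specific intensity statistics. A model that segments
phantoms well has demonstrated that the pipeline's plumbing, routing,
normalization and optimization work — not that it generalizes to clinical
MRI. All quantitative claims in the tests are claims about phantoms.

## Preprocessing

Slices are zero-padded to square (content centered, exactly invertible),
resized to the network input size (bilinear for intensities, nearest
neighbor for masks so they stay binary), and the volume is intensity-scaled
so its white-matter histogram peak lands on a reference value (default 1).

Peak detection builds a 256-bin histogram of above-background voxels. For T1
and DWI — where white matter sits among the brightest compartments — the peak
is the highest-count bin in the upper half of the above-background range;
for FLAIR and T2* the global mode is used, since white matter dominates by
volume. A `tissue_hint` mask can override the heuristic. The map is
multiplicative only (no offset), which preserves the zero background and
makes the operation exactly invariant under global rescaling of the input —
the property that makes scans from different scanners comparable. Whether
histogram alignment should be multiplicative, affine or piecewise was an
open choice; multiplicative is the fixed one here because it is the smallest
map with the invariance the tests demand.

## Segmentors

Each class gets its own U-Net via `segmentor_spec()`:

| class | input sequences |
|---|---|
| INFARCT | DWI b1000 |
| WMH | T2-FLAIR |
| LACUNE | T1 + T2-FLAIR |
| MICROBLEED | T2*-GRE |

Lacunes are identified as CSF-like hypointensities on T1 with FLAIR as the
reference sequence; whether the network should see FLAIR at all is
ambiguous, so the default is the two-channel variant with
`input_modalities = "T1"` available as a switch.

The architecture is the standard encoder–decoder: `depth` levels of two 3×3
convolutions + ReLU followed by 2×2 max-pooling, channels
`base_channels · channel_growth^level` (growth 2 by default), a two-conv
bottleneck, transpose-convolution upsampling with skip connections, and a
1×1 sigmoid head. Layers are implemented in the package with
RcppArmadillo (im2col + BLAS matmul, analytic backward passes) and verified
against finite differences in the test suite.

**Accuracy.** The training/validation "accuracy" is defined as mean
per-slice Dice of thresholded predictions (empty-vs-empty slices score 1).
Pixel accuracy would sit at ≈ 1 for any model because lesions occupy ~1% of
pixels, which would make an accuracy-based stopping criterion fire
immediately; mean Dice keeps it meaningful.

**Stopping rule.** Training halts when training accuracy exceeds 0.98 while
diverging from validation accuracy by more than 0.15 — i.e. when overfitting
is demonstrable. The divergence is directional (`train − val > 0.15`), and
because the rule fires *after* overfitting sets in, the returned model
carries the weights of the best-validation epoch, not the final epoch.

**Loss.** The default loss is soft Dice plus binary cross-entropy (`"SUM"`).
Pure soft Dice is offered but not default: on cohorts where ~75% of slices
carry no lesion it can collapse to all-empty predictions, and once the
sigmoid saturates the Dice gradient (which carries a `p(1−p)` factor)
underflows to exactly zero, freezing training irrecoverably. The
cross-entropy term is computed in logit space, where its gradient `p − y`
never vanishes, so a collapsed model can always recover. Optimization is
Adam (`learning_rate` default 1e-3) with everything — weight initialization
(He-normal), the patient-level train/validation split, and batch shuffling —
derived from `spec$seed`, so runs are bit-reproducible.

Two further stabilizers address the extreme foreground sparsity (~1% of
pixels): the cross-entropy weights lesion pixels by the batch's
background/lesion ratio (capped at 50), and every minibatch is guaranteed
about a third lesion-bearing slices (forced-foreground sampling), so no
update is pure background pressure. Training under this landscape is still
bistable — a run can settle into the all-empty local optimum — so the
trainer checks the best-validation model's Dice on lesion-bearing
validation slices and deterministically restarts with a shifted
initialization seed (up to twice) if it is near zero. A step decay (×0.3
over the last quarter of the epoch budget) sharpens small-lesion
boundaries.

Scale invariance across the in-plane spacing range can be pursued with the
opt-in `augment_zoom_range` random-resize augmentation; the desk-scale tests
fix the spacing instead and leave it off.

## Mask combination

WMH, lacune and infarct can claim the same voxels (an acute infarct looks
like WMH on FLAIR), so the final output subtracts, in order: infarct from
WMH, then the *raw* lacune mask from WMH, then infarct from lacune.
Microbleeds live on T2* and are never modified. The raw-vs-cleaned lacune
ambiguity turns out to be vacuous: any lacune voxel the cleaning removes
lies in the infarct mask and has already left WMH in the first subtraction,
so both orders produce identical output — the package exposes the flag
anyway and a property test asserts the equivalence. After combination the
three masks are pairwise disjoint, total positive voxels never increase, and
the operation is idempotent.

## Evaluation suite

* **Dice** per patient and class, `2|P∩R|/(|P|+|R|)`, with both-empty pairs
  scoring 1 and flagged; whether such patients enter the class means is a
  switch (default: included), since evaluation cohorts contain
  class-negative patients.
* **Patch-wise Dice**: both masks are max-pooled over square patches (a
  patch is positive if any pixel is) and Dice is computed on the patch
  grids, forgiving localization errors smaller than a patch. The default
  patch edge is `round(sqrt(image edge))`; at edge 1 it equals pixel Dice,
  and with the patch equal to the image it degenerates to presence/absence
  agreement — the multi-label classification limit.
* **Region-wise F1**: connected components (8-connectivity in 2D,
  26-connectivity in 3D; volumes are scored in 3D by default since 6–8 mm
  slice gaps rarely merge lesions) are matched by any-overlap: a predicted
  blob covering two reference lesions scores two true positives and no
  false positive. A greedy one-to-one matcher is available as an option.
* **FROC**: lesion sensitivity and false-positive component counts across
  probability thresholds. Sensitivity is provably non-increasing in the
  threshold and is property-tested; the false-positive count usually falls
  too but can transiently rise when a shrinking component splits, so it is
  not asserted.
* Cohort aggregates are unweighted arithmetic means over patients within
  class. The overall row is reported **both** as the mean of class means and
  as the pooled mean over patient-class pairs, because published summaries
  rarely state which convention they use.

All four metric families are checked exactly against independent brute-force
oracles (set counting, pure-R flood fill, double-loop max-pooling,
exhaustive overlap matrices) on hundreds of random masks.

## Problem sizes and numerical choices

The desk-scale study conditions used throughout the tests and the
acceptance script: 8-slice 64×64 phantoms at 1 mm in-plane spacing (so the
native slice matches the 64 px network input and no resampling error enters
the recovery experiments), noise SD 5, cohorts of 24 training and 5–8
evaluation patients, U-Nets of depth 2 with 8 base channels trained up to
40 epochs with batch size 8. Under these conditions each class's tiny U-Net
recovers held-out phantom lesions with mean Dice ≥ 0.6 — a deliberately
scaled-down stand-in for training on clinical cohorts, not a reproduction
of any clinical figure.

Other fixed numerical choices: binarization threshold 0.5; soft-dice
smoothing epsilon 1e-6; histogram bins 256; background threshold 0 (the
padded border); bounded lesion-placement retries (60) before a placement
error; ReLU subgradient 0 at the kink; Adam β = (0.9, 0.999), ε = 1e-8.

## Known limitations

* Phantom realism is intentionally minimal (see above); recovery scores on
  phantoms say nothing quantitative about clinical MRI.
* The segmentors are 2D and see each slice independently, as the wide slice
  spacing of the target protocols suggests; volumetric (3D-convolution)
  variants are out of scope.
* Inputs are assumed co-registered; no registration is performed and grid
  mismatches are rejected rather than resolved.
* Training at clinical scale (hundreds of 256×256 volumes, deeper networks)
  is outside the intended envelope of the pure-R/Rcpp training loop, which
  is sized for reproducible desk-scale experiments.
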