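---
title: "Slice-wise lung segmentation in CT: models, phantoms, and evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Slice-wise lung segmentation in CT: models, phantoms, and evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

## The problem

Segmenting the left and right lung in thoracic CT is a prerequisite for most
downstream quantitative lung analysis. Thresholding-style methods work well on
aerated lung (around -700 HU, in high contrast to the surrounding soft
tissue), but fail exactly where segmentation matters clinically: dense
pathologies such as pleural effusion, consolidation, atelectasis, or tumours
push lung-field intensities up into the soft-tissue range. `thoraxseg`
implements a deliberately generic alternative: a vanilla encoder–decoder
semantic segmentation network applied slice by slice, trained so that dense
anomalies are *included* in the lung target, together with the evaluation
machinery (volumetric overlap and surface distances) and a synthetic thorax
phantom generator that makes the whole pipeline testable and trainable
without any clinical data.

The package's working hypothesis — which the built-in diversity experiment
probes at desk scale — is that segmentation quality on pathological cases is
governed far more by the *diversity of the training data* than by the choice
of architecture.

## Conventions

All volumes live in memory as `(z, y, x)` arrays under the LPS anatomical
convention: x grows toward the patient's Left, y toward Posterior, z toward
Superior. Label 1 is the right lung (lower x), label 2 the left lung, and the
trachea is excluded from both. NIfTI files in any orientation are reoriented
on read; DICOM series (explicit/implicit VR little endian, single series per
directory) are rescaled to HU via the slope/intercept tags.

## The pipeline

1. **Body crop** (`crop_to_body`): threshold at -500 HU, binary closing with
   a 2-voxel ball, largest 6-connected component, tight 3-D bounding box
   plus a 2-voxel margin. One box per volume, not per slice, so all slices
   of a scan share their geometry. The threshold and radii were chosen to
   separate body from air and the patient table on phantoms and typical CT;
   table removal relies solely on the largest-component step.
2. **Intensity normalisation** (`normalize_slice`): clip to the window
   [-1024, 600] HU, map linearly to [0, 1].
3. **Rescale** (`resize_slice`): anisotropic stretch to the network input
   size (256 × 256 by default), bilinear for images and nearest-neighbour
   for labels. Stretching (rather than letterboxing) keeps the inverse
   mapping trivial; its geometric distortion is identical at train and test
   time and therefore harmless to the network.
4. **Per-slice prediction** and **back-projection**
   (`backproject_mask`): predicted label slices are resized back into the
   bounding box (nearest-neighbour) and placed in the original grid, with
   background outside the crop. Evaluation always happens on the
   reassembled 3-D volumes.
5. **Cleanup**: largest 6-connected component per lung label; components
   below 0.5 % of the foreground are dropped. `relabel_left_right()` then
   enforces the labelling convention positionally: each component takes
   the side of the body midline its centroid falls on, and a single fused
   component spanning the midline is split there. This makes whole-volume
   results robust to a model that has learned the lung boundary but not
   yet a stable left/right assignment — a real failure mode of very small
   training profiles. Optional `remove_dense_areas()` deletes mask voxels
   with HU strictly inside (-50, 70) and repairs with an anti-extensive
   opening — useful only for comparison against ground truths that
   exclude dense pathology, and off by default.

## Architectures

`build_model()` provides two variants. `unet` is the classic
encoder–decoder with skip connections, the single adaptation being batch
normalisation after every convolution (conv → BN → ReLU). `resunet`
additionally adds an identity (or 1×1-projected) residual connection around
each down- and up-sampling double-convolution block. Up-sampling uses
learned 2×2 transposed convolutions; decoding is softmax + argmax. The
engine is written in C++ (single precision, im2col + BLAS GEMM) and trains
on a single CPU.

The full-size profile is base width 64 and depth 4 as in the original
design. Most of this vignette's examples and the test suite use reduced
profiles (base width 16 at 128×128, or base width 8 at 64×64). One caveat
discovered while sizing the reduced profiles: distinguishing left from
right lung requires a bottleneck receptive field that covers most of the
slice, because the two lungs are locally near-identical and the network
must use its distance-to-border context. At 64×64, depth 4 (bottleneck
4×4) learns laterality reliably while depth 3 often does not; the reduced
profiles therefore keep depth 4.

## Training regime

Mini-batches are stratified: 14 slices, of which exactly 7 contain lung and
7 do not, so the network sees abundant negative anatomy even in
lung-dominated cohorts. An epoch covers the majority stratum once in a
seeded permutation; the minority stratum is resampled with replacement.
Augmentation applies, to image and label jointly, a random rotation
(±10°), a smooth deformation field (Gaussian displacements, sd 2 px, on a
4×4 control grid, bilinearly upsampled), and, to the image only, Gaussian
noise (sd 0.02 in normalised units). The optimiser is plain SGD with
momentum 0.9 on per-pixel cross-entropy; a Dice loss is deliberately not
used, keeping the models "vanilla". The default learning rate is 0.01;
the bundled 128×128/base-16 example uses 0.02 and the small
64×64/base-8 experiment profile uses 0.1 — on the high-contrast phantoms
the small profile spends most of its optimisation escaping the
all-background basin induced by class imbalance, and the larger rate cuts
that phase several-fold without observed instability.
Validation splits are by *case* (15 % by default), never by
slice, to avoid leakage between neighbouring slices; the best-validation
checkpoint is returned. One master seed drives cohort sampling, batch
order, augmentation and weight initialisation, and training is
single-threaded, so runs are reproducible bit for bit.

Divergence (non-finite loss) aborts with a diagnostic rather than
returning a silently broken model.

## The synthetic thorax phantom

`generate_phantom()` builds, on a configurable grid (default 16 × 96 × 96
voxels at 5 × 1.8 × 1.8 mm — a thick-slice routine-CT-like geometry), a
soft-tissue body ellipsoid, two lung ellipsoids, a heart, a tubular
trachea (air, excluded from the lung target), and a vertebral column.
The anatomy is deliberately chiral, as a real thorax is: the heart sits
left-anterior and carves a cardiac notch out of the left lung, and the
right lung is wider and shorter. Without such cues a left/right-labelling
network has only its distance-to-border context to tell the sides apart,
which small training profiles learn late and unreliably. Habitus, lung
size and position vary per case (a few percent each) so that a model
cannot simply memorise where lungs sit on the grid — coverage of dense
pathology must be appearance-driven, which is precisely what the
diversity experiment measures. Intensities are drawn per tissue class (air
-1000 HU, lung -740 ± 40, soft tissue 40 ± 15, bone 600 ± 120) with
additive global noise (sd 20 HU). Per case, at most one pathology is drawn
from the spec's mix:

* **effusion** — a dependent dense layer (10 ± 15 HU) replacing the caudal
  portion (25–40 %) of one lung, kept inside the lung ground truth;
* **consolidation** — a dense intra-lung blob (40 ± 20 HU), in the ground
  truth;
* **tumour** — a sphere of 8–25 mm diameter at or near the pleural border
  (30 ± 20 HU), in the ground truth; specs whose grid cannot contain it are
  rejected with a sizing error;
* **pneumothorax** — an air crescent between a collapsed lung and the chest
  wall; pleural air is *not* lung and is excluded from the target.

The default mix (40 % none, 20 % each effusion/consolidation/tumour)
emulates an edge-case-enriched training cohort. Cranial and caudal slices
deliberately contain body but no lung so stratified batching is always
exercisable.

What the phantom does **not** emulate: airway trees, vasculature, fibrosis
texture, beam hardening, streaks, scanner/kernel variation, or anatomical
shape variability beyond jittered ellipsoids. Consequently, passing the
phantom-based tests demonstrates that the pipeline's machinery (geometry,
learning dynamics, metrics, the direction of the diversity effect) is
correct — it does not certify clinical segmentation accuracy, and effect
sizes measured on phantoms need not match clinical effect sizes.

## Evaluation

Metrics are computed on the 3-D volumes, per lung label, then averaged
across the two lungs (`evaluate_case`); a whole-lung mode merges the
labels for comparison against single-label methods.

* **DSC** = 2|X∩Y| / (|X|+|Y|). Empty-vs-empty is defined as 1 (perfect
  agreement), empty-vs-non-empty as 0.
* **HD95**: surfaces are 6-neighbourhood border voxels; distances are
  Euclidean between voxel centres in mm using the full anisotropic
  spacing (no isotropic resampling). Each directed value is the 95th
  percentile (linear interpolation between order statistics, R's type 7)
  of nearest-surface distances; the symmetric value is the max of the two
  directions.
* **MSD**: directed mean nearest-surface distance; the symmetric form is
  the **maximum** of the two directed means by default. The more common
  convention averages them; `msd(..., convention = "mean")` provides it.
  The max convention is the package's reference behaviour and is what the
  acceptance checks use; the switch exists because both conventions occur
  in the literature and they differ on asymmetric errors.
* Undefined distances (empty prediction against non-empty truth) are
  reported as `NA`, excluded from aggregates and counted, rather than
  silently imputed.
* Implementation note: nearest-surface distances come from an exact
  anisotropic Euclidean distance transform (separable lower-envelope
  algorithm) evaluated at the other surface's voxels. The test suite
  checks it against an independent brute-force all-pairs oracle to
  1e-9 mm.

Cohort comparisons use classical two-sided paired t-tests on per-case
values (`paired_t`); zero-variance differences are an error, not a p-value.

## The diversity experiment

`run_diversity_experiment()` is a desk-scale replica of the central
training-data-diversity comparison: equal-size cohorts that differ only in
pathology mix, identical architecture and training, one shared
pathology-rich test set, and paired t-tests between cohorts on per-case
DSC. The default design (`default_diversity_design()`) uses two cohorts —
pathology-free versus mixed-pathology — with n = 16 cases each, a U-net at
base width 8, depth 4 on 64×64 slices, 20 epochs at learning rate 0.1,
12 shared test cases, and 3 replicate seeds. These sizes are the package's
chosen desk-scale study conditions: large enough that the mixed-trained
model demonstrably learns to include dense lesions (its coverage of
consolidation and tumour voxels is several-fold that of the
pathology-free-trained model) while staying runnable on one CPU in
minutes. Training and test seeds are drawn from disjoint streams and
asserted disjoint.

One desk-scale limitation deserves emphasis: at 64×64 with a base width
of 8, inclusion of *effusion* — a fluid layer whose outer boundary is a
subtle ~30 HU step against the chest wall — is learned too slowly to
carry signal within this budget, so the default test mix weights the
intra-lung lesion types (consolidation, tumour) that the profile does
learn, and keeps only a small effusion share. Only the *direction* of the
diversity effect is claimed to replicate; magnitudes on phantoms are not
interpretable clinically. The architecture-marginality observation
(U-net versus ResU-net differing far less than cohorts differ) can be
reproduced by adding `"resunet"` to `variants`; it is reported, not
hard-asserted.

## Numerical and design choices worth knowing

* Surfaces and components use 6-connectivity throughout.
* `crop_to_body` on an all-air volume raises "no body found" rather than
  guessing.
* `relabel_left_right` splits a single fused component at the sagittal
  midline of the body bounding box, conserving voxel count; with separate
  components it enforces one label per component by majority vote and
  keeps the largest component per side.
* Batch-norm inference uses running statistics, so predictions are
  batch-size invariant; the suite asserts a slice predicted alone equals
  the same slice inside a batch.
* Weight initialisation is He-normal, drawn from R's RNG so `set.seed()`
  reproduces models exactly.
* Checkpoints embed the architecture; loading into a mismatched
  architecture is an error.
* Volumes are written as int16 clipped to [-1024, 3071] HU, masks as
  uint8, both with LPS geometry in the NIfTI header.

## Known limitations

* The DICOM reader is minimal by design: uncompressed little-endian CT
  slices, one series per directory, axial identity orientation. Anything
  else should be converted to NIfTI first.
* Phantom realism limits are listed above; in particular the phantom
  cannot probe scanner/kernel appearance variability, one of the real
  sources of domain shift.
* Training is CPU-bound and single-threaded; the full 256×256 / base-64
  profile is provided and functional but impractical to train on one CPU.
* The per-slice design cannot use 3-D context; this mirrors the reference
  pipeline's field-of-view flexibility argument, not a claim of
  optimality.
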