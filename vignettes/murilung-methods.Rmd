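---
title: "Detecting murine lung nodules in micro-CT: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting murine lung nodules in micro-CT: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

murilung implements an automated pipeline for finding lung nodules in
micro-CT scans of mice: lung segmentation, training-data augmentation by
synthetic tumor insertion, a volumetric convolutional detector, and
detection scoring. This vignette explains the models behind each stage, the
parameters that matter, and the design decisions taken where the problem
left the design open.

## Images, units and geometry

All volumes are 3-D scalar grids in Hounsfield units (HU) with isotropic
spacing; axis order is x (left-right), y (ventral-dorsal), z
(cranio-caudal), and the voxel at index `(i, j, k)` (1-based in R) is
centered at `origin_mm + (index - 1) * spacing_um / 1000`. The HU scale is
the standard affine normalization of linear attenuation,

$$X_{HU} = 1000\left(\frac{X - \mu_{air}}{\mu_{water} - \mu_{air}} - 1\right),$$

so air maps to -1000 HU and water to 0 HU regardless of the scanner's
absolute attenuation calibration. For synthetic work the default
calibration is $\mu_{water} = 0.02\,\mathrm{mm}^{-1}$, $\mu_{air} = 0$;
only the ratio structure of the formula matters, and real calibrations can
be supplied anywhere a `hu_calibration` is accepted.

Every anatomical criterion in the pipeline (lung volumes, minimum nodule
volumes) is expressed in cubic millimetres computed from the spacing, never
in voxel counts. This lets the test suite run at coarser spacings
(150-300 µm) than a real scanner (63 µm) without changing any threshold.

I/O is NIfTI-1 (optionally gzipped) through RNifti. Anisotropic headers are
rejected unless the caller explicitly requests resampling; nothing is ever
silently reinterpreted. Mask resampling interpolates linearly and
re-binarizes at 0.5 — deterministic and consistent with how smoothed masks
are treated elsewhere in the pipeline.

## The digital thorax phantom

The phantom generator is first-class, tested code: it defines the study
conditions under which every downstream stage is validated, without any
real scan. A phantom contains background air at -1000 HU, an elliptical
soft-tissue body (clamped to 100-300 HU with a smooth low-frequency
variation), two lung lobes as randomly deformed ellipsoids at -500 HU,
recursive random branching vessel trees inside the lungs (0-150 HU, radius
decaying per generation), a spine and rib arcs above 300 HU, an air-filled
cradle channel connected to the volume border, and a small intestinal gas
pocket. Additive Gaussian noise (default sigma 25 HU) is applied last.

The defaults (150 µm spacing, 160 x 160 x 200 grid, 600 mm³ total lung
volume split into two ~300 mm³ lobes) were chosen so that each lobe clears
the 200 mm³ per-region acceptance floor of the segmentation stage while the
whole phantom stays desk-scale; the noise level is typical of
bilateral-filtered micro-CT lung protocols. The vessels exist specifically
to create nodule-like bright confounders inside the lungs — the known
dominant failure mode of detection in this imaging regime. The cradle and
gas pocket exist to exercise the segmentation rejection rules (border
connectivity, volume and mean-HU bounds).

What the phantom does *not* emulate: beam hardening, scatter, respiratory
motion, anatomically exact murine airway/lobe anatomy, and contrast-agent
kinetics. Tests passing on phantoms therefore validate the *mechanics* of
the pipeline (geometry, reconstruction, statistics, learning dynamics), not
clinical-grade performance on real mice.

Tumor templates are synthetic metaball blobs — unions of overlapping random
ellipsoids, Gaussian-smoothed, re-thresholded and rescaled to a target
volume — standing in for a bank of manually segmented real tumors. Each
template is guaranteed to be a single 26-connected component. Template
intensity statistics default to soft-tissue-like values (mean 30 HU, SD
40 HU) and are configurable, since no reliable HU statistics exist for the
real nodules being emulated.

## Lung segmentation

Segmentation is rule-based: threshold at -175 HU (below soft tissue and
bone, above lung parenchyma), morphological closing then opening with a
ball element, 26-connected region analysis, and selection by three
rejection criteria:

1. a region connected to the background air around the animal is rejected
   (this removes the cradle air);
2. the region's mean HU must lie in the closed interval [-600, -175]
   (pure-air regions are far darker);
3. the region's volume must lie within [200, 1200] mm³.

If more than two regions survive, regions are ranked by the distance
between the two k-means centers of their voxel coordinates and the top two
are kept: lungs have two distinct centers of mass, and the k-means
separation is large either for a single region containing both lobes or for
elongated lung-like shapes. Design choices where the procedure was open:

* *Background air* is defined as the union of 6-connected sub-threshold
  components containing volume-border voxels; criterion 1 tests
  26-adjacency to that set.
* The structuring element radius defaults to 0.25 mm: larger than vessel
  cross-sections (so closing re-includes vasculature and nodules in the
  mask), smaller than the inter-lobe gap (so the two lobes stay separate).
* k-means uses k = 2 with 10 seeded restarts; a split whose smaller cluster
  holds under 25 % of the voxels is not "two groups of similar size" and
  scores a separation of zero.
* With exactly one or two survivors the k-means ranking is not applied —
  the left and right lungs legitimately appear as two separate components.
* The mean-HU interval is read as closed, [-600, -175].

Failure is explicit: if no region survives, `segment_lungs()` raises a
"no lung found" error rather than returning an empty mask.

## Synthetic tumor insertion

Training data are augmented by inserting synthetic tumors into (here:
phantom) scans through the projection domain, which reproduces the
reconstruction-induced blur and sampling structure a real inserted lesion
would have:

1. **Augment**: each template receives a uniform random SO(3) rotation, a
   random shear (off-diagonal elements up to ±0.2 — the problem statement
   bounds neither the shear model nor its magnitude, so "skew" is realized
   as a linear shear with a conservative bound), and an isotropic scale
   chosen so the output volume follows the calibrated size law below.
2. **Retexture**: the warped mask is filled with Gaussian noise at the
   template's intensity statistics, lightly smoothed and renormalized to
   the exact target mean/SD; the binary mask is Gaussian-smoothed
   (default edge sigma 0.15 mm) into soft blend weights so composited
   tumors have no abrupt gray-value step.
3. **Place**: candidate centers inside the working lung mask are drawn with
   probability proportional to the inverse Euclidean distance to the
   nearest mask boundary (clamped at half a voxel so boundary voxels keep
   finite weight) — murine lung tumors favour lung boundaries. A position
   is accepted only if at most 10 % of the tumor's voxels (fraction of
   binary mask voxels, the most literal reading) fall outside the lung mask
   and none overlap a previously placed tumor; accepted tumors are carved
   out of the working mask, so subsequent tumors preferentially cluster
   around them.
4. **Insert in the projection domain**: with $A$ the cone-beam forward
   projector, the edited projections are
   $p' = p + A(w \cdot \mu_{tumor}) - A(w \cdot \mu_{original})$, where $w$
   are the soft blend weights and $\mu$ denotes attenuation. Because HU is
   affine in attenuation, this equals an alpha blend
   $(1-w)\,\mathrm{orig} + w\,\mathrm{tumor}$ performed before projection;
   the voxel-domain blend (`compose_voxel()`) is retained as the reference
   against which the projection route is validated.
5. **Reconstruct** with FDK, apply bilateral filtration, then one random
   magnification drawn uniformly from ±10 % and a crop to the lung bounding
   box padded by 30 voxels per side.

The **size distribution** of augmented tumors is a log-normal with median
0.65 mm³ and 90th percentile 10 mm³, clipped to [0.03, 70] mm³. A
log-uniform law over the full range cannot satisfy those quantiles
simultaneously (its median would be 1.45 mm³ and only ~75 % of draws fall
below 10 mm³), so the calibrated log-normal — which reproduces the median,
the 90th percentile and, through clipping, the full range — is used.

The default dataset recipe generates 60 sets of 2 tumors each with 13 sets
held out for training validation; all counts are configurable, and the test
suite uses smaller counts.

## Cone-beam projection and FDK reconstruction

The projector is ray-driven (Joseph-style): for each view the source
rotates in the axial plane at the source-isocenter distance, and each
detector pixel integrates trilinearly interpolated attenuation at
half-voxel steps along the source-pixel ray, after clipping the ray to the
volume's bounding box. The operator is linear in attenuation, and an
all-air volume projects to zero.

Reconstruction is Feldkamp-Davis-Kress filtered backprojection:
projections are rescaled to a virtual detector through the isocenter,
cosine-weighted by $sod/\sqrt{sod^2 + u'^2 + v'^2}$, row-filtered with the
discrete Ram-Lak ramp (with the standard factor ½ of the fan-beam
convolver, FFT-based with 4x zero padding; an optional Hann window is
provided since the original filter choice is not documented), and
backprojected with $(sod/L)^2$ distance weighting. The implementation is
quantitative: on a 64³ sphere phantom with 180 views the reconstructed
interior attenuation is correct to well under 1 %, and the projector
matches analytic chord-length integrals within 2 %.

Default desk geometry: source-object 200 mm, source-detector 400 mm
(magnification 2), detector pitch matched to `voxel x magnification`, and a
detector sized to cover the projected volume at every angle — these
distances affect only the cone angle and are freely configurable; 360 views
over 360° remains the full-scale default. A warning (not an error) is
issued when the view count is far below the angular demand of the grid.

The bilateral filter is the brute-force windowed form with spatial scale in
mm (default 0.2 mm) and range scale in HU (default 150 HU), radius
2.5 sigma capped at 5 voxels.

## The volumetric detector

The detector is a V-Net-style fully convolutional encoder/decoder,
implemented from first principles in this package (C++ kernels for the
convolutions, analytic backpropagation verified against finite
differences):

* 5 x 5 x 5 convolutions, each followed by batch normalization, PReLU, and
  dropout at rate 0.01;
* stages at successive resolutions; each stage's convolution block is
  wrapped in a residual connection;
* 2 x 2 x 2 stride-2 down-convolutions between encoder stages; 2 x 2 x 2
  stride-2 transposed convolutions in the decoder;
* skip connections concatenating each encoder stage's output into the
  matching decoder stage;
* a final 1 x 1 x 1 convolution to one channel with a sigmoid, so the
  output is a probability map in [0, 1] of the input's spatial shape.

The exact trainable parameter count is reported by `build_vnet()`. The
full-scale configuration (5 stages, channels 8-16-32-64-128, one to three
convolutions per stage, 96³ patches) mirrors the original V-Net design; a
total parameter budget in the millions does not uniquely determine the
per-stage widths, so they are configuration, not constants. The tested
desk-scale profile is 2 stages, channels 4-8, one convolution per stage,
32³ patches.

Training uses a soft Dice loss $1 - 2|P \cap T| / (|P| + |T|)$ computed on
the sigmoid output (both-empty defined as Dice 1), Adam with initial
learning rate 0.01 and $\beta_1 = 0.9$ (the natural reading of "momentum
0.9" for Adam), batch size 3 (2 in the desk profile), and a learning-rate
decay of x0.9 every 100 steps. Patches are sampled so that 80 % contain at
least one label voxel — tumors are rare, and biased sampling keeps the
gradient signal alive — with left-right flips (augmentation in the coronal
plane) at probability 0.5, and intensities divided by 1000 (HU is already a
calibrated scale, so full standardization is unnecessary). For full-scale
data, volumes are resampled from the native 63 µm to 100 µm first; the
desk profile trains at the phantom's native spacing and sets
`resample_um = NULL`. Label masks follow the same linear-interpolation +
0.5-threshold resampling as all other masks.

Four training strategies are provided: simulated-only (one network trained
once on all simulated training sets), real-only and combined (one network
per cross-validation fold; combined adds the full simulated training set to
each fold's real training data), and transfer (the simulated-only weights
initialize a per-fold retraining on real data). Folds are balanced random
partitions: every scan is in exactly one test set. In fully synthetic work,
phantom-derived sets stand in for the "real" arm.

Inference is stitched sliding-window prediction: overlapping patches at a
configurable stride (default 12), per-voxel mean over all covering patches,
edge patches clamped to the volume, batch-norm running statistics in
evaluation mode.

Numerical notes: He initialization, PReLU slopes initialized at 0.25,
batch-norm epsilon 1e-5 with momentum-0.9 running statistics, Adam epsilon
1e-8, soft-Dice epsilon 1e-6. Training is single-threaded and bit
deterministic given the seed.

## Detection evaluation

Post-processing of a probability map: zero outside the lung mask, binarize
at the decision threshold, 26-connected component labeling, and rejection
of components below 0.15 mm³ (the smallest nodule the modeled scanner
images reliably). A label counts as detected if any detection overlaps it
(*direct hit*) or any detection's centroid lies within 1.5 x the label's
equivalent sphere radius $r = (3V/4\pi)^{1/3}$ of the label centroid
(*near hit*); detections matching no label are false positives; multiple
detections on one label add no extra TP or FP; a detection overlapping two
labels credits both and is no FP. Precision $TP/(TP+FP)$, recall
$TP/(TP+FN)$ and the detection Dice $2TP/(2TP+FP+FN)$ follow; degenerate
denominators are reported as 0 with a warning rather than NaN.

The operating threshold is chosen by sweeping a grid (default step 0.01)
and locating the precision-recall intersection by linear interpolation of
$P - R$ between adjacent grid points; if the curves never cross, the
threshold maximizing the detection Dice is returned with a warning. On
plateaus where $P = R$ over a range (perfect predictions), the first
intersection point is reported.

A detection task has no true negatives, so no textbook ROC exists. The
ROC-like curve reported here plots recall against a *pseudo-FPR*: the FP
count normalized by its maximum over the sweep, with (0,0) and (1,1)
anchors and a monotone upper-hull staircase for the trapezoidal AUC. These
AUCs are internally consistent but must not be compared with AUC values
computed under other FPR conventions. One concrete consequence: a
label-independent chance detector does not score 0.5 here but roughly half
its chance recall, because recall (not a TP *rate* over a fixed negative
class) caps the curve height; the perfect detector still scores exactly 1.

Size-binned detection rates use bins with edges 0.15, 0.25, 0.5, 1 and
5 mm³ and an open top bin (the decision-relevant sizes in this problem);
empty bins are NA, and the edges are configurable.

## Problem sizes used by the test suite

The suite validates every stage at desk scale: phantoms of 96³-200³ voxels
at 150-300 µm, 120-180 view projections on 48³-96³ grids, 10⁴-draw
statistics for the augmentation and patch-sampling laws, and detector
training runs of ~120 steps on 32³ patches (channels 4-8) with three seeds
for the learning check. These sizes were chosen as the smallest at which
each property is genuinely informative; all full-scale settings (5 stages,
96³ patches, 360 views, 63 µm) remain available through configuration.

## Known limitations

* The phantom's realism is structural, not radiometric: no scatter, beam
  hardening, motion, or detector blur.
* The k-means "two distinct centers of mass" rule is implemented as a
  ranking key; the original weighting scheme is not quantified anywhere.
* Whether a single detection near-hitting two labels should double-count
  is undocumented; this implementation credits both labels.
* The pseudo-FPR AUC is a documented substitute, not a reproduction, of
  ROC analysis for this no-true-negative task.
* DICOM series I/O is not provided; the package reads and writes NIfTI
  only.
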