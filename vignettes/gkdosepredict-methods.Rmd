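---
title: "Isodose-aware plan-quality prediction for Gamma Knife radiosurgery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isodose-aware plan-quality prediction for Gamma Knife radiosurgery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(GKDosePredict)
```

## The problem

Gamma Knife (GK) radiosurgery treats brain metastases with many converging
beams delivered as "shots" at chosen isocentres through 4, 8 or 16 mm
collimators. Plan quality is judged through a small set of volume ratios
derived from the 100% and 50% prescription isodose surfaces:

* coverage = |TV ∩ PIV| / |TV|
* selectivity = |TV ∩ PIV| / |PIV|
* gradient index GI = |PIV~0.5Rx~| / |PIV|
* intermediate dose spillage CI50 = |PIV~0.5Rx~| / |TV|

where TV is the target volume, PIV the volume receiving at least the
prescription Rx, and PIV~0.5Rx~ the volume receiving at least half of it.
What counts as a *good* value of selectivity or GI depends strongly on the
size and shape of the lesion, so absolute thresholds are poor quality
gates. This package implements a lesion-level regression approach: a 3D
network maps the patient geometry (a label volume marking tumor and skull)
to the dose distribution a clinically accepted plan would achieve, and the
plan-quality metrics computed from that predicted dose serve as a
patient-specific reference against which a proposed plan can be judged.

Because the ratios above are read off two specific isodose surfaces, the
training objective augments a voxelwise weighted MSE with smoothed-Dice
penalties that act exactly on those surfaces:

$$\mathrm{Loss} = \mathrm{wMSE} + \alpha\,D_{1.0} + \beta\,D_{0.5},
\qquad
D_a = \frac{\sum_i (\sigma(p_i - a) - \sigma(t_i - a))^2}
           {\sum_i (\sigma(p_i-a)^2 + \sigma(t_i-a)^2)},$$

with $\sigma(x) = 1/(1+e^{-kx})$ a steep sigmoid ($k = 1000$ on the
fraction-of-Rx scale), $p$ and $t$ the predicted and reference doses
normalized by Rx, and weights $\alpha = 100$, $\beta = 10$. The wMSE
weights voxels at or above Rx in the reference dose by 8 and all other
tumor-space voxels by 1. When every voxel sits away from a threshold the
smoothed term equals one minus the hard-threshold Dice coefficient of the
two isodose surfaces; near the surface it is differentiable, which is what
lets gradients pull the predicted isodose line onto the reference one.
Setting $\alpha = \beta = 0$ with uniform weights recovers the
conventional MSE baseline (`mseBaselineConfig()`), which the evaluation
battery uses as the comparator.

## Training samples: tumor spaces

Each lesion becomes one training sample: a cubic crop (128³ voxels at
0.5 mm by default) centred on the tumor centroid. The regression target is
the clinical dose divided by Rx and zeroed below 30% of Rx — the "tumor
space". The 30% level is the practical compromise: the metrics need the
50% surface with context, a lower threshold would inflate the sample size,
and 30% of the highest prescription used in this setting (25 Gy, giving
7.5 Gy) stays below the lowest cranial organ-at-risk tolerance (8 Gy to
2 cc of the optical pathway), so the crop is clinically safe to reason
about. The input channel is a label volume coded 2 for tumor, 1 for
skull, 0 elsewhere; it is *truncated* from patient-level masks rather than
masked by any isodose region, so it can be built for new patients whose
dose does not exist yet. The skull channel lets the network distinguish
superficial from deeply seated lesions, whose dose falloff patterns
differ.

Two label-code decisions were genuinely open. In-body soft tissue that is
neither tumor nor skull is coded 0, the same as outside-body background:
the three-code scheme keeps the skull distinguishable, which is its stated
purpose, and a separate body code would add an input channel the
architecture does not call for. Overlapping tumor and skull labels resolve
to tumor. Both choices are configurable at the `buildInputMask()` surface.

Cohort hygiene follows two exclusion filters. `filterNearOAR()` excludes
a lesion only when an organ at risk intersects its tumor space *and* that
organ's clinical dose endpoint exceeds half its tolerance (brainstem
lesions whose prescription was already reduced to tolerance are retained
via an explicit exception flag). `filterAdjacent()` flags lesion pairs
whose dose fields overlap at the prescription or half-prescription level,
where PIV attribution — hence selectivity and GI — becomes ambiguous.

## The synthetic phantom

The clinical cohort behind this method is not publicly available, so the
package ships a seeded generator (`phantomSpec()`, `generateCohort()`)
that emulates its envelope and provides ground truth with *known*
metrics:

* lesions are randomly oriented ellipsoids with axis ratios in [0.6, 1]
  and volumes drawn log-uniformly over 14.875–5995.875 mm³ (the
  published cohort range); the distribution shape inside that range is a
  stand-in, not a claim about any clinical population;
* prescriptions come from the clinical 12–21 Gy menu, with larger lesions
  biased toward lower prescriptions;
* dose is a superposition of isotropic Gaussian kernels, one per shot,
  with FWHM equal to the collimator diameter (4/8/16 mm; the scale is
  configurable). Shots are packed greedily, largest collimator first, at
  jittered grid positions where the half-maximum ball fits inside the
  target;
* a single global weight factor is calibrated so that the 1st percentile
  of in-target dose equals Rx (`coverage_target = 0.99`), reproducing the
  near-universal ≥ 99% coverage of accepted clinical plans;
* a spherical skull shell (inner radius 70 mm, 5 mm thick) is placed at a
  sampled lesion depth, so superficial cases carry skull signal in the
  window.

The Gaussian kernel is the simplest model with GK-like steep falloff; it
reproduces realistic coverage/selectivity/CI50 ranges and, for isolated
shots, admits the closed-form oracle used throughout the tests: the
v-level isodose of a peak-P shot is a sphere of radius
$\sigma\sqrt{2\ln(P/v)}$. What it does *not* reproduce: beam-channel
anisotropy, sector blocking, tissue heterogeneity, or the planner-to-
planner variability of real clinical plans. Phantom GI values can dip
below the clinical minimum when a kernel's peak-to-Rx ratio is large;
range *overlap* with the published envelope is therefore the honest check
the tests apply, not range equality. Passing on phantoms shows the
machinery learns shot-composed Gaussian dose patterns; it cannot certify
clinical accuracy.

## Network

The regressor is a hierarchically densely connected 3D U-Net: encoder
levels alternate *dense convolutions* (each concatenating
`growth_rate = 16` newly computed features onto the carried tensor) and
*dense down-samplings* (strided convolution adds 16 features while the
carried features are max-pooled); the decoder's *U-Net up-sampling*
returns `upsample_features = 64` features (channel-reducing convolution
followed by nearest-neighbour doubling — a transposed-convolution
equivalent) concatenated with the same-level skip tensor, followed by a
dense convolution; a final convolution with ReLU enforces the
non-negative single-channel dose output. All convolutions are 3³ with
zero padding; dropout (rate 0.10) follows each dense convolution block;
the input is the raw 0/1/2 label volume as a single channel. The number
of levels is not part of the published architecture description; the
default is 5 for 128³ inputs (an 8³ bottleneck) and 3 for the 32³
configuration used in the reduced-scale experiments.

No deep-learning framework exists in this package's dependency
footprint, so the forward and backward passes are implemented directly in
compiled code (`src/hdunet.cpp`): direct 3³ convolutions as
cache-resident saxpy/dot sweeps, exact max-pool argmax bookkeeping, and
Adam updates. Gradient correctness is established by central
finite-difference tests on a double-precision instance; training uses
single precision for speed. Construction is audited at build time: the
per-layer channel counts must match the dense-growth arithmetic
(`expectedFeatureCounts()`), and the parameter count is a pure function
of the configuration.

## Training schedule and augmentation

The reference schedule (`trainConfig()`) is ten-fold cross-validation, 80
epochs per fold of 200 batches of size 2, Adam starting at 0.001 with the
learning rate multiplied by 0.93 every 200 batches. Epoch sampling draws
without replacement from a reshuffling queue, so the training data are
seen approximately once per epoch. The optimizer is not part of the
published description; Adam with standard moments (0.9/0.999) is the
package's choice and is recorded in every checkpoint's provenance.

Augmentation (`augmentPolicy()`) respects the 8-fold rotational symmetry
of the GK source sectors: with probability 0.75 a sample is augmented by
exactly one of an integer translation or a rotation about the
superior–inferior axis drawn from the eight multiples of 45°, followed by
a left–right flip with probability 0.5. No elastic or affine deformation
is ever applied — deforming a dose field would silently change the very
metrics the model is trained to get right. The translation bound is not
published; the default ±10 voxels (±5 mm) keeps the tumor inside the
window and is resampled when it would not. Masks are resampled
nearest-neighbour (integer codes), doses trilinearly. Grid-preserving
isometries (flips, 90° rotations, integer translations) permute voxels
and therefore leave all four metrics *exactly* unchanged — a property the
tests assert — while 45°-family rotations perturb them only at the
interpolation level (≤ 2% for lesions above the smallest volume group).

## Evaluation battery

`evaluatePredictions()` computes per-lesion records: metric values for
truth and prediction, signed errors (predicted − truth, coverage in
percentage points), absolute errors, and Dice scores of the 100% and 50%
isodose surfaces. Lesions are stratified into four volume groups whose
boundaries are the volumes of spheres with collimator diameters — 33.5,
268.1 and 2144.7 mm³ for 4, 8, 16 mm — using lower-inclusive half-open
intervals. Group tables report MAE ± SD and mean ± SD; `boxStats()`
returns median/mean/quartiles with whiskers at 1.5 × IQR.
`pairedWilcoxon()` implements the signed-rank test with zeros discarded,
an exact dynamic-programming null for n ≤ 25 (valid under tied ranks),
and a tie-corrected normal approximation beyond; `compareMethods()` runs
the two-sided battery on signed errors and the one-sided battery on
absolute errors, per group and overall, without multiplicity correction
(none is part of the reference analysis).

## Numerical choices

* Isodose thresholds are inclusive (≥), matching "receiving at least".
* Volumes are voxel counts times voxel volume; no sub-voxel surface
  estimation. For very small lesions this granularity visibly moves
  coverage — one reason the smallest volume group is the hardest.
* The sigmoid exponent is clamped at ±60 (unchanged saturated values in
  double precision); the Dice denominator guard is 1e−7, returning a
  zero loss for degenerate all-subthreshold fields.
* The loss averages over all N = edge³ voxels of the sample including
  zero padding; a mask-restricted sum is a configuration away but the
  padded convention is the default because the tumor space definition
  already zeroes the outside.
* Doses are stored pre-normalized by Rx, so the conventional 1/Rx²
  factor in the wMSE is identically absorbed (set to 1); normalization
  happens exactly once, in `extractTumorSpace()`.
* Crop centring rounds the centroid half-values toward the lower index;
  lesions whose 30% isodose exceeds the window are clipped with a counted
  warning rather than rejected.
* Weight initialization is the standard He-scaled normal with zero
  biases. One consequence deserves flagging: at the reduced scale of the
  packaged experiments, the plain-MSE baseline reliably suffers
  permanent die-off of its ReLU output head — early optimization of a
  mostly-zero target drives every output pre-activation negative, after
  which no gradient flows and the model predicts zero dose everywhere.
  The composite objective does not share this fate: its up-weighted
  in-target voxels and steep isodose terms keep enough gradient on the
  head. Non-standard rescues were explored (non-negative "half-normal"
  head weights revive the baseline impressively) but they destabilize
  the 50%-isodose fitting of the composite arm on small lesions, so the
  standard initialization is kept for both arms and the baseline's
  collapse is reported as an observed property of plain-MSE training at
  this scale, not hidden by a bespoke initialization. Comparisons
  against the baseline in the packaged checks should be read with this
  in mind.
* Training arithmetic is single precision with float denormals flushed
  to zero (gradients shrink exponentially through the layer stack and
  denormal stalls would dominate runtime); the finite-difference
  gradient checks run a double-precision instance of the same kernels.

## Reduced-scale study conditions

The full-scale schedule is far beyond a desk-scale test budget, so the
package's empirical self-checks run a scaled-down version of the whole
pipeline, chosen once as follows and used by both the test suite and the
acceptance script: a seeded phantom cohort of 200 lesions on 32³ grids at
0.5 mm (volumes 14.875–120 mm³, collimators 4 and 8 mm, prescriptions
14–18 Gy, depths 3–10 mm), an 80%/20% train/held-out split, a 3-level
network with growth 4 and 8 up-sampling features, 10 epochs of batch-2
training with the standard learning-rate schedule, and the standard
augmentation policy with a ±2-voxel translation bound. On these
conditions the checks assert the *directional* claims: training loss
falls by at least half, and the composite objective is no worse than the
plain-MSE baseline on held-out 50%-isodose Dice and CI50 error — the
scaled analogue of the full study's finding that enforcing isodose
agreement most helps the metrics derived from the 50% surface.

## Known limitations

* The phantom's dose model is a Gaussian superposition; absolute metric
  levels (especially GI for hot plans) can leave the clinical envelope.
* The DICOM reader handles axial little-endian RT-Dose grids only; it is
  an adapter for conventional exports, not a general DICOM
  implementation. RT-Struct contour rasterization is out of scope: masks
  enter as volumes.
* Containers are directory stores (NIfTI + JSON manifest) rather than a
  single binary file; the layout is self-describing and versioned by the
  manifest `kind` field.
* Training at full 128³ scale is functional but sized for accelerator
  budgets, not for routine CPU use; the compiled kernels cache one
  sample's activations at a time.
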