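---
title: "Atlas-based 2D/3D registration with projective spatial transforms: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atlas-based 2D/3D registration: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(prostreg)
```

## The problem

A pair of calibrated radiographs (an anterior-posterior and a roughly lateral
view) is often all the 3D information available for orthopaedic planning.
`prostreg` registers a 3D atlas volume -- a reference femur CT with a label
map -- to such a biplanar pair: it regresses a spatial transformation under
which the atlas, projected through each view's cone-beam geometry, matches the
radiographs.  Because the output is a deformation of the atlas rather than a
free-form reconstruction, implausible shapes are discouraged and any
annotation defined on the atlas (labels, landmarks, density calibration) can
be transported to the patient by the same warp.

The transformation is decomposed into a global affine pose `T` (seven
parameters: three rotations, three translations, one isotropic log-scale, all
acting about the isocentre) followed by a local diffeomorphic deformation
field `phi`.  Both are produced by one feed-forward network, so registration
at inference time is a single pass, not an iterative optimisation.

## Projective and inverse-projective transforms

The geometric heart of the package is a pair of resampling operators linking
the volume grid ("physical space") with a ray-aligned grid ("beam space"):

* **ProST** (`prost()`): for a calibrated geometry -- LAO/RAO angle,
  cranio-caudal angle, source-detector distance (SDD, default 1000 mm),
  source-isocentre distance (default 925 mm), detector size and pixel pitch --
  a canonical grid of `Sx x Sy x K` points is laid out with `K` samples
  uniformly spaced in depth along each ray from the source to a detector pixel
  centre.  The geometry transform rotates this grid about the isocentre, and
  the volume is interpolated trilinearly at the rotated points.  Summing over
  the ray axis and scaling by the depth increment (`project()`) gives a
  cone-beam line-integral radiograph (`drr()`).
* **inv-ProST** (`inv_prost()`): each voxel centre is mapped to its fractional
  beam coordinates -- the detector intersection (i, j) of the ray through the
  voxel and the depth index k of the voxel's distance from the source -- and
  the beam-space volume is interpolated there.  Voxels outside the cone are
  exactly zero.  Applying inv-ProST after ProST reproduces the volume up to
  interpolation error inside the cone (the round-trip NRMSE on a smooth
  in-cone phantom is a few percent at beam-space resolution comparable to the
  voxel grid).

Both operators are gathers with trilinear weights followed by sums, hence
linear in the voxel values and differentiable by construction; the package
implements their forward passes and exact adjoint/backward passes, verified
against finite differences and against explicitly assembled matrix forms.

Intensities are monoenergetic line integrals: no spectrum, no scatter, no
Beer-Lambert exponentiation.  The network consumes min-max normalised images,
so the overall projection scale is immaterial; whether the ray sum is scaled
by the sample spacing is a flag (`scaled`, default on).

### Geometry conventions and defaults

World coordinates are in mm, right-handed, origin at the isocentre; volumes
are centred on the origin; axis 1 is the patient's lateral axis, axis 2
anterior-posterior, axis 3 cranio-caudal.  Positive LAO/RAO angle rotates the
source counter-clockwise about the cranio-caudal axis viewed from the
patient's head; the canonical (0 deg) source lies on the +y axis.  These
conventions, and the following quantities the source publication leaves open,
are fixed here as configuration with defaults:

* **K (samples per ray)**: default equal to the largest volume dimension, so
  beam-space depth resolution matches the voxel grid.
* **Depth window**: centred on the isocentre distance with length equal to
  the diagonal of the volume bounding box (`geometry_for_volume()`), which
  covers the whole volume at any rotation.
* **Detector pixel pitch**: chosen at construction so the detector field of
  view covers the magnified volume (magnification SDD/iso ~ 1.081 at the
  defaults), overridable.
* **Angle handedness**: as stated above; `write_geometry()`/`read_geometry()`
  serialise all of it to YAML/JSON.

## Warping machinery

Displacement fields are stored in mm on the volume grid, backward convention:
the output voxel at x samples the input at x + u(x).  `integrate_velocity()`
turns a stationary velocity field into a diffeomorphic displacement by
scaling and squaring (`u <- u + u o (Id + u)`, default 7 squarings; 6 in the
tiny preset).  Field-on-field compositions clamp to the boundary value rather
than reading zeros outside, which keeps the flow well-behaved near the edges.
`jacobian_determinant()` provides the standard diffeomorphism diagnostic.

The seven-parameter pose is `Translate(t) R(angles) exp(s) Id` about the
volume centre: a rigid femur pose plus isotropic scale for size variation --
the natural minimal model behind "seven parameters", and its zero vector is
the identity.  The network's total field is the displacement form of
"affine first, then local": `Psi(x) = T^{-1}(x + phi(x)) - x`, so a single
resampling of the atlas by `Psi` reproduces the two-stage warp up to one
interpolation.  (A literal sum of the two displacement fields is not a valid
composition.)  `phi` lives on the grid of the affine-warped atlas -- the
local module's input space.

## Network

The affine module projects the atlas through both geometries, pairs each
projection with the corresponding input radiograph as a 2-channel image, and
encodes each pair with a strided-convolution/batch-norm/leaky-ReLU encoder
(features double as resolution halves).  At every level the AP and LAT
features are concatenated with the running combined map (average-pooled from
the previous level) and convolved -- disabling this intermediate fusion is the
"two separate affine encoders" ablation switch.  A dense layer regresses the
seven pose parameters.  Two implementation choices matter here:

* the dense head is zero-bias, narrow-normal (sd 1e-4), so the initial pose
  is the identity;
* the raw outputs pass through a scaled tanh (defaults +-15 deg per rotation,
  +-6 mm per translation, +-0.08 log-scale at tiny scale -- a margin beyond
  the +-10 deg / +-4 mm pose prior of the training data).  Bounding the pose
  matters twice: an unbounded head can throw the atlas fully off the volume
  early in training, where the image term goes flat and Adam's drift diverges
  irrecoverably; and the bounds are tight enough that even a saturated pose
  keeps the atlas overlapping the target, so the correlation gradient never
  vanishes and training can recover from saturation.  Within the bounds the
  parameterisation is unchanged and the initial transform is still identity.

The local module is a pair of U-shaped networks, one per view: a 2D encoder
(strided + non-strided conv per level) over the (projected warped atlas,
radiograph) pair; the final 2D map is copied M times along the ray axis
(M = 4 at full scale, 2 in the tiny preset) and decoded by stride-1 3D
convolutions with nearest-neighbour x2 upsampling (feature schedule
[64, 32, 32, 16, 16, 16] at full scale).  Upsampling in beam space has a
geometric meaning: the ray axis gains samples per ray, the in-plane axes gain
rays.  Skip connections copy each 2D encoder map along the ray axis to the
matching decoder resolution, pass it through conv/batch-norm/leaky-ReLU and
concatenate.  When the input size is not a power-of-two multiple of the
coarsest map, per-axis integer upsampling factors are distributed over the
steps by the shape algebra in `local_plan()` (checked at build time).

Each view's decoded beam-space feature map is carried into physical space by
inv-ProST (out-of-cone voxels zeroed), the two views are concatenated, and a
3x3x3 convolution (narrow-normal init) fuses them into a 3-channel stationary
velocity field, integrated to `phi`.  Like the pose, the velocity is bounded:
`v = b tanh(raw/b)` (b = 8 mm in the tiny preset, 20 mm at full scale, both
comfortably above the deformations the data contain), which is the identity
map near zero but prevents an aggressive optimisation step from inflating the
flow beyond the grid.  Ablation switches mirror the structural
variants studied at full scale: `skip_connections`, `dual_decoders` (off =
per-level concatenation with a single shared decoder; its single beam-space
output is referred to the AP geometry), and `use_inv_prost` (off = the beam
map is resampled onto the volume grid with no ray geometry).

Batch size is 1 throughout, so batch normalisation normalises each channel
over its spatial locations; inference applies the same computation, making
it deterministic without running statistics.

## Training loss

With a ground-truth target volume `V_f` available (the semi-supervised
regime: label maps are used to mask the images, not in the loss),

```
L = -NCC(V o T, V_f) - NCC(V o Psi, V_f) + delta * smoothness(phi)
```

with `delta = 0.01`.  NCC is the global zero-normalised cross-correlation
computed over the whole volume.  The volumes entering the network are already
masked (zero background), which makes the plain global statistic informative;
restricting it to a thin dilated-label region was tried and abandoned -- once
the warped atlas slides off that region the masked statistic has zero
variance, its gradient vanishes, and training cannot recover.  The smoothness
term is the mean squared forward-difference gradient of `phi` summed over
channels; a translation costs nothing.  The loss is bounded below by -2,
attained only at a perfect double match with a gradient-free field.

Optimisation is Adam, batch 1, with two stabilisers: global gradient-norm
clipping (1.0) and, for affine-only training, evaluation of the image term on
a stride-2 voxel subgrid -- the pose is a global 7-parameter quantity, and the
subsampled NCC estimator carries the same signal at an eighth of the
sampling cost.  Training and inference are deterministic given the seed.

At full scale the reference regime is 300 epochs at lr 1e-5.  The tiny preset
uses lr 1e-3 as its default; the bundled demonstrations train in two stages:
an affine-only stage with warm-up plus decay
(`lr = c(rep(1e-3, 5), rep(3e-3, 30), rep(1e-3, 15))`), then a local stage at
3e-3 with the affine parameters frozen (`freeze = "^aff_"`) and the
best-validation-Dice parameters kept.  The staging reflects the model's own
decomposition -- the local module's input is the affine-warped atlas, so it
trains on sensible inputs from its first step -- and freezing isolates the
local module's contribution, which at desk scale is small compared to the
epoch-to-epoch noise of joint training.

## Synthetic phantom data

Real training data for this problem are femur-centred, masked angio-CT
volumes.  The generator stands in for them with an analytic femur-like solid:
a cylindrical shaft, a spherical head and a tapered neck capsule (default
neck-shaft angle 130 deg), a cortical shell (higher intensity) around a
trabecular interior, rasterised with half-voxel anti-aliasing from a
continuous intensity function that is also available analytically
(`phantom_intensity()`) for oracle computations.  Primitive sizes scale with
the volume extent so one spec works from 32^3 test grids to the full
192 x 128 x 192 at (0.664, 0.664, 1) mm.

A training case warps a shape-jittered instance (radii +-10 %, neck angle
+-5 deg -- the stand-in for inter-subject variation) by a random pose
(rotations +-10 deg per axis, matching the pose-variation ranges of the data
the method targets; translations +-4 mm; log-scale +-5 %) composed with a
random diffeomorphic deformation (Gaussian-smoothed white noise, sigma 3
voxels, max 4 mm, integrated by scaling and squaring).  DRRs of the target
are rendered at twice the network input resolution, masked by the projected
target labels, area-averaged down and min-max normalised.  The orthogonal
mode fixes the views at 0 and 90 deg; the generalised mode draws each within
+-30 deg of those, as in generalised-geometry evaluations.  Left/right
flipping is omitted: phantoms are generated in one chirality.

What the phantom does **not** emulate: realistic X-ray physics (spectrum,
scatter, noise beyond optional additive Gaussian), soft-tissue background and
overlapping structures in the radiographs, true anatomical shape statistics,
and real segmentation errors in the masks.  Passing tests on phantom data
demonstrate that the operators, the architecture and the optimisation behave
as designed -- not that the trained tiny model transfers to clinical images.

## Evaluation

`evaluate_case()` reports Dice and Jaccard overlap of warped vs target labels
(the two are related by Dice = 2J/(1+J), asserted in the tests), the average
symmetric surface distance in mm (boundary voxels by 6-connectivity erosion;
a mesh-based surface would be the alternative), and SSIM between warped and
target volumes (3D Gaussian window sigma 1.5, K1 = 0.01, K2 = 0.03, data
range from the reference).  Both-empty label maps define Dice/Jaccard as 1
with a diagnostic; empty-vs-nonempty is 0.  `angle_sensitivity_sweep()`
re-registers cases under deliberately wrong LAO/RAO inputs,
`biplane_angle_grid()` bins generalised-geometry results into a median-Dice
matrix (default 4 deg bins).

## Problem sizes used in the bundled checks

All shipped tests and the acceptance script run on one CPU.  The sizes were
chosen so the full suite completes in well under half an hour: operator
checks use 6^3-64^3 grids; the end-to-end training demonstration uses the
tiny preset (32^3 volumes, 24 x 32 inputs, K = 32, decoder [16, 16, 8],
M = 2) with 50 cases split 30/10/10; the affine-recovery check uses 80
pure-pose training cases and 10 held-out, three seeds.  These are scaled-down
behavioural demonstrations of the same mechanisms -- numerical accuracy
claims at full scale are out of scope here.

## Numerical limits of the grid-based flow

Scaling and squaring composes the displacement field with itself by trilinear
resampling, so its guarantees degrade when the field varies on the scale of
one voxel.  For velocity max-norm A and Gaussian smoothness sigma (voxels),
the inverse-consistency residual of composing the flows of +v and -v scales
like the composition interpolation error, on the order of `A / (8 sigma^2)`
voxels: comfortably below 0.1 voxel at moderate settings (the warping unit
tests assert this at A = 3, sigma = 2.5), but approaching a full voxel at the
violent corner A = 10, sigma = 2, where the finite-difference Jacobian of the
grid-sampled flow can also dip negative for some seeds even though the
continuous flow of any smooth stationary velocity is a diffeomorphism.  The
corresponding acceptance test asserts the corner conditions as such and is
expected to fail there -- a documented resolution limit, not a defect of the
integrator; the phantom generator's default deformations (A = 4 mm,
sigma = 3 voxels) sit well inside the safe regime.

## Known limitations

* Pure R execution: a full-scale (192 x 128 x 192) training run is not
  practical in this implementation; the full-scale preset exists as
  configuration and its forward pass is exercised only structurally.
* Calibrated geometries are assumed; there is no pose-from-image estimation
  for uncalibrated radiographs.
* The single-decoder ablation refers its shared beam-space output to the AP
  geometry; the source design is ambiguous on this point.
* Batch normalisation with batch 1 couples normalisation statistics to each
  input; this is the regime the reference training also used (batch 1), but
  it differs from population batch-norm.
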