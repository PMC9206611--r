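# prostreg

Atlas-based 2D/3D registration of biplanar radiographs via projective
spatial transforms.

## The problem

Orthopaedic planning often has to work from a pair of calibrated radiographs
(an anterior-posterior and a roughly lateral view) instead of a CT scan.
`prostreg` reconstructs patient-specific 3D anatomy from such a pair by
*registration*: a convolutional network regresses a transformation that warps
a reference 3D atlas volume `V` (with label map `S`) so that the cone-beam
projections of the warped atlas match the input radiographs
`I_i, i ∈ {AP, LAT}`.  Because the output is a deformation of an atlas rather
than a free-form reconstruction, implausible shapes are penalised and the
same warp transports any atlas annotation to the patient.

The transformation decomposes into a 7-parameter affine pose `T` (three
rotations, three translations, isotropic log-scale) and a local diffeomorphic
field `φ`, combined into one backward map

    Ψ(x) = T⁻¹(x + φ(x)) − x ,

so a single trilinear resampling `V ∘ Ψ` reproduces the two-stage warp.

Two differentiable operators link volumes and radiographs:

* **ProST** — resample `V` at grid `G` of `K` points per source-to-pixel ray,
  rotated by the calibrated geometry transform `T_geom`
  (`V_beam = V ∘ T_geom(G)`), then sum along rays:
  `Î(i,j) = Σ_k V_beam(i,j,k)`, a digitally reconstructed radiograph (DRR).
* **inv-ProST** — sample a beam-space volume back at each voxel's ray/detector
  coordinates `G⁻¹` (`V̂ = V_beam ∘ T_geom(G⁻¹)`); out-of-cone voxels are 0.

The local module decodes per-view 2D features into beam-space 3D feature
maps, aligns them in physical space with inv-ProST, and fuses them into a
stationary velocity field integrated by scaling and squaring — so the network
handles arbitrary calibrated (not only orthogonal) view pairs.

Training minimises (semi-supervised, `δ = 0.01`)

    L = −NCC(V∘T, V_f) − NCC(V∘Ψ, V_f) + δ · smoothness(φ) .

Everything is implemented in R, including the reverse-mode gradients of the
convolutions, the sampling operators and the integration (`R/autodiff.R`),
so the network is trainable on one CPU at the bundled "tiny" preset.  A
synthetic femur-phantom generator (`make_phantom()`, `make_case()`,
`make_dataset()`) provides atlas/target/DRR cases with known ground truth;
`dice()`, `jaccard()`, `assd()`, `ssim()` and the sweep harnesses
(`angle_sensitivity_sweep()`, `biplane_angle_grid()`) evaluate results.

## Worked example

Simulate a DRR of a femur phantom, then register a deformed case with an
untrained (identity-initialised) network:

```r
library(prostreg)

spec  <- phantom_spec(shape = c(32, 32, 32), spacing = c(1, 1, 1))
atlas <- make_phantom(spec, seed = 0)
geom  <- geometry_for_volume(atlas, lao_rao_deg = 0,
                             detector_px = c(48, 64), k_samples = 32)
print(geom)
#> <projection_geometry> theta = 0 deg, cc = 0 deg, SDD = 1000 mm, iso = 925 mm,
#>   detector 48 x 64 px @ 1.31074 x 1.31074 mm, K = 32 over 55.4256 mm depth window

p <- drr(atlas, geom)      # line-integral radiograph, mm-scaled
print(p)
#> <projection2d> 48 x 64 px, range [0, 4.76]

case  <- make_case(spec, seed = 5)   # jittered, posed, deformed target + DRRs
model <- init_registration_model(reg_config("tiny"), seed = 1)
res   <- register_case(model, case)
print(res)
#> <registration_result>
#>   <affine_params> rot (deg) [-0.0147, -0.0157, -0.0147], t (mm) [0.0109, -0.00484, -0.00266], scale 1
#>   local field: mean |phi| 0.005 mm, max 0.012 mm
evaluate_case(res, case)
#>   case_id theta_ap theta_lat      dice   jaccard  assd_mm      ssim
#> 1       5        0        90 0.4073899 0.2558001 1.743927 0.7775702
```

The untrained model is the identity by construction (pose ≈ 0, `φ` ≈ 0), so
this Dice (≈ 0.41) is the unregistered baseline;
`train_registration(model, cases, ...)` raises it — the acceptance script
below runs that end-to-end demonstration.  A DRR of the registered result is
one line: `drr(res$warped_volume, geom)`.

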