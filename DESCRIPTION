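Package: prostreg
Title: Atlas-Based 2D/3D Registration of Biplanar Radiographs via
    Projective Spatial Transforms
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Registers a 3D atlas volume (with its label map) to a pair of
    calibrated biplanar radiographs by regressing an affine pose and a local
    diffeomorphic deformation field with a convolutional network.  Provides
    differentiable cone-beam projective (ProST) and inverse-projective
    (inv-ProST) spatial transforms, digitally-reconstructed-radiograph (DRR)
    simulation, stationary-velocity-field integration by scaling and squaring,
    a femur-like synthetic phantom and case generator, registration quality
    metrics (Dice, Jaccard, average symmetric surface distance, SSIM), and a
    CPU-trainable reverse-mode implementation of the registration network with
    its normalised-cross-correlation plus smoothness training loss.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    png,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
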