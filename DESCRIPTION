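Package: turbmri
Title: Turbulence Mapping from Multipoint Phase-Contrast MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to simulate and analyse multipoint, six-direction
    phase-contrast MRI acquisitions of turbulent blood flow. Implements the
    Gaussian intra-voxel velocity signal model, construction of multi-VENC
    tensor encoding schemes, Bayesian multipoint estimation of mean velocity
    and intra-voxel standard deviation, pseudoinverse recovery of the full
    Reynolds stress tensor, turbulent kinetic energy and maximum principal
    turbulent shear stress maps, a synthetic stenotic-jet phantom generator,
    Monte-Carlo accuracy/precision experiments over SNR and voxel size, and a
    locally low-rank reconstruction of undersampled cardiac- and
    respiratory-binned Cartesian k-space.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    graphics,
    stats,
    utils,
    tools,
    RNifti,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
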