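# turbmri

Turbulence mapping from multipoint phase-contrast MRI: simulation,
estimation and reconstruction of Reynolds stresses in blood flow.

## What it is for

Turbulent flow downstream of stenoses and prosthetic heart valves dissipates
energy and stresses blood cells. Phase-contrast MRI can measure it: velocity
fluctuations inside a voxel dephase spins and attenuate the signal magnitude,
while the mean velocity appears as a phase. With six non-collinear encoding
directions at several velocity-encoding strengths (VENCs), the full Reynolds
stress tensor (RST) of every voxel becomes measurable, analogous to
diffusion-tensor imaging. `turbmri` is aimed at MR physicists and
cardiovascular-flow researchers who want to design, simulate and validate
such acquisitions, and at analysts who need the estimation and
reconstruction chain as reusable components.

## The model

For a Gaussian intra-voxel velocity distribution with mean $\bar v$ and
standard deviation $\sigma$ (IVSD) along an encoding with first moment
$k_v = \pi/\mathrm{VENC}$:

$$S(k_v) = S_0\,e^{-\sigma^2 k_v^2/2}\,e^{-ik_v\bar v},
\qquad
|S(\mathbf k_v)| = |S_0|\,e^{-\mathbf k_v^\top R\,\mathbf k_v/(2\rho)}$$

with $R$ the RST in Pa and $\rho$ the fluid density. Six directional
variances $\sigma_i^2 = (2/|k_{v,i}|^2)\ln(|S(0)|/|S(k_{v,i})|)$ determine
$R$ through a quadratic design matrix and its pseudoinverse; the redundant
directional phases determine $\bar v$ the same way. Derived metrics are the
turbulent kinetic energy $\mathrm{TKE} = \tfrac12\mathrm{tr}(R)$ (J/m³) and
the maximum principal turbulent shear stress
$\tau_{max} = (\delta_1 - \delta_3)/2$ (Pa) from the tensor eigenvalues.
Multi-VENC measurements per direction are fused by a Bayesian
(maximum-likelihood) grid search that resolves low-VENC phase aliasing and
vanished-magnitude cases. Undersampled cardiac/respiratory-binned k-space is
reconstructed with a locally low-rank model: nuclear-norm penalties on
Casorati matrices of image blocks across all frames, minimized by proximal
gradient descent with per-block singular-value thresholding.

The package covers: a synthetic stenotic-jet phantom with ground-truth RST
(`generateJetPhantom`), the 19-point encoding scheme (`encodingScheme`),
acquisition simulation at any resolution and SNR (`encodePhantom`,
`windowDownsample`, `addNoise`), estimation (`estimateStack`,
`bayesianMultipoint`, `solveRst`, `solveMeanVelocity`), metrics (`tke`,
`mptss`, `medianFilterRst`), Monte-Carlo accuracy experiments
(`accuracyPrecisionExperiment`), and the binned reconstruction
(`goldenAngleMask`, `viewShare`, `llrReconstruct`). A command-line wrapper
(`inst/cli/turbmri`, subcommands `phantom`, `encode`, `simulate-experiment`,
`estimate`, `metrics`, `recon`, `report`) drives the same functions from
YAML configurations with reproducible manifests.

## Worked example

Simulate a patient-like stenotic jet, acquire it at 30 dB with the 19-point
scheme, and recover the turbulence maps:

```r
library(turbmri)

phantom <- generateJetPhantom(dims = c(24, 24, 48), peakIvsd = 0.8, seed = 42)
phantom
#> PhantomField 24x24x48 @ 0.625 mm, 11828 lumen voxels
#>   peak IVSD 0.800 m/s, peak |v| 2.165 m/s, density 1200 kg/m^3

scheme <- encodingScheme()   # 6 directions x VENC {0.5, 1.5, 4.5} + reference
stack  <- addNoise(encodePhantom(phantom, scheme), targetSnrDb = 30, seed = 42)
est    <- estimateStack(stack, rho = fluidDensity(phantom))
maps   <- turbulenceMaps(medianFilterRst(est$rst, est$mask, size = 3), est$mask)
truth  <- turbulenceMaps(rstTensor(phantom), lumenMask(phantom))

mean(maps$tke[maps$mask]);  mean(truth$tke[lumenMask(phantom)])
#> [1] 225.9   # estimated masked TKE mean, J/m^3
#> [1] 227.3   # ground truth
mean(maps$mptss[maps$mask]); mean(truth$mptss[lumenMask(phantom)])
#> [1] 57.1    # estimated masked MPTSS mean, Pa
#> [1] 56.8    # ground truth
```

At 30 dB both metrics land within ~1 % of the phantom's ground truth;
lowering the SNR or coarsening the voxels (via `windowDownsample`) biases
MPTSS upward much faster than TKE, which is the behavior the accuracy
experiments quantify.

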