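---
title: "Mapping Reynolds stresses with multipoint phase-contrast MRI: models and methods"
author: "turbmri"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping Reynolds stresses with multipoint phase-contrast MRI: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(turbmri)
```

## The measurement problem

Turbulent blood flow downstream of diseased or prosthetic heart valves
dissipates energy and exerts shear forces on blood constituents. Phase-contrast
MRI can probe not only the time-averaged velocity field but also the intensity
of velocity fluctuations inside each voxel: fluctuations dephase spins and
attenuate the signal magnitude, while the mean velocity appears as a signal
phase. `turbmri` implements the full computational chain for this measurement —
forward simulation, encoding design, estimation, turbulence metrics,
Monte-Carlo accuracy experiments and the compressed-sensing reconstruction of
highly undersampled, cardiac- and respiratory-binned acquisitions.

## Signal model

With a Gaussian distribution of velocities inside a voxel (mean $\bar v$,
standard deviation $\sigma$ along the encoding axis — the *intra-voxel
standard deviation*, IVSD) and a bipolar encoding gradient with first moment
$k_v = \pi/\mathrm{VENC}$, the complex signal is

$$S(k_v) = S_0\, e^{-\sigma^2 k_v^2/2}\, e^{-i k_v \bar v}.$$

In three dimensions the fluctuation statistics are the Reynolds stress tensor
(RST) $R = \rho\,\overline{v' v'^{\top}}$ (Pa, density folded in), and the
magnitude generalizes to
$|S(\mathbf k_v)| = |S_0| \exp(-\mathbf k_v^\top R \mathbf k_v / (2\rho))$.
The package composes this magnitude with the phase of the one-dimensional
model; only phase differences matter downstream, and the sign convention
($e^{-ik_v\bar v}$) is fixed package-wide. The model is generative at the fine
phantom scale only — at coarse voxel sizes the Gaussian assumption fails, which
is precisely the partial-volume effect the resolution experiments quantify.

The attenuation is informative only over a limited range of $\sigma$: its
inflection point in $\sigma$ — the zero of $\partial^2|S|/\partial\sigma^2$,
the conventional operating point — sits at $k_v = 1/\sigma$
(`optimalVenc()`), and for $\sigma \gtrsim 3/k_v$ the signal vanishes and the
estimate saturates. This motivates the multipoint scheme: each of six
non-collinear directions (three axes and three face diagonals,
`buildDirections()`) is acquired at VENCs of 0.5, 1.5 and 4.5 m/s, plus one
reference — 19 encodings. The two lower VENCs cover the physiological IVSD
range (up to ~0.3 m/s in healthy aortae, ~0.8 m/s in valve disease); the
highest VENC keeps the mean-velocity phase unaliased. The reference
($k_v = 0$) measurement is modeled as the 19th point because the ratio
$|S(0)|/|S(k_v)|$ anchors all variance estimates.

## Estimation

Per direction, the variance along the encoding axis follows from
$\sigma^2 = (2/|k_v|^2)\,\ln(|S(0)|/|S(k_v)|)$; six directional variances
determine all six unique RST entries through a quadratic design matrix whose
row for unit direction $d$ is
$(d_x^2, d_y^2, d_z^2, 2d_xd_y, 2d_xd_z, 2d_yd_z)$ — the velocity analogue of
diffusion-tensor encoding. `solveRst()` applies the Moore–Penrose pseudoinverse
$(H^\top H)^{-1}H^\top$; with the canonical six directions the system is square
and full rank, so consistent inputs invert exactly. Mean velocity uses the
redundant projection system solved the same way (`solveMeanVelocity()`).

The multipoint combination is a maximum-a-posteriori search: with circular
complex Gaussian noise and flat priors over
$[-\mathrm{VENC}_{\max}, \mathrm{VENC}_{\max}] \times [0, \sigma_{\max}]$
(defaults 4.5 m/s and 1.2 m/s), the posterior maximizer of the joint
likelihood of all VENCs of one direction is located on a grid (default
0.005 m/s) and refined by bounded quasi-Newton steps
(`bayesianMultipoint()`). Aliased low-VENC phases are resolved because the
VENC set \{0.5, 1.5, 4.5\} has a joint phase period of 9 m/s, making the
likelihood unimodal over the search box; a vanished low-VENC magnitude is
itself informative about $\sigma$. Exact grid ties break towards the smallest
$|\bar v|$, deterministically.

Two open design points were decided as follows. First, the reference method
for multipoint unfolding is described in the literature only by its principle
("select the most likely values"), so the grid-MAP realization here is a
faithful but independent implementation. Second, whether $\sigma$ and
$\bar v$ were estimated jointly or sequentially in vivo is not documented;
`estimateStack()` uses a *sequential* MAP for whole volumes — $\sigma$ from
magnitudes on a shared grid, $\bar v$ from phases, then $\sigma$ again
conditioned on $\bar v$, each refined by parabolic interpolation — because it
vectorizes across voxels (three small matrix products per direction) and
agrees with the joint search at high SNR, while `bayesianMultipoint()` keeps
the joint 2-D search for per-voxel work. A closed-form path
(`method = "ratio"`: best usable magnitude ratio plus phase unwrapping from
the highest VENC downwards) is exact on noise-free data and serves as the
numerical reference.

Noise can drive apparent variances negative; `solveRst()` output diagonals
are clamped at zero before metrics, and affected voxels carry a quality flag.
The clamp keeps the turbulent kinetic energy well defined and only activates
in the noise-dominated regime.

## Turbulence metrics

With $R$ in Pa, turbulent kinetic energy is the half-trace,
$\mathrm{TKE} = \tfrac12\mathrm{tr}(R)$ (J/m³), and the maximum principal
turbulent shear stress is the eigenvalue half-range,
$\tau_{max} = (\delta_1-\delta_3)/2$ (Pa). A `units` tag distinguishes
stress-unit tensors from velocity-variance tensors so the density
($\rho = 1060$ kg/m³ for blood, 1200 kg/m³ for the phantom's
blood-mimicking fluid) is never applied twice. Eigenvalues are computed with
the closed-form trigonometric solution for symmetric 3×3 matrices, vectorized
over voxels. A component-wise median filter of size 3, restricted to the
analysis mask (nearest padding at boundaries, out-of-mask voxels never
contribute), suppresses salt-and-pepper artifacts before metric computation —
filtering precedes metrics, the literal reading of the processing
description. Distribution summaries use a Gaussian kernel density estimate
with Scott's rule-of-thumb bandwidth (overridable) plus sample mean and SD.

## The synthetic jet phantom

No reference flow measurement is publicly available, so
`generateJetPhantom()` builds an analytic stand-in that reproduces the
documented summary conditions: 0.625 mm isotropic voxels, a 64 % area
stenosis, fluid density 1200 kg/m³, and peak IVSD 0.8 m/s (patient-like) or
0.3 m/s (healthy-like). The geometry is a cylindrical vessel along $z$ with a
smooth Gaussian constriction; the jet has a thin tanh velocity interface
whose core tracks the widening lumen, while the turbulence annulus around it
is deliberately broader and tapers towards the wall — the scale separation of
post-stenotic shear layers. The RST is anisotropic (axial-to-transverse
variance ratio 2 by default, moderate as measured in shear-dominated flows)
with the principal axis tilted towards radial inside the shear layer, which
produces non-zero covariances while remaining positive semidefinite by
construction.

Two seeded, band-limited random components add realism: a few smooth
low-frequency modes modulating velocity and IVSD by ±5 %, and a fine-scale
component (wavelengths 1.4–2.9 mm, ~10–15 % of peak velocity, all three
velocity components) confined to the jet. The fine-scale roughness matters
for the resolution experiments: a phase-averaged turbulent jet is not smooth
at the millimetre scale, and it is exactly this sub-voxel mean-flow structure
that coarse acquisitions convert into apparent turbulence. The IVSD field is
normalized so its maximum equals the configured peak exactly, making the RST
scale quadratically in that parameter. The IVSD scalarization used for
normalization and histograms is $\sqrt{\mathrm{tr}(R)/(3\rho)}$ — the
direction-averaged convention, since the tensor case admits several. What the
phantom does *not* emulate: actual fluid dynamics (no Navier–Stokes solve),
cohort-shaped IVSD distributions (only their support ranges), pulsatility,
and wall motion. Passing trend tests on this phantom therefore demonstrates
correct pipeline behavior under the stated conditions, not in-vivo accuracy.

## Acquisition simulation and the accuracy/precision experiments

`encodePhantom()` applies the forward model voxel-wise; coarser voxel sizes
are emulated by `windowDownsample()`, which crops the central k-space region
(bandwidth inversely proportional to the factor) and transforms back on the
reduced grid — an ideal rectangular low-pass by default (no window shape is
prescribed; a Hann option exists for sensitivity checks). The DC coefficient
is untouched, so image-domain means are preserved exactly. Complex Gaussian
noise is added in image space after downsampling (equivalent to k-space noise
under a unitary FFT), scaled so that $20\log_{10}$(mean masked magnitude over
all encodings / per-channel SD) hits the target SNR.

`accuracyPrecisionExperiment()` runs the full chain — encode, downsample, add
seeded noise, estimate, median-filter, metrics — over an SNR × resolution
grid with repetitions, recording masked distribution means and SDs per cell,
and `summarizeExperiment()` aggregates mean ± SD over repetitions. The
reference experiment tables' printed values are tied to an unavailable
dataset; the package reproduces the experiment *structure* and its trends on
the phantom: decreasing SNR inflates MPTSS while TKE stays within a fraction
of a percent between 40 and 30 dB, and coarser voxels inflate MPTSS
disproportionately more than TKE (at the 0.625→2.5 mm factor, roughly
10 % vs 8 % on this phantom at 30 dB).

Problem sizes were chosen so each experiment finishes in minutes on one core:
the SNR trend uses a 24×24×48 grid (≈12 k lumen voxels, 10 repetitions ×
4 SNRs), the resolution trend a 48×48×96 grid (≈96 k voxels, 5 repetitions,
factors 1/2/4/8 so the coarsest grid still holds a usable lumen). All
per-repetition seeds derive deterministically from one base seed.

## Locally low-rank reconstruction

In vivo, k-space is acquired continuously along a Cartesian tiny-golden-angle
pseudo-spoke ordering (`goldenAngleMask()`; increment
$180°/(\varphi+6) \approx 23.63°$), sorted into 25 cardiac phases × 4
respiratory states, with view sharing across neighboring respiratory states
capping each frame's acceleration at 35 (`viewShare()`; a frame's own
acquired lines are never overwritten and borrowed lines are flagged). Each
velocity encoding is reconstructed independently by minimizing

$$\|\Omega \mathcal F \mathcal C(S) - d\|_2^2 +
  \lambda \sum_b \|\mathcal R_b(S)\|_*,$$

where $\mathcal R_b$ reshapes image blocks across all frames into Casorati
matrices ($n_xn_yn_z \times N_{hp}N_{rs}$, cardiac index fastest) whose
nuclear norms are penalized. The solver is proximal gradient descent: with a
unitary FFT and normalized coils the data-term gradient step at step size 1/2
is an exact data-consistency projection, and the proximal step is singular-
value soft-thresholding per block. Plain (unaccelerated) iterations make the
objective provably non-increasing — the default, and the property the tests
assert each iteration. FISTA acceleration and geometric
$\lambda$-continuation (start high to suppress aliasing, anneal to the target
$\lambda$) are available for large problems, where they converge an order of
magnitude faster at the cost of strict monotonicity; cycle spinning of the
block grid (seeded) is likewise optional because shifting tiles between
iterations changes the penalty being monotonically decreased. $\lambda$ is
defined relative to data normalized so the zero-filled reconstruction has
unit maximum magnitude; the in-vivo-scale default is $\lambda = 0.005$ with
22³ blocks, and desk-scale tests use 32³ volumes with 16³ blocks — the same
block-to-volume proportion. Non-overlapping tiling with truncated boundary
blocks keeps the per-iteration cost at one thin SVD per block.

The synthetic recovery experiment (`dynamicRankPhantom()`) builds an exact
rank-2 series: smooth Gaussian-blob spatial modes weighted by distinct
temporal signatures (one mode with a DC-dominated cardiac profile, the other
on the second cardiac harmonic). Distinct signatures matter: if both modes
share a near-identical temporal shape the mode-separation problem is
ill-conditioned for *any* solver, which says nothing about the
implementation. At 8× undersampling (32³, 8 phases × 4 states) the solver
recovers the series to NRMSE < 0.05 in 150 accelerated iterations.

Coil-sensitivity maps are accepted by the operator interface but default to a
single uniform coil — multi-channel calibration and pre-whitening are scanner
procedures outside this package's scope. Binning labels (which readout
belongs to which cardiac/respiratory frame) are likewise inputs, not
estimated. Only the expiratory state is conventionally carried into metric
analysis.

## Numerical choices and degenerate inputs

* Symmetric-eigenvalue computation clamps the acos argument to $[-1,1]$;
  near-isotropic tensors return the mean eigenvalue, and the half-range is
  insensitive to the ordering of the middle eigenvalue.
* `ivsdFromMagnitudeRatio()` clamps noise-driven negative variances to zero
  (flag `"clamped"`) and returns the saturation value with flag
  `"saturated"` when the encoded magnitude falls below $10^{-4}$ of the
  reference.
* The MAP grids bound $\sigma$ at 1.2 m/s — 50 % above the largest
  physiological peak the encoding set was designed for.
* Downsampling factors must divide the grid; odd retained bandwidths split
  the band asymmetrically (one extra positive frequency), matching the
  unshifted FFT layout.
* All randomness flows from one base seed through a documented integer
  derivation, so every pipeline artifact is bit-reproducible; run manifests
  deliberately exclude timestamps.

## Known limitations

The phantom is analytic, so systematic effects that depend on genuine
turbulent spectra (e.g. non-Gaussian velocity distributions at fine scale)
are only represented through the band-limited roughness proxy. The
acceleration-35, 25-phase in-vivo configuration is exercised at reduced desk
scale; absolute in-vivo values are out of reach without scanner data. The
reconstruction assumes provided binning labels and coil maps, and the
pseudo-replica SNR measurement on reconstructed data is not implemented
(requires real multi-coil scans).
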