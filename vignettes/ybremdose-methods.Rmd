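---
title: "Models and methods behind ybremdose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind ybremdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Yttrium-90 radioembolization delivers beta-emitting microspheres to liver
tumours. Because 90Y has no gamma line, post-therapy imaging relies on
bremsstrahlung SPECT of the continuous X-ray spectrum (up to the 2.28 MeV
beta endpoint), acquired in a wide 105-195 keV window. Two physics problems
make this quantitatively hard:

1. **Scatter.** Downscatter from the high-energy continuum dominates the
   acquisition window. Without an estimate of the mean scatter contribution
   per projection bin, reconstruction grossly overestimates and blurs the
   activity.
2. **Dose blurring.** Even a well-corrected SPECT reconstruction has
   limited resolution, so voxel dosimetry computed from it (by kernel
   convolution or Monte Carlo) inherits partial-volume bias, especially in
   small lesions.

`ybremdose` implements a three-stage framework addressing both:

* **Stage I** - a projection-space CNN estimates the scatter projection for
  each view from the measured projection and the projected attenuation map.
* **Stage II** - OS-EM reconstruction of the Poisson model
  `y ~ Poisson(A x + r̄)` with attenuation, collimator-detector response
  (CDR) and the stage-I scatter mean `r̄`.
* **Stage III** - voxel dose-rate estimation: a fast dose-voxel-kernel
  (DVK) convolution provides a physics baseline, and a residual network
  learns only the difference between that baseline and ground-truth Monte
  Carlo dose-rate maps, effectively deblurring the dosimetry.

Everything needed to train and evaluate the pipeline at desk scale is part
of the package: a virtual-patient phantom generator, a photon Monte Carlo
producing ground-truth scatter, an electron Monte Carlo producing
ground-truth dose, and the evaluation metrics.

# Synthetic phantoms

`make_virtual_patient()` builds an activity/density pair plus VOI masks: a
liver as a union of two ellipsoids, ellipsoidal lesions whose voxelised
volumes match the request to within one voxel volume (binary search on the
ellipsoid scale, with deterministic sub-voxel centre jitter for small
lesions), a soft-tissue body, low-density lungs and a bone insert. Activity
is base concentration x lesion uptake ratio x a multiplicative log-normal
texture (Gaussian-filtered white noise, exponentiated, normalised to mean
one inside the liver), then rescaled so the map sums exactly to the
configured administered activity. The texture matters: networks trained on
piecewise-constant activity generalise poorly, so non-uniform livers are
the default (`texture_sigma = 0.3`, correlation length 20 mm).

Compartment densities default to lung 0.30, soft tissue 1.00 and bone
1.40 g/cm^3. CT numbers are converted to density by a two-segment
piecewise-linear calibration anchored at (-1000 HU, 0.0012), (0, 1.0) and
(+1000, 1.60) g/cm^3 - a conventional stand-in for a scanner-specific
measured curve. Attenuation maps are density times the mass-attenuation
coefficient of water at 150 keV, the centre of the acquisition window.

`make_torso_phantom()` provides a calibration-phantom preset: a 1200 mL
liver background with a 29 mL ovoid and 16/8 mL spherical inserts, lungs
and a spine insert. The printed compartment concentrations
(6.4-7.8 MBq/mL inserts, 1.3 MBq/mL background) and the printed 2.0 GBq
total are not exactly mutually consistent; the preset uses insert
concentrations at the top of that range (7.8/7.7/7.6 MBq/mL) with the
1200 mL at 1.3 MBq/mL so the total lands on 2.0 GBq within 2%.

The fixture generator `make_fixtures()` produces a set of virtual patients
with lesion volumes spanning 5.7-932 mL and assigns disjoint
train/validation/test roles for the two networks, so no network is ever
evaluated on a phantom it saw during training; `validate_split()` enforces
this.

# The SPECT system model

`spect_system()` assembles the linear operator `A` per view:

1. rotate the volume into the detector frame (sparse, bilinear,
   *mass-preserving splatting*: each voxel distributes its content at its
   rotated position, so weights sum to one per voxel and counts are
   conserved for objects inside the inscribed field of view),
2. attenuate each voxel by `exp(-∫ mu dl)` along the ray towards the
   detector (half-voxel self-attenuation at the source voxel),
3. blur each constant-depth plane with a Gaussian whose FWHM grows
   affinely with distance to the collimator, `fwhm(d) = c0 + c1 d`
   (defaults 2 mm + 0.05 d - a broad, high-energy-collimator-like
   response; kernels are normalised to sum one),
4. sum along the ray axis and scale by the detector efficiency.

Because every step is an explicit linear operator, `backproject()` is the
exact matrix adjoint - `<Ax, p> = <x, A'p>` holds to machine precision -
which is the property OS-EM correctness rests on, and is tested directly.
The projector requires the voxel pitch to equal the bin pitch (resample
first; no silent interpolation). View angles are equally spaced over 360
degrees, counter-clockwise from zero.

`osem()` is the classic multiplicative update over interleaved view
subsets (maximal angular spacing ordering), with the denominator clamped
at 1e-12, a uniform positive start inside the attenuation support, a fixed
iteration count (default 4 subsets x 16 iterations) and no post-filter.
With one subset it reduces exactly to MLEM, whose Poisson log-likelihood
ascent is verified per iteration in the tests.

# Photon Monte Carlo (scatter ground truth)

`simulate_projections()` is an analog photon transport: decay sites are
sampled from the activity map, photon energies from a thick-target
bremsstrahlung shape `I(E) ∝ (Emax - E)/E` on 50-2280 keV, directions
isotropically. Tracking through the density map uses Woodcock (delta)
tracking; interactions are Compton scattering (Klein-Nishina sampling by
rejection; cross-section from the KN formula times the electron density of
water scaled by mass density) and photoelectric absorption (embedded water
table scaled by density; coherent scattering is neglected above the 105 keV
window edge). A photon escaping within the acceptance half-angle (default
2 degrees) of a view normal is propagated to the detector plane - which
naturally produces the distance-dependent geometric blur of a parallel-hole
collimator - and scored if its Gaussian-blurred energy (FWHM fraction 0.095
at 140 keV, scaling as 1/sqrt(E)) falls inside the window. Photons with at
least one interaction score to scatter, unscattered photons to primary.
Analog scoring keeps the code auditable as an oracle; there is no forced
detection or septal-penetration model.

**The desk-scale measurement model.** A billion-history label per view is
out of reach on one CPU, so study simulation (`simulate_study()`)
composes: the *scatter* mean from the Monte Carlo (8e6 histories,
smoothed as a denoised label with a Gaussian of FWHM 8 bins in-view plus
4 views across the angle axis - the scatter mean is smooth in all three
indices, and the smoothing level was calibrated so two independently
seeded labels agree to ~7% NRMSE), the *primary*
mean from the analytic system model scaled to the MC primary total (the
primary is exactly what `A` describes; this preserves the MC
scatter-to-primary ratio, about 3:1 in the acquisition window), and
Poisson noise at the clinical ~1e7 total counts.

# Electron transport and dosimetry

The 90Y beta spectrum uses the allowed (Fermi) shape with a
non-relativistic Coulomb factor for the Z = 40 daughter, tabulated at
10 keV steps to the 2.28 MeV endpoint; its mean (0.948 MeV) sits within 1%
of the accepted 0.94 MeV. Electron transport is condensed-history CSDA:
the Katz-Penfold range-energy relation
`R(E) = 0.412 E^(1.265 - 0.0954 ln E)` g/cm^2, steps of 1/20 of the
residual range (floored at 2e-3 g/cm^2), energy deposition by exact
table decrement (so deposited + escaped = sampled energy to machine
precision), and Gaussian multiple-scattering deflection with the Highland
width per step. Bremsstrahlung energy loss in beta transport is neglected
(a few-percent effect, reflected in the 2% energy tolerance used for
kernel checks).

`generate_dvk()` scores a kernel around a central-voxel source in water,
with dimensions `2 round(11 mm / pitch) + 1` per axis (round half away
from zero), the smallest odd box covering the 11 mm maximum beta range -
23 x 23 x 13 at 0.98 x 0.98 x 2 mm voxels. `dvk_convolve()` convolves
activity with the kernel by zero-padded FFT, divides voxel-wise by density
and zeroes voxels below the density cutoff. The cutoff defaults to
1.0 g/cm^3 exactly as conventionally printed, but note this zeroes lung
and fat dose; it is therefore an explicit parameter. `mc_dose_rate()`
transports electrons through the heterogeneous density map (steps consume
density-scaled mass pathlength) with batch-based per-voxel uncertainties,
and applies the same cutoff rule. Dose-rate units are nGy/s (per MBq for
kernels), using 1 MBq = 1e6 decays/s and voxel mass = density x volume.
`dose_rate_to_dose()` multiplies by the decay time integral
`T_half / ln 2` - with permanently trapped microspheres this constant is
the only difference between dose-rate and dose maps.

**On "maximum penetration".** The commonly quoted maximum range of 90Y
betas in tissue, 11 mm, is the CSDA range of the endpoint energy
(`R(2.28 MeV) = 1.10 g/cm^2`). Radial penetration from a point source is
shorter: multiple scattering makes tracks wander, and the spectrum carries
almost no energy near the endpoint. With this package's transport, the
radius enclosing 99.9% of deposited energy
(`beta_max_penetration()`) comes out near 8 mm, and the largest radius
with any deposit near 10 mm - both physically expected, and the
distinction is worth keeping in mind when comparing with the quoted
11 mm. The kernel box is nevertheless sized by the 11 mm CSDA range so no
deposit is truncated.

# The two networks

No deep-learning framework is available to this package's target
environment, so both networks are implemented from first principles:
Rcpp convolution kernels with hand-derived backpropagation (verified
against finite differences in the tests) and an Adam optimiser. All
initialisation and shuffling is seeded; training and inference are
deterministic.

**Scatter network.** Two branches of three 3x3 conv + ReLU layers (16
channels by default) process the scaled total projection and the projected
attenuation map; their concatenation passes through three trunk layers (32
channels) and a pointwise convolution with a terminal ReLU, so estimates
are non-negative and the spatial size is preserved throughout. Input
scaling: the projection (and the scatter label) are divided by the study's
total counts x 1e-4, the attenuation projection by 10 (line integrals are
O(1-10)); the scale factors are inverted at the output. Training minimises
pixel-wise MSE against the MC scatter labels with Adam; one study is held
out for validation and the best-validation parameters are kept. The
paper-scale recipe (lr 1e-4, 800 epochs) is preserved as
`scatter_train_recipe_paper()`; desk runs use lr 3e-4 for ~40 epochs.
Hidden conv biases are initialised at +0.01: with a terminal ReLU and
ReLU hidden units, zero-bias initialisation starts the network in a
mostly-dead regime where training stalls.

**Residual dose network.** Inputs are packs of 11 adjacent slices of the
scaled activity (reconstruction) and density, stacked as two channels. A
three-layer 3-D convolutional extractor whose axial kernel depths
(default 5, 5, 3; the 5, 3, 3 variant with a 9-slice pack is also
constructible) collapses the pack to the middle slice; a 2-D U-Net
(mean-pooling downsampler, nearest-neighbour upsampling, skip
concatenation; 4 levels / 32 base channels by default, 2 levels / 8
channels at desk scale) produces a residual; the DVK dose-rate slice is
added and the terminal transform divides the residual by density (floored
at 0.3 g/cm^3) and by the stored residual unit. The final convolution is
zero-initialised, so **the untrained network reproduces DVK dosimetry
exactly** - training can only move away from the physics baseline where
the data support it. The residual unit `d_scale` is set at training time
to the RMS of (MC ground truth - DVK baseline) over the training set, so
the network optimises O(1) quantities. Activity packs are scaled to unit mean (each study's scaled voxels sum
to the voxel count), which keeps the input magnitude independent of grid
size and administered activity. Slices cover all axial positions with replicate
padding at the volume ends; negative outputs are clamped to zero at
inference with the clamped fraction logged. The single-stage ablation
variant shares the architecture, is tagged in its checkpoint, and refuses
scatter-corrected reconstructions as input.

A note on symmetry: with freely-learned axial kernel depths the network is
*not* equivariant to axial flips (the depth kernels are asymmetric), and
no such property is claimed; in-plane shift equivariance (up to padding
and pooling alignment) is the symmetry the architecture actually has, and
that is what the tests check.

# Metrics

`nmae()` is the absolute difference of the VOI means over the ground-truth
mean, in percent - a bias-of-means metric (voxelwise errors that cancel in
the mean give zero); this is the form used in the dosimetry tables this
framework is compared with, and a genuinely voxelwise `voxelwise_mae()` is
provided separately. `nrmse()` is RMSE over the root-mean-square of the
ground truth. `drvh()` builds the cumulative dose-rate volume histogram;
`d_at(h, f)` returns D_f with the step-function convention "largest
threshold whose coverage is at least f" (so D10 >= D90).
`lesion_to_background()` constructs the background VOI by translating the
lesion mask (nearest feasible integer offsets within 50 mm, ranked by local
coefficient of variation) so it lies in a uniform liver region with
identical size and shape.

# Problem sizes and numerical choices

Desk-scale defaults keep every stage interactive on one CPU: a
64x64x40 grid at 5 mm (`desk_grid()`; the full 512x512x194 clinical grid
remains available via `full_grid()`), 64 views of 64x40 bins, 2e5-8e6
photon histories, 2e5 electron histories for kernels and ~2e6 for dose
maps. The packaged end-to-end experiment (the one exercised by the
acceptance tests) uses 9 virtual patients on a 48x48x32 grid at 5 mm with
48 views, roles 3/3/3 for scatter-net training, dose-net training and
final testing, 80 scatter-net epochs (with random flip augmentation and
flip-averaged inference) and 20 dose-net epochs - chosen so
the whole study (simulation, training, reconstruction, dosimetry,
evaluation) completes in minutes while leaving the directional comparisons
clearly resolvable.

Other numerical choices: OS-EM denominators clamped at 1e-12 and zero
sensitivity voxels excluded; FFT convolution negatives (round-off) clamped
at zero; DRVH ties resolved by the step-function convention; the
lesion-to-background search capped at 400 feasible candidates
(nearest-first); reconstruction calibrated to the administered activity
when it is known, which is standard practice for 90Y.

# What the synthetic data do and do not show

The virtual patients emulate the statistical structure that matters for
this pipeline - non-uniform liver uptake, lesions across the clinical
volume range, realistic count levels, heterogeneous densities - but they
are ellipsoid-based, share one body plan, have no respiratory motion or
registration error, and the photon model omits septal penetration,
coherent scattering and camera backscatter. Passing tests therefore
demonstrate the internal consistency and the claimed *relative* behaviour
of the framework (scatter correction helps reconstruction by a large
factor; residual learning improves lesion dosimetry over MC-on-
reconstruction), not absolute clinical accuracy on patient data.

# Known limitations

* The bremsstrahlung dose component of 90Y (a few percent) and
  internal-pair 511 keV photons are not modelled.
* The CDR is a Gaussian with affine FWHM; real high-energy collimators add
  long septal-penetration tails.
* The density cutoff of 1.0 g/cm^3, implemented as printed, zeroes lung
  dose; lower it explicitly if lung shunt dosimetry matters.
* Networks here are deliberately small; at clinical matrix sizes the same
  architecture would be trained on a GPU framework.
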