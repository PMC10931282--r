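---
title: "Local MVCT position verification and transit dosimetry: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local MVCT position verification and transit dosimetry: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Patient setup errors in radiotherapy are conventionally caught with a
kilovoltage cone-beam CT mounted on the gantry, a second imaging chain whose
rotation center must be kept consistent with the treatment isocenter.
`epidmvct` implements the alternative this package is built around: image the
patient with the *treatment beam itself*. Ten EPID open-field/transmission
image pairs, acquired over a half rotation at 1 MU per angle, are enough to
reconstruct a local megavoltage CT (MVCT) around the isocenter. Registering
that MVCT to the planning CT yields the couch-shift error directly in the
machine frame, and the imaging dose — being treatment-beam dose — can be
accumulated into the session total.

Because the measured data behind this design (a clinical linac and a
commercial thorax phantom) are not distributable, the package ships a
synthetic acquisition module and re-enacts the study end to end on a digital
thorax phantom. Everything below is therefore testable: every stage is unit-
and property-tested, and `scripts/acceptance.R` recomputes the headline
numbers from scratch.

## Coordinate conventions

No convention was imposed by the problem, so one is fixed and used
everywhere: the isocenter is the world origin; x points to the patient's
left, y anterior-to-posterior, z superior-to-inferior; all lengths are mm.
At gantry angle 0 the source sits on +y at distance SAD (default 1000) and
the beam travels toward −y; the detector plane is perpendicular to the beam
axis at SID (default 1540) from the source, spanned by an in-plane lateral
axis u and v = +z. Volumes are arrays indexed `[x, y, z]`; the world position
of 0-based voxel index i is `origin + (i + 0.5) * voxel_size`. Detector
images are matrices with rows along v and columns along u.

## Synthetic acquisition

`build_thorax_phantom()` paints analytic inserts (body ellipse, two lungs, a
spine cylinder, a lesion sphere) onto a voxel grid by center-of-voxel
membership; attenuation values are nominal 6 MV linear coefficients (water
0.005/mm, lung 0.0012/mm, bone 0.008/mm). `simulate_epid_pair()` produces an
open-field image (`I0_level` inside the collimated field footprint, zero
outside) and a transmission image `I = I0 · exp(−∑ μ·ℓ)` with the ray sums
computed by exact Siddon voxel traversal from a point source (cone beam; a
parallel-beam toggle exists for oracle tests). Couch shifts are applied as
rigid trilinear translations of the attenuation grid so sub-voxel shifts are
representable.

Two generator choices had no external anchor and were fixed once:

* **Open-field level and profile.** `I0_level = 1e4` grayscale units with a
  flat profile. Integrated portal images have per-pixel SNR well above 100,
  so optional Poisson noise at this level is ~1 % of the maximum signal. A
  gentle radial profile is available but not default; the projection
  conversion uses only the ratio I0/I, so the profile largely cancels.
* **What the generator does not emulate.** Detector glare/lag, beam-hardening
  spectra, leaf sequences and patient-like heterogeneity in z are out of
  scope. Passing tests therefore demonstrate the *algorithms* — projector /
  reconstructor consistency, registration accuracy at grid precision,
  algebraic correctness of the inversion — not clinical image quality.

## Projection preprocessing

`to_projection()` computes `P = ln(I0 / I)` with both intensities clamped at
a floor (default `1e-6 · max(I0)`) because the logarithm is undefined at the
unexposed zero pixels; negative projections (noise making I > I0) are clamped
to zero since attenuation line integrals are non-negative. The chain then
resamples bilinearly to 1 mm (output side `round(n · pitch_in / pitch_out)`,
physical center preserved — registration depends on the world footprint
staying put), crops the unexposed border using the open-field mask (genuine
zero projections inside the field must survive, so the projection itself is
never used as the validity mask), center-crops/pads to 300 × 300 mm, and
resamples to 3 mm. The final grid is 100 × 100 at 3 mm regardless of the
native detector sampling; that invariant, not any intermediate shape, is
what reconstruction relies on.

## ART-TV reconstruction

One iteration sweeps every ray (views in acquisition order, row-major within
a view). Per ray i:

1. Kaczmarz update `x ← x + λ (pᵢ − wᵢᵀx)/‖wᵢ‖² · wᵢ`, with wᵢ the exact
   intersection lengths of ray i — the same Siddon trace used by the forward
   simulation, so projector and backprojector are self-consistent. The
   update is applied whenever `‖wᵢ‖ > 0`; zero-norm (missing) rays are
   skipped.
2. Non-negativity projection on the touched voxels.
3. A total-variation descent step `x ← x − μ d v/‖v‖₂`, where
   `v = ∂‖x‖_TV/∂x` is the smoothed TV derivative (smoothing constant
   ε = 1e-8 in the denominators; boundary terms whose neighbours fall
   outside the grid are dropped, mirroring the valid-index convention of the
   TV sum) and `d` is the L2 norm of the ART-induced change. TV is evaluated
   per axial slice: the equations are two-dimensional and the 3 mm slice
   spacing is anisotropic against the 2 mm in-plane voxels.

Running step 3 after literally every ray costs a whole-volume gradient per
ray, which is intractable at full problem size, so the step cadence is
configurable: `per_ray` (the literal algorithm), `per_view` (default) and
`per_iteration`. For the batched cadences `d` is the net L2 norm of the
ART-induced change accumulated since the previous TV step (the TV movement
itself is excluded). A linear accumulation of per-ray step sizes was tried
and rejected: the literal algorithm interleaves its many small TV steps with
ART corrections, and summing their magnitudes into one batched step
over-smooths drastically.

Defaults follow the study protocol: 12 iterations, λ = 0.1, μ = 1,
x⁽⁰⁾ = 0, early stop when the per-sweep change norm falls below
`1e-6 · ‖x‖`. The full-scale output grid is 128 × 128 × 122 at 2 × 2 × 3 mm³
— a local volume around the isocenter; voxels never crossed by a ray stay
zero and are excluded from registration via the ray-support mask.

**Convergence.** The literal per-ray iteration settles fast: on the bundled
noiseless convergence study (40 × 40 projections, 32 × 32 × 8 grid — the
scale at which per-ray TV is affordable) the relative image change
`‖x⁽ᵗ⁾ − x⁽ᵗ⁻¹⁾‖/‖x⁽ᵗ⁾‖` drops below 1 % by iteration 4 and keeps falling
(recomputed by `scripts/acceptance.R` and asserted in the test suite). The
batched `per_view` cadence takes its TV step two orders of magnitude less
often and approaches its stationary point more slowly; it is the throughput
choice for full-size runs, where registration accuracy — not the convergence
trace — is the quantity of interest.

Two properties pin the ART core independently of any study number: with TV
off, λ = 1 and a fully determined consistent system, repeated sweeps converge
to the direct linear-algebra solution; and the exported single-ray update is
bit-reproduced by the C++ sweep.

## Mutual-information registration

The reconstructed MVCT (floating window) slides in one-voxel steps over the
planning CT within a search radius (default ±15 voxels per axis) of the
planned position; at each offset the mutual information
`MI = H(R) + H(F) − H(R,F)` is computed in bits from one joint histogram.
Decisions with no external anchor:

* **Binning:** 64 bins; the floating image's bin edges are fixed from its
  masked voxels, the reference's from the whole search region, so MI values
  are comparable across offsets.
* **Mask:** only ray-supported MVCT voxels enter the histogram —
  unreconstructed zeros would bias the joint distribution.
* **Units:** MVCT attenuation and planning-CT Hounsfield-like values are
  left in native units; MI is invariant to monotone rebinning, so no
  cross-calibration is applied (the synthetic planning CT is deliberately
  stored on a HU-like scale to keep this honest).
* **Ties:** broken by the smallest Euclidean offset, then lexicographically
  in (z, y, x), making the search deterministic.

Window centers are reported in the half-voxel convention natural for
even-sized windows (a 64-wide window centered in a 128-wide CT has center
64.5), and the couch shift is `t = (c₀ − c) · voxelsize` componentwise.
With a one-voxel search step the recovered shift is quantized to the voxel
size, so per-axis errors up to half a voxel (1 mm in-plane at 2 mm voxels)
are the expected systematic floor — exactly what the shift experiment shows
for off-grid shifts.

## Fluence inversion and dose

`invert_primary_fluence()` implements
`ψ_p(t′, r, d) = f · SID²/d² · ψ_EPID(t, r) / exp(−a(r) t′ / (1 + b(r) t′))`:
a linear grayscale-to-fluence conversion `f` (calibratable from an open
field by least squares), inverse-square scaling from the EPID plane to the
calculation plane at distance d, and removal of the attenuation between that
plane and the EPID, parameterized by a softening coefficient `a(r)` and a
hardening coefficient `b(r)`. Water-equivalent thicknesses t (source→EPID)
and t′ (plane→EPID) are Siddon ray sums through the CT converted to relative
water density. Unanchored choices: `a(r) = a₀ + a₂ (r/100)²` with
`a₀ = 0.005`/mm (water-like at 6 MV) and `a₂ = b₀ = 0` by default; the
off-axis radius r is measured at the EPID plane and rescaled by d/SID at
depth. The synthetic forward model (`epid_from_fluence()`) is the exact
algebraic inverse with the same a, b, f — the gamma acceptance therefore
tests the inversion chain and its noise robustness, never a machine
calibration this package cannot have. A scatter-correction hook (`none` or
single-Gaussian subtraction) marks where a measured scatter model would
plug in.

Dose follows a three-component pencil-beam convolution
`D(x, y, d) = Σⱼ D′ⱼ(d) · (Ψ_p ⊛ Wⱼ)`: exponential depth curves
`D′ⱼ(d) = cⱼ exp(−μⱼ d)` with weights (0.8, 0.15, 0.05) and depth constants
(0.005, 0.004, 0.003)/mm, a delta kernel for the primary and normalized
Gaussians of σ = 3 and 20 mm for small- and large-scale scatter — generic
6 MV-like shapes in arbitrary model units, all configurable; no absolute
calibration is attempted and no heterogeneity correction is applied. Tests
assert only structural properties (linearity, impulse response, normalized
kernels, scatter-width monotonicity), never these default values. Imaging
dose (ten 1 MU fields) and treatment dose are accumulated on the
registration-corrected planning CT (`apply_registration_correction()`
resamples the CT at grid points translated by −t) with the imaging fraction
reported.

## Gamma comparison

Global gamma with 3 % dose tolerance (of the reference maximum), 2 mm
distance to agreement and a 10 % evaluation threshold. The evaluated map is
sampled bilinearly on a disk of radius 3 × DTA at 0.2 mm steps (offsets
visited in distance order with early exit); boundary pixels use in-map
samples only; γ ≤ 1 — including exactly 1 — counts as a pass. A brute-force
R implementation in the test suite pins the C++ search to 1e-6.

## Study conditions and problem sizes

Component constructors default to the full-scale protocol (1280 × 1280
detector at 0.336 mm; 128 × 128 × 122 reconstruction; 256-wide planning CT).
The bundled experiments and the acceptance script run a desk-scale study
chosen once so a complete five-group experiment finishes in well under a
minute on one CPU: planning CT 128 × 128 × 40 at 2 × 2 × 3 mm³,
reconstruction 64 × 64 × 32 at the same voxel size, simulation panel
320 × 320 at 1.344 mm, thorax inserts scaled by 0.35 so the whole body fits
the local reconstruction footprint (keeping the in-plane voxel size at the
full-scale 2 mm preserves the registration quantization behaviour, including
exact recovery of the grid-aligned −10 mm shift). The shift experiment is
noiseless; the fluence experiment keeps Poisson noise on, since the gamma
criterion exists to absorb measurement noise.

## Known limitations

* Rigid translations only — no rotations, no deformable registration, no
  sub-voxel MI interpolation; z-direction accuracy is implemented
  symmetrically with x/y but has no experimental anchor.
* The scatter, softening and hardening models are hooks with water-like
  defaults, not measured calibrations; dose is relative, in model units.
* Integrated-mode acquisition only: one image per static field; arc (VMAT)
  deliveries cannot provide per-angle transmission images in this mode.
* The TV-weight sweet spot is narrow: the adaptive step with μ well above 1
  overshoots and can destabilize the sweep rather than smooth further (the
  test suite asserts monotone smoothing only up to μ = 1).
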