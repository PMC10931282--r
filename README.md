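# epidmvct

Position verification and transit dosimetry for megavoltage radiotherapy,
using only the images a linac's electronic portal imaging device (EPID)
already produces.

Cone-beam CT setup verification needs a second imaging chain whose rotation
center can disagree with the treatment isocenter. An alternative is to image
the patient with the treatment beam itself: acquire EPID open-field and
transmission image pairs at a handful of gantry angles, reconstruct a *local
megavoltage CT* (MVCT) around the isocenter, and register it to the planning
CT to read off the couch-shift error. Because the imaging dose is delivered
by the treatment beam, it can be folded into the session's total dose.
`epidmvct` implements that whole chain, exercised end to end on a synthetic
digital thorax phantom, for medical-physics researchers who want a
self-contained, testable reference implementation.

## What the package computes

- **Projection conversion** — each open/transmission pair becomes a
  log-projection `P = ln(I0 / I)` (Beer–Lambert line integrals), then is
  resampled 0.336 mm → 1 mm, cropped to the exposed field, and resampled to
  3 mm, ending at a 100 × 100 projection grid.
- **ART-TV reconstruction** — ray-by-ray Kaczmarz updates
  `x ← x + λ (pᵢ − wᵢᵀx) / ‖wᵢ‖² · wᵢ` over exact Siddon ray traces, a
  non-negativity projection after every ray, and an adaptive total-variation
  descent step `x ← x − μ d v / ‖v‖₂` where `v = ∂‖x‖_TV/∂x` and `d` is the
  norm of the preceding ART-induced change. Defaults: 10 views over 0–180°,
  12 iterations, λ = 0.1, μ = 1.
- **Mutual-information registration** — exhaustive one-voxel sliding search
  of the MVCT window inside the planning CT, maximizing
  `MI(R, F) = H(R) + H(F) − H(R, F)` (64-bin joint histogram); the matched
  window center converts to a couch shift `t = (c₀ − c) · voxelsize`.
- **Primary-fluence inversion** — EPID grayscale back to accelerator output
  fluence, `ψ_p = f · SID²/d² · ψ_EPID / exp(−a(r) t′ / (1 + b(r) t′))`,
  with water-equivalent thickness maps traced through the CT.
- **Pencil-beam dose** — `D(x, y, d) = Σⱼ D′ⱼ(d) · (Ψ_p ⊛ Wⱼ)(x, y)` with a
  primary and two scatter components, plus imaging + treatment dose
  accumulation on the registration-corrected CT.
- **Gamma comparison** — global gamma index (3 % / 2 mm, 10 % threshold)
  with sub-pixel search and the passing-rate summary.

The heavy kernels (Siddon tracing, the ART-TV sweep, the MI search, gamma)
are C++ via Rcpp; everything else is plain R. A synthetic data module
(voxelized thorax phantom, cone-beam forward projection, Poisson noise,
programmable couch shifts) stands in for the non-deposited measured data and
is itself first-class, tested code.

## Worked example

Recover the five reference couch shifts — (0,0), (−10,0), (0,−3), (5,10),
(3,−3) mm — on the desk-scale study (64 × 64 × 32 reconstruction grid at
2 × 2 × 3 mm³ voxels; runs in ~20 s):

```r
library(epidmvct)
cfg <- workflow_config()          # desk-scale defaults, seed 1
report <- run_shift_experiment(cfg)
report[, c("group", "gold_sx_mm", "gold_sy_mm", "tx_mm", "ty_mm",
           "err_x_mm", "err_y_mm")]
#>   group gold_sx_mm gold_sy_mm tx_mm ty_mm err_x_mm err_y_mm
#> 1     1          0          0     0     0        0        0
#> 2     2        -10          0   -10     0        0        0
#> 3     3          0         -3     0    -4        0       -1
#> 4     4          5         10     6    10        1        0
#> 5     5          3         -3     4    -4        1       -1
```

The zero-shift group registers exactly; the grid-aligned −10 mm shift is
recovered exactly; off-grid shifts land on the nearest 2 mm voxel, so their
per-axis error is at most 1 mm — the quantization limit of a one-voxel
search step.

Fluence inversion closes the loop on synthetic IMRT-like fields (sums of
rectangular and Gaussian apertures) forward-modelled through the phantom
with Poisson noise and inverted back:

```r
run_fluence_experiment(cfg)[, c("field", "passing_rate", "n_evaluated")]
#>   field passing_rate n_evaluated
#> 1     1          100         979
#> 2     2          100        2183
#> 3     3          100        5093
```

Each command is also available from a shell through the thin CLI at
`inst/cli/epidmvct.R` (`simulate`, `preprocess`, `reconstruct`, `register`,
`invert-fluence`, `gamma`, `experiment shift|fluence`).

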