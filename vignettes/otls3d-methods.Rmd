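---
title: "Models and methods behind otls3d"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind otls3d}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(otls3d)
```

otls3d reconstructs, in fully synthetic and therefore fully ground-truthed
form, the computational pipeline of a rapid 3D pathology workflow for
prostate needle-core biopsies: open-top light-sheet (OTLS) imaging of
nuclear-stained, cleared cores; shear reconstruction; edge enhancement;
multiresolution storage; pipelined batch scheduling; and multi-rater
diagnostic evaluation. This vignette explains the models, the parameters
that matter, what the synthetic data does and does not emulate, and the
design decisions taken where the original pipeline left them open.

## Acquisition geometry

A stage-scanned OTLS microscope sweeps the specimen past a light sheet
inclined at angle θ (default 45°) to the flat specimen surface. Camera frame
`k` (0-based), row `r`, column `c` samples the specimen at

    x = k·s + r·p·cosθ      (scan axis)
    y = c·p                  (lateral axis)
    z = r·p·sinθ             (depth from the surface)

with `s` the stage travel between frames and `p` the binned pixel pitch.
The key parameters, all in `acq_geometry()`:

| parameter | default | unit | rationale |
|---|---|---|---|
| `native_pixel_pitch` | 0.44 | µm/px | near-Nyquist sampling of the optics |
| `binning` | 2 | — | halves imaging time and data volume; pitch 0.88 µm |
| `sheet_angle` | 45 | ° | the open-top illumination geometry |
| `frame_interval` | `p·cosθ` ≈ 0.62 | µm | matches scan sampling to the row pitch (isotropic deskewed grid) |
| `roi_rows` × `roi_cols` | 256 × 2048 | px | 2048 columns span a ~0.9 mm strip, the width of an 18-gauge core; 256 rows best cover the ~80 µm usable vertical field of view |

`derive_geometry()` makes each derivation explicit; in particular
`roi_rows_for_fov` selects the power-of-two row count `n` in {64, …, 2048}
minimising `|n·pitch·sinθ − vertical_fov|`, and the nominal resolution is
reported as twice the binned pitch (the sampling-limited value; the true
optical point-spread function is not modelled).

## Synthetic phantoms: the stated world

`generate_phantom()` emulates a nuclear-channel-only fluorescence volume of
a needle core pressed into a 0.9 mm × 0.6 mm × 25 mm holder slot:

- **Nuclei** are solid ellipsoids (radius 3 µm by default, mild random
  anisotropy between 0.8× and 1.2×) at a uniform peak intensity. A single
  channel suffices because the assay stains nucleic acids only.
- **Benign glands** carry two concentric nuclear shells around an unstained
  lumen (secretory plus basal layer); **Gleason-3 glands** carry one shell
  around a small lumen; **Gleason-4 glands** are laid down in groups whose
  centres sit ~1.2 lumen-radii apart, so their lumens merge, and whose
  `fused_partners` fields are mutually symmetric.
- **Stroma** sits at 5% of the nuclear peak (`stroma_frac`); the real images
  show dark stroma but no published ratio exists, so this is a package
  choice, exposed as a parameter.
- A phantom is labelled `cancer` exactly when it contains at least one
  Gleason-3/4 gland, and every voxel rendered from a cancer gland is marked
  in a parallel label volume, which is what makes depth-restricted-lesion
  experiments checkable.
- `depth_range` confines cancer glands to a depth band; the placement
  margins account for the largest nuclear semi-axis, so no labelled voxel
  can escape the band. This reproduces the clinically interesting scenario
  of a lesion visible only at a specific image depth (e.g. 70 µm), which
  2D sections would likely miss.

What the generator does **not** emulate: optical blur (resolution enters
only through sampling pitch), staining and clearing kinetics, intensity
texture within nuclei, stromal structure, tissue deformation, or
multi-strip stitching. A green test therefore establishes the correctness
of the geometry, noise, reconstruction and statistics code — not the
realism of prostate histology.

## Acquisition forward model

`simulate_acquisition()` samples the phantom by trilinear interpolation at
the mapped coordinates, then applies, in order: exponential depth
attenuation `exp(−z/attenuation_length)` (default 100 µm, motivated by the
assay's stated attainable imaging depth; no published attenuation model
exists), Poisson shot noise at `photon_scale` detected photons per intensity
unit (default 50), additive Gaussian read noise (default SD 1 intensity
unit), and clipping at zero. `photon_scale = Inf`, `read_noise_sd = 0`,
`attenuation_length = Inf` (`noiseless_params()`) give the exact noiseless
model used by the oracle tests.

Two conventions were open and are fixed as follows:

- **Axial origin**: the tissue surface sits at `z = 0` of camera row 0, and
  frame `k` sits at stage position `k·s` exactly. A consequence is that the
  oblique sheet cannot reach specimen points with `x < z·cotθ` (a leading
  wedge of at most ~80 µm at the defaults — negligible against a 2 cm core,
  but visible in very short test phantoms, whose fixtures therefore place
  deep structure away from the leading edge). The trailing edge is covered
  by extending the sweep (`ceil((rows−1)·p·cosθ/s)` extra frames).
- **Seeds are explicit everywhere**; the package saves and restores the
  global RNG state around every stochastic operation, so library calls never
  perturb a caller's random stream.

## Deskew and enhancement

`deskew_stack()` inverts the acquisition geometry by shearing: frame `k`,
row `r` belongs at scan position `k·s + r·p·cosθ`. When `s` is matched to
`p·cosθ` (relative difference ≤ 10⁻³), the shear is an exact integer shift —
`out[z=r, y=c, x=k+r] = frame_k[r,c]` — which is lossless (each input pixel
lands in exactly one voxel; the pixel sum is conserved exactly). Otherwise
each row is resampled along x by 1D linear interpolation at its fractional
offset. The unfilled sheared corners carry a logical validity mask rather
than sentinel values, so downstream statistics can ignore them. Deeper rows
map to larger x by default; the sign is a flag (`shear_sign`) because the
orientation is a convention, not a measurable. Deskewed pitches are
`(z, y, x) = (p·sinθ, p, s)`.

The original pipeline's edge enhancement is described only as "Sobel-based";
its exact formula is unpublished. otls3d fixes a concrete, testable form:
for each en-face plane, Gaussian presmoothing (σ = 1 px, disableable), a
3×3 Sobel gradient magnitude with replicate padding, rescaling of the
magnitude so its maximum equals the plane's maximum, then
`clip(plane + α·M)` to the input volume's value range with α = 0.5. Only
the qualitative role (edge sharpening) is inherited; the additive unsharp
form, the rescaling and the defaults are this package's design, chosen so
that α = 0 is exactly the identity, output is monotone in α, and the value
range is preserved. Enhancement is applied after deskewing (the upstream
description lists shear first); enhancing raw frames instead would blur
edges across the oblique axis during deskew interpolation.

## Multiresolution XML/HDF5

`write_bdv()` re-saves a volume in the BigDataViewer-style container: one
setup, one timepoint, per-level datasets at `t00000/s00/<L>/cells`, with
`s00/resolutions` and `s00/subdivisions` tables. Levels are block means
(edge blocks average the available voxels), default factors (1,1,1), (2,2,2),
(4,4,4) with 64³ chunks, stored as unsigned 16-bit (values rounded and
clamped; integer-valued input round-trips bit-exactly). Compression is off
by default and exposed as a flag — the original container parameters are
unpublished. The XML affine is pure voxel scaling `diag(px, py, pz)`: the
shear has already been applied upstream, so registering any shear here would
double-apply it.

## Workflow timing model

`build_schedule()` models the pipelined 12-biopsy batch: staining (5 min)
and rinsing (3 × 30 s) happen for all cores simultaneously; loading is one
batch step; imaging (2 min/biopsy) is strictly sequential; processing
(8 min/biopsy) starts the instant a biopsy's imaging ends, with an
unbounded worker pool by default (worker count is unpublished; a limited
pool queues FIFO); a single reader diagnoses datasets in order
(35 s/biopsy). The loading time is **not reported anywhere**; the default of
3 min is an explicit assumption, which is why the model's absolute batch
total is validated against a discrete-event simulation oracle rather than
against a published turnaround figure. Rinsing and loading are modelled
strictly serially (overlap is unstated). `turnaround_summary()` decomposes
the total into prep, the imaging span, the processing tail and the
diagnosis tail — at the defaults the imaging span (24 min) dominates.

## Rater statistics

With cancer as the positive class, `diagnostic_metrics()` reports
sensitivity, specificity, accuracy, PPV and NPV both raw and rounded
half-up to two decimals (matching clinical table formatting; R's default
round-half-to-even would differ on exact ties). Ratios with zero
denominators are reported as absent (`NA`), never as 0.
`majority_vote()` uses the strict majority; with an even rater count the
tie label is configurable and defaults to benign (conservative; the study
used three raters, so ties never arise there).

Agreement uses Randolph's free-marginal formulation:
`P_o = (N·R·(R−1))⁻¹ ΣᵢΣⱼ nᵢⱼ(nᵢⱼ−1)`, κ = (P_o − 1/k)/(1 − 1/k). For
three raters a unanimous case contributes 1 to the per-case agreement and a
2–1 split contributes 1/3. The published agreement table prints "percent
overall agreement" without defining it; the unanimous-fraction reading is
inconsistent with the printed kappa under Randolph's formula, while the
P_o reading reproduces both printed numbers, so P_o is what
`overall_agreement()` computes. The confidence interval is a case-resampled
percentile bootstrap with an explicit seed; the original CI method is
unstated, so the published interval is treated as a sanity bracket, not a
reproduction target. Because the bootstrap distribution of κ on a 44-case
table is discrete, intervals from different seeds can coincide exactly.

`fixture_table()` ships the canonical 44-case × 3-rater table recovered by
inverting every published marginal (per-rater confusion counts, majority
confusion, the agreement and the cancer prevalence). The solution is unique
up to permutation of cases within their rating-pattern groups; every
statistic the package computes is permutation-invariant, which the
acceptance script demonstrates by shuffling case order under its seed.

## Numerical choices and degenerate inputs

- Trilinear sampling outside the phantom grid returns 0 (dark surround),
  and interpolation weights are never renormalised at boundaries.
- "Matched" frame interval means a relative deviation ≤ 10⁻³ from
  `p·cosθ`; beyond that the interpolating deskew path is used.
- Convolution padding is replicate (edge-clamp) for both the Gaussian and
  Sobel kernels; the Gaussian kernel is truncated at 3σ and renormalised.
- Empty stacks, NaN pixels, non-positive attenuation lengths, zero-size
  volumes, glands that cannot fit their extent (reported with the offending
  gland kind), misaligned case ids, single-rater agreement and
  single-case bootstraps are all rejected with explicit errors rather than
  silently propagated.
- The multi-page TIFF interface is implemented in-package (uncompressed,
  little-endian, grayscale uint16/float32, one strip per page) because no
  TIFF package is available in the supported runtime; it was validated
  against an independent Python TIFF implementation during development.
  Float volumes round-trip at single precision (~7 significant digits).

## Known limitations

- No optical PSF, light-sheet thickness profile, deconvolution, flat-field
  or destriping model: resolution is purely sampling-limited.
- Single channel, single strip, single timepoint; no stitching of
  overlapping strips (one 0.9 mm strip matches one core width).
- The workflow model has no file-transfer or viewer latency (the review
  server is independent of acquisition) and treats the reader as a single
  serial pathologist.
- The leading oblique wedge (`x < z·cotθ`) is unsampled by construction;
  production-scale cores make this negligible, short test phantoms must
  account for it.
- Gleason grading concordance and ROC analysis are out of scope: the
  ratings modelled are binary.
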