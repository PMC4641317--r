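---
title: "Methods: mucosal shell construction and OCC-versus-MSC dosimetry"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mucosal shell construction and OCC-versus-MSC dosimetry}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mucoshell)
```

## The model

Oral mucositis is driven by dose to the mucosal lining, a layer a few
millimetres thick on the walls of the oral cavity and the tongue
surface. A solid oral-cavity contour (OCC) used as the organ at risk
contains mostly non-mucosal tissue (tongue muscle, fat), so its
dose–volume statistics mix high-dose wall mucosa with low-dose deep
tissue. This package models the mucosa as a **mucosal surface contour
(MSC)**: a wall of finite thickness built around a delineated mucosal
*sheet*, i.e. a one-voxel-thick surface marking where the mucosa lies.

Three geometric constructions are provided:

- `expand_sheet_to_shell(sheet, thickness)` — the MSC. Every voxel
  whose centre lies within `thickness / 2` mm of the sheet (Euclidean
  distance in world millimetres) is included, so the sheet grows
  symmetrically by half the thickness on each side. With
  `side = "within"` the expansion is one-sided and clipped to a
  supplied solid mask, for workflows where the sheet marks the outer
  mucosal boundary rather than its mid-surface.
- `derive_occ_surface(solid, thickness)` — the inward annulus of a
  solid contour: voxels of the solid whose centre is within `thickness`
  mm of the solid's exterior. This approximates the mucosa from an OCC
  alone, without a sheet delineation.
- `overlap_volume`, `structure_volume` — voxel-counting volumes
  (voxel volume × count), which is the convention the rest of the
  pipeline assumes.

Dosimetry:

- `eqd2_convert(dose, scheme)` re-expresses per-voxel total physical
  dose \(D\) delivered in \(n\) fractions as
  \(\mathrm{EQD2} = D\,(d + \alpha/\beta)/(2 + \alpha/\beta)\) with
  \(d = D/n\). The whole plan shares one fraction count, so \(d\)
  varies across voxels with \(D\).
- `sample_dose` reads the EQD2 field at the structure's voxel centres.
- `compute_dvh` builds the cumulative relative DVH (volume receiving
  at least \(D\), percent).
- `build_patient_comparison` / `compare_cohort` assemble per-patient
  mean-dose reductions, hot-spot location flags, and cohort
  median/range statistics with median-DVH envelopes.

## Parameters and defaults

| Parameter | Default | Rationale |
|---|---|---|
| shell thickness | 3 mm | thick enough to be resolvable on typical CT grids, thin enough to exclude deep non-mucosal tissue; configurable everywhere |
| \(\alpha/\beta\) | 10 Gy | standard value for acutely responding mucosa |
| EQD2 reference | 2 Gy/fraction | the conversion is the identity exactly at 2 Gy per fraction |
| DVH bin width | 0.1 Gy | fine enough that binning error is negligible for mean-dose work; the axis always extends one bin past the maximum so curves reach 0 % |
| phantom spacing | 1 mm | resolves a 3 mm wall with \(\pm 1.5\) mm half-thickness; at 2 mm the symmetric wall is under-resolved and collapses toward the sheet |

## What the phantom emulates — and what it does not

`generate_phantom()` builds a synthetic oral cavity: an ellipsoidal
cavity (semi-axes 35, 45, 30 mm) whose one-voxel boundary layer is the
mucosal sheet, minus a posterior cap (half-angle 40°) where the cavity
opens to the oropharynx and no mucosal wall exists; plus the superior
surface of an inner tongue ellipsoid as the tongue dorsum. A spherical
PTV overlaps the posterior cavity, and the dose field is a 65 Gy
plateau inside the PTV with a Gaussian falloff (σ = 10 mm of distance
to the PTV surface) outside. `generate_cohort()` jitters semi-axes,
PTV centre and radius per patient under a fixed seed, redrawing any
draw that violates the anatomical invariants.

This reproduces the *geometric* essence of the problem — a dose
gradient across a cavity whose wall is the structure of interest — and
so exercises every stage of the pipeline. It does **not** emulate real
anatomy (no dentition, palate complexity, or air gaps), real plan dose
(no beam model; the plateau is idealised), or inter-observer contouring
variability. Cohort statistics from the phantom characterise the
*pipeline*, not any patient population.

One idealisation has a visible consequence: because the plateau is
exactly flat, the maximum EQD2 inside the OCC is degenerate over the
whole PTV∩OCC region. The reported hot-spot location is therefore
decided purely by the deterministic tie-break (below), and in jittered
cohort cases where the PTV pokes laterally past the cavity wall the
tie-break can select a voxel inside the MSC wall even though the
"hot spot" is equally a large interior region. Real dose fields have
unique maxima and do not show this degeneracy.

## Numerical choices

- **Exact anisotropic distance transform.** All morphology uses a
  squared Euclidean distance transform (separable lower-envelope
  algorithm, compiled C++) with per-axis spacing in millimetres, so
  distances are exact on anisotropic grids — no structuring-element
  approximations.
- **Voxel-centre membership with inclusive ties.** A voxel belongs to
  a shell when its centre distance is `<=` the threshold; a slack of
  `1e-9` mm is added so that thresholds landing exactly on a voxel
  centre (common with spacings like 0.1 mm that are not binary-exact)
  do not flip on floating-point noise.
- **Interpolate dose, never masks.** Dose is a smooth field and is
  sampled trilinearly at structure voxel centres when grids differ
  (with constant extrapolation over the half-voxel margin at the
  boundary; centres outside that margin are an error, not silently
  clamped). Occupancy is categorical: masks are resampled, if at all,
  by nearest neighbour.
- **Deterministic hot-spot tie-break.** Ties at the maximum are broken
  by the smallest `(i, j, k)` voxel index lexicographically, making
  reports byte-reproducible.
- **Seed hygiene.** `generate_phantom`/`generate_cohort` save and
  restore the caller's RNG state, so seeded generation never perturbs
  an enclosing analysis.
- **Tangency tolerance.** The default tongue grazes the cavity wall
  (implicit ellipsoid value ≈ 1.00007 at one boundary point);
  containment is checked with a `1e-3` tolerance, which admits
  sub-voxel tangency but still rejects genuine protrusion.
- **NIfTI conventions.** Grids are carried in the sform affine only
  (the quaternion form cannot represent anisotropic scaling exactly);
  oblique or axis-flipping affines are rejected rather than resampled
  so geometry stays exact. Masks are stored as uint8 (bit-exact
  round-trip), dose as float32.

## Problem sizes and runtime

The default phantom is a 101 × 121 × 91 grid at 1 mm (≈ 1.1 M voxels);
a single case generates and compares in a few seconds, and the full
11-patient cohort pipeline in `scripts/acceptance.R` runs in well under
a minute. Unit tests use 2 mm phantoms where the behaviour under test
is resolution-independent.

## Known limitations

- Volumes are voxel counts; partial-volume effects make thin-structure
  volumes converge only linearly in spacing, and a one-voxel *sheet*'s
  volume is proportional to spacing by construction (it is a surface,
  not a volume — compare shells, not sheets, across resolutions).
- Digital shells carry a half-voxel outward bias relative to the
  continuum object, noticeable for structures only a few voxels thick.
- The flat-plateau dose degeneracy described above affects hot-spot
  *location* flags on the phantom, not dose statistics.
- Only axis-aligned, positive-spacing grids are supported; data on
  oblique grids must be resampled upstream.

```{r example, eval = FALSE}
case <- generate_phantom(phantom_spec())
pc <- build_patient_comparison(case$occ_solid, case$msc_truth, NULL,
                               case$ptv, case$dose, case$scheme)
pc$reduction_pct  # ~30.2 on the default case
```
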