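---
title: "Methods: virtual bore-probe analysis of transpubic screw corridors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: virtual bore-probe analysis of transpubic screw corridors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(corridorprobe)
```

## The screening model

A transpubic screw corridor is screened by a rigid, straight cylindrical
probe between two landmarks: the entry at the pubic tubercle and the exit
at the posterior lateral ilium, both in world millimetres. The probe is a
geometric stand-in for the screw; the decision is purely radiological:

* At stations spaced `step_mm` (default **1 mm**) along the entry-exit
  segment, the probe cross-section is sampled on concentric rings of points
  (default 2 rings x 16 angles plus the centre, outer ring exactly at the
  probe radius) and the HU volume is interpolated trilinearly at each
  point.
* A station is *cortical* if the **maximum** over its disc samples strictly
  exceeds `cortical_threshold_hu` (default **400 HU**, the conventional
  cortical/trabecular boundary on calibrated CT). The maximum, rather than
  the centre or mean, is used so that grazing contact at the probe surface
  counts as contact; ties at exactly 400 are non-cortical (strict
  inequality).
* Maximal contiguous runs of cortical stations are computed. The run
  containing the first station is the entry crossing; the run containing
  the last is the exit crossing. A bicortical screw must cross these two
  cortices, so they are exempt. Every other ("interior") run is an
  undesired perforation.
* The corridor is **accessible** iff there is no interior run *and* the
  entry and exit runs are distinct. A single run spanning the whole
  corridor means the probe never traverses trabecular bone and is ruled
  not accessible.
* Accessible corridors contribute their Euclidean landmark distance as
  screw length. Excluded corridors are classified by where their interior
  runs fall — `ramus` or `acetabulum`, looked up at each run's arc midpoint
  in a region map (arc-fraction intervals, or a label volume by
  nearest-neighbour lookup): group 1 = ramus only, 2 = acetabulum only,
  3 = both.

### Assumptions

The probe is straight (rigid implants), the analysis is done entirely in
world coordinates through the volume's affine (no axis-aligned-anatomy
assumption, no left/right mirroring logic), and a probe sample falling
outside the scanned volume is an error rather than NaN — it indicates
misplaced landmarks, and silently extrapolating HU would corrupt the
verdict.

### Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `probe_diameter_mm` | 7.5 | mm | screening diameter for a 7.3 mm clinical implant; configurable, and accessibility is monotone (non-increasing) in it |
| `step_mm` | 1.0 | mm | station spacing; the exit point is always appended as a final station so the last partial interval is covered |
| `cortical_threshold_hu` | 400 | HU | cortical-bone rule; accessibility is monotone (non-decreasing) in it |
| `n_rings`, `n_angles` | 2, 16 | – | disc sampling density: ~1.5 mm outer-ring arc spacing at radius 3.75 mm, below the native voxel size |

## Grey-value profiles and cohort outputs

Per-station summaries are kept three ways (`center_hu`, `mean_hu`,
`max_hu`). Cohort profiles use `mean_hu`: the maximum is a detection
statistic (extreme-value biased), while the disc mean is the natural
estimate of local bone stock. Each accessible corridor's `mean_hu` sequence
is resampled by linear interpolation onto `round(mean accessible length)
+ 1` equally spaced points — i.e. normalized to the average screw length at
1 mm nominal spacing — and averaged pointwise; endpoints are preserved
exactly and interpolation cannot leave the original value range. Length
statistics (mean, min, max, sample SD with the n−1 denominator, as in
common statistics packages) are computed over accessible corridors only;
accessibility rates per stratum and perforation-group tallies over excluded
corridors complete the summary. Rates are rounded to one decimal only at
presentation.

Inference uses a two-sided Mann–Whitney U (lengths by sex/ethnicity) and
Pearson's chi-square (accessibility by sex). The U test enumerates the full
permutation null (`choose(n1+n2, n1)` assignments, midranks for ties) when
both groups have ≤ 8 observations, and otherwise uses the tie-corrected
normal approximation with a 0.5 continuity correction; the reported
statistic is min(U1, U2). The chi-square is the plain Pearson sum without
continuity correction — statistics suites print both corrected and
uncorrected 2×2 values, and the uncorrected form is the one that matches
hand evaluation of Σ(O−E)²/E; a `yates` flag is available. No
multiple-testing adjustment is applied, mirroring the source analysis.

## The phantom generator: what it emulates

`phantom_spec()`/`make_phantom()` build a curved arc-tube bone analogue:

* a **circular-arc centerline** with chord `chord_length_mm` and
  `sagitta_mm` (max deviation of arc from chord) — the curvature of the
  superior pubic ramus;
* a trabecular medullary tube of `inner_radius_mm` (optionally narrowed
  mid-corridor by `waist_mm`), a cortical shell of `cortex_thickness_mm`,
  hemispherical end caps, and HU levels per tissue (means 40 background /
  150 ramus trabecular / 350 periacetabular trabecular / 800 cortex /
  1100 exit cortex, Gaussian noise per voxel);
* the landmarks sit mid-cortex in the two end caps, separated by exactly
  `chord_length_mm`, so the probe's first and last stations are cortical
  (the permitted crossings) and measured length equals the nominal length
  with no voxelization error;
* an optional **acetabular wall** — a solid cortical spherical cap offset
  from the corridor near 2/3 arc length — whose offset is the knob that
  produces acetabulum-region (group 2) perforations.

Accessibility of the straight probe has the closed form **clearance =
inner radius − sagitta ≥ probe radius** (reduced further by the waist or an
intruding wall), computed analytically before voxelization and returned as
ground truth with every phantom.

Cohorts (`cohort_spec()`/`sample_cohort()`) draw per-corridor lengths from
one truncated normal — mean 131.7 mm, SD 10.71 mm, truncated at the
observed extremes 104.9/161.4 mm — identically for both sexes and
ethnicities, and per-sex narrowness parameters (male: inner radius
N(6.0, 0.5), sagitta N(1.88, 0.6); female: N(5.8, 0.5) and N(1.95, 0.6),
truncated at 4.5 mm and 0) chosen once so that the analytic accessibility
rule gives ≈ 68% in males and ≈ 55% in females: females get narrower, more
curved corridors, while length carries no sex signal. Two corridors per
specimen; ethnicity labels (2:1) have no geometric effect. Everything
derives deterministically from `master_seed`, and both `make_phantom()` and
`sample_cohort()` restore the caller's RNG state.

### Numerical and calibration choices

* **Periacetabular noise SD = 15 HU.** The perforation detector maximizes
  over thousands of interpolated samples per corridor, so a tissue mean
  within ~3 SD of 400 HU would perforate essentially every corridor by
  noise alone. At mean 350, SD 15 keeps the false-positive probability
  negligible while leaving visible texture; the other tissues sit far
  enough from 400 to tolerate SDs of 15–100.
* **Voxel spacing** defaults to 0.7 × 0.7 × 0.6 mm (native CT resolution);
  cohort work uses a 1.5 mm isotropic coarse mode for speed.
* **Truncation of the length distribution** at the observed extremes
  shrinks the sample SD from the nominal 10.71 to ≈ 10.3 mm and shifts the
  mean by ≈ +0.1 mm; recovery checks account for this.
* **Detection bias at voxel scale.** Trilinear interpolation smooths the
  voxelized cortex boundary outward, and the disc maximum flips as soon as
  any sample crosses 400, so the effective clearance threshold sits up to
  ~1 voxel above the analytic 3.75 mm (conservative: borderline corridors
  are called inaccessible). Consequently the *measured* accessibility rate
  of a cohort falls below the analytic calibration at coarse resolution —
  at 1.5 mm voxels roughly 20–35% instead of ~60%. Verdicts are
  grid-faithful: they agree with a brute-force voxel-enumeration oracle
  away from half a voxel diagonal of the analytic boundary, and the flip
  point itself is within one voxel diagonal of 3.75 mm.
* **Run-rule blind spot.** The entry/exit exemption is parameter-free
  (contiguity with the first/last station). A perforation that merges
  contiguously with an entry or exit crossing is therefore absorbed into
  it; this can only happen when wall contact extends essentially to the
  corridor ends (very shallow curvature with a large clearance deficit),
  a regime far from the anatomy the screen targets.

### What a green test does not establish

The phantom is a tube, not a pelvis: no real cortical thickness variation,
no trabecular architecture, no marrow fat, no beam hardening or metal
artefacts, no landmark placement error, and its curvature is a single
circular arc. Green pipeline tests establish that the *decision rule and
its implementation* are correct on worlds with known truth — not that the
default narrowness distributions describe any real population (they are
free parameters, deliberately not estimates).

## Degenerate inputs and tie-breaks

Coincident landmarks, non-invertible affines, empty samples, zero
chi-square margins and region-less events are errors, not warnings.
Exactly-400 HU samples are non-cortical. An all-cortical profile is one
run flagged both entry and exit, hence not accessible. Empty cohort strata
report n = 0 with absent statistics rather than dividing by zero. Excluded
corridors whose events have no ramus/acetabulum region are tallied as
`unclassified` rather than being forced into a group.

## Known limitations

Volumes must fit in memory as dense arrays; DICOM series are not read
(convert upstream); the probe is straight, so curved implant paths are out
of scope; and the statistical-shape-model machinery that would produce
landmarks automatically is deliberately absent — landmarks are inputs.
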