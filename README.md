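# corridorprobe

Virtual bore-probe feasibility analysis of retrograde transpubic screw
corridors on CT volumes, with a parametric synthetic bone-phantom generator
for end-to-end validation.

## The problem

Retrograde transpubic screws stabilize fractures of the anterior pelvic
ring through the superior pubic ramus. Whether a rigid screw of a given
diameter actually fits is an anatomical question: the corridor between the
pubic tubercle (entry) and the posterior lateral ilium (exit) is narrow and
curved, and in a substantial fraction of pelves a 7.5 mm cylinder cannot
pass without breaching cortical bone at the acetabular joint surface or
along the ramus. `corridorprobe` implements the screening analysis used to
answer that question on calibrated CT data in Hounsfield units (HU):

1. place a straight cylindrical **bore probe** (default diameter 7.5 mm)
   between user-supplied entry/exit landmarks (world mm);
2. sample interpolated HU over the probe cross-section at **1 mm stations**
   (trilinear interpolation, 2 rings x 16 angles per disc by default);
3. a station is **cortical** when any disc sample strictly exceeds
   **400 HU**; maximal contiguous cortical runs containing the first or
   last station are the permitted entry/exit crossings;
4. any **interior cortical run** is an undesired perforation: the corridor
   is *not accessible* and is excluded from length analysis, with the
   perforation site classified as group 1 (pubic ramus), 2 (acetabulum) or
   3 (both) from a region map;
5. accessible corridors contribute their landmark distance as **screw
   length** and their station HU sequence, normalized to the cohort's
   average screw length, to the **mean grey-value profile**;
6. cohort contrasts use the **Mann-Whitney U** test (exact enumeration for
   small groups) and **Pearson's chi-square** (no continuity correction by
   default), two-sided at alpha = 0.05.

Because clinical CT cohorts are not redistributable, the package ships a
first-class phantom generator: a curved arc-tube bone analogue whose
accessibility has the closed form *clearance = inner radius − sagitta ≥
probe radius*, known before voxelization. Cohorts of phantoms reproduce the
statistical structure the analysis assumes (lengths ~ truncated normal
(131.7, 10.71) mm on [104.9, 161.4]; narrowness differing by sex so that
accessibility does, while length does not).

## Worked example

```r
library(corridorprobe)

# one phantom at the native CT resolution (0.7 x 0.7 x 0.6 mm)
spec <- phantom_spec(chord_length_mm = 131.7, sagitta_mm = 1.5,
                     inner_radius_mm = 6)
ph <- make_phantom(spec, specimen_id = "S0001")
ph$volume
#> <hu_volume> 207 x 45 x 50 voxels, spacing 0.7 x 0.7 x 0.6 mm
#>   HU range [-33.232, 1500]

an <- analyze_corridor(ph$volume, ph$landmarks, analysis_config(), ph$regions)
an$result
#> <accessibility_result> S0001/left accessible, length 131.7 mm
head(an$profile$stations, 4)
#>   index arc_mm center_hu  mean_hu   max_hu is_cortical
#> 1     0      0  824.3217 696.8293 866.1955        TRUE
#> 2     1      1  805.3575 812.7851 918.4848        TRUE
#> 3     2      2  168.6275 457.0240 863.1181        TRUE
#> 4     3      3  136.9103 191.7476 280.0750       FALSE
```

The clearance here is 6 − 1.5 = 4.5 mm ≥ 3.75 mm, so the probe fits; the
first stations are cortical (the permitted entry crossing through the
pubic-tubercle cortex) and the profile then drops to trabecular values.

A small synthetic cohort, end to end (coarse 1.5 mm voxels for speed):

```r
co  <- cohort_spec(n_specimens = 15, master_seed = 2026)
run <- analyze_phantom_cohort(sample_cohort(co))
summarize_cohort(run$results)
#> <cohort_summary> 30 corridors, 7 accessible (23.3%)
#>   screw length: mean 130.0 mm (SD 10.09, range 117.2-147.2, n = 7)

cohort_tests(run$results)$length_by_sex
#> <test_result> Mann-Whitney U (exact enumeration): statistic = 1, p = 0.1905 (alpha = 0.05)
```

Accessible corridors have mean length ≈ 130 mm with SD ≈ 10 — the length
distribution is recovered regardless of resolution, because length is a
landmark distance. The accessibility *rate* at coarse resolution is lower
than the analytic clearance rule predicts: trilinear sampling on 1.5 mm
voxels detects the cortical wall up to ~1 voxel early, a conservative bias
that shrinks with voxel size (see the methods vignette). Verdicts more than
half a voxel diagonal away from the analytic clearance boundary agree with
a brute-force voxel-enumeration oracle.

Full report bundle (CSV tables, station JSON, Markdown report, provenance):

```r
run_pipeline(list(cohort = co), "out_dir")
```

or from the shell, `inst/cli/corridorprobe synth|run --cohort cohort.json
--out DIR`.

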