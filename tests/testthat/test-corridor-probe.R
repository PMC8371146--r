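# bore-probe sampling, cortical run detection, accessibility decision,
# perforation-site classification

test_that("constant-0 volume: no cortical stations, accessible, exact length", {
  vol <- const_volume(0, n = 40, spacing = c(1, 1, 1))
  lm <- landmark_pair(c(10, 20, 20), c(30, 20, 20))
  prof <- sample_bore_probe(vol, lm)
  expect_true(all(prof$stations$max_hu == 0))
  expect_false(any(prof$stations$is_cortical))
  res <- assess_accessibility(prof)
  expect_true(res$accessible)
  expect_equal(res$length_mm, 20)
  expect_equal(nrow(res$events), 0L)
})

test_that("station summaries satisfy center <= max, mean <= max, arcs increase", {
  spec <- phantom_spec(chord_length_mm = 60, sagitta_mm = 1,
                       spacing_mm = c(1.5, 1.5, 1.5), noise_seed = 4)
  ph <- make_phantom(spec)
  prof <- sample_bore_probe(ph$volume, ph$landmarks)
  expect_true(all(prof$stations$center_hu <= prof$stations$max_hu + 1e-9))
  expect_true(all(prof$stations$mean_hu <= prof$stations$max_hu + 1e-9))
  expect_true(all(diff(prof$stations$arc_mm) > 0))
  expect_equal(prof$length_mm, prof$stations$arc_mm[nrow(prof$stations)])
})

test_that("straight tube crossed at entry/exit only: cortical runs are exactly those", {
  spec <- phantom_spec(chord_length_mm = 80, sagitta_mm = 0, inner_radius_mm = 6,
                       hu_levels = default_hu_levels(0), spacing_mm = c(1, 1, 1))
  ph <- make_phantom(spec)
  prof <- sample_bore_probe(ph$volume, ph$landmarks)
  runs <- find_cortical_runs(prof)
  expect_equal(nrow(runs), 2L)
  expect_true(runs$is_entry[1] && !runs$is_exit[1])
  expect_true(runs$is_exit[2] && !runs$is_entry[2])
  # cross-check against the voxel-enumeration oracle
  orc <- oracle_accessibility(ph$volume, ph$landmarks)
  expect_true(orc$accessible)
  expect_true(assess_accessibility(prof)$accessible)
})

test_that("probe leaving the volume names the offending station", {
  vol <- const_volume(0, n = 20, spacing = c(1, 1, 1))
  lm <- landmark_pair(c(10, 10, 10), c(40, 10, 10))
  expect_error(sample_bore_probe(vol, lm), "station")
})

test_that("cortical runs from explicit patterns", {
  runs <- find_cortical_runs(profile_from_pattern(c(T, T, F, F, T, F, T)))
  expect_equal(runs$start, c(0L, 4L, 6L))
  expect_equal(runs$end, c(1L, 4L, 6L))
  expect_equal(runs$is_entry, c(TRUE, FALSE, FALSE))
  expect_equal(runs$is_exit, c(FALSE, FALSE, TRUE))

  expect_equal(nrow(find_cortical_runs(profile_from_pattern(rep(FALSE, 6)))), 0L)

  all_true <- find_cortical_runs(profile_from_pattern(rep(TRUE, 5)))
  expect_equal(nrow(all_true), 1L)
  expect_true(all_true$is_entry && all_true$is_exit)
})

test_that("accessibility rule: interior runs exclude; spanning run excludes", {
  expect_true(assess_accessibility(profile_from_pattern(c(T, T, F, F, F, T)))$accessible)
  r <- assess_accessibility(profile_from_pattern(c(T, F, F, T, F, T)))
  expect_false(r$accessible)
  expect_true(is.na(r$length_mm))
  expect_equal(nrow(r$events), 1L)
  expect_equal(r$events$start, 3L)
  # a fully cortical corridor never traverses trabecular bone
  r2 <- assess_accessibility(profile_from_pattern(rep(TRUE, 7)))
  expect_false(r2$accessible)
})

test_that("arc-tube clearance rule: r - h vs probe radius", {
  # inner radius 6, sagitta 1: clearance 5 >= 3.75 -> accessible
  ok <- phantom_spec(chord_length_mm = 70, sagitta_mm = 1, inner_radius_mm = 6,
                     hu_levels = default_hu_levels(0), spacing_mm = c(1, 1, 1))
  ph <- make_phantom(ok)
  expect_true(ph$truth$accessible_expected)
  expect_equal(ph$truth$min_clearance_mm, 5, tolerance = 1e-6)
  expect_true(assess_accessibility(sample_bore_probe(ph$volume, ph$landmarks))$accessible)

  # inner radius 5, sagitta 2: clearance 3 < 3.75 -> interior event near mid
  bad <- phantom_spec(chord_length_mm = 70, sagitta_mm = 2, inner_radius_mm = 5,
                      hu_levels = default_hu_levels(0), spacing_mm = c(1, 1, 1))
  ph2 <- make_phantom(bad)
  expect_false(ph2$truth$accessible_expected)
  res <- assess_accessibility(sample_bore_probe(ph2$volume, ph2$landmarks),
                              ph2$regions)
  expect_false(res$accessible)
  expect_gte(nrow(res$events), 1L)
  mid <- (res$events$arc_start_mm + res$events$arc_end_mm) / 2
  expect_true(any(abs(mid - 35) < 15))
})

test_that("accessibility is monotone in probe diameter and in threshold", {
  spec <- phantom_spec(chord_length_mm = 60, sagitta_mm = 1.8,
                       inner_radius_mm = 5.6, hu_levels = default_hu_levels(0),
                       spacing_mm = c(1, 1, 1))
  ph <- make_phantom(spec)
  verdict <- function(diam, thr = 400) {
    cfg <- analysis_config(probe_diameter_mm = diam, cortical_threshold_hu = thr)
    assess_accessibility(sample_bore_probe(ph$volume, ph$landmarks, cfg))$accessible
  }
  acc <- vapply(c(3, 5, 6.5, 7.5, 9), verdict, logical(1))
  expect_true(all(diff(acc) <= 0))            # non-increasing in diameter
  thr <- vapply(c(200, 400, 900, 1200), function(t) verdict(7.5, t), logical(1))
  expect_true(all(diff(thr) >= 0))            # non-decreasing in threshold
})

test_that("perforation-site groups from event region sets", {
  ev <- function(regions) data.frame(start = seq_along(regions), end = seq_along(regions),
                                     arc_start_mm = 1, arc_end_mm = 2,
                                     region = regions)
  expect_equal(classify_perforation_site(ev("ramus")), 1L)
  expect_equal(classify_perforation_site(ev(c("acetabulum", "acetabulum"))), 2L)
  expect_equal(classify_perforation_site(ev(c("ramus", "acetabulum"))), 3L)
  expect_equal(classify_perforation_site(ev(c("ramus", "other"))), 1L)
  expect_error(classify_perforation_site(ev("ramus")[0, ]), "at least one")
  expect_error(classify_perforation_site(ev(c("other", "unassigned"))), "no perforation event")
})

test_that("acetabular wall cap produces a group-2 exclusion", {
  spec <- phantom_spec(chord_length_mm = 80, sagitta_mm = 0.5, inner_radius_mm = 6,
                       hu_levels = default_hu_levels(0), spacing_mm = c(1, 1, 1),
                       acetabular_wall = list(frac = 0.67, offset_mm = 2,
                                              radius_mm = 4))
  ph <- make_phantom(spec)
  expect_false(ph$truth$accessible_expected)
  res <- assess_accessibility(sample_bore_probe(ph$volume, ph$landmarks),
                              ph$regions)
  expect_false(res$accessible)
  expect_equal(res$group, 2L)
})

test_that("region lookup works from a label volume as well as intervals", {
  # label volume: first 60% of x labelled 1 (ramus), rest 2 (acetabulum)
  n <- 40
  lab <- array(1, c(n, 9, 9))
  lab[25:n, , ] <- 2
  lvol <- hu_volume(lab, rbind(cbind(diag(c(1, 1, 1)), c(0, -4, -4)), c(0, 0, 0, 1)))
  rmap <- region_label_volume(lvol, c("1" = "ramus", "2" = "acetabulum"))
  prof <- profile_from_pattern(c(TRUE, rep(FALSE, 9), TRUE, rep(FALSE, 24), TRUE,
                                 rep(FALSE, 3), TRUE))
  res <- assess_accessibility(prof, rmap)
  expect_false(res$accessible)
  expect_equal(res$events$region, c("ramus", "acetabulum"))
  expect_equal(res$group, 3L)
})
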