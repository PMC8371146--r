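# phantom generator: spec validation, ground truth, seed contract, cohorts

test_that("phantom_spec rejects specs that cannot express 'cortical'", {
  lev <- default_hu_levels()
  lev$cortex <- c(350, 10)
  expect_error(phantom_spec(hu_levels = lev), "must exceed 400")
  lev2 <- default_hu_levels()
  lev2$trabecular_periacetabular <- c(450, 10)
  expect_error(phantom_spec(hu_levels = lev2), "below 400")
  expect_error(phantom_spec(sagitta_mm = -1), "sagitta")
  expect_error(phantom_spec(inner_radius_mm = 0), "inner_radius")
  expect_error(phantom_spec(chord_length_mm = 10), "too short")
})

test_that("noise-free straight tube: accessible, length equals the chord", {
  spec <- phantom_spec(chord_length_mm = 90, sagitta_mm = 0, inner_radius_mm = 6,
                       hu_levels = default_hu_levels(0), spacing_mm = c(1.5, 1.5, 1.5))
  ph <- make_phantom(spec)
  expect_true(ph$truth$accessible_expected)
  expect_equal(ph$truth$min_clearance_mm, 6, tolerance = 1e-6)
  res <- assess_accessibility(sample_bore_probe(ph$volume, ph$landmarks))
  expect_true(res$accessible)
  expect_equal(res$length_mm, 90)   # landmark distance, independent of voxels
})

test_that("ground truth closed form: clearance = inner radius - sagitta", {
  spec <- phantom_spec(chord_length_mm = 80, sagitta_mm = 2, inner_radius_mm = 5,
                       hu_levels = default_hu_levels(0))
  gt <- phantom_ground_truth(spec)
  expect_equal(gt$min_clearance_mm, 3, tolerance = 1e-4)
  expect_false(gt$accessible_expected)
  expect_equal(gt$length_mm, 80)
  # waist narrows the clearance further
  spec2 <- phantom_spec(chord_length_mm = 80, sagitta_mm = 2, inner_radius_mm = 5,
                        waist_mm = 1)
  expect_equal(phantom_ground_truth(spec2)$min_clearance_mm, 2, tolerance = 1e-3)
})

test_that("noise seed contract: same truth, reproducible fields", {
  base <- list(chord_length_mm = 60, sagitta_mm = 1, inner_radius_mm = 5.5,
               spacing_mm = c(1.5, 1.5, 1.5))
  s1 <- do.call(phantom_spec, c(base, noise_seed = 1))
  s2 <- do.call(phantom_spec, c(base, noise_seed = 2))
  p1 <- make_phantom(s1); p2 <- make_phantom(s2)
  expect_equal(p1$truth, p2$truth)
  expect_false(identical(p1$volume$values, p2$volume$values))
  expect_identical(make_phantom(s1)$volume$values, p1$volume$values)
})

test_that("make_phantom does not disturb the caller's RNG stream", {
  set.seed(123); a <- runif(1)
  set.seed(123)
  invisible(make_phantom(phantom_spec(chord_length_mm = 40,
                                      spacing_mm = c(2, 2, 2), margin_mm = 4)))
  expect_identical(runif(1), a)
})

test_that("sample_cohort is deterministic given master_seed", {
  co <- cohort_spec(n_specimens = 12, master_seed = 77)
  d1 <- sample_cohort(co)
  d2 <- sample_cohort(co)
  expect_identical(d1, d2)
  d3 <- sample_cohort(cohort_spec(n_specimens = 12, master_seed = 78))
  expect_false(identical(d1$chord_length_mm, d3$chord_length_mm))
  expect_equal(nrow(d1), 24L)   # two corridors per specimen
})

test_that("cohort lengths follow the stated truncated normal", {
  d <- sample_cohort(cohort_spec(n_specimens = 1000, master_seed = 5))
  len <- d$chord_length_mm
  expect_true(all(len >= 104.9 & len <= 161.4))
  se <- sd(len) / sqrt(length(len))
  expect_lt(abs(mean(len) - 131.7), 3 * se + 0.2)  # truncation shifts ~+0.1
  expect_lt(abs(sd(len) - 10.71), 0.1 * 10.71)     # truncation shrinks to ~10.3
  # identical distribution across sexes
  expect_gt(mann_whitney_u(len[d$sex == "male"],
                           len[d$sex == "female"])$p_value, 0.01)
})

test_that("male clearance stochastically dominates female clearance", {
  d <- sample_cohort(cohort_spec(n_specimens = 250, master_seed = 9))
  acc <- d$clearance_mm >= 3.75
  rate_m <- mean(acc[d$sex == "male"])
  rate_f <- mean(acc[d$sex == "female"])
  expect_gt(rate_m, rate_f)
  # and at the distribution level, not just the rate
  expect_gt(mean(d$clearance_mm[d$sex == "male"]),
            mean(d$clearance_mm[d$sex == "female"]))
})

test_that("pipeline recovers ground truth on a noise-free mini cohort", {
  co <- cohort_spec(n_specimens = 6, master_seed = 31)
  d <- sample_cohort(co)
  # strip noise for exact recovery away from the boundary
  d$spec <- lapply(d$spec, function(s) { s$hu_levels <- default_hu_levels(0); s })
  an <- analyze_phantom_cohort(d, keep_profiles = FALSE)
  res <- an$results
  diag_mm <- sqrt(sum(c(1.5, 1.5, 1.5)^2))
  clear <- res$min_clearance_mm
  away <- abs(clear - 3.75) > diag_mm / 2
  expect_true(all(res$accessible[away] == res$accessible_expected[away]))
  expect_equal(res$length_mm[res$accessible], d$chord_length_mm[res$accessible],
               tolerance = 1e-9)
})
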