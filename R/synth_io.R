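# Write a synthetic cohort to disk in the same formats the analysis reads:
# NIfTI volumes, a landmarks CSV, per-corridor region-interval JSON, and
# ground-truth/covariate CSVs. Used by the `synth` CLI subcommand and by
# round-trip tests.

#' Materialize a synthetic cohort on disk
#'
#' @param cohort a [cohort_spec] (or data.frame from [sample_cohort]).
#' @param out_dir output directory.
#' @param format volume format extension: `"nii.gz"` (default), `"nii"`,
#'   `"mha"`.
#' @return data.frame listing, per corridor, the written volume path plus
#'   covariates and ground truth, invisibly. Files written:
#'   `volumes/<id>_<side>.<format>`, `landmarks.csv`, `regions.json`,
#'   `ground_truth.csv`, `covariates.csv`.
#' @export
write_synthetic_cohort <- function(cohort, out_dir, format = "nii.gz") {
  drawn <- if (inherits(cohort, "cohort_spec")) sample_cohort(cohort) else cohort
  dir.create(file.path(out_dir, "volumes"), showWarnings = FALSE,
             recursive = TRUE)
  n <- nrow(drawn)
  lms <- vector("list", n)
  gt <- vector("list", n)
  paths <- character(n)
  for (i in seq_len(n)) {
    ph <- make_phantom(drawn$spec[[i]], specimen_id = drawn$specimen_id[i],
                       side = drawn$side[i])
    paths[i] <- file.path(out_dir, "volumes",
                          sprintf("%s_%s.%s", drawn$specimen_id[i],
                                  drawn$side[i], format))
    write_volume(ph$volume, paths[i])
    lms[[i]] <- ph$landmarks
    gt[[i]] <- data.frame(
      specimen_id = drawn$specimen_id[i], side = drawn$side[i],
      accessible_expected = ph$truth$accessible_expected,
      min_clearance_mm = ph$truth$min_clearance_mm,
      length_mm = ph$truth$length_mm)
  }
  write_landmarks(lms, file.path(out_dir, "landmarks.csv"))
  gt <- do.call(rbind, gt)
  utils::write.csv(gt, file.path(out_dir, "ground_truth.csv"),
                   row.names = FALSE)
  covars <- drawn[, c("specimen_id", "side", "sex", "ethnicity",
                      "chord_length_mm", "inner_radius_mm", "sagitta_mm",
                      "clearance_mm")]
  utils::write.csv(covars, file.path(out_dir, "covariates.csv"),
                   row.names = FALSE)
  # all phantoms share the analytic two-interval region map
  ri <- phantom_ground_truth(drawn$spec[[1]])$region_intervals
  jsonlite::write_json(ri$breaks, file.path(out_dir, "regions.json"),
                       auto_unbox = TRUE, digits = 8)
  out <- cbind(volume = paths, covars, gt[, -(1:2)])
  invisible(out)
}
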