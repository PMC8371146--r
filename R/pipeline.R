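# End-to-end pipeline: analyze corridors (from files or a synthetic
# cohort), aggregate, test, and write a deterministic report bundle.
# All outputs are plain text (CSV/JSON/Markdown); reruns with identical
# config and seeds produce byte-identical files.

#' Analyze one corridor
#'
#' Samples the bore probe and assesses accessibility in one call.
#'
#' @param vol an [hu_volume].
#' @param lm a [landmark_pair].
#' @param cfg an [analysis_config].
#' @param regions optional region map.
#' @return list with `profile` (`probe_profile`) and `result`
#'   (`accessibility_result`).
#' @export
analyze_corridor <- function(vol, lm, cfg = analysis_config(), regions = NULL) {
  profile <- sample_bore_probe(vol, lm, cfg)
  result <- assess_accessibility(profile, regions)
  list(profile = profile, result = result)
}

#' Analyze a synthetic phantom cohort
#'
#' Voxelizes each phantom spec drawn by [sample_cohort], runs the bore
#' probe, and collects per-corridor results with covariates. Each phantom's
#' own analytic region map classifies perforation sites.
#'
#' @param cohort_df data.frame from [sample_cohort].
#' @param cfg an [analysis_config].
#' @param keep_profiles keep `probe_profile` objects (needed for the mean
#'   grey-value profile); default TRUE.
#' @return list with `results` (data.frame: covariates + `accessible`,
#'   `length_mm`, `n_events`, `group`, `min_clearance_mm`,
#'   `accessible_expected`) and `profiles` (list, accessible corridors only,
#'   NULL when `keep_profiles` is FALSE).
#' @export
analyze_phantom_cohort <- function(cohort_df, cfg = analysis_config(),
                                   keep_profiles = TRUE) {
  n <- nrow(cohort_df)
  profiles <- if (keep_profiles) vector("list", n) else NULL
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    ph <- make_phantom(cohort_df$spec[[i]],
                       specimen_id = cohort_df$specimen_id[i],
                       side = cohort_df$side[i])
    an <- analyze_corridor(ph$volume, ph$landmarks, cfg, ph$regions)
    res <- an$result
    rows[[i]] <- data.frame(
      specimen_id = cohort_df$specimen_id[i],
      side = cohort_df$side[i],
      sex = cohort_df$sex[i],
      ethnicity = cohort_df$ethnicity[i],
      accessible = res$accessible,
      length_mm = res$length_mm,
      n_events = nrow(res$events),
      group = res$group,
      min_clearance_mm = ph$truth$min_clearance_mm,
      accessible_expected = ph$truth$accessible_expected,
      stringsAsFactors = FALSE
    )
    if (keep_profiles && res$accessible) profiles[[i]] <- an$profile
  }
  results <- do.call(rbind, rows)
  if (keep_profiles) profiles <- profiles[!vapply(profiles, is.null, logical(1))]
  list(results = results, profiles = profiles)
}

#' Run the full pipeline and write a report bundle
#'
#' Two input modes. Synthetic: `config$cohort` is a [cohort_spec] (or a
#' list of its arguments) and phantoms are generated on the fly. Files:
#' `config$volumes` is a vector of volume paths matched one-to-one with the
#' rows of the landmark file `config$landmarks`; `config$regions` may name a
#' JSON file with arc-fraction region intervals.
#'
#' Outputs in `out_dir`: `results.csv` (one row per corridor),
#' `results.json` (full station-level records), `table1_lengths.csv`,
#' `table2_groups.csv`, `mean_profile.csv`, `tests.json`, `report.md`,
#' `provenance.json`.
#'
#' @param config list (or path to a JSON config file).
#' @param out_dir output directory (created if missing).
#' @return the report bundle, invisibly: `results`, `summary`, `profile`
#'   (cohort mean profile or NULL), `tests`.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- if (!is.null(config$analysis)) {
    if (inherits(config$analysis, "analysis_config")) config$analysis
    else do.call(analysis_config, config$analysis)
  } else analysis_config()

  if (!is.null(config$cohort)) {
    cohort <- if (inherits(config$cohort, "cohort_spec")) config$cohort
              else do.call(cohort_spec, config$cohort)
    drawn <- sample_cohort(cohort)
    an <- analyze_phantom_cohort(drawn, cfg)
    results <- an$results
    profiles <- an$profiles
    seeds <- list(master_seed = cohort$master_seed)
  } else if (!is.null(config$volumes)) {
    lms <- read_landmarks(config$landmarks)
    if (length(config$volumes) != length(lms))
      stop("need one volume path per landmark row", call. = FALSE)
    regions <- if (!is.null(config$regions)) {
      rb <- jsonlite::fromJSON(config$regions)
      region_intervals(as.data.frame(rb), unit = "fraction")
    } else NULL
    covar <- config$covariates %||% list()
    rows <- list(); profiles <- list()
    for (i in seq_along(lms)) {
      vol <- read_volume(config$volumes[i])
      an <- tryCatch(analyze_corridor(vol, lms[[i]], cfg, regions),
                     error = function(e) e)
      if (inherits(an, "error")) {
        warning("corridor ", lms[[i]]$specimen_id, "/", lms[[i]]$side,
                " failed: ", conditionMessage(an), call. = FALSE)
        next
      }
      res <- an$result
      rows[[length(rows) + 1L]] <- data.frame(
        specimen_id = res$specimen_id, side = res$side,
        sex = covar$sex[i] %||% NA_character_,
        ethnicity = covar$ethnicity[i] %||% NA_character_,
        accessible = res$accessible, length_mm = res$length_mm,
        n_events = nrow(res$events), group = res$group,
        stringsAsFactors = FALSE)
      if (res$accessible) profiles[[length(profiles) + 1L]] <- an$profile
    }
    results <- do.call(rbind, rows)
    seeds <- list()
  } else {
    stop("config must provide either $cohort or $volumes + $landmarks",
         call. = FALSE)
  }

  has_covar <- !any(is.na(results$sex)) && !any(is.na(results$ethnicity))
  summary <- if (has_covar) summarize_cohort(results) else NULL
  profile <- if (length(profiles) > 0L) aggregate_profiles(profiles) else NULL
  tests <- if (has_covar) cohort_tests(results) else list()

  write_report_bundle(results, summary, profile, tests, profiles, cfg, seeds,
                      out_dir)
  invisible(list(results = results, summary = summary, profile = profile,
                 tests = tests))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inferential tests on a cohort results table
#'
#' Mann-Whitney U on accessible screw length by sex and by ethnicity;
#' Pearson chi-square on the accessible-by-sex 2 x 2 table.
#'
#' @param results cohort results data.frame (see [summarize_cohort]).
#' @return named list of `test_result` objects (entries dropped when a
#'   stratum is empty).
#' @export
cohort_tests <- function(results) {
  out <- list()
  acc <- results[results$accessible, ]
  two <- function(v) length(unique(v)) == 2L
  if (two(acc$sex) && all(table(acc$sex) > 0))
    out$length_by_sex <- mann_whitney_u(
      acc$length_mm[acc$sex == "male"], acc$length_mm[acc$sex == "female"])
  if (two(acc$ethnicity))
    out$length_by_ethnicity <- mann_whitney_u(
      acc$length_mm[acc$ethnicity == unique(acc$ethnicity)[1]],
      acc$length_mm[acc$ethnicity == unique(acc$ethnicity)[2]])
  tab <- table(results$sex, factor(results$accessible, c(TRUE, FALSE)))
  if (nrow(tab) == 2L && all(rowSums(tab) > 0) && all(colSums(tab) > 0))
    out$accessibility_by_sex <- pearson_chi_square(unclass(tab))
  out
}

write_report_bundle <- function(results, summary, profile, tests, profiles,
                                cfg, seeds, out_dir) {
  wcsv <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  wcsv(results[, setdiff(names(results), "spec")], "results.csv")
  if (!is.null(summary)) {
    wcsv(summary$length_stats, "table1_lengths.csv")
    wcsv(summary$group_tally, "table2_groups.csv")
    wcsv(summary$accessibility, "accessibility.csv")
  }
  if (!is.null(profile)) {
    wcsv(data.frame(arc_fraction = profile$arc_fraction,
                    mean_hu = profile$mean_hu, sd_hu = profile$sd_hu),
         "mean_profile.csv")
  }
  station_records <- lapply(profiles, function(p) {
    list(specimen_id = p$specimen_id, side = p$side,
         length_mm = p$length_mm, stations = p$stations)
  })
  jsonlite::write_json(station_records, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = 8)
  jsonlite::write_json(
    lapply(tests, function(t) list(method = t$method, statistic = t$statistic,
                                   df = t$df, p_value = t$p_value,
                                   n = as.list(t$n), alpha = t$alpha)),
    file.path(out_dir, "tests.json"), auto_unbox = TRUE, digits = 8)

  cfg_json <- jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE, digits = 10)
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  prov <- list(
    package = "corridorprobe",
    version = as.character(utils::packageVersion("corridorprobe")),
    config = unclass(cfg),
    config_md5 = unname(tools::md5sum(tmp)),
    seeds = seeds
  )
  unlink(tmp)
  jsonlite::write_json(prov, file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = 10)
  writeLines(report_markdown(results, summary, tests),
             file.path(out_dir, "report.md"))
}

report_markdown <- function(results, summary, tests) {
  lines <- c("# Corridor feasibility report", "")
  n <- nrow(results); na <- sum(results$accessible)
  lines <- c(lines, sprintf(
    "A corridor of the configured diameter was accessible in %d of %d bore probes (%.1f%%).",
    na, n, 100 * na / n), "")
  if (!is.null(summary)) {
    ls <- summary$length_stats[summary$length_stats$stratum == "all", ]
    if (ls$n > 0)
      lines <- c(lines, sprintf(
        "Mean screw length over accessible corridors: %.1f mm (SD %.2f mm, range %.1f-%.1f mm, n = %d).",
        ls$mean, ls$sd, ls$min, ls$max, ls$n), "")
  }
  for (nm in names(tests)) {
    t <- tests[[nm]]
    sig <- if (t$p_value < t$alpha) "significant" else "not significant"
    lines <- c(lines, sprintf("- %s: %s statistic %.4g, p = %.4g (%s at alpha = %g)",
                              nm, t$method, t$statistic, t$p_value, sig, t$alpha))
  }
  lines
}
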