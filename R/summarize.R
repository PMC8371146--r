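# Cohort summary tables: screw-length statistics over accessible corridors
# (excluded corridors contribute no length), accessibility counts and rates
# per stratum, and perforation-site group tallies over excluded corridors.

#' Summarize a cohort of corridor results
#'
#' @param results data.frame with one row per corridor and columns
#'   `specimen_id`, `side`, `sex` (`male`/`female`), `ethnicity`,
#'   `accessible` (logical), `length_mm` (NA when not accessible) and
#'   `group` (1/2/3 for excluded corridors, NA otherwise).
#' @return object of class `cohort_summary` with elements:
#'   * `length_stats`: per stratum (`all`, each sex, each ethnicity) the
#'     accessible-corridor count `n`, `mean`, `min`, `max` and sample `sd`
#'     of length in mm (NA when the stratum has no accessible corridor);
#'   * `accessibility`: per stratum `n_total`, `n_accessible`, `rate`
#'     (fraction in [0, 1]) and `percent` (1 d.p. presentation value);
#'   * `group_tally`: per sex the excluded count `n_excluded` and counts of
#'     perforation groups 1 (pubic ramus), 2 (acetabulum), 3 (both).
#' @export
summarize_cohort <- function(results) {
  req <- c("specimen_id", "side", "sex", "ethnicity", "accessible",
           "length_mm", "group")
  miss <- setdiff(req, names(results))
  if (length(miss))
    stop("results missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(is.na(results$sex)) || any(is.na(results$ethnicity)))
    stop("every corridor needs sex and ethnicity covariates", call. = FALSE)
  if (any(results$accessible & is.na(results$length_mm)))
    stop("accessible corridors must carry a length", call. = FALSE)

  strata <- c(list(all = rep(TRUE, nrow(results))),
              stats::setNames(lapply(sort(unique(results$sex)),
                                     function(s) results$sex == s),
                              sort(unique(results$sex))),
              stats::setNames(lapply(sort(unique(results$ethnicity)),
                                     function(e) results$ethnicity == e),
                              sort(unique(results$ethnicity))))

  length_stats <- do.call(rbind, lapply(names(strata), function(nm) {
    sel <- strata[[nm]] & results$accessible
    x <- results$length_mm[sel]
    if (length(x) == 0L) {
      data.frame(stratum = nm, n = 0L, mean = NA_real_, min = NA_real_,
                 max = NA_real_, sd = NA_real_)
    } else {
      data.frame(stratum = nm, n = length(x), mean = mean(x), min = min(x),
                 max = max(x),
                 sd = if (length(x) > 1L) stats::sd(x) else NA_real_)
    }
  }))

  accessibility <- do.call(rbind, lapply(names(strata), function(nm) {
    sel <- strata[[nm]]
    nt <- sum(sel); na <- sum(results$accessible[sel])
    rate <- if (nt > 0L) na / nt else NA_real_
    data.frame(stratum = nm, n_total = nt, n_accessible = na, rate = rate,
               percent = round(100 * rate, 1))
  }))

  group_tally <- do.call(rbind, lapply(sort(unique(results$sex)), function(s) {
    sel <- results$sex == s & !results$accessible
    g <- results$group[sel]
    data.frame(sex = s, n_excluded = sum(sel),
               group1 = sum(g == 1L, na.rm = TRUE),
               group2 = sum(g == 2L, na.rm = TRUE),
               group3 = sum(g == 3L, na.rm = TRUE),
               unclassified = sum(is.na(g)))
  }))

  structure(list(length_stats = length_stats, accessibility = accessibility,
                 group_tally = group_tally, n_total = nrow(results)),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  acc <- x$accessibility[x$accessibility$stratum == "all", ]
  cat(sprintf("<cohort_summary> %d corridors, %d accessible (%.1f%%)\n",
              x$n_total, acc$n_accessible, 100 * acc$rate))
  len <- x$length_stats[x$length_stats$stratum == "all", ]
  if (len$n > 0)
    cat(sprintf("  screw length: mean %.1f mm (SD %.2f, range %.1f-%.1f, n = %d)\n",
                len$mean, len$sd, len$min, len$max, len$n))
  invisible(x)
}
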