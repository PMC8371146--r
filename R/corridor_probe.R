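# Core corridor analysis: place the virtual bore probe between the entry and
# exit landmarks, sample HU per 1 mm station over the probe cross-section,
# flag cortical stations (HU strictly > 400 anywhere on the disc), and decide
# accessibility: any contiguous cortical run not containing the first or last
# station is an undesired perforation and excludes the corridor.

#' Analysis configuration
#'
#' Houses the three named screening parameters - probe diameter 7.5 mm,
#' 1 mm station stepping, 400 HU cortical threshold - plus the disc
#' sampling density.
#'
#' @param probe_diameter_mm bore probe diameter, default 7.5 mm.
#' @param step_mm station spacing, default 1 mm.
#' @param cortical_threshold_hu HU above which bone counts as cortical
#'   (strict inequality), default 400.
#' @param n_rings,n_angles cross-section sampling density (default 2 rings
#'   of 16 points: arc spacing ~1.5 mm at the 3.75 mm outer ring, below the
#'   native voxel size).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(probe_diameter_mm = 7.5, step_mm = 1,
                            cortical_threshold_hu = 400,
                            n_rings = 2L, n_angles = 16L) {
  if (!is.finite(probe_diameter_mm) || probe_diameter_mm <= 0)
    stop("probe_diameter_mm must be > 0", call. = FALSE)
  if (!is.finite(step_mm) || step_mm <= 0)
    stop("step_mm must be > 0", call. = FALSE)
  if (!is.finite(cortical_threshold_hu))
    stop("cortical_threshold_hu must be finite", call. = FALSE)
  structure(list(probe_diameter_mm = probe_diameter_mm, step_mm = step_mm,
                 cortical_threshold_hu = cortical_threshold_hu,
                 n_rings = as.integer(n_rings), n_angles = as.integer(n_angles)),
            class = "analysis_config")
}

#' Sample the virtual bore probe along a corridor
#'
#' Places a straight cylindrical probe of the configured diameter between the
#' entry and exit landmarks and samples interpolated HU on a disc of points
#' at every station. A station is cortical when the maximum over its disc
#' samples strictly exceeds the threshold, so wall grazing at the probe
#' boundary is detected, not just axis contact.
#'
#' @param vol an [hu_volume]; every probe sample point must lie inside it.
#' @param lm a [landmark_pair].
#' @param cfg an [analysis_config].
#' @return object of class `probe_profile`: `stations` data.frame with
#'   columns `index` (0-based), `arc_mm`, `center_hu`, `mean_hu`, `max_hu`,
#'   `is_cortical`; plus `length_mm`, `specimen_id`, `side`, `config`.
#' @export
sample_bore_probe <- function(vol, lm, cfg = analysis_config()) {
  stopifnot(inherits(vol, "hu_volume"), inherits(lm, "landmark_pair"),
            inherits(cfg, "analysis_config"))
  st <- probe_stations(lm, cfg$step_mm)
  radius <- cfg$probe_diameter_mm / 2
  n_st <- length(st$arc_mm)
  n_per <- if (radius > 0) 1L + cfg$n_rings * cfg$n_angles else 1L
  pts <- do.call(rbind, lapply(seq_len(n_st), function(i) {
    disc_samples(st$points[i, ], st$axis, radius, cfg$n_rings, cfg$n_angles)
  }))
  hu <- tryCatch(interpolate_hu(vol, pts), error = function(e) {
    bad <- tryCatch({  # identify the first offending station for the message
      for (i in seq_len(n_st)) {
        d <- disc_samples(st$points[i, ], st$axis, radius, cfg$n_rings, cfg$n_angles)
        ok <- tryCatch({ interpolate_hu(vol, d); TRUE }, error = function(e2) FALSE)
        if (!ok) break
      }
      i
    }, error = function(e2) NA_integer_)
    stop(sprintf("probe leaves the volume at station %d (arc %.1f mm): %s",
                 bad - 1L, st$arc_mm[bad], conditionMessage(e)), call. = FALSE)
  })
  hu_m <- matrix(hu, nrow = n_per)
  stations <- data.frame(
    index = seq_len(n_st) - 1L,
    arc_mm = st$arc_mm,
    center_hu = hu_m[1L, ],
    mean_hu = colMeans(hu_m),
    max_hu = apply(hu_m, 2L, max)
  )
  stations$is_cortical <- stations$max_hu > cfg$cortical_threshold_hu
  structure(list(specimen_id = lm$specimen_id, side = lm$side,
                 stations = stations, length_mm = st$length_mm,
                 entry = lm$entry, exit = lm$exit, config = cfg),
            class = "probe_profile")
}

#' @export
print.probe_profile <- function(x, ...) {
  cat(sprintf("<probe_profile> %s/%s  %.1f mm, %d stations, %d cortical\n",
              x$specimen_id, x$side, x$length_mm, nrow(x$stations),
              sum(x$stations$is_cortical)))
  invisible(x)
}

#' Maximal contiguous cortical runs along a profile
#'
#' The run containing station 0 is flagged `entry`, the run containing the
#' final station is flagged `exit` (a single all-cortical run carries both
#' flags); every other run is an interior perforation candidate.
#'
#' @param profile a `probe_profile`.
#' @return data.frame with one row per run: `start`, `end` (0-based station
#'   indices, inclusive), `arc_start_mm`, `arc_end_mm`, `is_entry`, `is_exit`.
#'   Zero rows when no station is cortical.
#' @export
find_cortical_runs <- function(profile) {
  stopifnot(inherits(profile, "probe_profile"))
  cort <- profile$stations$is_cortical
  n <- length(cort)
  if (!any(cort)) {
    return(data.frame(start = integer(0), end = integer(0),
                      arc_start_mm = numeric(0), arc_end_mm = numeric(0),
                      is_entry = logical(0), is_exit = logical(0)))
  }
  r <- rle(cort)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  starts <- starts[keep]; ends <- ends[keep]
  data.frame(
    start = starts - 1L, end = ends - 1L,
    arc_start_mm = profile$stations$arc_mm[starts],
    arc_end_mm = profile$stations$arc_mm[ends],
    is_entry = starts == 1L,
    is_exit = ends == n
  )
}

#' Decide corridor accessibility
#'
#' A corridor is accessible iff it has no interior cortical run and the
#' entry and exit runs are distinct (a single cortical run spanning the
#' whole corridor means the probe never traverses trabecular bone, hence not
#' accessible). Each interior run becomes a perforation event; when a region
#' map is supplied, events get an anatomical region (`ramus` /
#' `acetabulum` / `other`) looked up at the run's arc midpoint, and the
#' excluded corridor is assigned a perforation-site group.
#'
#' @param profile a `probe_profile`.
#' @param regions optional region map from [region_intervals] or
#'   [region_label_volume].
#' @return object of class `accessibility_result`: `accessible`,
#'   `length_mm` (NA when not accessible: excluded from length analysis),
#'   `events` data.frame (`start`, `end`, `arc_start_mm`, `arc_end_mm`,
#'   `region`), `group` (1/2/3 or NA).
#' @export
assess_accessibility <- function(profile, regions = NULL) {
  stopifnot(inherits(profile, "probe_profile"))
  runs <- find_cortical_runs(profile)
  interior <- runs[!runs$is_entry & !runs$is_exit, , drop = FALSE]
  spanning <- any(runs$is_entry & runs$is_exit)
  accessible <- nrow(interior) == 0L && !spanning
  events <- interior[, c("start", "end", "arc_start_mm", "arc_end_mm")]
  if (spanning) {
    # whole-corridor cortical run: record it as a single event so the
    # exclusion is visible downstream
    sp <- runs[runs$is_entry & runs$is_exit, , drop = FALSE]
    events <- rbind(events, sp[, c("start", "end", "arc_start_mm", "arc_end_mm")])
  }
  rownames(events) <- NULL
  events$region <- if (nrow(events) > 0L && !is.null(regions)) {
    mid <- (events$arc_start_mm + events$arc_end_mm) / 2
    lookup_region(regions, mid, profile)
  } else {
    rep("unassigned", nrow(events))
  }
  group <- if (accessible) NA_integer_ else
    tryCatch(classify_perforation_site(events), error = function(e) NA_integer_)
  structure(list(specimen_id = profile$specimen_id, side = profile$side,
                 accessible = accessible,
                 length_mm = if (accessible) profile$length_mm else NA_real_,
                 events = events, group = group),
            class = "accessibility_result")
}

#' @export
print.accessibility_result <- function(x, ...) {
  if (x$accessible) {
    cat(sprintf("<accessibility_result> %s/%s accessible, length %.1f mm\n",
                x$specimen_id, x$side, x$length_mm))
  } else {
    cat(sprintf("<accessibility_result> %s/%s NOT accessible (%d event(s), group %s)\n",
                x$specimen_id, x$side, nrow(x$events),
                ifelse(is.na(x$group), "unclassified", x$group)))
  }
  invisible(x)
}

#' Classify the perforation site of an excluded corridor
#'
#' Group 1: perforation along the superior pubic ramus only; group 2:
#' perforation of the acetabular joint surface only; group 3: both. Events
#' with region `other`/`unassigned` do not contribute.
#'
#' @param events data.frame with a `region` column (from
#'   [assess_accessibility]).
#' @return integer 1, 2 or 3.
#' @export
classify_perforation_site <- function(events) {
  if (is.null(events) || nrow(events) == 0L)
    stop("classify_perforation_site requires at least one perforation event",
         call. = FALSE)
  regs <- unique(events$region)
  known <- intersect(regs, c("ramus", "acetabulum"))
  if (length(known) == 0L)
    stop("no perforation event has a ramus/acetabulum region assignment",
         call. = FALSE)
  has_ramus <- "ramus" %in% known
  has_acet <- "acetabulum" %in% known
  if (has_ramus && has_acet) 3L else if (has_acet) 2L else 1L
}

# ---- region maps ------------------------------------------------------------

#' Region map from arc-length intervals
#'
#' Labels positions along the corridor by arc fraction (0 = entry, 1 = exit)
#' or absolute arc mm. Intervals are `[lo, hi)` except the last, which is
#' closed.
#'
#' @param breaks data.frame with columns `lo`, `hi`, `region`
#'   (`ramus`/`acetabulum`/`other`).
#' @param unit `"fraction"` (of corridor length) or `"mm"`.
#' @return object of class `region_map`.
#' @export
region_intervals <- function(breaks, unit = c("fraction", "mm")) {
  unit <- match.arg(unit)
  stopifnot(all(c("lo", "hi", "region") %in% names(breaks)))
  if (any(breaks$hi <= breaks$lo)) stop("empty region interval", call. = FALSE)
  structure(list(kind = "intervals", breaks = breaks, unit = unit),
            class = "region_map")
}

#' Region map from a label volume
#'
#' Nearest-neighbour lookup of an integer label volume at world positions on
#' the probe axis.
#'
#' @param vol an [hu_volume] whose values are integer labels.
#' @param labels named vector mapping label values to region names, e.g.
#'   `c("1" = "ramus", "2" = "acetabulum")`; unlisted labels map to `other`.
#' @return object of class `region_map`.
#' @export
region_label_volume <- function(vol, labels) {
  stopifnot(inherits(vol, "hu_volume"))
  structure(list(kind = "labels", vol = vol, labels = labels),
            class = "region_map")
}

lookup_region <- function(regions, arc_mm, profile) {
  stopifnot(inherits(regions, "region_map"))
  if (regions$kind == "intervals") {
    pos <- if (regions$unit == "fraction") arc_mm / profile$length_mm else arc_mm
    vapply(pos, function(p) {
      b <- regions$breaks
      hit <- which(p >= b$lo & (p < b$hi | (p <= b$hi & b$hi == max(b$hi))))
      if (length(hit)) as.character(b$region[hit[1]]) else "other"
    }, character(1))
  } else {
    # world position on the straight probe axis, then nearest voxel label
    if (is.null(profile$entry) || is.null(profile$exit))
      stop("label-volume region lookup requires a profile with landmarks",
           call. = FALSE)
    axis <- (profile$exit - profile$entry) / profile$length_mm
    pts <- outer(arc_mm, axis) + rep(profile$entry, each = length(arc_mm))
    idx <- round(world_to_index(regions$vol, pts))
    lab <- vapply(seq_len(nrow(idx)), function(i) {
      ii <- pmin(pmax(idx[i, ], 0), regions$vol$dim - 1L)
      as.character(regions$vol$values[ii[1] + 1L, ii[2] + 1L, ii[3] + 1L])
    }, character(1))
    out <- unname(regions$labels[lab])
    out[is.na(out)] <- "other"
    out
  }
}
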