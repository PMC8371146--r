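# Length-normalized grey-value profiles: every accessible corridor's
# station-wise mean HU sequence is linearly resampled onto a common grid
# spanning [0, 1] of its own length, then averaged pointwise across the
# cohort. The reference grid has round(mean accessible length) + 1 points,
# i.e. 1 mm nominal spacing after normalization to the average screw length.

#' Resample a probe profile onto a fixed-length grid
#'
#' Linear interpolation of the station `mean_hu` sequence onto `n_ref`
#' equally spaced arc positions spanning `[0, length]`. Endpoint values are
#' preserved exactly and interpolated values never leave the original range.
#'
#' @param profile a `probe_profile` with >= 2 stations.
#' @param n_ref number of output samples (>= 2).
#' @param value which per-station summary to resample: `"mean_hu"`
#'   (default, used for cohort profiles), `"center_hu"` or `"max_hu"`.
#' @return object of class `normalized_profile`: `values` (length `n_ref`),
#'   `arc_fraction`, `n_ref`, `specimen_id`, `side`.
#' @export
normalize_profile <- function(profile, n_ref, value = "mean_hu") {
  stopifnot(inherits(profile, "probe_profile"))
  if (nrow(profile$stations) < 2L)
    stop("profile must have >= 2 stations", call. = FALSE)
  if (n_ref < 2L) stop("n_ref must be >= 2", call. = FALSE)
  value <- match.arg(value, c("mean_hu", "center_hu", "max_hu"))
  xout <- seq(0, profile$length_mm, length.out = n_ref)
  y <- stats::approx(profile$stations$arc_mm, profile$stations[[value]],
                     xout = xout, rule = 1)$y
  structure(list(values = y, arc_fraction = seq(0, 1, length.out = n_ref),
                 n_ref = as.integer(n_ref), specimen_id = profile$specimen_id,
                 side = profile$side),
            class = "normalized_profile")
}

#' Cohort mean grey-value profile
#'
#' Normalizes each accessible profile to the cohort's average screw length
#' (grid of `round(mean length) + 1` stations unless overridden) and
#' averages pointwise.
#'
#' @param profiles list of `probe_profile` objects (accessible corridors).
#' @param n_ref optional grid size; default `round(mean length in mm) + 1`.
#' @param value per-station summary to aggregate (see [normalize_profile]).
#' @return list with `mean_hu`, `sd_hu` (pointwise, sample SD), `n_ref`,
#'   `arc_fraction`, `n_profiles`, `mean_length_mm`.
#' @export
aggregate_profiles <- function(profiles, n_ref = NULL, value = "mean_hu") {
  if (length(profiles) == 0L)
    stop("aggregate_profiles requires >= 1 profile", call. = FALSE)
  lens <- vapply(profiles, function(p) p$length_mm, numeric(1))
  if (is.null(n_ref)) n_ref <- as.integer(round(mean(lens)) + 1)
  mat <- vapply(profiles,
                function(p) normalize_profile(p, n_ref, value)$values,
                numeric(n_ref))
  mat <- matrix(mat, nrow = n_ref)
  list(
    mean_hu = rowMeans(mat),
    sd_hu = if (ncol(mat) > 1L) apply(mat, 1L, stats::sd) else rep(NA_real_, n_ref),
    n_ref = as.integer(n_ref),
    arc_fraction = seq(0, 1, length.out = n_ref),
    n_profiles = length(profiles),
    mean_length_mm = mean(lens)
  )
}
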