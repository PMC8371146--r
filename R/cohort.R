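# Synthetic cohort sampling. The stated world mirrors the study cohort:
# corridor lengths are drawn from one truncated normal (mean 131.7 mm,
# SD 10.71 mm, truncated at the observed extremes 104.9 / 161.4 mm)
# identically for both sexes and ethnicities, while the narrowness
# parameters (inner tube radius, arc sagitta) differ by sex so that male
# clearance stochastically dominates female clearance: corridors are less
# often accessible in females although lengths do not differ.

#' Cohort specification
#'
#' Defaults give expected accessibility of ~68% in males and ~55% in
#' females at the 7.5 mm reference probe (clearance = inner radius -
#' sagitta, accessible iff clearance >= 3.75 mm).
#'
#' @param n_specimens number of specimens; each contributes a left and a
#'   right corridor, so `2 * n_specimens` bore probes.
#' @param sex_ratio proportion of male specimens (default 0.54, i.e. 81 of
#'   150).
#' @param ethnicity_ratio proportion labelled `European` (default 2/3); the
#'   label has no effect on any geometric parameter.
#' @param length_dist list `(mean, sd, min, max)` of the truncated-normal
#'   corridor length in mm; drawn per corridor, identical across sexes.
#' @param narrowness list with elements `male` and `female`, each a list
#'   `(inner_radius = c(mean, sd), sagitta = c(mean, sd))` in mm; sagitta
#'   draws are truncated at 0, inner radius at 4.5 mm.
#' @param coarse logical; TRUE (default) uses 1.5 mm isotropic phantom
#'   voxels, FALSE the native 0.7 x 0.7 x 0.6 mm.
#' @param master_seed integer; every random draw (and each phantom's noise
#'   seed) derives deterministically from it.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_specimens = 150L,
                        sex_ratio = 0.54,
                        ethnicity_ratio = 2 / 3,
                        length_dist = list(mean = 131.7, sd = 10.71,
                                           min = 104.9, max = 161.4),
                        narrowness = list(
                          male = list(inner_radius = c(6.0, 0.5),
                                      sagitta = c(1.88, 0.6)),
                          female = list(inner_radius = c(5.8, 0.5),
                                        sagitta = c(1.95, 0.6))),
                        coarse = TRUE,
                        master_seed = 20210817L) {
  if (n_specimens < 1L) stop("n_specimens must be >= 1", call. = FALSE)
  if (length_dist$min >= length_dist$max)
    stop("length truncation bounds must be ordered", call. = FALSE)
  ok <- function(x) all(is.finite(unlist(x)))
  if (!ok(length_dist) || !ok(narrowness))
    stop("distribution parameters must be finite", call. = FALSE)
  if (length_dist$sd <= 0) stop("length sd must be > 0", call. = FALSE)
  structure(list(n_specimens = as.integer(n_specimens), sex_ratio = sex_ratio,
                 ethnicity_ratio = ethnicity_ratio, length_dist = length_dist,
                 narrowness = narrowness, coarse = coarse,
                 master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

# inverse-CDF sampling of a truncated normal (exact, vectorized)
rtruncnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  pa <- stats::pnorm(lo, mean, sd)
  pb <- stats::pnorm(hi, mean, sd)
  stats::qnorm(pa + stats::runif(n) * (pb - pa), mean, sd)
}

#' Draw a synthetic cohort of phantom specifications
#'
#' Reproducible given `master_seed`: per-phantom noise seeds are derived
#' deterministically and the caller's RNG state is restored on exit.
#'
#' @param cohort a [cohort_spec].
#' @return data.frame with one row per corridor (`2 * n_specimens` rows):
#'   covariates `specimen_id`, `side`, `sex`, `ethnicity`, the drawn
#'   geometric parameters, and a list-column `spec` of [phantom_spec]
#'   objects.
#' @export
sample_cohort <- function(cohort) {
  stopifnot(inherits(cohort, "cohort_spec"))
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  }, add = TRUE)
  set.seed(cohort$master_seed)
  ns <- cohort$n_specimens
  sex <- ifelse(stats::runif(ns) < cohort$sex_ratio, "male", "female")
  eth <- ifelse(stats::runif(ns) < cohort$ethnicity_ratio, "European", "Japanese")
  n <- 2L * ns
  row_sex <- rep(sex, each = 2L)
  ld <- cohort$length_dist
  lengths <- rtruncnorm(n, ld$mean, ld$sd, ld$min, ld$max)
  inner <- numeric(n); sag <- numeric(n)
  for (s in c("male", "female")) {
    pick <- row_sex == s
    nd <- cohort$narrowness[[s]]
    inner[pick] <- rtruncnorm(sum(pick), nd$inner_radius[1], nd$inner_radius[2],
                              lo = 4.5)
    sag[pick] <- rtruncnorm(sum(pick), nd$sagitta[1], nd$sagitta[2], lo = 0)
  }
  noise_seeds <- (as.double(cohort$master_seed) %% 1e6) * 1000 +
    seq_len(n) * 7 + 3
  noise_seeds <- as.integer(noise_seeds %% 2^31)
  spacing <- if (cohort$coarse) c(1.5, 1.5, 1.5) else c(0.7, 0.7, 0.6)
  specs <- lapply(seq_len(n), function(i) {
    phantom_spec(chord_length_mm = lengths[i], sagitta_mm = sag[i],
                 inner_radius_mm = inner[i], spacing_mm = spacing,
                 noise_seed = noise_seeds[i])
  })
  out <- data.frame(
    specimen_id = sprintf("S%04d", rep(seq_len(ns), each = 2L)),
    side = rep(c("left", "right"), times = ns),
    sex = row_sex,
    ethnicity = rep(eth, each = 2L),
    chord_length_mm = lengths,
    inner_radius_mm = inner,
    sagitta_mm = sag,
    clearance_mm = inner - sag,
    stringsAsFactors = FALSE
  )
  out$spec <- specs
  out
}
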