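# Parametric arc-tube bone phantom: a curved tubular "superior pubic ramus"
# analogue with a cortical shell (> 400 HU), low-HU trabecular interior, an
# intermediate-HU periacetabular zone, a dense exit cortex (lateral-ilium
# analogue) and optional acetabular wall cap. The medullary centerline is a
# circular arc; corridor narrowness is controlled by the inner tube radius
# and the arc sagitta, so accessibility of the straight chord probe has the
# closed form: accessible iff inner_radius - sagitta >= probe radius.
#
# Geometry (phantom frame): the entry landmark is at the origin, the exit at
# (chord_length, 0, 0). The centerline arc spans between points inset from
# the landmarks by inner_radius + cortex_thickness/2 along the chord, so
# both landmarks sit mid-cortex in the hemispherical end caps: the probe's
# first and last stations are cortical (the permitted entry/exit crossings)
# and the landmark separation equals the nominal corridor length exactly.

#' Default phantom HU levels
#'
#' Mean/SD pairs per tissue. Means straddle the 400 HU cortical rule
#' unambiguously and reproduce the canonical corridor profile ordering:
#' entry cortex > periacetabular trabecular > ramus trabecular, exit cortex
#' maximal. SDs are kept small enough relative to the distance from 400
#' that voxel noise alone essentially never flips a tissue across the
#' cortical rule (the perforation detector takes a max over thousands of
#' interpolated samples, so a tissue within ~3 SD of 400 would perforate
#' every corridor).
#'
#' @param noise_sd_scale multiply all SDs (0 = noise-free tissue classes).
#' @return named list of `c(mean, sd)` pairs.
#' @export
default_hu_levels <- function(noise_sd_scale = 1) {
  lapply(list(
    background = c(40, 15),
    trabecular_ramus = c(150, 30),
    trabecular_periacetabular = c(350, 15),
    cortex = c(800, 80),
    exit_cortex = c(1100, 100)
  ), function(x) c(x[1], x[2] * noise_sd_scale))
}

#' Phantom specification
#'
#' @param chord_length_mm corridor length (landmark separation), mm.
#' @param sagitta_mm maximum deviation of the centerline arc from its chord
#'   (>= 0; 0 gives a straight tube).
#' @param inner_radius_mm medullary tube radius, mm (> 0).
#' @param waist_mm optional mid-corridor narrowing: the inner radius shrinks
#'   smoothly to `inner_radius_mm - waist_mm` at mid-corridor (default 0).
#' @param cortex_thickness_mm cortical shell thickness, mm.
#' @param hu_levels named list of `c(mean, sd)` per tissue (see
#'   [default_hu_levels]); cortex mean must exceed 400, trabecular means
#'   must stay below 400.
#' @param periacetabular_span arc-fraction interval of the intermediate-HU
#'   trabecular zone, default `c(0.6, 0.9)`.
#' @param exit_cortex_frac arc fraction beyond which the cortical shell gets
#'   the dense exit (lateral ilium) HU level, default 0.9.
#' @param acetabular_wall optional list `(frac, offset_mm, radius_mm)`: a
#'   solid cortical spherical cap centered at arc fraction `frac`, displaced
#'   by `offset_mm` toward the chord (-y). Small offsets intrude into the
#'   corridor and produce acetabulum-region perforations.
#' @param spacing_mm voxel size triple, default `c(0.7, 0.7, 0.6)` (native
#'   CT resolution); use `c(1.5, 1.5, 1.5)` for a fast coarse mode.
#' @param margin_mm padding of the voxel grid around the bone, default 6.
#' @param noise_seed integer seed for the per-voxel Gaussian HU noise.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(chord_length_mm = 131.7, sagitta_mm = 1.5,
                         inner_radius_mm = 6, waist_mm = 0,
                         cortex_thickness_mm = 2.5,
                         hu_levels = default_hu_levels(),
                         periacetabular_span = c(0.6, 0.9),
                         exit_cortex_frac = 0.9,
                         acetabular_wall = NULL,
                         spacing_mm = c(0.7, 0.7, 0.6),
                         margin_mm = 6, noise_seed = 1L) {
  if (sagitta_mm < 0) stop("sagitta_mm must be >= 0", call. = FALSE)
  if (inner_radius_mm <= 0) stop("inner_radius_mm must be > 0", call. = FALSE)
  if (waist_mm < 0 || waist_mm >= inner_radius_mm)
    stop("waist_mm must be in [0, inner_radius_mm)", call. = FALSE)
  if (cortex_thickness_mm <= 0) stop("cortex_thickness_mm must be > 0", call. = FALSE)
  if (hu_levels$cortex[1] <= 400 || hu_levels$exit_cortex[1] <= 400)
    stop("invalid spec: cortical HU means must exceed 400", call. = FALSE)
  if (hu_levels$trabecular_ramus[1] >= 400 ||
      hu_levels$trabecular_periacetabular[1] >= 400)
    stop("invalid spec: trabecular HU means must stay below 400", call. = FALSE)
  cap <- inner_radius_mm + cortex_thickness_mm / 2
  if (chord_length_mm <= 2 * cap + 1)
    stop("chord too short for the end caps", call. = FALSE)
  structure(list(
    chord_length_mm = chord_length_mm, sagitta_mm = sagitta_mm,
    inner_radius_mm = inner_radius_mm, waist_mm = waist_mm,
    cortex_thickness_mm = cortex_thickness_mm, hu_levels = hu_levels,
    periacetabular_span = periacetabular_span,
    exit_cortex_frac = exit_cortex_frac, acetabular_wall = acetabular_wall,
    spacing_mm = spacing_mm, margin_mm = margin_mm,
    noise_seed = as.integer(noise_seed)
  ), class = "phantom_spec")
}

# arc geometry helpers -------------------------------------------------------

phantom_cap_inset <- function(spec)
  spec$inner_radius_mm + spec$cortex_thickness_mm / 2

# centerline arc endpoints (inset along the chord) and circle parameters
phantom_arc <- function(spec) {
  cl <- phantom_cap_inset(spec)
  x0 <- cl
  x1 <- spec$chord_length_mm - cl
  L <- x1 - x0
  h <- spec$sagitta_mm
  if (h < 1e-9) {
    return(list(straight = TRUE, x0 = x0, x1 = x1, L = L))
  }
  R <- (h^2 + (L / 2)^2) / (2 * h)
  C <- c((x0 + x1) / 2, h - R)
  th0 <- atan2(R - h, -(L / 2))  # angle of entry endpoint (> pi/2)
  th1 <- atan2(R - h, (L / 2))   # angle of exit endpoint (< pi/2)
  list(straight = FALSE, x0 = x0, x1 = x1, L = L, R = R, C = C,
       th0 = th0, th1 = th1)
}

# arc point (x, y) at fraction f in [0, 1]
phantom_arc_point <- function(spec, f) {
  a <- phantom_arc(spec)
  if (a$straight) return(cbind(a$x0 + f * a$L, 0))
  th <- a$th0 + f * (a$th1 - a$th0)
  cbind(a$C[1] + a$R * cos(th), a$C[2] + a$R * sin(th))
}

# local inner radius at arc fraction f (waist profile, mid-corridor minimum)
phantom_inner_radius <- function(spec, f) {
  spec$inner_radius_mm - spec$waist_mm * sin(pi * f)^2
}

# clamped distance to the centerline arc and the arc fraction of the nearest
# point, for a matrix of (x, y, z) phantom-frame points
phantom_arc_distance <- function(spec, pts) {
  a <- phantom_arc(spec)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  if (a$straight) {
    t <- pmin(pmax(x, a$x0), a$x1)
    d <- sqrt((x - t)^2 + y^2 + z^2)
    f <- (t - a$x0) / a$L
    return(list(dist = d, frac = f))
  }
  qx <- x - a$C[1]; qy <- y - a$C[2]
  rho <- sqrt(qx^2 + qy^2)
  phi <- atan2(qy, qx)
  inspan <- phi <= a$th0 & phi >= a$th1
  d_arc <- sqrt((rho - a$R)^2 + z^2)
  p0 <- c(a$x0, 0); p1 <- c(a$x1, 0)
  d0 <- sqrt((x - p0[1])^2 + (y - p0[2])^2 + z^2)
  d1 <- sqrt((x - p1[1])^2 + (y - p1[2])^2 + z^2)
  d <- ifelse(inspan, d_arc, pmin(d0, d1))
  f <- ifelse(inspan, (a$th0 - phi) / (a$th0 - a$th1), ifelse(d0 <= d1, 0, 1))
  list(dist = d, frac = pmin(pmax(f, 0), 1))
}

#' Analytic ground truth for a phantom
#'
#' Computed from the spec alone, before any voxelization. The minimum
#' clearance is the smallest distance from the straight landmark-to-landmark
#' probe axis to the inner cortical wall, minimized over the corridor
#' (closed form `inner_radius - sagitta` for a constant-radius tube),
#' further reduced by an intruding acetabular wall cap if present.
#'
#' @param spec a [phantom_spec].
#' @param probe_radius_mm reference probe radius, default 3.75 (7.5 mm bore).
#' @return list with `accessible_expected`, `min_clearance_mm`, `length_mm`,
#'   `region_intervals` (a [region_intervals] map: ramus before the
#'   periacetabular span, acetabulum from there on).
#' @export
phantom_ground_truth <- function(spec, probe_radius_mm = 3.75) {
  f <- seq(0, 1, length.out = 513L)
  arc <- phantom_arc_point(spec, f)
  dev <- abs(arc[, 2])                       # probe axis is the line y = 0
  clearance <- min(phantom_inner_radius(spec, f) - dev)
  if (!is.null(spec$acetabular_wall)) {
    w <- spec$acetabular_wall
    ctr <- phantom_arc_point(spec, w$frac)
    wall_center_y <- ctr[1, 2] - w$offset_mm
    # distance from the x-axis (probe axis) to the wall sphere surface
    d_axis <- abs(wall_center_y)
    clearance <- min(clearance, d_axis - w$radius_mm)
  }
  boundary <- spec$periacetabular_span[1]
  list(
    accessible_expected = clearance >= probe_radius_mm,
    min_clearance_mm = clearance,
    length_mm = spec$chord_length_mm,
    region_intervals = region_intervals(
      data.frame(lo = c(0, boundary), hi = c(boundary, 1),
                 region = c("ramus", "acetabulum")),
      unit = "fraction")
  )
}

#' Landmarks for a phantom without voxelizing it
#'
#' @param spec a [phantom_spec].
#' @param specimen_id,side passed to [landmark_pair].
#' @return a [landmark_pair]: entry at the origin, exit at
#'   `(chord_length_mm, 0, 0)`, separation exactly `chord_length_mm`.
#' @export
phantom_landmarks <- function(spec, specimen_id = "phantom", side = "left") {
  landmark_pair(c(0, 0, 0), c(spec$chord_length_mm, 0, 0),
                specimen_id = specimen_id, side = side)
}

#' Voxelize a phantom
#'
#' Assigns every voxel a tissue by signed distance to the centerline arc
#' (trabecular interior, cortical shell, hemispherical end caps, optional
#' acetabular wall cap, background), then adds Gaussian HU noise per tissue
#' using `noise_seed`. The global RNG state is preserved.
#'
#' @param spec a [phantom_spec].
#' @param specimen_id,side identifiers for the landmarks.
#' @return list with `volume` ([hu_volume]), `landmarks` ([landmark_pair]),
#'   `regions` (a [region_intervals] map) and `truth`
#'   ([phantom_ground_truth]).
#' @export
make_phantom <- function(spec, specimen_id = "phantom", side = "left") {
  stopifnot(inherits(spec, "phantom_spec"))
  truth <- phantom_ground_truth(spec)
  sp <- spec$spacing_mm
  outer_r <- spec$inner_radius_mm + spec$cortex_thickness_mm
  m <- spec$margin_mm
  ylo <- -(outer_r + m)
  if (!is.null(spec$acetabular_wall)) {
    w <- spec$acetabular_wall
    ctr <- phantom_arc_point(spec, w$frac)
    ylo <- min(ylo, ctr[1, 2] - w$offset_mm - w$radius_mm - m)
  }
  bounds <- list(
    x = c(-m, spec$chord_length_mm + m),
    y = c(ylo, spec$sagitta_mm + outer_r + m),
    z = c(-(outer_r + m), outer_r + m)
  )
  nx <- ceiling(diff(bounds$x) / sp[1]) + 1L
  ny <- ceiling(diff(bounds$y) / sp[2]) + 1L
  nz <- ceiling(diff(bounds$z) / sp[3]) + 1L
  xs <- bounds$x[1] + (seq_len(nx) - 1L) * sp[1]
  ys <- bounds$y[1] + (seq_len(ny) - 1L) * sp[2]
  zs <- bounds$z[1] + (seq_len(nz) - 1L) * sp[3]
  pts <- cbind(rep(xs, times = ny * nz),
               rep(rep(ys, each = nx), times = nz),
               rep(zs, each = nx * ny))
  ad <- phantom_arc_distance(spec, pts)
  rloc <- phantom_inner_radius(spec, ad$frac)
  tissue <- rep("background", nrow(pts))
  inside <- ad$dist <= rloc
  peri <- ad$frac >= spec$periacetabular_span[1] &
          ad$frac <= spec$periacetabular_span[2]
  tissue[inside & !peri] <- "trabecular_ramus"
  tissue[inside & peri] <- "trabecular_periacetabular"
  shell <- !inside & ad$dist <= rloc + spec$cortex_thickness_mm
  tissue[shell & ad$frac < spec$exit_cortex_frac] <- "cortex"
  tissue[shell & ad$frac >= spec$exit_cortex_frac] <- "exit_cortex"
  if (!is.null(spec$acetabular_wall)) {
    w <- spec$acetabular_wall
    ctr <- phantom_arc_point(spec, w$frac)
    cc <- c(ctr[1, 1], ctr[1, 2] - w$offset_mm, 0)
    dw <- sqrt((pts[, 1] - cc[1])^2 + (pts[, 2] - cc[2])^2 + (pts[, 3] - cc[3])^2)
    tissue[dw <= w$radius_mm] <- "cortex"
  }
  lev <- spec$hu_levels
  mu <- vapply(lev, `[`, numeric(1), 1L)
  sd <- vapply(lev, `[`, numeric(1), 2L)
  vals <- mu[tissue]
  if (any(sd > 0)) {
    old_seed <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
    }, add = TRUE)
    set.seed(spec$noise_seed)
    vals <- vals + stats::rnorm(length(vals)) * sd[tissue]
  }
  affine <- rbind(cbind(diag(sp), c(bounds$x[1], bounds$y[1], bounds$z[1])),
                  c(0, 0, 0, 1))
  vol <- hu_volume(array(vals, dim = c(nx, ny, nz)), affine)
  lm <- phantom_landmarks(spec, specimen_id, side)
  list(volume = vol, landmarks = lm, regions = truth$region_intervals,
       truth = truth)
}
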