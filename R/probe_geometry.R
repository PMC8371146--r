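# Probe geometry: stations along the corridor axis and circular cross-section
# sample points. All coordinates are world mm; nothing here assumes
# axis-aligned anatomy.

#' Station positions along the corridor axis
#'
#' Stations are placed at distances 0, step, 2*step, ... along the straight
#' entry-to-exit segment. The exit point is always appended as the final
#' station even when the last interval is shorter than `step_mm`, so the
#' full corridor length is covered.
#'
#' @param lm a [landmark_pair].
#' @param step_mm station spacing in mm (> 0), default 1.
#' @return list with `points` (matrix, one station per row, world mm),
#'   `arc_mm` (distance of each station from the entry), `axis` (unit
#'   direction vector) and `length_mm` (Euclidean entry-exit distance).
#' @export
probe_stations <- function(lm, step_mm = 1) {
  stopifnot(inherits(lm, "landmark_pair"))
  if (!is.finite(step_mm) || step_mm <= 0)
    stop("step_mm must be > 0", call. = FALSE)
  delta <- lm$exit - lm$entry
  len <- sqrt(sum(delta^2))
  if (len <= 0) stop("degenerate corridor: entry equals exit", call. = FALSE)
  axis <- delta / len
  arc <- seq(0, len, by = step_mm)
  if (arc[length(arc)] < len) arc <- c(arc, len)
  pts <- outer(arc, axis) + rep(lm$entry, each = length(arc))
  list(points = pts, arc_mm = arc, axis = axis, length_mm = len)
}

#' Sample points on the probe's circular cross-section
#'
#' Returns the center plus `n_rings` concentric rings of `n_angles` points
#' each in the plane orthogonal to `axis`; the outermost ring lies exactly
#' at `radius_mm`. Point count is `1 + n_rings * n_angles` (just the center
#' when `radius_mm` is 0).
#'
#' @param center world point (length-3, mm).
#' @param axis direction vector (need not be unit length, must be nonzero).
#' @param radius_mm disc radius in mm (>= 0).
#' @param n_rings number of concentric rings (default 2: radii r/2 and r).
#' @param n_angles points per ring (default 16; >= 4 when radius > 0).
#' @return matrix of world points, one per row; first row is the center.
#' @export
disc_samples <- function(center, axis, radius_mm, n_rings = 2L, n_angles = 16L) {
  nrm <- sqrt(sum(axis^2))
  if (!is.finite(nrm) || nrm == 0)
    stop("axis vector must be nonzero", call. = FALSE)
  if (radius_mm < 0) stop("radius_mm must be >= 0", call. = FALSE)
  if (radius_mm == 0) return(matrix(center, nrow = 1L))
  if (n_angles < 4L) stop("n_angles must be >= 4 for a positive radius", call. = FALSE)
  a <- axis / nrm
  # orthonormal in-plane basis, stable for any axis orientation
  ref <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- ref - sum(ref * a) * a
  u <- u / sqrt(sum(u^2))
  v <- c(a[2] * u[3] - a[3] * u[2],
         a[3] * u[1] - a[1] * u[3],
         a[1] * u[2] - a[2] * u[1])
  radii <- radius_mm * seq_len(n_rings) / n_rings
  theta <- 2 * pi * (seq_len(n_angles) - 1L) / n_angles
  offs <- do.call(rbind, lapply(radii, function(r) {
    outer(r * cos(theta), u) + outer(r * sin(theta), v)
  }))
  rbind(matrix(center, nrow = 1L),
        offs + rep(center, each = nrow(offs)))
}
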