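#' HU volume container
#'
#' An `hu_volume` holds a 3D scalar grid of CT grey values in Hounsfield
#' units together with a 4x4 index-to-world affine (world units mm,
#' 0-based voxel indices, column vectors). Voxel spacing is derived from
#' the affine column norms.
#'
#' @param values numeric 3D array of HU values (x fastest, NIfTI order).
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices
#'   `(i, j, k, 1)` to world coordinates in mm.
#' @return An object of class `hu_volume` with fields `values`, `affine`,
#'   `spacing` (per-axis voxel size in mm) and `dim`.
#' @export
hu_volume <- function(values, affine) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("values must be a 3D array", call. = FALSE)
  if (any(dim(values) < 2L))
    stop("volume must have >= 2 voxels per axis", call. = FALSE)
  affine <- as.matrix(affine)
  if (!identical(dim(affine), c(4L, 4L)) || any(!is.finite(affine)))
    stop("affine must be a finite 4x4 matrix", call. = FALSE)
  det3 <- det(affine[1:3, 1:3])
  if (!is.finite(det3) || abs(det3) < .Machine$double.eps * 100)
    stop("affine is not invertible", call. = FALSE)
  dimnames(affine) <- NULL
  spacing <- unname(sqrt(colSums(affine[1:3, 1:3]^2)))
  if (any(spacing <= 0)) stop("voxel spacing must be positive", call. = FALSE)
  structure(
    list(values = values, affine = affine, spacing = spacing,
         dim = dim(values)),
    class = "hu_volume"
  )
}

#' @export
print.hu_volume <- function(x, ...) {
  cat("<hu_volume> ", paste(x$dim, collapse = " x "),
      " voxels, spacing ", paste(signif(x$spacing, 4), collapse = " x "),
      " mm\n", sep = "")
  cat("  HU range [", signif(min(x$values), 5), ", ",
      signif(max(x$values), 5), "]\n", sep = "")
  invisible(x)
}

#' World point constructor
#'
#' @param x,y,z world coordinates in mm (finite scalars).
#' @return numeric length-3 vector named c("x","y","z").
#' @export
world_point <- function(x, y, z) {
  p <- c(x = as.numeric(x), y = as.numeric(y), z = as.numeric(z))
  if (any(!is.finite(p))) stop("world point must be finite", call. = FALSE)
  p
}

#' Convert world coordinates to (0-based) voxel index coordinates
#'
#' @param vol an [hu_volume].
#' @param pts numeric matrix, one world point per row (x, y, z in mm), or a
#'   single length-3 vector.
#' @return matrix of continuous 0-based index coordinates, one row per point.
#' @export
world_to_index <- function(vol, pts) {
  pts <- as_point_matrix(pts)
  inv <- solve(vol$affine)
  idx <- cbind(pts, 1) %*% t(inv)
  idx[, 1:3, drop = FALSE]
}

#' Convert (0-based) voxel index coordinates to world mm
#'
#' @inheritParams world_to_index
#' @param idx matrix of continuous 0-based index coordinates (one per row).
#' @return matrix of world coordinates in mm.
#' @export
index_to_world <- function(vol, idx) {
  idx <- as_point_matrix(idx)
  w <- cbind(idx, 1) %*% t(vol$affine)
  w[, 1:3, drop = FALSE]
}

as_point_matrix <- function(pts) {
  if (is.null(dim(pts))) {
    if (length(pts) != 3L) stop("point must have 3 components", call. = FALSE)
    pts <- matrix(as.numeric(pts), nrow = 1L)
  } else {
    pts <- as.matrix(pts)
    storage.mode(pts) <- "double"
    if (ncol(pts) != 3L) stop("points must have 3 columns", call. = FALSE)
  }
  pts
}

#' Trilinear HU interpolation at world points
#'
#' Samples the volume at arbitrary world-mm positions by trilinear
#' interpolation of the 8 surrounding voxels. Exact voxel-center queries
#' return the stored value. Points outside the index bounding box are an
#' error, never an extrapolation: a probe leaving the scanned volume
#' indicates bad landmarks.
#'
#' @param vol an [hu_volume].
#' @param pts world points, one per row (or a single length-3 vector).
#' @return numeric vector of interpolated HU values, one per point.
#' @export
interpolate_hu <- function(vol, pts) {
  idx <- world_to_index(vol, pts)
  d <- vol$dim
  eps <- 1e-9
  lo <- -eps
  hi <- d - 1 + eps
  bad <- idx[, 1] < lo | idx[, 1] > hi[1] |
         idx[, 2] < lo | idx[, 2] > hi[2] |
         idx[, 3] < lo | idx[, 3] > hi[3]
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "sample point outside volume (index coords %.3f, %.3f, %.3f; grid %d x %d x %d)",
      idx[i, 1], idx[i, 2], idx[i, 3], d[1], d[2], d[3]), call. = FALSE)
  }
  # clamp so that floor() of an exact boundary stays in range
  i0 <- pmin(pmax(floor(idx[, 1]), 0), d[1] - 2)
  j0 <- pmin(pmax(floor(idx[, 2]), 0), d[2] - 2)
  k0 <- pmin(pmax(floor(idx[, 3]), 0), d[3] - 2)
  fx <- idx[, 1] - i0
  fy <- idx[, 2] - j0
  fz <- idx[, 3] - k0
  v <- vol$values
  nx <- d[1]; nxy <- d[1] * d[2]
  base <- 1 + i0 + j0 * nx + k0 * nxy
  c000 <- v[base]
  c100 <- v[base + 1]
  c010 <- v[base + nx]
  c110 <- v[base + nx + 1]
  c001 <- v[base + nxy]
  c101 <- v[base + nxy + 1]
  c011 <- v[base + nxy + nx]
  c111 <- v[base + nxy + nx + 1]
  gx <- 1 - fx; gy <- 1 - fy; gz <- 1 - fz
  gz * (gy * (gx * c000 + fx * c100) + fy * (gx * c010 + fx * c110)) +
  fz * (gy * (gx * c001 + fx * c101) + fy * (gx * c011 + fx * c111))
}
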