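# Independent oracles, deliberately written from first principles and kept
# separate from the package's own code paths.

# Brute-force trilinear interpolation from the 8-corner formula, one point
# at a time, in index space.
oracle_trilinear <- function(values, idx) {
  i <- floor(idx[1]); j <- floor(idx[2]); k <- floor(idx[3])
  d <- dim(values)
  i <- min(max(i, 0), d[1] - 2); j <- min(max(j, 0), d[2] - 2)
  k <- min(max(k, 0), d[3] - 2)
  fx <- idx[1] - i; fy <- idx[2] - j; fz <- idx[3] - k
  acc <- 0
  for (di in 0:1) for (dj in 0:1) for (dk in 0:1) {
    w <- (if (di) fx else 1 - fx) * (if (dj) fy else 1 - fy) *
         (if (dk) fz else 1 - fz)
    acc <- acc + w * values[i + di + 1, j + dj + 1, k + dk + 1]
  }
  acc
}

# Brute-force accessibility oracle: every voxel whose center lies inside the
# probe cylinder is tested against the threshold, then the same 1 mm station
# run rule (entry/exit crossings exempt) is applied. A station counts as
# cortical when a > threshold voxel center lies within its axial window;
# the window is half the larger of the station step and the voxel pitch
# along the axis, so no station can fall between voxel planes and split a
# contiguous crossing artificially.
oracle_accessibility <- function(vol, lm, diameter = 7.5, step = 1,
                                 threshold = 400) {
  d <- vol$dim
  idx <- as.matrix(expand.grid(i = 0:(d[1] - 1), j = 0:(d[2] - 1),
                               k = 0:(d[3] - 1)))
  w <- cbind(idx, 1) %*% t(vol$affine)
  ctr <- w[, 1:3, drop = FALSE]
  a <- lm$entry; b <- lm$exit
  ax <- b - a; L <- sqrt(sum(ax^2)); ax <- ax / L
  rel <- sweep(ctr, 2, a)
  t_ <- rel %*% ax
  rad2 <- rowSums(rel^2) - t_^2
  inside <- t_ >= 0 & t_ <= L & rad2 <= (diameter / 2)^2
  hu <- as.vector(vol$values)
  cort_t <- t_[inside & hu > threshold]
  stations <- seq(0, L, by = step)
  if (stations[length(stations)] < L) stations <- c(stations, L)
  if (length(cort_t) == 0L) return(list(accessible = TRUE, n_interior = 0L))
  pitch <- max(abs(vol$affine[1:3, 1:3] %*% matrix(ax)))  # voxel pitch along axis
  win <- max(step, pitch) / 2 + 1e-9
  cortical <- vapply(stations, function(s) any(abs(cort_t - s) <= win),
                     logical(1))
  # voxel centers cannot resolve gaps below the voxel scale: close runs of
  # non-cortical stations shorter than one voxel diagonal
  diag_mm <- sqrt(sum(vol$spacing^2))
  g <- rle(cortical)
  if (length(g$lengths) > 2L) {
    cum <- cumsum(g$lengths)
    for (j in seq_along(g$values)) {
      if (!g$values[j] && j > 1L && j < length(g$values) &&
          g$lengths[j] * step <= diag_mm) {
        cortical[(cum[j] - g$lengths[j] + 1L):cum[j]] <- TRUE
      }
    }
  }
  r <- rle(cortical)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1
  runs <- cbind(starts, ends)[r$values, , drop = FALSE]
  if (nrow(runs) == 0L) return(list(accessible = TRUE, n_interior = 0L))
  # voxel-scale-tolerant entry/exit flags: a run starting (ending) within one
  # voxel diagonal of the corridor end is the entry (exit) crossing
  is_entry <- stations[runs[, 1]] <= diag_mm
  is_exit <- stations[runs[, 2]] >= L - diag_mm
  interior <- sum(!is_entry & !is_exit)
  spanning <- any(is_entry & is_exit)
  list(accessible = interior == 0L && !spanning, n_interior = interior)
}

# Full enumeration of the Mann-Whitney U permutation null, returning the
# two-sided p as twice the smaller tail (capped at 1).
oracle_mwu_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(n1 + n2, n1)
  u_all <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(u_all <= u_obs), mean(u_all >= u_obs)))
}

# Monte-Carlo permutation p for larger samples.
oracle_mwu_perm <- function(a, b, nperm = 1e4, seed = 1) {
  set.seed(seed)
  n1 <- length(a)
  pooled <- c(a, b)
  r <- rank(pooled)
  mu <- n1 * length(b) / 2
  u_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  dev_obs <- abs(u_obs - mu)
  hits <- replicate(nperm, {
    ix <- sample(length(pooled), n1)
    abs(sum(r[ix]) - n1 * (n1 + 1) / 2 - mu) >= dev_obs - 1e-9
  })
  mean(hits)
}

# Spreadsheet-style chi-square: explicit double loop over cells.
oracle_chisq <- function(O) {
  O <- as.matrix(O)
  n <- sum(O)
  stat <- 0
  for (i in seq_len(nrow(O))) for (j in seq_len(ncol(O))) {
    e <- sum(O[i, ]) * sum(O[, j]) / n
    stat <- stat + (O[i, j] - e)^2 / e
  }
  stat
}

# Small test volumes -----------------------------------------------------

const_volume <- function(value = 0, n = 24, spacing = c(1, 1, 1),
                         origin = c(0, 0, 0)) {
  aff <- rbind(cbind(diag(spacing), origin), c(0, 0, 0, 1))
  hu_volume(array(value, dim = rep(n, 3)), aff)
}

# a probe_profile built directly from a cortical flag pattern, for run-rule
# tests that need no volume
profile_from_pattern <- function(cortical, step = 1) {
  n <- length(cortical)
  arc <- (seq_len(n) - 1) * step
  stations <- data.frame(index = seq_len(n) - 1L, arc_mm = arc,
                         center_hu = ifelse(cortical, 800, 100),
                         mean_hu = ifelse(cortical, 800, 100),
                         max_hu = ifelse(cortical, 800, 100),
                         is_cortical = cortical)
  structure(list(specimen_id = "pat", side = "left", stations = stations,
                 length_mm = arc[n], entry = c(0, 0, 0),
                 exit = c(arc[n], 0, 0), config = analysis_config()),
            class = "probe_profile")
}
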